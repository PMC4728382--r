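#' Tidy a set of test results
#'
#' @param x an `rv_result` from [rv_test()].
#' @param ... unused.
#' @return A plain tibble, one row per test.
#' @method tidy rv_result
#' @export
tidy.rv_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rv_result")
  out
}

#' One-line summary of a set of test results
#'
#' @param x an `rv_result` from [rv_test()].
#' @param ... unused.
#' @return A one-row tibble: number of tests, smallest p-value and which
#'   test attained it, permutations used.
#' @method glance rv_result
#' @export
glance.rv_result <- function(x, ...) {
  i <- which.min(x$p_value)
  tibble::tibble(
    n_tests = nrow(x),
    min_p_value = x$p_value[i],
    best_test = x$test[i],
    b = x$b[i]
  )
}

#' Tidy an experiment result
#'
#' @param x an `rv_experiment`.
#' @param ... unused.
#' @return A plain tibble of per-(test, alpha) rejection rates.
#' @method tidy rv_experiment
#' @export
tidy.rv_experiment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rv_experiment")
  attr(out, "pvalues") <- NULL
  attr(out, "config") <- NULL
  attr(out, "designs") <- NULL
  out
}

#' One-line summary of an experiment
#'
#' @param x an `rv_experiment`.
#' @param ... unused.
#' @return A one-row tibble with the experiment scale and extreme rates.
#' @method glance rv_experiment
#' @export
glance.rv_experiment <- function(x, ...) {
  tibble::tibble(
    n_settings = nrow(x),
    reps = max(x$reps),
    B = max(x$B),
    min_rate = min(x$rate),
    max_rate = max(x$rate)
  )
}

#' Plot rejection rates of an experiment
#'
#' Type-I error experiments are drawn as per-test bars against the nominal
#' level (dashed line) with 3-SE Monte-Carlo error bars; power experiments
#' the same without the nominal reference being meaningful as a target.
#' Facets split nominal levels and, when the result stacks a grid, the
#' (tail, n) cells.
#'
#' @param object an `rv_experiment`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rv_experiment
#' @export
autoplot.rv_experiment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$rate - 3 * .data$mc_se),
                   ymax = .data$rate + 3 * .data$mc_se),
      width = 0.2
    ) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "rejection rate") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  facets <- c("alpha", intersect(c("tail", "n"),
                                 names(df)[vapply(df, function(v)
                                   length(unique(v)) > 1, logical(1))]))
  gg + ggplot2::facet_wrap(facets, labeller = ggplot2::label_both)
}

#' Power curves across sample sizes
#'
#' Line plot of power against sample size, one line per test, faceted by
#' tail fraction, in the style of the usual power-comparison figures.
#'
#' @param results a stacked `rv_experiment` (or tibble) of power runs over
#'   several `n`.
#' @return A ggplot object.
#' @export
plot_power_curves <- function(results) {
  df <- tibble::as_tibble(results)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$rate,
                                   colour = .data$test,
                                   group = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~tail, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size n", y = "power", colour = NULL) +
    ggplot2::theme_bw()
}
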