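#' Burden score statistic, linear model
#'
#' Score test of the common effect of the collapsed rare-variant burden on a
#' continuous trait: the square of the centered cross-product,
#' `[sum_i C_i (Y_i - Ybar)]^2 / sigma2`, where `sigma2` is the sample
#' variance of `Y` (denominator `n - 1`). The statistic is direction-free
#' (squared) and invariant to adding a constant to `Y`.
#'
#' @param burden integer vector of per-individual burden counts `C_i`.
#' @param phenotype continuous trait vector (or `rv_phenotype`).
#' @return The observed statistic (a single nonnegative number).
#' @export
#' @examples
#' burden_statistic_linear(c(0, 1, 2), c(1, 2, 3)) # 4
burden_statistic_linear <- function(burden, phenotype) {
  ph <- as_phenotype(phenotype, kind = "continuous")
  if (ph$kind != "continuous") {
    stop("linear burden statistic needs a continuous phenotype", call. = FALSE)
  }
  y <- ph$values
  stopifnot(length(burden) == length(y))
  s2 <- var(y)
  if (s2 == 0) stop("phenotype is constant", call. = FALSE)
  sum(burden * (y - mean(y)))^2 / s2
}

#' Burden score statistic, logistic model (extreme sampling)
#'
#' Score test of the burden's common effect on a dichotomized trait:
#' `[sum_i C_i (Y_i - Ybar)]^2` with `Ybar` the case fraction. Symmetric
#' under swapping case and control labels.
#'
#' @param burden integer vector of per-individual burden counts.
#' @param phenotype 0/1 case-control vector (or binary `rv_phenotype`).
#' @return The observed statistic.
#' @export
#' @examples
#' burden_statistic_binary(c(2, 1, 0, 1), c(1, 1, 0, 0)) # 1
burden_statistic_binary <- function(burden, phenotype) {
  ph <- as_phenotype(phenotype, kind = "binary")
  y <- ph$values
  stopifnot(length(burden) == length(y))
  sum(burden * (y - mean(y)))^2
}

#' Joint common-effect and variance-component scores, linear model
#'
#' For the model `Y = theta0 + theta1 * C + G beta + eps` with fixed common
#' effect `theta1` and random per-variant deviations `beta` (mean 0,
#' variance `sigma_beta^2`), the score statistic of
#' `H0: theta1 = 0, sigma_beta^2 = 0` has two components:
#' `S1 = sum_i C_i (Y_i - Ybar) / sigma2` (common effect) and
#' `S2 = U'U / 2 - tr(G'G) / (2 sigma2)` (variance component), with
#' `U_k = sum_i G_ik (Y_i - Ybar) / sigma2` and `sigma2` the sample variance
#' of `Y`. The burden `C` is the row sum of the supplied (already
#' rare-filtered) genotype matrix.
#'
#' @param genotypes [rv_genotypes] object or count matrix (rare-filtered).
#' @param phenotype continuous trait vector.
#' @return A list of class `rv_scores` with elements `s1`, `s2` and the
#'   per-variant score vector `u`.
#' @export
#' @examples
#' joint_scores_linear(matrix(c(0, 1, 2)), c(1, 2, 3))
joint_scores_linear <- function(genotypes, phenotype) {
  G <- if (inherits(genotypes, "rv_genotypes")) genotypes$counts else
    as.matrix(genotypes)
  ph <- as_phenotype(phenotype, kind = "continuous")
  y <- ph$values
  stopifnot(nrow(G) == length(y))
  s2y <- var(y)
  if (s2y == 0) stop("phenotype is constant", call. = FALSE)
  yc <- y - mean(y)
  u <- drop(crossprod(G, yc)) / s2y
  structure(
    list(
      s1 = sum(rowSums(G) * yc) / s2y,
      s2 = 0.5 * sum(u^2) - sum(G^2) / (2 * s2y),
      u = u
    ),
    class = "rv_scores"
  )
}

#' Joint common-effect and variance-component scores, logistic model
#'
#' Extreme-sampling analogue of [joint_scores_linear()] for dichotomized
#' traits: `S1 = sum_i (Y_i - Ybar) C_i`,
#' `U_k = sum_i G_ik (Y_i - Ybar)`, and
#' `S2 = U'U / 2 - tr(Ybar (1 - Ybar) G'G) / 2` with `Ybar` the case
#' fraction.
#'
#' @param genotypes [rv_genotypes] object or count matrix (rare-filtered).
#' @param phenotype 0/1 case-control vector.
#' @return A list of class `rv_scores` with elements `s1`, `s2`, `u`.
#' @export
#' @examples
#' joint_scores_binary(matrix(c(2, 0, 1, 1)), c(1, 1, 0, 0))
joint_scores_binary <- function(genotypes, phenotype) {
  G <- if (inherits(genotypes, "rv_genotypes")) genotypes$counts else
    as.matrix(genotypes)
  ph <- as_phenotype(phenotype, kind = "binary")
  y <- ph$values
  stopifnot(nrow(G) == length(y))
  ybar <- mean(y)
  yc <- y - ybar
  u <- drop(crossprod(G, yc))
  structure(
    list(
      s1 = sum(rowSums(G) * yc),
      s2 = 0.5 * sum(u^2) - 0.5 * ybar * (1 - ybar) * sum(G^2),
      u = u
    ),
    class = "rv_scores"
  )
}

#' @export
print.rv_scores <- function(x, ...) {
  cat(sprintf("<rv_scores> S1 = %.6g, S2 = %.6g (%d variants)\n",
              x$s1, x$s2, length(x$u)))
  invisible(x)
}

#' Fisher combination of two p-values
#'
#' `T = -2 log(p1) - 2 log(p2)` (natural log); larger values mean stronger
#' joint evidence. Calibrated here by permutation, not by the chi-square
#' reference distribution.
#'
#' @param p1,p2 p-values in `(0, 1]`.
#' @return The combined statistic (nonnegative).
#' @export
#' @examples
#' fisher_combine(0.05, 0.05) # 11.98293
fisher_combine <- function(p1, p2) {
  check_pvalue(p1)
  check_pvalue(p2)
  -2 * log(p1) - 2 * log(p2)
}

#' Minimum-p combination of two p-values
#'
#' `T = min(p1, p2)`; smaller values mean stronger evidence.
#'
#' @param p1,p2 p-values in `(0, 1]`.
#' @return The smaller of the two p-values.
#' @export
minp_combine <- function(p1, p2) {
  check_pvalue(p1)
  check_pvalue(p2)
  pmin(p1, p2)
}

check_pvalue <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' JOINT comparator statistic
#'
#' The sum of the standardized two-sided common-effect score and the
#' standardized variance-component score:
#' `(|S1| - mean|S1|) / sd|S1| + (S2 - mean S2) / sd S2`, with the null
#' moments estimated from a permutation sample.
#'
#' @param scores an `rv_scores` object (or list with `s1`, `s2`).
#' @param null_moments list with `mean_abs_s1`, `sd_abs_s1`, `mean_s2`,
#'   `sd_s2` estimated under permutation.
#' @return The observed JOINT statistic.
#' @export
joint_comparator_statistic <- function(scores, null_moments) {
  m <- null_moments
  if (m$sd_abs_s1 <= 0 || m$sd_s2 <= 0) {
    stop("degenerate permutation null: zero standard deviation", call. = FALSE)
  }
  (abs(scores$s1) - m$mean_abs_s1) / m$sd_abs_s1 +
    (scores$s2 - m$mean_s2) / m$sd_s2
}
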