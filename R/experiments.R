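#' Simulation configuration
#'
#' Collects every knob of the simulation study design: sample size, per-tail
#' fraction of the extreme design, causal-variant composition, intercept,
#' rare-variant threshold, permutation count, replication count and the root
#' seed. The implied population size is `N = round(n / (2 * tail))`, so both
#' designs draw from the same simulated population.
#'
#' @param n study sample size (even).
#' @param tail per-tail fraction for extreme sampling, in `(0, 0.5]`.
#' @param pct_causal fraction of rare pool sites that are causal (0 under
#'   the null model).
#' @param pct_positive fraction of causal sites with positive effect.
#' @param beta0 phenotype intercept (default 0.1).
#' @param maf_threshold rare-variant MAF threshold (default 0.03).
#' @param B permutations per test (default 500).
#' @param reps Monte-Carlo replications (default 1000).
#' @param seed root seed; every source of randomness in an experiment
#'   derives from it.
#' @param pool optional `rv_haplotype_pool` to simulate from; by default a
#'   synthetic pool of `pool_p` sites over `pool_size` haplotypes is built
#'   from the root seed.
#' @param pool_p,pool_size synthetic-pool dimensions (defaults 40 and 1394).
#' @return A list of class `rv_config`.
#' @export
simulation_config <- function(n = 500, tail = 0.1, pct_causal = 0,
                              pct_positive = 0.5, beta0 = 0.1,
                              maf_threshold = 0.03, B = 500, reps = 1000,
                              seed = 1, pool = NULL, pool_p = 40,
                              pool_size = 1394) {
  stopifnot(n %% 2 == 0, tail > 0, tail <= 0.5,
            pct_causal >= 0, pct_causal <= 1,
            pct_positive >= 0, pct_positive <= 1,
            B >= 1, reps >= 1)
  structure(
    list(n = as.integer(n), tail = tail, pct_causal = pct_causal,
         pct_positive = pct_positive, beta0 = beta0,
         maf_threshold = maf_threshold, B = as.integer(B),
         reps = as.integer(reps), seed = as.integer(seed), pool = pool,
         pool_p = pool_p, pool_size = pool_size),
    class = "rv_config"
  )
}

#' @export
print.rv_config <- function(x, ...) {
  cat(sprintf(
    "<rv_config> n = %d, tail = %g (N = %d), causal = %g%% (+%g%%), B = %d, reps = %d, seed = %d\n",
    x$n, x$tail, tail_fraction_to_population_size(x$n, x$tail),
    100 * x$pct_causal, 100 * x$pct_positive, x$B, x$reps, x$seed
  ))
  invisible(x)
}

test_labels <- function(designs) {
  labs <- character(0)
  if ("random" %in% designs) {
    labs <- c(labs, "JOINT", "RS_Fisher", "RS_min-p", "RS_burden")
  }
  if ("extreme" %in% designs) {
    labs <- c(labs, "ES_Fisher", "ES_min-p", "ES_burden")
  }
  labs
}

# One Monte-Carlo experiment: per replication simulate a population, draw
# the requested designs, rare-filter each drawn sample, and run all tests
# from a shared permutation pool per design. Returns the reps x tests
# p-value matrix. Replication seeds are drawn up front from the root seed,
# so results are reproducible regardless of evaluation order.
run_experiment_pvalues <- function(config, model = c("null", "alt"),
                                   designs = c("random", "extreme")) {
  model <- match.arg(model)
  designs <- match.arg(designs, c("random", "extreme"), several.ok = TRUE)
  if (model == "alt" && config$pct_causal <= 0) {
    stop("power experiment needs pct_causal > 0", call. = FALSE)
  }
  set.seed(config$seed)
  pool_seed <- sample.int(2^31 - 1, 1)
  rep_seeds <- sample.int(2^31 - 1, config$reps)
  pool <- config$pool
  if (is.null(pool)) {
    pool <- synthesize_haplotype_pool(p = config$pool_p,
                                      pool_size = config$pool_size,
                                      seed = pool_seed)
  }
  N <- tail_fraction_to_population_size(config$n, config$tail)
  labs <- test_labels(designs)
  pvals <- matrix(NA_real_, nrow = config$reps, ncol = length(labs),
                  dimnames = list(NULL, labs))
  n_degenerate <- 0L

  for (r in seq_len(config$reps)) {
    set.seed(rep_seeds[r])
    G_pop <- generate_genotypes(pool, N)
    y_pop <- if (model == "null") {
      simulate_null_phenotypes(N, beta0 = config$beta0)
    } else {
      eff <- assign_effects(pool, config$pct_causal, config$pct_positive,
                            maf_threshold = config$maf_threshold)
      simulate_alt_phenotypes(G_pop, eff, beta0 = config$beta0)
    }
    pop <- rv_population(G_pop, y_pop)

    for (d in designs) {
      smp <- if (d == "random") random_sample(pop, config$n) else
        extreme_sample(pop, config$n)
      methods <- if (d == "random") c("burden", "fisher", "minp", "joint") else
        c("burden", "fisher", "minp")
      res <- tryCatch(
        suppressMessages(rv_test(smp$genotypes, smp$phenotype,
                                 B = config$B,
                                 maf_threshold = config$maf_threshold,
                                 methods = methods)),
        error = function(e) NULL
      )
      if (is.null(res)) {
        # no rare variants survived in this draw: no evidence, p = 1
        n_degenerate <- n_degenerate + 1L
        cols <- intersect(test_labels(d), labs)
        pvals[r, cols] <- 1
      } else {
        pvals[r, res$test] <- res$p_value
      }
    }
  }
  attr(pvals, "n_degenerate") <- n_degenerate
  pvals
}

rates_from_pvalues <- function(pvals, alphas, config, model, designs) {
  reps <- nrow(pvals)
  grid <- tidyr::expand_grid(test = colnames(pvals), alpha = alphas)
  out <- dplyr::mutate(
    grid,
    rate = purrr::map2_dbl(.data$test, .data$alpha,
                           function(tst, a) mean(pvals[, tst] < a)),
    mc_se = sqrt(.data$rate * (1 - .data$rate) / reps),
    reps = reps,
    B = config$B,
    n = config$n,
    tail = config$tail,
    model = model
  )
  out <- tibble::as_tibble(out)
  class(out) <- c("rv_experiment", class(out))
  attr(out, "pvalues") <- pvals
  attr(out, "config") <- config
  attr(out, "designs") <- designs
  out
}

#' Empirical type-I error experiment
#'
#' Per replication: simulate a population of size `N = round(n / (2 tail))`
#' under the null phenotype model, draw a random sample and/or an extreme
#' sample of size `n`, rare-filter each drawn genotype matrix, and compute
#' all tests from a shared permutation pool per design. The empirical type-I
#' error of a test at level `alpha` is the proportion of replications with
#' `p < alpha` (strict).
#'
#' @param config a [simulation_config()] (its `pct_causal` is ignored; the
#'   null model has no genetic effects).
#' @param alphas nominal significance levels (default `c(0.01, 0.05)`).
#' @param designs which study designs to run; both by default. Restricting
#'   to one design halves the work when only its tests are of interest.
#' @return A tibble of class `rv_experiment` with one row per (test, alpha):
#'   `rate`, its binomial Monte-Carlo standard error `mc_se`
#'   (`sqrt(rate (1 - rate) / reps)`), and the setting columns. The full
#'   reps x tests p-value matrix is attached as attribute `"pvalues"`.
#' @export
run_type1_experiment <- function(config, alphas = c(0.01, 0.05),
                                 designs = c("random", "extreme")) {
  designs <- match.arg(designs, c("random", "extreme"), several.ok = TRUE)
  pvals <- run_experiment_pvalues(config, model = "null", designs = designs)
  rates_from_pvalues(pvals, alphas, config, "null", designs)
}

#' Empirical power experiment
#'
#' As [run_type1_experiment()], but phenotypes follow the alternative model
#' in which a random `pct_causal` fraction of rare pool sites carry
#' MAF-dependent effects (`|beta| = -0.2 log10(MAF)`), a `pct_positive`
#' fraction of them positive. Power is the proportion of replications with
#' `p < alpha`.
#'
#' @param config a [simulation_config()] with `pct_causal > 0`.
#' @param alpha nominal level (default 0.05).
#' @param designs which study designs to run.
#' @return A tibble of class `rv_experiment` (see [run_type1_experiment()]).
#' @export
run_power_experiment <- function(config, alpha = 0.05,
                                 designs = c("random", "extreme")) {
  designs <- match.arg(designs, c("random", "extreme"), several.ok = TRUE)
  pvals <- run_experiment_pvalues(config, model = "alt", designs = designs)
  rates_from_pvalues(pvals, alpha, config, "alt", designs)
}

#' Type-I error grid over sample sizes and tail fractions
#'
#' Runs [run_type1_experiment()] for every (tail, n) cell and stacks the
#' results; [format_type1_table()] pivots the stack into the classic layout
#' with one column per test.
#'
#' @param n_list sample sizes (default `c(500, 1000, 2000)`).
#' @param tail_list per-tail fractions (default `c(0.1, 0.2)`).
#' @param alphas nominal levels (default `c(0.01, 0.05)`).
#' @param reps replications per cell.
#' @param B permutations per test.
#' @param seed root seed; each cell gets a sub-seed derived from it.
#' @param designs which study designs to run.
#' @param ... further arguments passed to [simulation_config()].
#' @return A tibble of class `rv_experiment` stacking all cells.
#' @export
run_table1_grid <- function(n_list = c(500, 1000, 2000),
                            tail_list = c(0.1, 0.2),
                            alphas = c(0.01, 0.05),
                            reps = 1000, B = 500, seed = 1,
                            designs = c("random", "extreme"), ...) {
  stopifnot(length(n_list) > 0, length(tail_list) > 0, length(alphas) > 0)
  cells <- tidyr::expand_grid(tail = tail_list, n = n_list)
  set.seed(seed)
  cell_seeds <- sample.int(2^31 - 1, nrow(cells))
  out <- purrr::pmap(
    list(cells$tail, cells$n, cell_seeds),
    function(tail, n, cell_seed) {
      cfg <- simulation_config(n = n, tail = tail, B = B, reps = reps,
                               seed = cell_seed, ...)
      run_type1_experiment(cfg, alphas = alphas, designs = designs)
    }
  )
  res <- dplyr::bind_rows(out)
  class(res) <- c("rv_experiment", class(res))
  res
}

#' Pivot a type-I error grid into the classic wide layout
#'
#' One row per (tail, n, alpha), one column per test.
#'
#' @param grid output of [run_table1_grid()] (or any `rv_experiment` stack).
#' @return A wide tibble.
#' @export
format_type1_table <- function(grid) {
  tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(grid),
                  "tail", "n", "alpha", "test", "rate"),
    names_from = "test", values_from = "rate"
  )
}
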