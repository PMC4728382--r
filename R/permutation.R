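#' Permutation plan
#'
#' Describes how the permutation null is built: the number of sampled
#' phenotype reorderings `B`, the seed, and the mode. In `exhaustive` mode
#' all `n!` orderings are enumerated instead of sampled; this is only
#' allowed for small `n` (default cap `n! <= 5040`, i.e. `n <= 7`).
#'
#' @param B number of permutations (ignored in exhaustive mode).
#' @param seed integer seed for the sampled mode; `NULL` leaves the RNG
#'   state untouched.
#' @param mode `"sampled"` (default) or `"exhaustive"`.
#' @param exhaustive_cap largest admissible `n!` for exhaustive mode.
#' @return A list of class `rv_plan`.
#' @export
permutation_plan <- function(B = 500, seed = NULL,
                             mode = c("sampled", "exhaustive"),
                             exhaustive_cap = 5040) {
  mode <- match.arg(mode)
  stopifnot(B >= 1)
  structure(
    list(B = as.integer(B), seed = seed, mode = mode,
         exhaustive_cap = exhaustive_cap),
    class = "rv_plan"
  )
}

# Matrix whose columns are permuted copies of x (one column per ordering).
# Sampled mode draws uniform random orderings; exhaustive mode enumerates
# all n! orderings.
permutation_columns <- function(x, plan) {
  n <- length(x)
  if (plan$mode == "exhaustive") {
    if (factorial(n) > plan$exhaustive_cap) {
      stop(sprintf("exhaustive mode needs n! <= %d (n = %d)",
                   plan$exhaustive_cap, n), call. = FALSE)
    }
    idx <- t(e1071::permutations(n))
  } else {
    if (!is.null(plan$seed)) set.seed(plan$seed)
    idx <- vapply(seq_len(plan$B), function(b) sample.int(n), integer(n))
  }
  matrix(x[idx], nrow = n)
}

# Collapse values closer than ~1e-9 of the statistic's natural scale onto a
# grid, so orderings that are mathematically tied (but differ in floating
# noise from summation order) count as exact ties when ranked. The unit is
# an a-priori bound on the statistic, never derived from the realized
# values, so it is permutation-invariant.
quantize <- function(x, unit) {
  if (!is.finite(unit) || unit <= 0) return(x)
  round(x / unit, 9) * unit
}

#' Permutation pool of score statistics
#'
#' Computes the joint score components on the observed phenotype and on `B`
#' phenotype reorderings (or all `n!` in exhaustive mode), using the linear
#' model for continuous phenotypes and the logistic model for binary ones.
#' All tests derived from one pool share the same orderings, so results are
#' reproducible end-to-end from (data, seed, B).
#'
#' @param genotypes [rv_genotypes] object or count matrix, already restricted
#'   to the variant set under test.
#' @param phenotype trait vector or `rv_phenotype`.
#' @param plan a [permutation_plan()].
#' @return An object of class `rv_permpool`: observed scores, a `B x 2`
#'   matrix of permutation `(|S1|, S2)` values, and bookkeeping fields.
#' @export
permute_phenotype_statistics <- function(genotypes, phenotype,
                                         plan = permutation_plan()) {
  G <- if (inherits(genotypes, "rv_genotypes")) genotypes$counts else
    as.matrix(genotypes)
  ph <- as_phenotype(phenotype)
  y <- ph$values
  stopifnot(nrow(G) == length(y))
  C <- rowSums(G)
  yc <- y - mean(y)
  trGG <- sum(G^2)

  if (ph$kind == "continuous") {
    s2y <- var(y)
    if (s2y == 0) stop("phenotype is constant", call. = FALSE)
    scale <- s2y
    s2_const <- trGG / (2 * s2y)
    observed <- joint_scores_linear(G, ph)
  } else {
    ybar <- mean(y)
    scale <- 1
    s2_const <- 0.5 * ybar * (1 - ybar) * trGG
    observed <- joint_scores_binary(G, ph)
  }

  P <- permutation_columns(yc, plan)          # n x B, centered reorderings
  s1_perm <- drop(crossprod(C, P)) / scale
  UU <- crossprod(G, P) / scale               # p x B per-variant scores
  s2_perm <- 0.5 * colSums(UU^2) - s2_const

  max_yc <- max(abs(yc))
  unit_s1 <- sum(C) * max_yc / scale
  unit_s2 <- 0.5 * sum((colSums(G) * max_yc)^2) / scale^2 + abs(s2_const)

  structure(
    list(
      observed = c(abs_s1 = quantize(abs(observed$s1), unit_s1),
                   s2 = quantize(observed$s2, unit_s2)),
      observed_scores = observed,
      perms = cbind(abs_s1 = quantize(abs(s1_perm), unit_s1),
                    s2 = quantize(s2_perm, unit_s2)),
      kind = ph$kind,
      scale = scale,
      B = ncol(P),
      plan = plan
    ),
    class = "rv_permpool"
  )
}

#' @export
print.rv_permpool <- function(x, ...) {
  cat(sprintf("<rv_permpool> %s model, B = %d; observed |S1| = %.4g, S2 = %.4g\n",
              x$kind, x$B, x$observed["abs_s1"], x$observed["s2"]))
  invisible(x)
}

#' Component p-values from a permutation pool
#'
#' `p1` is the two-sided permutation p-value of the common-effect score S1
#' (upper tail of |S1|); `p2` is the one-sided upper p-value of the
#' variance-component score S2. Both use the add-one estimator
#' `(# exceedances + 1) / (B + 1)`, counting ties as exceedances, so no
#' p-value is ever zero.
#'
#' @param pool an `rv_permpool` from [permute_phenotype_statistics()].
#' @return Named numeric vector `c(p1 = , p2 = )`.
#' @export
component_pvalues <- function(pool) {
  B <- pool$B
  c(
    p1 = (sum(pool$perms[, "abs_s1"] >= pool$observed["abs_s1"]) + 1) / (B + 1),
    p2 = (sum(pool$perms[, "s2"] >= pool$observed["s2"]) + 1) / (B + 1)
  )
}

# Pseudo component p-values for each permutation row: the fraction of the B
# permutation values at least as large (ties count), i.e. rank within the
# single shared pool. Avoids nested permutation.
pseudo_pvalues <- function(v) {
  B <- length(v)
  (B - rank(v, ties.method = "min") + 1) / B
}

#' Combined permutation p-value
#'
#' Applies a p-value combiner (Fisher, minimum-p, or the JOINT
#' standardized-sum comparator) to the component p-values and calibrates the
#' combined statistic against the same permutation pool. For each
#' permutation, pseudo component p-values are obtained by ranking its
#' `(|S1|, S2)` against all `B` permutation rows; the observed statistic uses
#' the add-one component p-values of [component_pvalues()]. The final
#' p-value is `(# permutations at least as extreme + 1) / (B + 1)` — larger
#' is more extreme for `fisher` and `joint`, smaller for `minp`.
#'
#' @param pool an `rv_permpool`.
#' @param combiner `"fisher"`, `"minp"` or `"joint"`.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `p1`, `p2`, `b`.
#' @export
combined_pvalue <- function(pool, combiner = c("fisher", "minp", "joint")) {
  combiner <- match.arg(combiner)
  B <- pool$B
  comp <- component_pvalues(pool)

  if (combiner == "joint") {
    z <- function(v, obs) {
      s <- sd(v)
      if (!is.finite(s) || s == 0) return(list(perm = rep(0, B), obs = 0))
      list(perm = (v - mean(v)) / s, obs = (obs - mean(v)) / s)
    }
    z1 <- z(pool$perms[, "abs_s1"], pool$observed["abs_s1"])
    z2 <- z(pool$perms[, "s2"], pool$observed["s2"])
    t_perm <- z1$perm + z2$perm
    t_obs <- z1$obs + z2$obs
    n_extreme <- sum(t_perm >= t_obs)
  } else {
    p1_perm <- pseudo_pvalues(pool$perms[, "abs_s1"])
    p2_perm <- pseudo_pvalues(pool$perms[, "s2"])
    if (combiner == "fisher") {
      t_perm <- fisher_combine(p1_perm, p2_perm)
      t_obs <- fisher_combine(comp["p1"], comp["p2"])
      n_extreme <- sum(t_perm >= t_obs)
    } else {
      t_perm <- minp_combine(p1_perm, p2_perm)
      t_obs <- minp_combine(comp["p1"], comp["p2"])
      n_extreme <- sum(t_perm <= t_obs)
    }
  }

  tibble::tibble(
    test = combiner,
    statistic = unname(t_obs),
    p_value = (n_extreme + 1) / (B + 1),
    p1 = unname(comp["p1"]),
    p2 = unname(comp["p2"]),
    b = B
  )
}

#' Permutation p-value of the burden test
#'
#' One-sided upper permutation p-value of the squared burden statistic
#' ([burden_statistic_linear()] or [burden_statistic_binary()] according to
#' the phenotype kind); squaring makes the test direction-free.
#'
#' @param burden integer vector of per-individual burden counts.
#' @param phenotype trait vector or `rv_phenotype`.
#' @param plan a [permutation_plan()].
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `b`.
#' @export
burden_pvalue <- function(burden, phenotype, plan = permutation_plan()) {
  ph <- as_phenotype(phenotype)
  y <- ph$values
  stopifnot(length(burden) == length(y))
  yc <- y - mean(y)
  if (ph$kind == "continuous") {
    s2y <- var(y)
    if (s2y == 0) stop("phenotype is constant", call. = FALSE)
    stat <- function(cols) drop(crossprod(burden, cols))^2 / s2y
  } else {
    stat <- function(cols) drop(crossprod(burden, cols))^2
  }
  unit <- (sum(abs(burden)) * max(abs(yc)))^2
  if (ph$kind == "continuous") unit <- unit / var(y)
  obs <- quantize(stat(matrix(yc, ncol = 1)), unit)
  P <- permutation_columns(yc, plan)
  perm <- quantize(stat(P), unit)
  tibble::tibble(
    test = "burden",
    statistic = obs,
    p_value = (sum(perm >= obs) + 1) / (ncol(P) + 1),
    b = ncol(P)
  )
}

#' Region-based rare-variant association tests
#'
#' Runs the permutation-calibrated tests appropriate to the phenotype kind
#' from one shared pool of phenotype reorderings. For a continuous
#' (randomly sampled) trait the linear-model tests are reported as
#' `RS_burden`, `RS_Fisher`, `RS_min-p` and `JOINT`; for a binary
#' (extreme-sampled case/control) trait the logistic-model tests are
#' reported as `ES_burden`, `ES_Fisher` and `ES_min-p`.
#'
#' @param genotypes [rv_genotypes] object or allele-count matrix.
#' @param phenotype trait vector or `rv_phenotype`; 0/1 vectors are treated
#'   as binary.
#' @param B number of permutations (default 500).
#' @param seed integer seed for the permutation orderings.
#' @param methods subset of `c("burden", "fisher", "minp", "joint")`;
#'   defaults to all four for continuous phenotypes and the first three for
#'   binary ones.
#' @param maf_threshold if non-`NULL`, restrict the matrix to variants with
#'   `0 < MAF < maf_threshold` before testing (the usual rare-variant
#'   threshold is 0.03). `NULL` uses the matrix as supplied.
#' @param exhaustive enumerate all `n!` orderings instead of sampling
#'   (small `n` only).
#' @return A tibble of class `rv_result`, one row per test, with columns
#'   `test`, `statistic`, `p_value`, `p1`, `p2` (combination tests only)
#'   and `b` (number of permutations used).
#' @export
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(200, 2, 0.05), nrow = 50)
#' y <- rnorm(50)
#' rv_test(G, y, B = 99, seed = 42)
rv_test <- function(genotypes, phenotype, B = 500, seed = NULL,
                    methods = NULL, maf_threshold = NULL,
                    exhaustive = FALSE) {
  if (!inherits(genotypes, "rv_genotypes")) {
    genotypes <- rv_genotypes(genotypes)
  }
  if (!is.null(maf_threshold)) {
    genotypes <- filter_rare(genotypes, maf_threshold)
  }
  ph <- as_phenotype(phenotype)
  if (is.null(methods)) {
    methods <- if (ph$kind == "continuous") {
      c("burden", "fisher", "minp", "joint")
    } else {
      c("burden", "fisher", "minp")
    }
  }
  methods <- match.arg(methods, c("burden", "fisher", "minp", "joint"),
                       several.ok = TRUE)
  plan <- permutation_plan(
    B = B, seed = seed,
    mode = if (exhaustive) "exhaustive" else "sampled"
  )
  pool <- permute_phenotype_statistics(genotypes, ph, plan)
  prefix <- if (ph$kind == "continuous") "RS" else "ES"
  label <- c(
    burden = paste0(prefix, "_burden"),
    fisher = paste0(prefix, "_Fisher"),
    minp = paste0(prefix, "_min-p"),
    joint = "JOINT"
  )

  rows <- purrr::map(methods, function(m) {
    res <- if (m == "burden") {
      burden_from_pool(pool)
    } else {
      combined_pvalue(pool, m)
    }
    res$test <- unname(label[m])
    res
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "test", "statistic", "p_value")
  class(out) <- c("rv_result", class(out))
  attr(out, "kind") <- ph$kind
  attr(out, "seed") <- seed
  out
}

# Burden test recomputed from the shared pool: the squared burden statistic
# is a monotone function of |S1| at fixed phenotype scale (linear model:
# TB = (S1 * sigma2)^2 / sigma2; logistic: TB' = S1^2), so its one-sided
# permutation p-value equals the two-sided p-value of S1.
burden_from_pool <- function(pool) {
  to_burden <- if (pool$kind == "continuous") {
    function(a) a^2 * pool$scale
  } else {
    function(a) a^2
  }
  obs <- to_burden(pool$observed["abs_s1"])
  perm <- to_burden(pool$perms[, "abs_s1"])
  tibble::tibble(
    test = "burden",
    statistic = unname(obs),
    p_value = (sum(perm >= obs) + 1) / (pool$B + 1),
    b = pool$B
  )
}
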