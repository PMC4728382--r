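test_that("permutation pool is deterministic and has the stated shape", {
  G <- fixture_genotypes(12, 3)
  y <- rnorm(12)
  plan <- permutation_plan(B = 50, seed = 99)
  pool1 <- permute_phenotype_statistics(G, y, plan)
  pool2 <- permute_phenotype_statistics(G, y, plan)
  expect_identical(pool1$perms, pool2$perms)
  expect_equal(dim(pool1$perms), c(50L, 2L))
  expect_equal(pool1$B, 50L)

  # exhaustive mode on n = 3 yields all 6 orderings
  G3 <- matrix(c(1, 0, 2, 0, 1, 0), nrow = 3)
  pool3 <- permute_phenotype_statistics(
    G3, c(0.3, -1, 2), permutation_plan(mode = "exhaustive")
  )
  expect_equal(pool3$B, 6L)
  expect_error(
    permute_phenotype_statistics(fixture_genotypes(9, 2), rnorm(9),
                                 permutation_plan(mode = "exhaustive")),
    "exhaustive"
  )
})

test_that("component p-values use the add-one estimator with ties as exceedances", {
  mk_pool <- function(obs, perm) {
    structure(list(observed = c(abs_s1 = obs[1], s2 = obs[2]),
                   perms = cbind(abs_s1 = perm[, 1], s2 = perm[, 2]),
                   B = nrow(perm), kind = "continuous"),
              class = "rv_permpool")
  }
  # observed strictly above all B = 19 permutations -> 1/20
  pool <- mk_pool(c(5, 5), cbind(seq(0.1, 1.9, by = 0.1), seq(0.1, 1.9, by = 0.1)))
  expect_equal(unname(component_pvalues(pool)), c(0.05, 0.05))
  # observed tied with every permutation -> 1
  pool <- mk_pool(c(1, 1), cbind(rep(1, 19), rep(1, 19)))
  expect_equal(unname(component_pvalues(pool)), c(1, 1))
  # observed below all permutations -> 1
  pool <- mk_pool(c(0, 0), cbind(rep(1, 19), rep(1, 19)))
  expect_equal(unname(component_pvalues(pool)), c(1, 1))
})

test_that("degenerate pools give p = 1 for every combiner and the burden test", {
  # all genotype rows equal: every permutation row identical
  G <- matrix(1L, nrow = 8, ncol = 2)
  y <- rnorm(8)
  pool <- permute_phenotype_statistics(G, y, permutation_plan(B = 30, seed = 1))
  for (cmb in c("fisher", "minp", "joint")) {
    expect_equal(combined_pvalue(pool, cmb)$p_value, 1)
  }
  res <- burden_pvalue(rep(2L, 8), y, permutation_plan(B = 30, seed = 1))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("combined statistics satisfy their definitions on the component p-values", {
  G <- fixture_genotypes(15, 4)
  y <- rnorm(15)
  pool <- permute_phenotype_statistics(G, y, permutation_plan(B = 99, seed = 3))
  comp <- component_pvalues(pool)
  fish <- combined_pvalue(pool, "fisher")
  expect_equal(fish$statistic, -2 * log(comp["p1"]) - 2 * log(comp["p2"]),
               ignore_attr = TRUE)
  expect_equal(c(fish$p1, fish$p2), unname(comp))
  mp <- combined_pvalue(pool, "minp")
  expect_equal(mp$statistic, min(comp))
  # p-values respect the add-one lower bound
  for (cmb in c("fisher", "minp", "joint")) {
    expect_gte(combined_pvalue(pool, cmb)$p_value, 1 / (pool$B + 1))
  }
})

test_that("JOINT observed statistic matches the standalone comparator", {
  G <- fixture_genotypes(18, 5)
  y <- rnorm(18)
  pool <- permute_phenotype_statistics(G, y, permutation_plan(B = 60, seed = 8))
  mom <- list(
    mean_abs_s1 = mean(pool$perms[, "abs_s1"]),
    sd_abs_s1 = sd(pool$perms[, "abs_s1"]),
    mean_s2 = mean(pool$perms[, "s2"]),
    sd_s2 = sd(pool$perms[, "s2"])
  )
  # the pool ranks statistics on a ~1e-9 relative tie grid, so agreement
  # with the raw-score path is to that resolution, not to the last bit
  expect_equal(
    combined_pvalue(pool, "joint")$statistic,
    joint_comparator_statistic(pool$observed_scores, mom),
    tolerance = 1e-6
  )
})

test_that("permutation ranks of S2 equal ranks of U'U (trace term constant)", {
  G <- fixture_genotypes(14, 4)
  y <- rnorm(14)
  plan <- permutation_plan(B = 40, seed = 21)
  pool <- permute_phenotype_statistics(G, y, plan)
  # recompute u'u per permutation from scratch
  set.seed(21)
  yc <- y - mean(y)
  uu <- vapply(seq_len(40), function(b) {
    yp <- yc[sample.int(14)]
    sum((crossprod(G, yp) / var(y))^2)
  }, numeric(1))
  expect_equal(rank(pool$perms[, "s2"]), rank(uu))
})

test_that("p-values are invariant to phenotype shifts and label swaps", {
  G <- fixture_genotypes(16, 4)
  y <- rnorm(16)
  r1 <- rv_test(G, y, B = 80, seed = 5)
  r2 <- rv_test(G, y + 100, B = 80, seed = 5)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)

  yb <- rep(c(0, 1), 8)
  b1 <- rv_test(G, yb, B = 80, seed = 5)
  b2 <- rv_test(G, 1 - yb, B = 80, seed = 5)
  expect_equal(b1$p_value, b2$p_value)
})

test_that("sigma^2 convention cannot affect linear permutation p-values", {
  # scaling Y rescales sigma^2 and every statistic by a constant factor,
  # leaving all ranks, hence all p-values, unchanged
  G <- fixture_genotypes(16, 4)
  y <- rnorm(16)
  r1 <- rv_test(G, y, B = 80, seed = 5)
  r2 <- rv_test(G, y * 3.7, B = 80, seed = 5)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("exhaustive engine equals the brute-force oracle on all tests", {
  # continuous phenotype, n = 5: all 120 orderings. Integer trait values
  # with an exact mean keep both code paths in exact arithmetic, so ties
  # between mathematically equal orderings are exact on both sides.
  G <- fixture_genotypes(5, 3, seed = 13, maf = 0.3)
  y <- c(-2, 0, 1, 4, 7)
  res <- rv_test(G, y, exhaustive = TRUE)
  orc <- oracle_pvalues(G, y, "continuous")
  expect_equal(res$p_value[res$test == "RS_burden"], unname(orc["burden"]))
  expect_equal(res$p_value[res$test == "RS_Fisher"], unname(orc["fisher"]))
  expect_equal(res$p_value[res$test == "RS_min-p"], unname(orc["minp"]))
  expect_equal(res$p_value[res$test == "JOINT"], unname(orc["joint"]))
  expect_equal(res$p1[res$test == "RS_Fisher"], unname(orc["p1"]))
  expect_equal(res$p2[res$test == "RS_Fisher"], unname(orc["p2"]))

  # binary phenotype, n = 4: all 24 orderings
  Gb <- matrix(c(2, 0, 1, 1, 0, 1, 0, 1), nrow = 4)
  yb <- c(1, 1, 0, 0)
  resb <- rv_test(Gb, yb, exhaustive = TRUE)
  orcb <- oracle_pvalues(Gb, yb, "binary")
  expect_equal(resb$p_value[resb$test == "ES_burden"], unname(orcb["burden"]))
  expect_equal(resb$p_value[resb$test == "ES_Fisher"], unname(orcb["fisher"]))
  expect_equal(resb$p_value[resb$test == "ES_min-p"], unname(orcb["minp"]))
})

test_that("burden_pvalue agrees with the shared-pool burden test", {
  G <- fixture_genotypes(12, 3)
  y <- rnorm(12)
  direct <- burden_pvalue(collapse_burden(G), y, permutation_plan(B = 70, seed = 2))
  pooled <- rv_test(G, y, B = 70, seed = 2, methods = "burden")
  expect_equal(direct$p_value, pooled$p_value)
  expect_equal(direct$statistic, pooled$statistic, tolerance = 1e-6)
})

test_that("tidy and glance methods summarize results", {
  G <- fixture_genotypes(12, 3)
  res <- rv_test(G, rnorm(12), B = 50, seed = 4)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "rv_result"))
  gl <- glance(res)
  expect_equal(gl$n_tests, 4L)
  expect_equal(gl$min_p_value, min(res$p_value))
})
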