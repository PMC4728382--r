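test_that("synthetic haplotype pools are reproducible, polymorphic and rare-dominated", {
  pool <- synthesize_haplotype_pool(p = 40, pool_size = 600, seed = 9)
  expect_equal(dim(pool$haplotypes), c(600L, 40L))
  expect_true(all(pool$haplotypes %in% c(0L, 1L)))
  # every site polymorphic
  expect_true(all(pool$pool_mafs > 0 & pool$pool_mafs < 1))
  # same seed, same pool
  pool2 <- synthesize_haplotype_pool(p = 40, pool_size = 600, seed = 9)
  expect_identical(pool$haplotypes, pool2$haplotypes)
  # the default spectrum is dominated by rare sites
  expect_gt(mean(pool$pool_mafs < 0.03), 0.5)
  # realized frequencies track the drawn targets at the default pool size
  cors <- vapply(1:5, function(s) {
    pl <- synthesize_haplotype_pool(p = 40, pool_size = 1394, seed = s)
    cor(pl$pool_mafs, pl$target_mafs, method = "spearman")
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
})

test_that("degenerate spectra are honoured or clamped", {
  # point mass at 0.5 with H = 2: both alleles must be present
  pool <- synthesize_haplotype_pool(p = 1, pool_size = 2, seed = 1,
                                    maf_spectrum = function(m) rep(0.5, m))
  expect_equal(sum(pool$haplotypes), 1L)
  expect_warning(
    synthesize_haplotype_pool(p = 2, pool_size = 50, seed = 1,
                              maf_spectrum = function(m) rep(1e-4, m)),
    "clamping"
  )
})

test_that("haplotype pools round-trip through TSV", {
  pool <- synthesize_haplotype_pool(p = 6, pool_size = 40, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_pool(pool, path)
  back <- load_haplotype_pool(path)
  expect_equal(unname(back$haplotypes), unname(pool$haplotypes))
  expect_equal(back$pool_mafs, pool$pool_mafs)

  writeLines(c("0\t1", "0\t2"), path)
  expect_error(load_haplotype_pool(path), "non-binary")
  writeLines(character(0), path)
  expect_error(load_haplotype_pool(path), "cannot read")
})

test_that("genotypes arise from random pairing of haplotypes under HWE", {
  # two-haplotype pool {all zeros, all ones}: dosage is Binomial(2, 1/2)
  pool <- list(haplotypes = matrix(c(0L, 1L), nrow = 2, ncol = 1),
               pool_mafs = 0.5)
  class(pool) <- "rv_haplotype_pool"
  g <- generate_genotypes(pool, 8000, seed = 5)
  freq <- tabulate(g$counts + 1L, nbins = 3) / 8000
  expect_equal(freq, c(0.25, 0.5, 0.25), tolerance = 0.05)

  # HWE at every site of a synthetic pool: genotype frequencies match
  # (1-q)^2, 2q(1-q), q^2 within Monte-Carlo tolerance
  pool <- synthesize_haplotype_pool(p = 10, pool_size = 300, seed = 21)
  g <- generate_genotypes(pool, 20000, seed = 6)
  q <- pool$pool_mafs
  for (j in seq_len(10)) {
    obs <- tabulate(g$counts[, j] + 1L, nbins = 3) / 20000
    exp_hwe <- c((1 - q[j])^2, 2 * q[j] * (1 - q[j]), q[j]^2)
    expect_equal(obs, exp_hwe, tolerance = 0.02 + 3 * sqrt(max(exp_hwe *
      (1 - exp_hwe)) / 20000))
  }
  # sample MAF tracks pool MAF
  expect_lt(max(abs(colMeans(g$counts) / 2 - q)), 0.01)
  # determinism
  expect_identical(generate_genotypes(pool, 50, seed = 7)$counts,
                   generate_genotypes(pool, 50, seed = 7)$counts)
})

test_that("effect magnitudes follow the MAF-dependent rule", {
  pool <- structure(list(pool_mafs = c(0.01, 0.001, 0.02, 0.2)),
                    class = "rv_haplotype_pool")
  eff <- assign_effects(pool, pct_causal = 1, pct_positive = 1, seed = 2)
  # common site (MAF 0.2) is never causal
  expect_equal(eff$causal_mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(eff$betas[1], 0.4)   # -0.2 log10(0.01)
  expect_equal(eff$betas[2], 0.6)   # -0.2 log10(0.001)
  expect_equal(eff$betas[4], 0)
  # rarer causal variants get strictly larger magnitudes
  expect_true(abs(eff$betas[2]) > abs(eff$betas[1]))
  expect_true(abs(eff$betas[1]) > abs(eff$betas[3]))

  # sign and causal-count bookkeeping
  eff2 <- assign_effects(pool, pct_causal = 2 / 3, pct_positive = 0.5, seed = 3)
  expect_equal(sum(eff2$causal_mask), 2)   # round(2/3 * 3)
  expect_equal(sum(eff2$sign_mask), 1)
  expect_equal(sum(eff2$betas > 0), 1)
  expect_equal(sum(eff2$betas < 0), 1)

  expect_equal(sum(assign_effects(pool, 0, 1, seed = 1)$betas), 0)
  common_only <- structure(list(pool_mafs = c(0.2, 0.4)),
                           class = "rv_haplotype_pool")
  expect_error(assign_effects(common_only, 0.5, 1), "no rare")
})

test_that("null phenotypes are Gaussian around the intercept", {
  y <- simulate_null_phenotypes(10000, seed = 8)
  expect_lt(abs(mean(y) - 0.1), 3 / sqrt(10000))
  expect_lt(abs(var(y) - 1), 0.05)
  expect_identical(simulate_null_phenotypes(100, seed = 8),
                   simulate_null_phenotypes(100, seed = 8))
})

test_that("alternative phenotypes add genetic means and reduce to the null", {
  pool <- synthesize_haplotype_pool(p = 15, pool_size = 400, seed = 12)
  G <- generate_genotypes(pool, 5000, seed = 13)

  # zero causal fraction reproduces the null generator bit-for-bit
  eff0 <- assign_effects(pool, pct_causal = 0, pct_positive = 1, seed = 14)
  expect_identical(simulate_alt_phenotypes(G, eff0, seed = 15),
                   simulate_null_phenotypes(5000, seed = 15))

  # a single causal variant shifts carrier means by its beta
  betas <- numeric(15)
  j <- which.max(pool$pool_mafs)
  betas[j] <- 0.4
  eff1 <- list(betas = betas)
  y <- simulate_alt_phenotypes(G, eff1, seed = 16)
  carriers <- G$counts[, j] == 1
  non <- G$counts[, j] == 0
  expect_equal(mean(y[carriers]) - mean(y[non]), 0.4,
               tolerance = 3 * sqrt(1 / sum(carriers) + 1 / sum(non)))
})
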