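#' Synthesize a haplotype pool for a rare-variant region
#'
#' Builds an `H x p` binary haplotype matrix (allele 1 = minor) emulating a
#' sequenced gene region dominated by rare variants. Per-site target minor
#' allele frequencies are drawn from `maf_spectrum` (default: Beta(0.2, 4)
#' truncated to `[1/H, 0.3]`, so most sites fall below the 3% rare
#' threshold while a minority are common); alleles are then sampled
#' independently per haplotype at the target frequency. Sites that come out
#' fixed (0 or `H` copies) are redrawn, so every pool site is polymorphic.
#'
#' @param p number of variant sites (default 40, the size of the gene region
#'   the simulation design mimics).
#' @param pool_size number of haplotypes `H` (default 1394, i.e. 2 x 697
#'   phased individuals).
#' @param seed integer seed.
#' @param maf_spectrum function of one argument `m` returning `m` target
#'   MAFs; targets below `1/H` are clamped up to `1/H` with a warning.
#' @return An object of class `rv_haplotype_pool`: the binary `haplotypes`
#'   matrix and realized `pool_mafs` (column means).
#' @export
#' @examples
#' pool <- synthesize_haplotype_pool(p = 10, pool_size = 200, seed = 1)
#' summary(pool$pool_mafs)
synthesize_haplotype_pool <- function(p = 40, pool_size = 1394, seed = NULL,
                                      maf_spectrum = NULL) {
  stopifnot(pool_size >= 2, p >= 1)
  if (!is.null(seed)) set.seed(seed)
  H <- pool_size
  if (is.null(maf_spectrum)) {
    # Beta(0.2, 4) truncated to [1/H, 0.3]: rare-dominated with a common tail
    maf_spectrum <- function(m) {
      out <- numeric(0)
      while (length(out) < m) {
        draw <- rbeta(2 * m, 0.2, 4)
        out <- c(out, draw[draw >= 1 / H & draw <= 0.3])
      }
      out[seq_len(m)]
    }
  }
  targets <- maf_spectrum(p)
  if (any(targets < 1 / H)) {
    warning(sprintf("clamping %d target MAF(s) up to 1/H = %.3g",
                    sum(targets < 1 / H), 1 / H), call. = FALSE)
    targets <- pmax(targets, 1 / H)
  }
  hap <- matrix(0L, nrow = H, ncol = p)
  for (j in seq_len(p)) {
    repeat {
      col <- as.integer(stats::runif(H) < targets[j])
      s <- sum(col)
      if (s > 0L && s < H) break
    }
    hap[, j] <- col
  }
  colnames(hap) <- paste0("V", seq_len(p))
  structure(
    list(haplotypes = hap, pool_mafs = unname(colMeans(hap)),
         target_mafs = targets),
    class = "rv_haplotype_pool"
  )
}

#' @export
print.rv_haplotype_pool <- function(x, ...) {
  cat(sprintf(
    "<rv_haplotype_pool> %d haplotypes x %d sites; %d site(s) with MAF < 0.03\n",
    nrow(x$haplotypes), ncol(x$haplotypes), sum(x$pool_mafs < 0.03)
  ))
  invisible(x)
}

#' Load a haplotype pool from a TSV file
#'
#' Reads a 0/1 matrix, one row per haplotype and one column per site, for
#' users who want to simulate from real phased haplotypes instead of the
#' synthetic pool.
#'
#' @param path file path.
#' @param header does the first row hold site identifiers? Default `FALSE`.
#' @return An `rv_haplotype_pool`.
#' @export
load_haplotype_pool <- function(path, header = FALSE) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop(sprintf("cannot read haplotype pool: %s", path), call. = FALSE)
  }
  mat <- as.matrix(read.table(path, header = header, check.names = FALSE))
  if (!all(mat %in% c(0, 1))) {
    bad <- which(matrix(!(mat %in% c(0, 1)), nrow(mat)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary haplotype entry at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  if (is.null(colnames(mat))) colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  structure(
    list(haplotypes = mat, pool_mafs = unname(colMeans(mat)),
         target_mafs = unname(colMeans(mat))),
    class = "rv_haplotype_pool"
  )
}

#' Write a haplotype pool to TSV
#'
#' @param pool an `rv_haplotype_pool`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_haplotype_pool <- function(pool, path) {
  write.table(pool$haplotypes, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate genotypes by random haplotype pairing
#'
#' Each individual's genotype is the sum of two haplotypes drawn uniformly
#' with replacement from the pool — the random union of gametes, so site
#' genotype frequencies follow Hardy-Weinberg proportions at the pool MAF.
#'
#' @param pool an `rv_haplotype_pool`.
#' @param N number of individuals.
#' @param seed integer seed.
#' @return An [rv_genotypes] object of raw pool-oriented counts (no
#'   orientation flip or monomorphic filtering — that preprocessing belongs
#'   to the analysis of a drawn study sample).
#' @export
generate_genotypes <- function(pool, N, seed = NULL) {
  stopifnot(N >= 1)
  if (!is.null(seed)) set.seed(seed)
  H <- nrow(pool$haplotypes)
  counts <- pool$haplotypes[sample.int(H, N, replace = TRUE), , drop = FALSE] +
    pool$haplotypes[sample.int(H, N, replace = TRUE), , drop = FALSE]
  rv_genotypes(counts, orient = FALSE, drop_monomorphic = FALSE)
}

# round-half-up: 40% of 33 rare sites must be an integer
round_half_up <- function(x) floor(x + 0.5)

#' Assign causal effects to rare pool sites
#'
#' Picks a uniformly random subset of the rare sites (`pool MAF <
#' maf_threshold`) of size `round(pct_causal * #rare)` as causal, gives
#' `round(pct_positive * #causal)` of them positive sign (the rest
#' negative), and sets magnitudes by the MAF-dependent rule
#' `|beta_j| = -0.2 * log10(MAF_j)` — rarer variants get larger effects
#' (MAF 0.01 gives 0.4, MAF 0.001 gives 0.6). MAFs are the pool (population)
#' frequencies, a property of the generating model, not of any sample.
#'
#' @param pool an `rv_haplotype_pool`.
#' @param pct_causal fraction of rare sites that are causal, in `[0, 1]`.
#' @param pct_positive fraction of causal sites with positive effect.
#' @param maf_threshold rare threshold (default 0.03).
#' @param seed integer seed.
#' @return An object of class `rv_effects`: `betas` (length `p`),
#'   `causal_mask`, `sign_mask` (`TRUE` = positive).
#' @export
assign_effects <- function(pool, pct_causal, pct_positive,
                           maf_threshold = 0.03, seed = NULL) {
  stopifnot(pct_causal >= 0, pct_causal <= 1,
            pct_positive >= 0, pct_positive <= 1)
  if (!is.null(seed)) set.seed(seed)
  mafs <- pool$pool_mafs
  rare <- which(mafs > 0 & mafs < maf_threshold)
  if (length(rare) == 0L) {
    stop("pool has no rare sites below the MAF threshold", call. = FALSE)
  }
  n_causal <- round_half_up(pct_causal * length(rare))
  causal <- sort(sample(rare, n_causal))
  n_pos <- round_half_up(pct_positive * n_causal)
  pos <- if (n_causal > 0L) sort(sample(causal, n_pos)) else integer(0)

  p <- length(mafs)
  betas <- numeric(p)
  causal_mask <- seq_len(p) %in% causal
  sign_mask <- seq_len(p) %in% pos
  betas[causal_mask] <- -0.2 * log10(mafs[causal_mask])
  betas[causal_mask & !sign_mask] <- -betas[causal_mask & !sign_mask]
  structure(
    list(betas = betas, causal_mask = causal_mask, sign_mask = sign_mask),
    class = "rv_effects"
  )
}

#' Simulate phenotypes under the null model
#'
#' `Y_i = beta0 + eps_i` with standard normal noise: the trait is
#' independent of the genotypes.
#'
#' @param N number of individuals.
#' @param beta0 intercept (default 0.1).
#' @param seed integer seed.
#' @return Numeric vector of length `N`.
#' @export
simulate_null_phenotypes <- function(N, beta0 = 0.1, seed = NULL) {
  stopifnot(N >= 1)
  if (!is.null(seed)) set.seed(seed)
  beta0 + rnorm(N)
}

#' Simulate phenotypes under the alternative model
#'
#' `Y_i = beta0 + G_i . beta + eps_i` with standard normal noise. With all
#' betas zero and the same seed this reproduces
#' [simulate_null_phenotypes()] exactly (the noise stream is identical).
#'
#' @param genotypes [rv_genotypes] object or count matrix (`N x p`).
#' @param effects an `rv_effects` from [assign_effects()] (or a list with a
#'   `betas` vector).
#' @param beta0 intercept (default 0.1).
#' @param seed integer seed.
#' @return Numeric vector of length `N`.
#' @export
simulate_alt_phenotypes <- function(genotypes, effects, beta0 = 0.1,
                                    seed = NULL) {
  G <- if (inherits(genotypes, "rv_genotypes")) genotypes$counts else
    as.matrix(genotypes)
  stopifnot(ncol(G) == length(effects$betas))
  if (!is.null(seed)) set.seed(seed)
  beta0 + drop(G %*% effects$betas) + rnorm(nrow(G))
}
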