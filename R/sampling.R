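#' Simulated population container
#'
#' Couples an `N x p` genotype matrix with a continuous phenotype vector of
#' the same length, the sampling frame both study designs draw from.
#'
#' @param genotypes [rv_genotypes] object or allele-count matrix.
#' @param phenotypes numeric trait vector of length `N`.
#' @return An object of class `rv_population`.
#' @export
rv_population <- function(genotypes, phenotypes) {
  if (!inherits(genotypes, "rv_genotypes")) {
    genotypes <- rv_genotypes(genotypes, orient = FALSE,
                              drop_monomorphic = FALSE)
  }
  phenotypes <- as.numeric(phenotypes)
  stopifnot(nrow(genotypes$counts) == length(phenotypes))
  structure(list(genotypes = genotypes, phenotypes = phenotypes),
            class = "rv_population")
}

#' @export
print.rv_population <- function(x, ...) {
  cat(sprintf("<rv_population> N = %d, %d variants\n",
              length(x$phenotypes), ncol(x$genotypes$counts)))
  invisible(x)
}

subset_population <- function(population, idx, phenotype) {
  structure(
    list(
      genotypes = population$genotypes$counts[idx, , drop = FALSE],
      phenotype = phenotype,
      indices = idx
    ),
    class = "rv_sample"
  )
}

#' Random-sampling study design
#'
#' Draws `n` distinct individuals uniformly without replacement; the
#' phenotype stays continuous and the linear-model (RS) tests apply.
#'
#' @param population an [rv_population()].
#' @param n sample size, at most the population size.
#' @param seed optional integer seed.
#' @return An `rv_sample`: the `n x p` genotype count matrix, the
#'   continuous `rv_phenotype`, and the selected population `indices`.
#' @export
random_sample <- function(population, n, seed = NULL) {
  N <- length(population$phenotypes)
  if (n > N) stop("sample size n exceeds population size N", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(N, n))
  out <- subset_population(
    population, idx,
    rv_phenotype(population$phenotypes[idx], kind = "continuous")
  )
  out$design <- "random"
  out
}

#' Extreme-phenotype study design
#'
#' Ranks the population by trait value and dichotomizes: the top `n/2`
#' individuals become cases (`Y = 1`), the bottom `n/2` controls (`Y = 0`).
#' Ties at either cut are broken by population index (stable order), so the
#' design is deterministic.
#'
#' @param population an [rv_population()].
#' @param n even sample size, at most the population size.
#' @return An `rv_sample` with a binary phenotype: controls first, then
#'   cases, each block in increasing population-index order.
#' @export
extreme_sample <- function(population, n) {
  N <- length(population$phenotypes)
  if (n %% 2 != 0) stop("extreme design needs an even n", call. = FALSE)
  if (n > N) stop("sample size n exceeds population size N", call. = FALSE)
  ord <- order(population$phenotypes)        # stable: ties by index
  lo <- sort(ord[seq_len(n / 2)])
  hi <- sort(ord[seq(N - n / 2 + 1, N)])
  idx <- c(lo, hi)
  out <- subset_population(
    population, idx,
    rv_phenotype(rep(c(0, 1), each = n / 2), kind = "binary")
  )
  out$design <- "extreme"
  out
}

#' @export
print.rv_sample <- function(x, ...) {
  cat(sprintf("<rv_sample> %s design, n = %d (%s phenotype)\n",
              x$design, nrow(x$genotypes), x$phenotype$kind))
  invisible(x)
}

#' Population size implied by a per-tail fraction
#'
#' In the extreme design each tail holds `n/2` individuals equal to `tail`
#' of the population, so `N = round(n / (2 * tail))`. A 10% tail with
#' `n = 2000` therefore needs `N = 10000`; `tail = 0.5` degenerates to a
#' median split of the whole pool (`N = n`).
#'
#' @param n even sample size.
#' @param tail per-tail fraction in `(0, 0.5]`.
#' @return Integer population size `N`.
#' @export
tail_fraction_to_population_size <- function(n, tail) {
  if (!is.numeric(tail) || length(tail) != 1L || tail <= 0 || tail > 0.5) {
    stop("`tail` must be a single fraction in (0, 0.5]", call. = FALSE)
  }
  if (n %% 2 != 0) stop("extreme design needs an even n", call. = FALSE)
  as.integer(round(n / (2 * tail)))
}

#' Write a study sample to TSV files
#'
#' Serializes genotypes (one row per individual, header of variant IDs) and
#' the phenotype (`sample_id`, `value`) in the formats the readers expect.
#'
#' @param sample an `rv_sample` (or any list with `genotypes` matrix and
#'   `phenotype`).
#' @param genotype_path,phenotype_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_sample_tsv <- function(sample, genotype_path, phenotype_path) {
  G <- if (inherits(sample$genotypes, "rv_genotypes"))
    sample$genotypes$counts else sample$genotypes
  write.table(G, genotype_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ph <- as_phenotype(sample$phenotype)
  write.table(
    data.frame(sample_id = seq_along(ph$values), value = ph$values),
    phenotype_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(genotype_path, phenotype_path))
}
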