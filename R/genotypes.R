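#' Genotype matrix container
#'
#' Wraps an `n x p` matrix of minor-allele counts together with variant
#' identifiers and sample minor-allele frequencies. Construction enforces the
#' container's invariants: every entry is 0, 1 or 2, columns are oriented so
#' that counts refer to the minor allele (frequency at most 0.5), and
#' monomorphic columns are dropped.
#'
#' @param counts integer matrix, one row per individual, one column per
#'   variant; entries are allele counts in `{0, 1, 2}`.
#' @param variant_ids optional character vector of column labels; defaults to
#'   existing column names or `V1..Vp`.
#' @param orient if `TRUE` (default), columns whose allele frequency exceeds
#'   0.5 are recoded as `2 - G` so counts refer to the minor allele.
#' @param drop_monomorphic if `TRUE` (default), columns with no variation
#'   (allele frequency 0 after orientation) are removed with a message.
#'
#' @return An object of class `rv_genotypes`: a list with elements `counts`
#'   (integer matrix), `variant_ids` (character) and `mafs` (numeric, in
#'   `[0, 0.5]`).
#' @export
#' @examples
#' g <- rv_genotypes(matrix(c(0, 1, 2, 0, 0, 0), nrow = 3))
#' g$mafs
rv_genotypes <- function(counts, variant_ids = NULL, orient = TRUE,
                         drop_monomorphic = TRUE) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) {
    stop("genotype matrix is empty", call. = FALSE)
  }
  if (!all(counts %in% c(0, 1, 2))) {
    bad <- which(matrix(!(counts %in% c(0, 1, 2)), nrow(counts)),
                 arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "genotype entry at row %d, column %d is not 0, 1 or 2 (value: %s)",
      bad[1L], bad[2L], format(counts[bad[1L], bad[2L]])
    ), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(variant_ids)) {
    variant_ids <- colnames(counts)
  }
  if (is.null(variant_ids)) {
    variant_ids <- paste0("V", seq_len(ncol(counts)))
  }
  stopifnot(length(variant_ids) == ncol(counts))
  colnames(counts) <- variant_ids

  if (orient) {
    counts <- orient_minor(counts)
  }
  mafs <- compute_mafs(counts, orient = FALSE)
  if (drop_monomorphic) {
    mono <- mafs == 0
    if (any(mono)) {
      message(sprintf("dropping %d monomorphic variant(s)", sum(mono)))
      counts <- counts[, !mono, drop = FALSE]
      mafs <- mafs[!mono]
    }
    if (ncol(counts) == 0L) {
      stop("no polymorphic variants remain after filtering", call. = FALSE)
    }
  }
  structure(
    list(counts = counts, variant_ids = colnames(counts), mafs = unname(mafs)),
    class = "rv_genotypes"
  )
}

#' @export
print.rv_genotypes <- function(x, ...) {
  cat(sprintf(
    "<rv_genotypes> %d individuals x %d variants; MAF range [%.4g, %.4g]\n",
    nrow(x$counts), ncol(x$counts), min(x$mafs), max(x$mafs)
  ))
  invisible(x)
}

#' @export
dim.rv_genotypes <- function(x) dim(x$counts)

# Flip columns so stored counts are minor-allele counts; idempotent.
orient_minor <- function(counts) {
  freq <- colSums(counts) / (2 * nrow(counts))
  flip <- freq > 0.5
  if (any(flip)) {
    counts[, flip] <- 2L - counts[, flip, drop = FALSE]
  }
  counts
}

#' Minor-allele frequencies of a count matrix
#'
#' @param counts matrix of allele counts in `{0, 1, 2}` (rows = individuals),
#'   or an [rv_genotypes] object.
#' @param orient apply minor-allele orientation before computing frequencies,
#'   so every result is at most 0.5.
#' @return Numeric vector: column allele-count sums divided by `2n`.
#' @export
#' @examples
#' compute_mafs(matrix(c(0, 2, 0, 1, 0, 0), nrow = 3))
compute_mafs <- function(counts, orient = TRUE) {
  if (inherits(counts, "rv_genotypes")) {
    return(counts$mafs)
  }
  counts <- as.matrix(counts)
  if (length(counts) == 0L) {
    stop("genotype matrix is empty", call. = FALSE)
  }
  if (orient) counts <- orient_minor(counts)
  colSums(counts) / (2 * nrow(counts))
}

#' Rare-variant mask
#'
#' Flags variants whose minor-allele frequency is strictly below the
#' threshold and strictly above zero. The threshold itself is excluded
#' (rare means MAF < threshold), and monomorphic sites never qualify.
#'
#' @param mafs numeric vector of minor-allele frequencies.
#' @param threshold rare-variant MAF threshold in `(0, 0.5]`; default 0.03.
#' @return Logical vector, `TRUE` where `0 < maf < threshold`.
#' @export
#' @examples
#' rare_mask(c(0.01, 0.03, 0.25), threshold = 0.03)
rare_mask <- function(mafs, threshold = 0.03) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 0.5) {
    stop("`threshold` must be a single frequency in (0, 0.5]", call. = FALSE)
  }
  mafs > 0 & mafs < threshold
}

#' Collapse rare variants into a per-individual burden
#'
#' The burden of individual `i` is the total minor-allele count over the
#' masked variants, `C_i = sum_j G_ij`.
#'
#' @param genotypes an [rv_genotypes] object or a count matrix.
#' @param mask logical vector selecting the variants to collapse; defaults to
#'   all variants (the matrix is assumed already rare-filtered).
#' @return Integer vector of length `n` of burden counts.
#' @export
#' @examples
#' g <- matrix(c(0, 2, 0, 1, 0, 0), nrow = 3)
#' collapse_burden(g, mask = c(TRUE, TRUE))
collapse_burden <- function(genotypes, mask = NULL) {
  counts <- if (inherits(genotypes, "rv_genotypes")) genotypes$counts else
    as.matrix(genotypes)
  if (is.null(mask)) mask <- rep(TRUE, ncol(counts))
  stopifnot(length(mask) == ncol(counts))
  if (!any(mask)) {
    stop("no variants selected by the rare-variant mask", call. = FALSE)
  }
  as.integer(rowSums(counts[, mask, drop = FALSE]))
}

#' Restrict a genotype matrix to its rare variants
#'
#' Convenience wrapper combining [rare_mask()] and column subsetting.
#'
#' @inheritParams collapse_burden
#' @inheritParams rare_mask
#' @return An [rv_genotypes] object holding only variants with
#'   `0 < MAF < threshold`.
#' @export
filter_rare <- function(genotypes, threshold = 0.03) {
  if (!inherits(genotypes, "rv_genotypes")) {
    genotypes <- rv_genotypes(genotypes)
  }
  keep <- rare_mask(genotypes$mafs, threshold)
  if (!any(keep)) {
    stop("no rare variants below the MAF threshold", call. = FALSE)
  }
  structure(
    list(
      counts = genotypes$counts[, keep, drop = FALSE],
      variant_ids = genotypes$variant_ids[keep],
      mafs = genotypes$mafs[keep]
    ),
    class = "rv_genotypes"
  )
}

#' Read a genotype matrix from a delimited text file
#'
#' Expects a whitespace- or tab-delimited integer matrix with one row per
#' individual and one column per variant, optionally preceded by a header row
#' of variant identifiers. Entries must be allele counts in `{0, 1, 2}`;
#' anything else is a parse error naming the offending position.
#'
#' @param path file path.
#' @param header does the first row hold variant identifiers? Default `TRUE`.
#' @return An [rv_genotypes] object (minor-allele oriented, monomorphic
#'   columns dropped).
#' @export
read_genotypes_tsv <- function(path, header = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read genotype file: %s", path), call. = FALSE)
  }
  raw <- read.table(path, header = header, colClasses = "character",
                    check.names = FALSE)
  mat <- suppressWarnings(apply(as.matrix(raw), c(1, 2), as.numeric))
  bad <- which(is.na(mat) | !(mat %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-genotype entry '%s' at row %d, column %d of %s",
      as.matrix(raw)[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L], path
    ), call. = FALSE)
  }
  ids <- if (header) colnames(raw) else NULL
  rv_genotypes(mat, variant_ids = ids)
}

#' Read a genotype matrix from a VCF file
#'
#' Parses GT fields of a VCF (v4.x) into alternate-allele dosages, then
#' recodes to minor-allele counts. Multiallelic sites are skipped with a
#' warning (the count model is biallelic); missing genotypes are imputed to
#' the reference (0) with a message; monomorphic columns are dropped.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return An [rv_genotypes] object with one row per sample.
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read VCF file: %s", path), call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) {
    stop("VCF contains no variant records", call. = FALSE)
  }
  alt <- vcf@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multiallelic site(s)", sum(multi)),
            call. = FALSE)
    vcf <- vcf[!multi, ]
  }
  if (nrow(vcf@fix) == 0L) {
    stop("no biallelic variants remain", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcf@fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(vcf@fix[noid, "CHROM"], ":", vcf@fix[noid, "POS"])
  # alleles separated by / or |; dosage = number of ALT alleles
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(strsplit(g, "[/|]")[[1L]] == "1")
  })
  n_missing <- sum(is.na(dose))
  if (n_missing > 0L) {
    message(sprintf("imputing %d missing genotype(s) to reference", n_missing))
    dose[is.na(dose)] <- 0L
  }
  rv_genotypes(t(dose), variant_ids = ids)
}

#' Phenotype vector
#'
#' A trait vector tagged by kind: `continuous` for randomly sampled
#' quantitative traits, `binary` for case/control labels arising from
#' extreme-phenotype sampling.
#'
#' @param values numeric vector of trait values (0/1 for binary).
#' @param kind `"continuous"` or `"binary"`; guessed from the values when
#'   omitted (0/1-only vectors are treated as binary).
#' @return An `rv_phenotype` object.
#' @export
rv_phenotype <- function(values, kind = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("phenotype contains missing values", call. = FALSE)
  if (is.null(kind)) {
    kind <- if (all(values %in% c(0, 1))) "binary" else "continuous"
  }
  kind <- match.arg(kind, c("continuous", "binary"))
  if (kind == "binary") {
    if (!all(values %in% c(0, 1))) {
      stop("binary phenotype values must be 0 or 1", call. = FALSE)
    }
    if (length(unique(values)) < 2L) {
      stop("binary phenotype must contain both cases and controls",
           call. = FALSE)
    }
  }
  structure(list(values = values, kind = kind), class = "rv_phenotype")
}

#' @export
print.rv_phenotype <- function(x, ...) {
  cat(sprintf("<rv_phenotype> %s, n = %d\n", x$kind, length(x$values)))
  invisible(x)
}

#' @export
length.rv_phenotype <- function(x) length(x$values)

#' Read a phenotype from a TSV file
#'
#' Expects columns `sample_id` and `value` (header required).
#'
#' @param path file path.
#' @param kind passed to [rv_phenotype()]; guessed when `NULL`.
#' @return An `rv_phenotype` object ordered as in the file.
#' @export
read_phenotype_tsv <- function(path, kind = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read phenotype file: %s", path), call. = FALSE)
  }
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!all(c("sample_id", "value") %in% names(tab))) {
    stop("phenotype file needs columns 'sample_id' and 'value'", call. = FALSE)
  }
  rv_phenotype(tab$value, kind = kind)
}

as_phenotype <- function(phenotype, kind = NULL) {
  if (inherits(phenotype, "rv_phenotype")) return(phenotype)
  rv_phenotype(phenotype, kind = kind)
}
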