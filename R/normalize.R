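# Library-size normalisation: CPM, the low-expression filter, and a full
# implementation of trimmed-mean-of-M-values (TMM) composition correction.

#' Counts per million
#'
#' @param counts gene-by-sample matrix
#' @param norm_factors optional per-sample normalization factors (e.g. from
#'   [tmm_factors()]); effective library size is `colSums(counts) * factor`
#' @return matrix of CPM values
#' @export
cpm <- function(counts, norm_factors = NULL) {
  lib <- colSums(counts)
  if (any(lib == 0)) abort("zero library size")
  if (!is.null(norm_factors)) lib <- lib * norm_factors
  sweep(counts, 2, lib, "/") * 1e6
}

#' Filter genes below 1 CPM in every replicate of a pairwise comparison
#'
#' A gene is retained iff its CPM reaches `min_cpm` in at least one of the
#' samples involved in the comparison; genes below threshold in all
#' replicates are discarded before DE testing.
#'
#' @param counts gene-by-sample count matrix
#' @param samples character vector of sample ids in the pairwise comparison
#'   (default: all columns)
#' @param min_cpm CPM threshold (default 1)
#' @return character vector of retained gene ids
#' @export
cpm_filter <- function(counts, samples = colnames(counts), min_cpm = 1) {
  sub <- counts[, samples, drop = FALSE]
  if (any(colSums(sub) == 0)) abort("zero library size in comparison samples")
  keep <- rowSums(cpm(sub) >= min_cpm) > 0
  rownames(sub)[keep]
}

#' Trimmed mean of M-values normalization factors
#'
#' Per-sample composition-correction factors computed as the published TMM
#' algorithm does: log2 expression ratios (M) against a reference sample are
#' trimmed 30% on each tail, absolute-expression values (A) 5% on each tail,
#' the surviving M-values averaged with inverse asymptotic-variance weights,
#' and the factors rescaled to geometric mean 1. The reference defaults to
#' the sample whose upper-quartile CPM is closest to the mean upper quartile.
#'
#' @param counts gene-by-sample count matrix (at least two samples)
#' @param reference_sample optional column name or index of the reference
#' @param trim_m,trim_a two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05)
#' @return named numeric vector of factors, geometric mean 1
#' @export
tmm_factors <- function(counts, reference_sample = NULL,
                        trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2L) abort("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) abort("all-zero sample")
  if (is.null(reference_sample)) {
    f75 <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(reference_sample)) {
    ref <- match(reference_sample, colnames(counts))
    if (is.na(ref)) abort("reference sample not found")
  } else ref <- as.integer(reference_sample)

  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# one observed-vs-reference TMM factor (log2 weighted trimmed mean of M)
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  ok <- obs > 0 & ref > 0
  M <- log2(p_obs[ok] / p_ref[ok])
  A <- 0.5 * log2(p_obs[ok] * p_ref[ok])
  w <- (n_obs - obs[ok]) / (n_obs * obs[ok]) + (n_ref - ref[ok]) / (n_ref * ref[ok])
  # degenerate pair (identical columns leave M all zero)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}
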