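#' Center a post-QC dosage matrix on observed allele frequencies
#'
#' Column j of the result is `dosage - 2 * p_j`, with `p_j` the observed
#' ALT-allele frequency, so every column sums to zero. This is the marker
#' matrix entering both the genomic relationship matrix and the marker-effect
#' samplers.
#'
#' @param geno Post-QC dosage matrix (no missing values). Imputed dosages in
#'   `[0, 2]` are accepted.
#' @param allele_freqs Optional fixed frequencies (e.g. training-set values) to
#'   center against instead of the observed ones.
#' @return List with `M` (centered matrix) and `allele_freqs`.
#' @export
center_markers <- function(geno, allele_freqs = NULL) {
  if (anyNA(geno)) stop("genotypes must be imputed before centering (run_qc)")
  if (is.null(allele_freqs)) allele_freqs <- colMeans(geno) / 2
  stopifnot(length(allele_freqs) == ncol(geno))
  M <- sweep(geno, 2, 2 * allele_freqs, "-")
  list(M = M, allele_freqs = allele_freqs)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `K = M M' / c` with `c = 2 * sum(p_j * (1 - p_j))`, the expected variance
#' of the centered genotypes under Hardy-Weinberg proportions. The mean
#' diagonal approaches 1 as the marker panel grows.
#'
#' @param M Centered marker matrix from [center_markers()].
#' @param allele_freqs Per-marker allele frequencies used for centering.
#' @param jitter Ridge added to the diagonal for factorization stability
#'   (default 1e-8); set 0 to disable.
#' @return List with `K` (n x n symmetric PSD), `allele_freqs`, and the
#'   `scaling_constant` c.
#' @export
compute_grm <- function(M, allele_freqs, jitter = 1e-8) {
  stopifnot(ncol(M) == length(allele_freqs))
  cc <- 2 * sum(allele_freqs * (1 - allele_freqs))
  if (cc <= 0) stop("degenerate marker panel: scaling constant is zero")
  K <- tcrossprod(M) / cc
  K <- (K + t(K)) / 2
  if (jitter > 0) K <- K + diag(jitter, nrow(K))
  dimnames(K) <- list(rownames(M), rownames(M))
  list(K = K, allele_freqs = allele_freqs, scaling_constant = cc)
}

#' Per-marker genotype variances
#'
#' Empirical variance of each dosage column with denominator n (the population
#' variance). These are the `var(SNP_i)` weights in the marker-effect genetic
#' covariance.
#'
#' @param geno Post-QC dosage matrix or centered marker matrix (no missing).
#' @return Named numeric vector.
#' @export
marker_variances <- function(geno) {
  if (anyNA(geno)) stop("genotypes must be complete")
  mu <- colMeans(geno)
  colMeans(geno^2) - mu^2
}

#' Export a relationship matrix as TSV
#' @param grm List from [compute_grm()].
#' @param path Output path.
#' @export
write_grm <- function(grm, path) {
  dt <- data.table::data.table(animal_id = rownames(grm$K))
  dt <- cbind(dt, data.table::as.data.table(grm$K))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
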