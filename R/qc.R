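#' Genotype quality control
#'
#' Standard pre-GBLUP filters: animals with a genotype missing rate above
#' `missing_threshold` are excluded, then markers whose minor allele frequency
#' is not strictly greater than `maf_threshold` are excluded (this also removes
#' monomorphic markers), then residual missing dosages are mean-imputed.
#' MAF is computed on non-missing dosages as `p = mean(dosage)/2`,
#' `MAF = min(p, 1 - p)`, on the animal set retained by the first filter.
#'
#' @param geno Animals x markers dosage matrix (`NA` = missing).
#' @param maf_threshold Markers are kept iff MAF > this value (default 0.05).
#' @param missing_threshold Animals are kept iff their missing rate is <= this
#'   value (default 0.10).
#' @return List with `geno` (filtered, imputed, no `NA`) and `report`
#'   (a `qc_report`).
#' @export
run_qc <- function(geno, maf_threshold = 0.05, missing_threshold = 0.10) {
  a <- filter_animals(geno, missing_threshold)
  m <- filter_markers(a$geno, maf_threshold)
  imputed <- impute_missing(m$geno)
  report <- structure(list(
    maf_threshold = maf_threshold,
    missing_threshold = missing_threshold,
    n_animals_in = nrow(geno), n_animals_out = nrow(imputed),
    n_markers_in = ncol(geno), n_markers_out = ncol(imputed),
    removed_animal_ids = a$report$removed_animal_ids,
    removed_marker_ids = m$report$removed_marker_ids
  ), class = "qc_report")
  stopifnot(report$n_animals_out == report$n_animals_in - length(report$removed_animal_ids),
            report$n_markers_out == report$n_markers_in - length(report$removed_marker_ids))
  list(geno = imputed, report = report)
}

#' @rdname run_qc
#' @export
filter_animals <- function(geno, missing_threshold = 0.10) {
  stopifnot(missing_threshold >= 0, missing_threshold <= 1)
  miss_rate <- rowMeans(is.na(geno))
  drop <- miss_rate > missing_threshold
  if (all(drop)) stop("all animals exceed the missing-rate threshold")
  report <- list(missing_threshold = missing_threshold,
                 n_animals_in = nrow(geno), n_animals_out = sum(!drop),
                 removed_animal_ids = rownames(geno)[drop])
  list(geno = geno[!drop, , drop = FALSE], report = report)
}

#' @rdname run_qc
#' @export
filter_markers <- function(geno, maf_threshold = 0.05) {
  stopifnot(maf_threshold >= 0, maf_threshold <= 0.5)
  maf <- marker_maf(geno)
  keep <- !is.na(maf) & maf > maf_threshold
  if (!any(keep)) stop("all markers fail the MAF threshold")
  report <- list(maf_threshold = maf_threshold,
                 n_markers_in = ncol(geno), n_markers_out = sum(keep),
                 removed_marker_ids = colnames(geno)[!keep])
  list(geno = geno[, keep, drop = FALSE], report = report)
}

#' Per-marker minor allele frequency on non-missing dosages
#' @param geno Dosage matrix.
#' @return Named vector of MAF (NA for fully-missing markers).
#' @export
marker_maf <- function(geno) {
  p <- colMeans(geno, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Mean-impute residual missing genotypes
#'
#' Replaces each missing cell by the marker's mean non-missing dosage (a real
#' number in `[0, 2]`), which preserves the observed allele frequency.
#'
#' @param geno Dosage matrix; every marker must have at least one non-missing
#'   value.
#' @return Matrix with no missing values.
#' @export
impute_missing <- function(geno) {
  if (!anyNA(geno)) return(geno)
  mu <- colMeans(geno, na.rm = TRUE)
  if (anyNA(mu)) {
    stop("fully-missing marker(s) cannot be imputed: ",
         paste(head(colnames(geno)[is.na(mu)], 5), collapse = ", "))
  }
  idx <- which(is.na(geno), arr.ind = TRUE)
  geno[idx] <- mu[idx[, 2]]
  geno
}

#' Serialize a QC report
#'
#' Writes the thresholds and counts as JSON and, optionally, the removed ids
#' as plain text (one per line).
#'
#' @param report A `qc_report` from [run_qc()].
#' @param path Output JSON path.
#' @param id_dir If non-NULL, directory for `removed_animals.txt` /
#'   `removed_markers.txt`.
#' @export
write_qc_report <- function(report, path, id_dir = NULL) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(id_dir)) {
    dir.create(id_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(report$removed_animal_ids, file.path(id_dir, "removed_animals.txt"))
    writeLines(report$removed_marker_ids, file.path(id_dir, "removed_markers.txt"))
  }
  invisible(path)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  animals: %d -> %d (missing rate > %.0f%% removed)\n",
              x$n_animals_in, x$n_animals_out, 100 * x$missing_threshold))
  cat(sprintf("  markers: %d -> %d (MAF <= %.0f%% removed)\n",
              x$n_markers_in, x$n_markers_out, 100 * x$maf_threshold))
  invisible(x)
}
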