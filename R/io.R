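#' Read a genotype dosage matrix
#'
#' Reads allele-dosage genotypes into an animals x markers numeric matrix with
#' entries in \{0, 1, 2, NA\}. Two formats are supported:
#' \describe{
#'   \item{`dosage_tsv`}{Tab-separated, first column header `animal_id`,
#'     remaining headers are marker ids, cells `0`/`1`/`2`/`NA` (an empty cell
#'     is tolerated as missing).}
#'   \item{`vcf`}{Standard VCF; the GT field of biallelic sites is converted to
#'     the ALT-allele count, ignoring phasing. Multi-allelic records are
#'     skipped with a warning giving their count.}
#' }
#'
#' @param path Path to the genotype file.
#' @param format `"dosage_tsv"` (default) or `"vcf"`.
#' @return Numeric matrix, rows named by animal id, columns by marker id;
#'   missing genotypes are `NA`.
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  geno <- switch(format,
    dosage_tsv = read_dosage_tsv(path),
    vcf = read_vcf_dosages(path)
  )
  validate_genotypes(geno)
  geno
}

read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (names(dt)[1] != "animal_id") {
    stop("dosage TSV must have 'animal_id' as its first column header, found '",
         names(dt)[1], "'")
  }
  ids <- dt[[1]]
  cells <- as.matrix(dt[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!is.na(cells) & (is.na(num) | !(num %in% c(0, 1, 2))),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("malformed dosage at line %d (animal '%s', marker '%s'): '%s'",
                 bad[1, 1] + 1L, ids[bad[1, 1]],
                 colnames(cells)[bad[1, 2]], cells[bad[1, 1], bad[1, 2]]))
  }
  dimnames(num) <- list(ids, colnames(cells))
  num
}

read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  # count ALT alleles; phased and unphased separators both accepted
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  })
  ids <- vcfR::getID(v)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids)) {
    ids <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  }
  rownames(dose) <- ids
  t(dose)  # animals x markers
}

#' Write a genotype dosage matrix as TSV
#'
#' Inverse of [read_genotypes()] for the `dosage_tsv` dialect; missing
#' genotypes are written as `NA`.
#'
#' @param geno Animals x markers dosage matrix with dimnames.
#' @param path Output path.
#' @export
write_genotypes <- function(geno, path) {
  validate_genotypes(geno)
  dt <- data.table::data.table(animal_id = rownames(geno))
  dt <- cbind(dt, data.table::as.data.table(geno))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

validate_genotypes <- function(geno) {
  if (!is.matrix(geno) || !is.numeric(geno)) stop("genotypes must be a numeric matrix")
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("genotype matrix must carry animal ids (rownames) and marker ids (colnames)")
  }
  if (anyDuplicated(rownames(geno))) stop("duplicate animal ids in genotype matrix")
  if (anyDuplicated(colnames(geno))) stop("duplicate marker ids in genotype matrix")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("non-missing dosages must be exactly 0, 1 or 2")
  }
  invisible(geno)
}

PHENO_COLS <- c("animal_id", "MY", "MF", "MP", "ML", "MDM",
                "lactation_order", "farm", "dim")

#' Read a phenotype table
#'
#' CSV with header `animal_id,MY,MF,MP,ML,MDM,lactation_order,farm,dim`:
#' 305-day milk yield (kg), milk fat/protein/lactose/dry-matter percentages,
#' lactation order (level 1-3), farm (level 1-12), and days in milk.
#' Empty or unparseable trait cells become `NA`.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with one row per animal.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, na.strings = c("NA", ""))
  missing_cols <- setdiff(PHENO_COLS, names(dt))
  if (length(missing_cols)) {
    stop("phenotype CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ph <- as.data.frame(dt[, PHENO_COLS, with = FALSE])
  ph$animal_id <- as.character(ph$animal_id)
  if (anyDuplicated(ph$animal_id)) {
    dup <- unique(ph$animal_id[duplicated(ph$animal_id)])
    stop("duplicate animal_id in phenotype table: ", paste(head(dup, 5), collapse = ", "))
  }
  for (tr in DEFAULT_TRAITS) ph[[tr]] <- suppressWarnings(as.numeric(ph[[tr]]))
  ph$lactation_order <- as.integer(ph$lactation_order)
  ph$farm <- as.integer(ph$farm)
  ph$dim <- as.numeric(ph$dim)
  validate_phenotypes(ph)
  ph
}

#' @rdname read_phenotypes
#' @param pheno Phenotype `data.frame` to write.
#' @export
write_phenotypes <- function(pheno, path) {
  validate_phenotypes(pheno)
  data.table::fwrite(pheno[, PHENO_COLS], path, sep = ",", na = "NA", quote = FALSE)
  invisible(path)
}

validate_phenotypes <- function(pheno) {
  stopifnot(is.data.frame(pheno), all(PHENO_COLS %in% names(pheno)))
  if (anyDuplicated(pheno$animal_id)) stop("duplicate animal_id in phenotype table")
  for (tr in DEFAULT_TRAITS) {
    v <- pheno[[tr]]
    if (any(!is.na(v) & !is.finite(v))) stop("non-finite value in trait ", tr)
  }
  ok_lact <- is.na(pheno$lactation_order) | pheno$lactation_order %in% 1:3
  if (!all(ok_lact)) stop("lactation_order outside declared levels {1,2,3}")
  ok_farm <- is.na(pheno$farm) | pheno$farm %in% 1:12
  if (!all(ok_farm)) stop("farm outside declared levels {1..12}")
  if (any(!is.na(pheno$dim) & pheno$dim < 0)) stop("dim must be non-negative")
  invisible(pheno)
}

#' Align genotypes and phenotypes on shared animals
#'
#' Restricts both inputs to the intersection of animal ids, ordered as in the
#' genotype matrix, and reports how many records were dropped from each side.
#'
#' @param geno Dosage matrix from [read_genotypes()].
#' @param pheno Phenotype table from [read_phenotypes()].
#' @return List with elements `geno`, `pheno` (aligned), and `dropped`
#'   (named counts).
#' @export
align_animals <- function(geno, pheno) {
  shared <- intersect(rownames(geno), pheno$animal_id)
  if (length(shared) == 0) stop("no animals shared between genotypes and phenotypes")
  keep <- rownames(geno)[rownames(geno) %in% shared]
  dropped <- c(genotypes = nrow(geno) - length(keep),
               phenotypes = nrow(pheno) - length(keep))
  if (any(dropped > 0)) {
    message("align_animals: dropped ", dropped[["genotypes"]],
            " genotype and ", dropped[["phenotypes"]], " phenotype record(s)")
  }
  pheno_aligned <- pheno[match(keep, pheno$animal_id), , drop = FALSE]
  rownames(pheno_aligned) <- NULL
  list(geno = geno[keep, , drop = FALSE], pheno = pheno_aligned, dropped = dropped)
}

#' Save or load posterior draws
#'
#' Round-trip container for a fitted model's retained MCMC draws, including all
#' chain metadata (iterations, burn-in, thinning, seed, model tag).
#'
#' @param draws A `posterior_draws` object from [fit_st()] or [fit_mt()].
#' @param path File path (conventionally `.rds`).
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  saveRDS(draws, path)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  if (!file.exists(path)) stop("draws container not found: ", path)
  draws <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt draws container at ", path, ": ", conditionMessage(e))
  })
  if (!inherits(draws, "posterior_draws")) {
    stop("file does not contain posterior draws: ", path)
  }
  draws
}
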