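#' Random train/test split of animals
#'
#' Uniform split without replacement (a single random hold-out, the standard
#' validation design for this pipeline: e.g. 400 training and 97 test animals
#' out of 497).
#'
#' @param animal_ids Character vector of ids.
#' @param n_train Number of training animals (`< length(animal_ids)`).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `train` and `test` id vectors (original order preserved
#'   within each).
#' @export
split_train_test <- function(animal_ids, n_train, seed = NULL) {
  n <- length(animal_ids)
  if (n_train >= n) stop("n_train must be smaller than the number of animals")
  if (n_train < 1) stop("n_train must be positive")
  if (!is.null(seed)) set.seed(seed)
  train_idx <- sort(sample.int(n, n_train))
  list(train = animal_ids[train_idx], test = animal_ids[-train_idx])
}

#' Prediction accuracy
#'
#' Pearson correlation between observed phenotypes and GEBVs in the
#' validation set. Undefined (NA, with a warning) when either vector has zero
#' variance.
#'
#' @param y_obs Observed phenotypes of the test animals.
#' @param gebv_hat Predicted GEBVs, same animals and order.
#' @return Correlation `r`.
#' @export
accuracy <- function(y_obs, gebv_hat) {
  ok <- !is.na(y_obs) & !is.na(gebv_hat)
  if (sum(ok) < 3) stop("need at least 3 test animals with observed phenotype")
  if (stats::sd(y_obs[ok]) == 0 || stats::sd(gebv_hat[ok]) == 0) {
    warning("zero variance: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(y_obs[ok], gebv_hat[ok])
}

#' Dispersion bias
#'
#' Slope of the ordinary least-squares regression of observed phenotype on
#' GEBV in the validation set. A slope greater than one means the GEBVs are
#' under-dispersed relative to the phenotypes (underestimation).
#'
#' @inheritParams accuracy
#' @return Regression slope `b`.
#' @export
bias <- function(y_obs, gebv_hat) {
  ok <- !is.na(y_obs) & !is.na(gebv_hat)
  if (sum(ok) < 3) stop("need at least 3 test animals with observed phenotype")
  vg <- stats::var(gebv_hat[ok])
  if (vg == 0) {
    warning("zero GEBV variance: bias undefined")
    return(NA_real_)
  }
  stats::cov(y_obs[ok], gebv_hat[ok]) / vg
}

#' Spearman rank correlations of marker-effect magnitudes
#'
#' For every trait pair, the Spearman correlation between per-marker effect
#' magnitudes — by default the squared posterior-mean effect, the scale on
#' which marker effects are usually displayed. Ties get average ranks;
#' two-sided p-values use the t approximation.
#'
#' @param effects markers x traits matrix of posterior-mean effects.
#' @param magnitude `"squared"` (default), `"absolute"` or `"raw"`.
#' @return List with `rho` and `p_value` (t x t matrices).
#' @export
marker_rank_correlations <- function(effects,
                                     magnitude = c("squared", "absolute", "raw")) {
  magnitude <- match.arg(magnitude)
  effects <- as.matrix(effects)
  if (nrow(effects) < 3) stop("need at least 3 markers")
  mag <- switch(magnitude, squared = effects^2, absolute = abs(effects),
                raw = effects)
  t_ <- ncol(mag)
  traits <- colnames(mag)
  rho <- p_val <- matrix(NA_real_, t_, t_, dimnames = list(traits, traits))
  diag(rho) <- 1
  diag(p_val) <- 0
  n <- nrow(mag)
  ranks <- apply(mag, 2, rank)  # average ranks on ties
  for (i in seq_len(t_ - 1)) {
    for (j in seq(i + 1, t_)) {
      r <- stats::cor(ranks[, i], ranks[, j])
      tt <- r * sqrt((n - 2) / (1 - r^2))
      rho[i, j] <- rho[j, i] <- r
      p_val[i, j] <- p_val[j, i] <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  list(rho = rho, p_value = p_val, magnitude = magnitude)
}

#' Run the full validation protocol
#'
#' End-to-end orchestration: genotype QC, marker centering, a seeded
#' train/test split, single-trait fits per trait and one joint multi-trait
#' fit on the training animals, GEBV prediction for the hold-out animals, and
#' the summary quantities — accuracy `r` and bias `b` per trait and method,
#' the MT-ST accuracy difference, marker-effect rank correlations, and
#' posterior genetic parameters from the multi-trait fit.
#'
#' @param geno Dosage matrix (QC is applied internally; already-clean input
#'   passes through unchanged).
#' @param pheno Phenotype table.
#' @param chain A [chain_config()] (its `seed` drives every stochastic stage).
#' @param traits Ordered trait names.
#' @param n_train Training-set size.
#' @param maf_threshold,missing_threshold QC thresholds.
#' @param magnitude Magnitude scale for rank correlations.
#' @param adjusted If TRUE, accuracies/biases use test phenotypes adjusted for
#'   the fixed effects (residuals of an OLS fit on lactation order and farm);
#'   default uses raw phenotypes.
#' @param include_dim_in_h2 Heritability denominator includes the DIM
#'   variance.
#' @param fit_single_trait If FALSE, skip the per-trait ST fits (multi-trait
#'   results only).
#' @return A `validation_run` list: `results` (trait x method table with
#'   `r`, `b`, `accuracy_diff`), `rank_corr`, `params`, `split`, `qc_report`,
#'   and the fitted draws.
#' @export
run_validation <- function(geno, pheno, chain = chain_config(),
                           traits = DEFAULT_TRAITS, n_train = 400,
                           maf_threshold = 0.05, missing_threshold = 0.10,
                           magnitude = "squared", adjusted = FALSE,
                           include_dim_in_h2 = TRUE,
                           fit_single_trait = TRUE) {
  al <- align_animals(geno, pheno)
  qc <- run_qc(al$geno, maf_threshold, missing_threshold)
  pheno_qc <- al$pheno[al$pheno$animal_id %in% rownames(qc$geno), , drop = FALSE]

  seed <- chain$seed
  if (!is.null(seed)) set.seed(seed)
  # independent sub-seeds per stochastic stage, derived from the master seed
  sub_seed <- function() if (is.null(seed)) NULL else sample.int(2^31 - 2, 1)
  split_seed <- sub_seed()
  st_seeds <- lapply(traits, function(.) sub_seed())
  names(st_seeds) <- traits
  mt_seed <- sub_seed()

  split <- split_train_test(rownames(qc$geno), n_train, seed = split_seed)

  # center on training-set allele frequencies; the shift is constant per
  # marker so test-set accuracy and bias are unaffected by this choice
  p_train <- colMeans(qc$geno[split$train, , drop = FALSE]) / 2
  cm <- center_markers(qc$geno, allele_freqs = p_train)
  M <- cm$M
  snp_vars <- marker_variances(qc$geno[split$train, , drop = FALSE])

  mt_chain <- chain
  mt_chain$seed <- mt_seed
  mt_frame <- build_mt_model_frame(pheno_qc, M, split$train, traits)
  mt_draws <- fit_mt(mt_frame, mt_chain)
  mt_gebv <- gebv_mt(mt_draws, M[split$test, , drop = FALSE])

  st_draws <- list()
  st_gebv <- matrix(NA_real_, length(split$test), length(traits),
                    dimnames = list(split$test, traits))
  if (fit_single_trait) {
    for (tr in traits) {
      st_chain <- chain
      st_chain$seed <- st_seeds[[tr]]
      frame <- build_model_frame(pheno_qc, tr, M, split$train)
      st_draws[[tr]] <- fit_st(frame, st_chain)
      st_gebv[, tr] <- gebv(st_draws[[tr]], M[split$test, , drop = FALSE])
    }
  }

  ph_test <- pheno_qc[match(split$test, pheno_qc$animal_id), , drop = FALSE]
  y_test <- as.matrix(ph_test[, traits, drop = FALSE])
  if (adjusted) y_test <- adjust_phenotypes(ph_test, traits)

  rows <- list()
  for (tr in traits) {
    r_mt <- accuracy(y_test[, tr], mt_gebv[, tr])
    b_mt <- bias(y_test[, tr], mt_gebv[, tr])
    r_st <- b_st <- NA_real_
    if (fit_single_trait) {
      r_st <- accuracy(y_test[, tr], st_gebv[, tr])
      b_st <- bias(y_test[, tr], st_gebv[, tr])
    }
    rows[[tr]] <- data.frame(trait = tr, r_mt = r_mt, b_mt = b_mt,
                             r_st = r_st, b_st = b_st,
                             accuracy_diff = r_mt - r_st)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  rank_corr <- marker_rank_correlations(posterior_mean_effects(mt_draws),
                                        magnitude = magnitude)
  params <- genetic_params(mt_draws, snp_vars, pheno = pheno_qc,
                           include_dim = include_dim_in_h2)

  structure(list(results = results, rank_corr = rank_corr, params = params,
                 split = c(split, list(seed = split_seed)),
                 qc_report = qc$report,
                 mt_draws = mt_draws, st_draws = st_draws,
                 mt_gebv = mt_gebv,
                 st_gebv = if (fit_single_trait) st_gebv else NULL,
                 traits = traits, adjusted = adjusted),
            class = "validation_run")
}

# Residuals of each trait on the fixed effects (intercept + lactation order +
# farm), used for the covariate-adjusted accuracy option.
adjust_phenotypes <- function(ph, traits) {
  X <- fixed_incidence(ph)
  out <- sapply(traits, function(tr) {
    y <- ph[[tr]]
    ok <- !is.na(y)
    res <- rep(NA_real_, length(y))
    res[ok] <- stats::lsfit(X[ok, -1, drop = FALSE], y[ok])$residuals
    res
  })
  rownames(out) <- ph$animal_id
  out
}

#' @export
print.validation_run <- function(x, ...) {
  cat("Hold-out validation (", length(x$split$train), "train /",
      length(x$split$test), "test )\n")
  print(transform(x$results,
                  r_mt = round(r_mt, 3), b_mt = round(b_mt, 3),
                  r_st = round(r_st, 3), b_st = round(b_st, 3),
                  accuracy_diff = round(accuracy_diff, 3)))
  invisible(x)
}

#' Write validation results as CSVs
#'
#' `path` receives the trait x method accuracy/bias table (with the MT-ST
#' accuracy-difference column); `rank_path`, if given, the trait x trait
#' marker-effect rank-correlation matrix.
#'
#' @param run A `validation_run`.
#' @param path Accuracy/bias CSV path.
#' @param rank_path Optional rank-correlation CSV path.
#' @export
write_validation_csv <- function(run, path, rank_path = NULL) {
  utils::write.csv(run$results, path, row.names = FALSE)
  if (!is.null(rank_path)) {
    df <- data.frame(trait = rownames(run$rank_corr$rho), run$rank_corr$rho,
                     check.names = FALSE)
    utils::write.csv(df, rank_path, row.names = FALSE)
  }
  invisible(path)
}

#' Export per-trait marker-effect magnitudes as TSV
#'
#' One row per marker with the chosen magnitude per trait — the flat-file
#' behind per-trait squared-effect plots.
#'
#' @param effects markers x traits posterior-mean effects.
#' @param path Output TSV path.
#' @param magnitude As in [marker_rank_correlations()].
#' @export
write_marker_effects <- function(effects, path, magnitude = "squared") {
  mag <- switch(match.arg(magnitude, c("squared", "absolute", "raw")),
                squared = effects^2, absolute = abs(effects), raw = effects)
  dt <- data.table::data.table(marker_id = rownames(effects))
  dt <- cbind(dt, data.table::as.data.table(mag))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
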