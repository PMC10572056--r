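#' Genetic covariance from one draw of marker effects
#'
#' For a markers x traits effect matrix `alpha_k` at one MCMC iteration and
#' per-marker genotype variances `var(SNP_i)`, the genetic covariance term is
#' `sum_i var(SNP_i) * a_i a_i'` — symmetric positive semidefinite by
#' construction.
#'
#' @param alpha_k markers x traits matrix of effects at one iteration.
#' @param snp_vars Per-marker genotype variances (non-negative).
#' @return traits x traits matrix.
#' @export
genetic_covariance_draw <- function(alpha_k, snp_vars) {
  alpha_k <- as.matrix(alpha_k)
  stopifnot(nrow(alpha_k) == length(snp_vars), all(snp_vars >= 0))
  crossprod(alpha_k, alpha_k * snp_vars)
}

#' Posterior genetic covariance from retained draws
#'
#' Applies [genetic_covariance_draw()] to every retained draw and averages;
#' the per-draw series is returned for downstream standard errors and
#' correlations.
#'
#' @param draws A `posterior_draws` object.
#' @param snp_vars Per-marker genotype variances, aligned to the fitted panel.
#' @return List with `mean` (t x t) and `series` (t x t x draws array).
#' @export
genetic_covariance <- function(draws, snp_vars) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$n_draws == 0) stop("no retained draws")
  stopifnot(length(snp_vars) == length(draws$marker_ids))
  t_ <- length(draws$traits)
  series <- array(NA_real_, dim = c(t_, t_, draws$n_draws),
                  dimnames = list(draws$traits, draws$traits, NULL))
  for (k in seq_len(draws$n_draws)) {
    series[, , k] <- genetic_covariance_draw(
      matrix(draws$alpha[k, , ], ncol = t_), snp_vars)
  }
  list(mean = apply(series, c(1, 2), mean), series = series)
}

#' Posterior genetic correlations
#'
#' Per draw, `corr(t1, t2) = sigma_g[t1,t2] / sqrt(sigma_g[t1,t1] *
#' sigma_g[t2,t2])`; the posterior mean over retained draws is reported.
#' Draws with a non-positive diagonal are skipped and counted.
#'
#' @param sigma_g_series t x t x draws array from [genetic_covariance()].
#' @return List with `mean` (t x t correlation matrix), `series`, and
#'   `n_skipped`.
#' @export
genetic_correlation <- function(sigma_g_series) {
  t_ <- dim(sigma_g_series)[1]
  nd <- dim(sigma_g_series)[3]
  keep <- logical(nd)
  corr <- array(NA_real_, dim = dim(sigma_g_series),
                dimnames = dimnames(sigma_g_series))
  for (k in seq_len(nd)) {
    S <- sigma_g_series[, , k]
    if (any(diag(S) <= 0)) next
    keep[k] <- TRUE
    corr[, , k] <- stats::cov2cor(S)
  }
  if (!any(keep)) stop("every draw had a non-positive genetic variance")
  m <- apply(corr[, , keep, drop = FALSE], c(1, 2), mean)
  diag(m) <- 1
  list(mean = m, series = corr, n_skipped = sum(!keep))
}

#' Posterior heritabilities with standard errors
#'
#' Per draw and trait, `h2 = sigma_g / (sigma_g + sigma_dim + sigma_e)`: the
#' genetic variance from the marker-effect formula over the total of genetic,
#' days-in-milk and residual variance. The point estimate is the posterior
#' mean and the standard error the posterior standard deviation across
#' retained draws. Set `include_dim = FALSE` to drop the DIM variance from
#' the denominator.
#'
#' @param draws A `posterior_draws` object.
#' @param sigma_g_series t x t x draws array from [genetic_covariance()].
#' @param include_dim Include the DIM variance in the phenotypic total.
#' @return List with `h2`, `h2_se` (named per trait) and the per-draw `series`
#'   (draws x traits).
#' @export
heritability <- function(draws, sigma_g_series, include_dim = TRUE) {
  stopifnot(inherits(draws, "posterior_draws"))
  t_ <- length(draws$traits)
  nd <- draws$n_draws
  stopifnot(dim(sigma_g_series)[3] == nd)
  series <- matrix(NA_real_, nd, t_, dimnames = list(NULL, draws$traits))
  for (k in seq_len(nd)) {
    sg <- diag(matrix(sigma_g_series[, , k], t_, t_))
    sdim <- if (include_dim) draws$sigma2_d[k, ] else rep(0, t_)
    se <- diag(matrix(draws$R[, , k], t_, t_))
    series[k, ] <- sg / (sg + sdim + se)
  }
  list(h2 = colMeans(series), h2_se = apply(series, 2, stats::sd),
       series = series)
}

#' Phenotypic Pearson correlations with p-values
#'
#' Pairwise-complete Pearson correlations of the raw trait values, with
#' two-sided p-values from the usual t transform. Pairs with fewer than 3
#' complete observations are left undefined.
#'
#' @param pheno Phenotype table.
#' @param traits Trait columns to correlate.
#' @return List with `corr` and `p_value` matrices.
#' @export
phenotypic_correlation <- function(pheno, traits = DEFAULT_TRAITS) {
  t_ <- length(traits)
  corr <- p_val <- matrix(NA_real_, t_, t_, dimnames = list(traits, traits))
  diag(corr) <- 1
  diag(p_val) <- 0
  for (i in seq_len(t_ - 1)) {
    for (j in seq(i + 1, t_)) {
      x <- pheno[[traits[i]]]; y <- pheno[[traits[j]]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) next
      r <- stats::cor(x[ok], y[ok])
      n <- sum(ok)
      tt <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      corr[i, j] <- corr[j, i] <- r
      p_val[i, j] <- p_val[j, i] <- p
    }
  }
  list(corr = corr, p_value = p_val)
}

#' Posterior genetic-parameter summary
#'
#' Convenience wrapper assembling, from a multi-trait (or single-trait) fit:
#' heritabilities with standard errors, the posterior genetic correlation
#' matrix, and (when a phenotype table is supplied) phenotypic correlations.
#'
#' @param draws A `posterior_draws` object.
#' @param snp_vars Per-marker genotype variances of the training panel.
#' @param pheno Optional phenotype table for phenotypic correlations.
#' @param include_dim Passed to [heritability()].
#' @return A `genetic_params` list.
#' @export
genetic_params <- function(draws, snp_vars, pheno = NULL, include_dim = TRUE) {
  gc <- genetic_covariance(draws, snp_vars)
  h2 <- heritability(draws, gc$series, include_dim = include_dim)
  out <- list(h2 = h2$h2, h2_se = h2$h2_se, sigma_g_mean = gc$mean,
              sigma_g_series = gc$series, h2_series = h2$series,
              traits = draws$traits)
  if (length(draws$traits) > 1) {
    gcorr <- genetic_correlation(gc$series)
    out$genetic_corr <- gcorr$mean
    out$genetic_corr_series <- gcorr$series
  } else {
    out$genetic_corr <- matrix(1, 1, 1, dimnames = list(draws$traits, draws$traits))
  }
  if (!is.null(pheno)) {
    pc <- phenotypic_correlation(pheno, draws$traits)
    out$phenotypic_corr <- pc$corr
    out$phenotypic_p <- pc$p_value
  }
  structure(out, class = "genetic_params")
}

#' @export
print.genetic_params <- function(x, ...) {
  cat("Posterior genetic parameters\n  h2 (SE):\n")
  for (tr in x$traits) {
    cat(sprintf("    %-4s %.4f (%.4f)\n", tr, x$h2[[tr]], x$h2_se[[tr]]))
  }
  if (length(x$traits) > 1) {
    cat("  genetic correlations:\n")
    print(round(x$genetic_corr, 3))
  }
  invisible(x)
}

#' Write genetic parameters as a combined-triangle CSV
#'
#' One t x t table: genetic correlations below the diagonal, phenotypic
#' correlations above it, and `h2 +/- SE` on the diagonal. A tidy long-format
#' CSV is written alongside when `tidy_path` is given.
#'
#' @param params A `genetic_params` object (with phenotypic correlations).
#' @param path Output CSV path.
#' @param tidy_path Optional long-format CSV path.
#' @export
write_genetic_params_csv <- function(params, path, tidy_path = NULL) {
  traits <- params$traits
  t_ <- length(traits)
  tab <- matrix("", t_, t_, dimnames = list(traits, traits))
  for (i in seq_len(t_)) {
    tab[i, i] <- sprintf("%.4f +/- %.4f", params$h2[[i]], params$h2_se[[i]])
    for (j in seq_len(t_)) {
      if (j > i && !is.null(params$phenotypic_corr)) {
        tab[i, j] <- sprintf("%.3f", params$phenotypic_corr[i, j])
      } else if (j < i) {
        tab[i, j] <- sprintf("%.3f", params$genetic_corr[i, j])
      }
    }
  }
  df <- data.frame(trait = traits, tab, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(tidy_path)) {
    rows <- list()
    for (i in seq_len(t_)) {
      rows[[length(rows) + 1]] <- data.frame(
        trait1 = traits[i], trait2 = traits[i], quantity = "h2",
        value = params$h2[[i]], se = params$h2_se[[i]])
      for (j in seq_len(t_)) {
        if (j >= i) next
        rows[[length(rows) + 1]] <- data.frame(
          trait1 = traits[i], trait2 = traits[j], quantity = "genetic_corr",
          value = params$genetic_corr[i, j], se = NA_real_)
        if (!is.null(params$phenotypic_corr)) {
          rows[[length(rows) + 1]] <- data.frame(
            trait1 = traits[i], trait2 = traits[j], quantity = "phenotypic_corr",
            value = params$phenotypic_corr[i, j], se = NA_real_)
        }
      }
    }
    utils::write.csv(do.call(rbind, rows), tidy_path, row.names = FALSE)
  }
  invisible(path)
}
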