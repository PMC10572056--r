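#' Fit the single-trait marker-effect model by Gibbs sampling
#'
#' Bayesian ridge regression (SNP-BLUP): `y = Xb + Wd + M alpha + e` with
#' `alpha_j ~ N(0, sigma2_alpha)` iid, `d_l ~ N(0, sigma2_d)` iid and
#' `e ~ N(0, sigma2_e I)`; `b` carries a flat prior. The induced genetic
#' values `g = M alpha` have covariance proportional to the genomic
#' relationship matrix, so this is the marker-effect parameterization of
#' GBLUP. Variance components get scaled-inverse-chi-square priors whose mode
#' splits `var(y)` according to `config$var_split`.
#'
#' Each Gibbs iteration samples, in order: the fixed effects jointly from
#' their multivariate-normal full conditional; each DIM class effect; each
#' marker effect (single-site updates); then the three variance components
#' from their scaled-inverse-chi-square full conditionals.
#'
#' @param frame A `model_frame` from [build_model_frame()].
#' @param config A [chain_config()].
#' @return A `posterior_draws` object; marker-effect draws are stored as a
#'   `draws x markers x traits` array (here with one trait).
#' @export
fit_st <- function(frame, config = chain_config()) {
  stopifnot(inherits(frame, "model_frame"), inherits(config, "chain_config"))
  y <- frame$y
  vy <- stats::var(y)
  has_dim <- !is.null(frame$W) && ncol(frame$W) > 0
  W <- if (has_dim) frame$W else matrix(0, length(y), 0)
  sumV <- sum(marker_variances(frame$M))

  split <- config$var_split
  # scaled-inv-chi2 mode = nu*S/(nu+2)  =>  S = mode*(nu+2)/nu
  mode_a <- split[["genetic"]] * vy / sumV
  mode_d <- split[["dim"]] * vy
  mode_e <- split[["residual"]] * vy
  S_a <- mode_a * (config$nu_a + 2) / config$nu_a
  S_d <- mode_d * (config$nu_d + 2) / config$nu_d
  S_e <- mode_e * (config$nu_e + 2) / config$nu_e

  init <- config$init
  sigma2_a <- init$sigma2_a %||% mode_a
  sigma2_d <- init$sigma2_d %||% mode_d
  sigma2_e <- init$sigma2_e %||% mode_e

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- gibbs_st_cpp(y, frame$X, W, frame$M,
                      config$n_iter, config$burn_in, config$thin,
                      config$nu_a, config$nu_d, config$nu_e,
                      S_a, S_d, S_e, sigma2_a, sigma2_d, sigma2_e,
                      config$fix_variances)
  n_keep <- res$n_kept
  p <- ncol(frame$M)
  alpha <- array(res$alpha, dim = c(n_keep, p, 1),
                 dimnames = list(NULL, frame$marker_ids, frame$trait))
  Sigma_a <- array(res$sigma2_a, dim = c(1, 1, n_keep),
                   dimnames = list(frame$trait, frame$trait, NULL))
  R <- array(res$sigma2_e, dim = c(1, 1, n_keep),
             dimnames = list(frame$trait, frame$trait, NULL))
  new_posterior_draws(model_tag = "ST", traits = frame$trait, alpha = alpha,
                      b = res$b, d = if (has_dim) res$d else NULL,
                      Sigma_a = Sigma_a, R = R,
                      sigma2_d = matrix(if (has_dim) res$sigma2_d else 0,
                                        n_keep, 1,
                                        dimnames = list(NULL, frame$trait)),
                      config = config, marker_ids = frame$marker_ids,
                      animal_ids = frame$animal_ids)
}

#' Fit the multi-trait marker-effect model by Gibbs sampling
#'
#' Joint model over `t` traits: each marker carries a `t`-vector of effects
#' `a_i ~ N(0, Sigma_alpha)` with unstructured covariance, residual rows are
#' `N(0, R)` with unstructured `R`, and the DIM random effect is iid per trait
#' with diagonal covariance across traits. The induced genetic values have the
#' Kronecker covariance `Sigma (x) K` of multi-trait GBLUP. `Sigma_alpha` and
#' `R` get inverse-Wishart priors (default degrees of freedom `t + 3`) whose
#' mode splits the per-trait phenotypic variances via `config$var_split` with
#' diagonal scale matrices.
#'
#' @param frame An `mt_model_frame` from [build_mt_model_frame()].
#' @param config A [chain_config()].
#' @return A `posterior_draws` object with `model_tag = "MT"`.
#' @export
fit_mt <- function(frame, config = chain_config()) {
  stopifnot(inherits(frame, "mt_model_frame"), inherits(config, "chain_config"))
  Y <- frame$Y
  t_ <- ncol(Y)
  vy <- apply(Y, 2, stats::var)
  has_dim <- !is.null(frame$W) && ncol(frame$W) > 0
  W <- if (has_dim) frame$W else matrix(0, nrow(Y), 0)
  sumV <- sum(marker_variances(frame$M))

  split <- config$var_split
  nu_a <- max(config$nu_a, t_ + 3)
  nu_e <- max(config$nu_e, t_ + 3)
  # inverse-Wishart mode = S/(nu+t+1)  =>  S = mode*(nu+t+1)
  mode_a <- diag(split[["genetic"]] * vy / sumV, t_)
  mode_e <- diag(split[["residual"]] * vy, t_)
  S_a <- mode_a * (nu_a + t_ + 1)
  S_e <- mode_e * (nu_e + t_ + 1)
  mode_d <- split[["dim"]] * vy
  S_d <- mode_d * (config$nu_d + 2) / config$nu_d

  init <- config$init
  Sigma_a0 <- init$Sigma_a %||% mode_a
  R0 <- init$R %||% mode_e
  sigma2_d0 <- init$sigma2_d %||% mode_d

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- gibbs_mt_cpp(Y, frame$X, W, frame$M,
                      config$n_iter, config$burn_in, config$thin,
                      nu_a, config$nu_d, nu_e,
                      S_a, S_d, S_e, Sigma_a0, sigma2_d0, R0,
                      config$fix_variances)
  n_keep <- res$n_kept
  alpha <- aperm(res$alpha, c(3, 1, 2))  # draws x markers x traits
  dimnames(alpha) <- list(NULL, frame$marker_ids, frame$traits)
  Sigma_a <- res$Sigma_a
  R <- res$R
  dimnames(Sigma_a) <- dimnames(R) <- list(frame$traits, frame$traits, NULL)
  new_posterior_draws(model_tag = "MT", traits = frame$traits, alpha = alpha,
                      b = res$b, d = if (has_dim) res$d else NULL,
                      Sigma_a = Sigma_a, R = R,
                      sigma2_d = {
                        sd2 <- if (has_dim) res$sigma2_d else matrix(0, n_keep, t_)
                        dimnames(sd2) <- list(NULL, frame$traits); sd2
                      },
                      config = config, marker_ids = frame$marker_ids,
                      animal_ids = frame$animal_ids)
}

new_posterior_draws <- function(model_tag, traits, alpha, b, d, Sigma_a, R,
                                sigma2_d, config, marker_ids, animal_ids) {
  n_keep <- dim(alpha)[1]
  expected <- (config$n_iter - config$burn_in) %/% config$thin
  stopifnot(n_keep == expected)
  structure(list(model_tag = model_tag, traits = traits, alpha = alpha,
                 b = b, d = d, Sigma_a = Sigma_a, R = R, sigma2_d = sigma2_d,
                 config = config, marker_ids = marker_ids,
                 animal_ids = animal_ids, n_draws = n_keep),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("%s marker-effect model: %d trait(s), %d markers, %d retained draws\n",
              x$model_tag, length(x$traits), length(x$marker_ids), x$n_draws))
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  cat(sprintf("  chain: %d iterations, %d burn-in, thin %d\n",
              x$config$n_iter, x$config$burn_in, x$config$thin))
  invisible(x)
}

#' Posterior-mean marker effects
#' @param draws A `posterior_draws` object.
#' @return markers x traits matrix.
#' @export
posterior_mean_effects <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  eff <- apply(draws$alpha, c(2, 3), mean)
  dimnames(eff) <- list(draws$marker_ids, draws$traits)
  eff
}

#' Genomic estimated breeding values
#'
#' `GEBV = M %*% posterior-mean effects`; computable for any animals whose
#' centered marker rows match the fitted marker panel, in particular the
#' hold-out validation set.
#'
#' @param draws A `posterior_draws` object.
#' @param M_new Centered marker matrix (any animals x same markers, same
#'   order).
#' @return animals x traits matrix of GEBVs (a plain vector for single-trait
#'   fits via [gebv()]).
#' @export
gebv_mt <- function(draws, M_new) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (ncol(M_new) != length(draws$marker_ids) ||
      !identical(colnames(M_new), draws$marker_ids)) {
    stop("marker columns of M_new do not match the fitted marker panel")
  }
  M_new %*% posterior_mean_effects(draws)
}

#' @rdname gebv_mt
#' @export
gebv <- function(draws, M_new) {
  g <- gebv_mt(draws, M_new)
  if (ncol(g) == 1) stats::setNames(as.vector(g), rownames(M_new)) else g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
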