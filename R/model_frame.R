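#' MCMC chain configuration
#'
#' Defaults follow standard practice for this class of model: 100,000
#' iterations with 20,000 discarded as burn-in. Thinning (default 10) bounds
#' draw storage; prior degrees of freedom give weakly informative
#' scaled-inverse-chi-square / inverse-Wishart priors whose mode splits the
#' phenotypic variance as `var_split` (genetic / DIM / residual).
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before retention; `0 < burn_in < n_iter`.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; when set, a fit is bit-reproducible.
#' @param nu_a,nu_d,nu_e Prior degrees of freedom for the genetic, DIM and
#'   residual variances (single-trait; the multi-trait sampler uses
#'   `n_traits + 3` for its inverse-Wishart priors unless overridden).
#' @param var_split Prior-mode split of phenotypic variance, named
#'   `genetic`/`dim`/`residual`, summing to 1.
#' @param fix_variances If TRUE all variance components stay at `init`
#'   (diagnostic mode used to check the sampler against closed-form ridge /
#'   mixed-model solutions).
#' @param init Optional named list of initial values: `sigma2_a` (marker-effect
#'   variance), `sigma2_d`, `sigma2_e`, or for multi-trait `Sigma_a`, `R`.
#' @return A `chain_config` list.
#' @export
chain_config <- function(n_iter = 100000, burn_in = 20000, thin = 10,
                         seed = NULL, nu_a = 5, nu_d = 5, nu_e = 5,
                         var_split = c(genetic = 0.30, dim = 0.05, residual = 0.65),
                         fix_variances = FALSE, init = NULL) {
  stopifnot(burn_in > 0, burn_in < n_iter, thin >= 1)
  stopifnot(all(c("genetic", "dim", "residual") %in% names(var_split)))
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 nu_a = nu_a, nu_d = nu_d, nu_e = nu_e,
                 var_split = var_split, fix_variances = fix_variances,
                 init = init),
            class = "chain_config")
}

#' Assign days-in-milk to 30-day classes
#'
#' Bins follow the monthly milk-recording rhythm: days 1-30 are class 1,
#' 31-60 class 2, and so on. `dim = 0` maps to class 1.
#'
#' @param dim Numeric days in milk.
#' @param width Class width in days (default 30).
#' @return Integer class labels.
#' @export
dim_class <- function(dim, width = 30) {
  pmax(1L, as.integer(floor((dim - 1) / width) + 1))
}

#' Build the single-trait model frame
#'
#' Assembles, for one trait and a set of training animals: the response `y`;
#' the full-rank fixed-effect incidence `X` (intercept + treatment-coded
#' lactation-order and farm dummies for the levels present); the days-in-milk
#' random-effect incidence `W` (30-day classes); and the centered marker
#' matrix rows `M`. Animals missing the trait or a covariate are excluded with
#' a warning.
#'
#' @param pheno Phenotype table.
#' @param trait Trait name, one of `MY, MF, MP, ML, MDM`.
#' @param M_centered Centered marker matrix (all animals, rownames = ids).
#' @param animals Training animal ids.
#' @param dim_width DIM class width in days.
#' @return A `model_frame` list (`y`, `X`, `W`, `M`, ids, level maps).
#' @export
build_model_frame <- function(pheno, trait, M_centered, animals,
                              dim_width = 30) {
  stopifnot(trait %in% names(pheno))
  ph <- pheno[match(animals, pheno$animal_id), , drop = FALSE]
  ok <- !is.na(ph[[trait]]) & !is.na(ph$lactation_order) &
    !is.na(ph$farm) & !is.na(ph$dim)
  if (!all(ok)) {
    warning(sum(!ok), " training animal(s) excluded for missing trait/covariate: ",
            paste(head(ph$animal_id[!ok], 5), collapse = ", "))
    ph <- ph[ok, , drop = FALSE]
  }
  if (nrow(ph) < 2) stop("fewer than 2 usable training animals for trait ", trait)
  missing_geno <- setdiff(ph$animal_id, rownames(M_centered))
  if (length(missing_geno)) stop("training animals absent from marker matrix: ",
                                 paste(head(missing_geno, 5), collapse = ", "))
  X <- fixed_incidence(ph)
  W <- dim_incidence(ph$dim, dim_width)
  structure(list(y = ph[[trait]], X = X, W = W,
                 M = M_centered[ph$animal_id, , drop = FALSE],
                 trait = trait, animal_ids = ph$animal_id,
                 marker_ids = colnames(M_centered),
                 dim_width = dim_width),
            class = "model_frame")
}

#' Build the multi-trait model frame
#'
#' Same incidence layout as [build_model_frame()], shared across traits;
#' training is restricted to complete cases (animals with every trait and
#' covariate observed). Trait order is fixed and recorded.
#'
#' @inheritParams build_model_frame
#' @param traits Ordered trait names (default all five).
#' @return An `mt_model_frame` list (`Y`, `X`, `W`, `M`, ids).
#' @export
build_mt_model_frame <- function(pheno, M_centered, animals,
                                 traits = DEFAULT_TRAITS, dim_width = 30) {
  stopifnot(length(traits) >= 1, all(traits %in% names(pheno)))
  ph <- pheno[match(animals, pheno$animal_id), , drop = FALSE]
  ok <- stats::complete.cases(ph[, c(traits, "lactation_order", "farm", "dim")])
  if (!all(ok)) {
    warning(sum(!ok), " training animal(s) dropped for incomplete records")
    ph <- ph[ok, , drop = FALSE]
  }
  if (nrow(ph) < 2) stop("fewer than 2 complete-case training animals")
  X <- fixed_incidence(ph)
  W <- dim_incidence(ph$dim, dim_width)
  Y <- as.matrix(ph[, traits, drop = FALSE])
  rownames(Y) <- ph$animal_id
  structure(list(Y = Y, X = X, W = W,
                 M = M_centered[ph$animal_id, , drop = FALSE],
                 traits = traits, animal_ids = ph$animal_id,
                 marker_ids = colnames(M_centered),
                 dim_width = dim_width),
            class = "mt_model_frame")
}

# Intercept + treatment-coded dummies for the lactation-order and farm levels
# observed in the data; full column rank by construction.
fixed_incidence <- function(ph) {
  df <- data.frame(lactation_order = factor(ph$lactation_order),
                   farm = factor(ph$farm))
  terms <- c(if (nlevels(df$lactation_order) > 1) "lactation_order",
             if (nlevels(df$farm) > 1) "farm")
  fml <- if (length(terms)) stats::reformulate(terms) else ~1
  X <- stats::model.matrix(fml, df)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect incidence is rank deficient")
  rownames(X) <- ph$animal_id
  X
}

dim_incidence <- function(dim, width = 30) {
  cls <- factor(dim_class(dim, width))
  W <- stats::model.matrix(~ cls - 1)
  colnames(W) <- paste0("dim", levels(cls))
  W
}
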