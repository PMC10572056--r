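#' Configuration of the synthetic dairy population
#'
#' Defaults emulate a post-QC Polish Holstein-Friesian milk-recording dataset:
#' 497 cows on 12 farms across 3 lactation orders, five traits (305-day milk
#' yield in kg and fat/protein/lactose/dry-matter percentages), heritabilities
#' in the low 0.2s with protein percentage highest, and a weak genetic
#' correlation structure whose strongest entry is fat-dry matter at ~0.5.
#' Markers are independent biallelic loci with allele frequencies drawn
#' uniformly from `maf_range`.
#'
#' @param n_animals Number of animals.
#' @param n_markers Number of markers (2000 by default; set 12906 to emulate
#'   a full 15k-chip panel after QC).
#' @param maf_range Uniform range for per-marker allele frequencies.
#' @param missing_rate Per-cell genotype missingness probability.
#' @param traits Ordered trait names.
#' @param h2_true Per-trait narrow-sense heritabilities.
#' @param genetic_corr_true t x t genetic correlation matrix (symmetric
#'   positive definite, unit diagonal).
#' @param residual_corr_true Residual correlation matrix; defaults to
#'   `genetic_corr_true`.
#' @param trait_means,trait_sds Phenotypic means and standard deviations.
#' @param n_farms,n_lactation Numbers of farm and lactation-order levels,
#'   assigned uniformly at random.
#' @param farm_sd_frac,lactation_sd_frac Fixed-effect standard deviations as
#'   fractions of the phenotypic SD.
#' @param dim_variance_frac Share of phenotypic variance from the random
#'   days-in-milk (30-day class) effect; `h2 + dim_variance_frac < 1` per
#'   trait.
#' @param ld_rho Correlation of adjacent markers within blocks of
#'   `ld_block_size` (Gaussian copula); 0 = independent loci (default).
#' @param ld_block_size Markers per LD block when `ld_rho > 0`.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_animals = 497, n_markers = 2000,
                       maf_range = c(0.05, 0.5), missing_rate = 0.01,
                       traits = DEFAULT_TRAITS,
                       h2_true = c(MY = 0.2424, MF = 0.2223, MP = 0.3029,
                                   ML = 0.2171, MDM = 0.2437),
                       genetic_corr_true = default_genetic_corr(),
                       residual_corr_true = NULL,
                       trait_means = c(MY = 8000, MF = 4.10, MP = 3.35,
                                       ML = 4.85, MDM = 13.0),
                       trait_sds = c(MY = 1200, MF = 0.55, MP = 0.30,
                                     ML = 0.20, MDM = 0.90),
                       n_farms = 12, n_lactation = 3,
                       farm_sd_frac = 0.25, lactation_sd_frac = 0.15,
                       dim_variance_frac = 0.05,
                       ld_rho = 0, ld_block_size = 10,
                       seed = NULL) {
  t_ <- length(traits)
  h2_true <- unname(h2_true)[seq_len(t_)]
  stopifnot(length(h2_true) == t_, all(h2_true >= 0), all(h2_true < 1),
            all(h2_true + dim_variance_frac < 1))
  genetic_corr_true <- as.matrix(genetic_corr_true)[seq_len(t_), seq_len(t_)]
  check_corr_matrix(genetic_corr_true, "genetic_corr_true")
  if (is.null(residual_corr_true)) residual_corr_true <- genetic_corr_true
  residual_corr_true <- as.matrix(residual_corr_true)[seq_len(t_), seq_len(t_)]
  check_corr_matrix(residual_corr_true, "residual_corr_true")
  structure(list(n_animals = n_animals, n_markers = n_markers,
                 maf_range = maf_range, missing_rate = missing_rate,
                 traits = traits, h2_true = stats::setNames(h2_true, traits),
                 genetic_corr_true = genetic_corr_true,
                 residual_corr_true = residual_corr_true,
                 trait_means = stats::setNames(unname(trait_means)[seq_len(t_)], traits),
                 trait_sds = stats::setNames(unname(trait_sds)[seq_len(t_)], traits),
                 n_farms = n_farms, n_lactation = n_lactation,
                 farm_sd_frac = farm_sd_frac,
                 lactation_sd_frac = lactation_sd_frac,
                 dim_variance_frac = dim_variance_frac,
                 ld_rho = ld_rho, ld_block_size = ld_block_size,
                 seed = seed),
            class = "sim_config")
}

#' Default genetic correlation matrix of the five milk traits
#'
#' Weak correlations typical of milk yield versus component percentages:
#' yield slightly negative against fat, protein and dry matter, near zero
#' against lactose; fat-dry matter moderately positive (~0.5).
#'
#' @return 5 x 5 correlation matrix.
#' @export
default_genetic_corr <- function() {
  traits <- DEFAULT_TRAITS
  C <- diag(5)
  dimnames(C) <- list(traits, traits)
  lower <- c(MY_MF = -0.104, MY_MP = -0.092, MY_ML = 0.001, MY_MDM = -0.080,
             MF_MP = 0.132, MF_ML = 0.017, MF_MDM = 0.499,
             MP_ML = 0.021, MP_MDM = 0.218, ML_MDM = 0.041)
  pairs <- strsplit(names(lower), "_")
  for (k in seq_along(lower)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    C[i, j] <- C[j, i] <- lower[[k]]
  }
  C
}

check_corr_matrix <- function(C, name) {
  if (!isSymmetric(unname(C), tol = 1e-8)) stop(name, " must be symmetric")
  if (any(abs(diag(C) - 1) > 1e-8)) stop(name, " must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop(name, " must be positive definite")
  invisible(C)
}

#' Simulate a genotype matrix
#'
#' Independent biallelic loci: per marker an allele frequency drawn uniformly
#' from `maf_range`, dosages `Binomial(2, p)` iid across animals. With
#' `ld_rho > 0`, dosages within blocks of adjacent markers are generated
#' through a Gaussian copula with AR(1) correlation, giving block LD.
#' Missingness is applied uniformly at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return Dosage matrix (`NA` = missing).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_animals; p <- config$n_markers
  freqs <- runif(p, config$maf_range[1], config$maf_range[2])
  if (config$ld_rho > 0) {
    G <- matrix(NA_real_, n, p)
    rho <- config$ld_rho; bs <- config$ld_block_size
    starts <- seq(1, p, by = bs)
    for (s in starts) {
      cols <- s:min(s + bs - 1, p)
      w <- length(cols)
      Z <- matrix(rnorm(n * w), n, w)
      if (w > 1) for (j in 2:w) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
      # two latent draws per locus -> two allele copies per animal
      Z2 <- matrix(rnorm(n * w), n, w)
      if (w > 1) for (j in 2:w) Z2[, j] <- rho * Z2[, j - 1] + sqrt(1 - rho^2) * Z2[, j]
      for (j in seq_along(cols)) {
        pj <- freqs[cols[j]]
        G[, cols[j]] <- (pnorm(Z[, j]) < pj) + (pnorm(Z2[, j]) < pj)
      }
    }
  } else {
    G <- matrix(rbinom(n * p, 2, rep(freqs, each = n)), n, p)
  }
  if (config$missing_rate > 0) {
    G[runif(n * p) < config$missing_rate] <- NA_real_
  }
  dimnames(G) <- list(sprintf("A%04d", seq_len(n)), sprintf("M%05d", seq_len(p)))
  G
}

#' Simulate true marker effects
#'
#' Per-marker effect vectors drawn iid `N(0, Sigma_alpha)` with
#' `Sigma_alpha = Sigma_g_target / sum_i var(SNP_i)`, so the marker-effect
#' genetic covariance `sum_i var(SNP_i) a_i a_i'` matches the target genetic
#' covariance (`h2 * phenotypic variance` on the diagonal, scaled by
#' `genetic_corr_true` off it) in expectation.
#'
#' @param config A [sim_config()].
#' @param geno Complete dosage matrix to scale against (impute first if
#'   needed).
#' @return markers x traits effect matrix.
#' @export
simulate_effects <- function(config, geno) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(geno)) stop("effects must be scaled against complete genotypes")
  if (!is.null(config$seed)) set.seed(config$seed)
  sumV <- sum(marker_variances(geno))
  sg_sd <- sqrt(config$h2_true) * config$trait_sds
  Sigma_g <- outer(sg_sd, sg_sd) * config$genetic_corr_true
  Sigma_alpha <- Sigma_g / sumV
  # eigen square root tolerates zero-heritability traits (PSD target)
  ev <- eigen(Sigma_alpha, symmetric = TRUE)
  if (min(ev$values) < -1e-10) stop("target genetic covariance is not PSD")
  half <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values)) %*%
    t(ev$vectors)
  p <- ncol(geno)
  A <- matrix(rnorm(p * length(config$traits)), p) %*% half
  dimnames(A) <- list(colnames(geno), config$traits)
  A
}

#' Simulate phenotypes from genotypes and true effects
#'
#' `y = mean + lactation effect + farm effect + DIM class effect + M a + e`
#' per trait, with farm and lactation order assigned uniformly at random,
#' days in milk uniform on 5-360 binned into 30-day classes, DIM class
#' effects iid normal per trait, and residuals multivariate normal with the
#' configured residual correlation. Residual variances are set so the
#' random-component total matches the phenotypic variances:
#' `var_e = (1 - h2 - dim_variance_frac) * sd^2`.
#'
#' @param config A [sim_config()].
#' @param geno Complete dosage matrix.
#' @param effects markers x traits true effects.
#' @return List with `pheno` (phenotype table) and `truth` (a `truth_record`:
#'   true effects, genetic values, realized h2 and genetic correlations, and
#'   all fixed/random effect values).
#' @export
simulate_phenotypes <- function(config, geno, effects) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(geno)) stop("phenotype simulation needs complete genotypes")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(geno); t_ <- length(config$traits)
  M <- center_markers(geno)$M
  g <- M %*% effects  # true genetic values

  lact <- sample.int(config$n_lactation, n, replace = TRUE)
  farm <- sample.int(config$n_farms, n, replace = TRUE)
  dim_days <- sample(5:360, n, replace = TRUE)
  dcls <- dim_class(dim_days)
  n_dcls <- max(dcls)

  lact_eff <- matrix(rnorm(config$n_lactation * t_), ncol = t_) *
    rep(config$lactation_sd_frac * config$trait_sds, each = config$n_lactation)
  farm_eff <- matrix(rnorm(config$n_farms * t_), ncol = t_) *
    rep(config$farm_sd_frac * config$trait_sds, each = config$n_farms)
  dim_sd <- sqrt(config$dim_variance_frac) * config$trait_sds
  dim_eff <- matrix(rnorm(n_dcls * t_), ncol = t_) * rep(dim_sd, each = n_dcls)

  res_var <- (1 - config$h2_true - config$dim_variance_frac) * config$trait_sds^2
  res_sd <- sqrt(res_var)
  Sigma_e <- outer(res_sd, res_sd) * config$residual_corr_true
  E <- matrix(rnorm(n * t_), n) %*% chol(Sigma_e)

  Y <- matrix(rep(config$trait_means, each = n), n) +
    lact_eff[lact, , drop = FALSE] + farm_eff[farm, , drop = FALSE] +
    dim_eff[dcls, , drop = FALSE] + g + E
  colnames(Y) <- config$traits

  pheno <- data.frame(animal_id = rownames(geno), Y,
                      lactation_order = lact, farm = farm, dim = dim_days)
  rownames(pheno) <- NULL

  dim_assigned <- dim_eff[dcls, , drop = FALSE]
  realized_h2 <- sapply(seq_len(t_), function(k) {
    vg <- stats::var(g[, k])
    vg / (vg + stats::var(dim_assigned[, k]) + stats::var(E[, k]))
  })
  truth <- structure(list(
    effects = effects, genetic_values = g,
    realized_h2 = stats::setNames(realized_h2, config$traits),
    # NA rows/cols for zero-heritability traits (no genetic variance)
    realized_genetic_corr = suppressWarnings(stats::cor(g)),
    lactation_effects = lact_eff, farm_effects = farm_eff,
    dim_effects = dim_eff, residuals = E,
    assignments = data.frame(animal_id = rownames(geno), lactation_order = lact,
                             farm = farm, dim = dim_days, dim_class = dcls)
  ), class = "truth_record")
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete dataset with known truth
#'
#' Composition of [simulate_genotypes()], [simulate_effects()] and
#' [simulate_phenotypes()] under a single seed stream: genotypes are drawn
#' complete, effects and phenotypes are generated from them, and missingness
#' is applied to the released genotype matrix only (the truth is computed on
#' the complete dosages).
#'
#' @param config A [sim_config()].
#' @return List with `geno` (with missingness), `pheno`, `truth`, and
#'   `geno_complete`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  inner <- config
  inner$seed <- NULL  # one stream: no re-seeding inside components
  inner$missing_rate <- 0
  geno_complete <- simulate_genotypes(inner)
  effects <- simulate_effects(inner, geno_complete)
  sim <- simulate_phenotypes(inner, geno_complete, effects)
  geno <- geno_complete
  if (config$missing_rate > 0) {
    geno[runif(length(geno)) < config$missing_rate] <- NA_real_
  }
  list(geno = geno, pheno = sim$pheno, truth = sim$truth,
       geno_complete = geno_complete)
}

#' Write a simulated dataset to disk
#'
#' Emits the dosage TSV, phenotype CSV and a truth JSON (true h2, genetic
#' correlations, realized values) into `dir`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if absent).
#' @return Invisible named vector of file paths.
#' @export
write_sim_dataset <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.json"))
  write_genotypes(sim$geno, paths[["genotypes"]])
  write_phenotypes(sim$pheno, paths[["phenotypes"]])
  jsonlite::write_json(list(
    h2_true = as.list(config$h2_true),
    genetic_corr_true = config$genetic_corr_true,
    realized_h2 = as.list(sim$truth$realized_h2),
    realized_genetic_corr = sim$truth$realized_genetic_corr,
    seed = config$seed
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
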