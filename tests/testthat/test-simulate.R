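test_that("genotype simulation honors missingness, frequency and seed", {
  cfg0 <- sim_config(n_animals = 50, n_markers = 40, missing_rate = 0, seed = 1)
  G0 <- simulate_genotypes(cfg0)
  expect_false(anyNA(G0))
  expect_true(all(G0 %in% 0:2))
  expect_equal(dim(G0), c(50L, 40L))
  # fixed frequency 0.5: empirical frequencies concentrate at 0.5
  cfgf <- sim_config(n_animals = 2000, n_markers = 50,
                     maf_range = c(0.5, 0.5), missing_rate = 0, seed = 2)
  Gf <- simulate_genotypes(cfgf)
  expect_lt(max(abs(colMeans(Gf) / 2 - 0.5)), 0.02)
  # seeded determinism
  cfg1 <- sim_config(n_animals = 30, n_markers = 20, missing_rate = 0.05, seed = 9)
  expect_identical(simulate_genotypes(cfg1), simulate_genotypes(cfg1))
  G1 <- simulate_genotypes(cfg1)
  expect_gt(mean(is.na(G1)), 0)
})

test_that("block-LD mode induces correlation between adjacent markers", {
  cfg <- sim_config(n_animals = 400, n_markers = 40, missing_rate = 0,
                    ld_rho = 0.8, ld_block_size = 10, seed = 4)
  G <- simulate_genotypes(cfg)
  r_adj <- mean(sapply(seq(1, 39), function(j) {
    if (j %% 10 == 0) return(NA)  # block boundary
    cor(G[, j], G[, j + 1])
  }), na.rm = TRUE)
  expect_gt(r_adj, 0.3)
})

test_that("true effects hit the target genetic covariance in expectation", {
  cfg <- sim_config(n_animals = 400, n_markers = 2000, missing_rate = 0, seed = 31)
  G <- simulate_genotypes(cfg)
  A <- simulate_effects(cfg, G)
  sv <- marker_variances(G)
  Sg <- genetic_covariance_draw(A, sv)
  target <- outer(sqrt(cfg$h2_true) * cfg$trait_sds,
                  sqrt(cfg$h2_true) * cfg$trait_sds) * cfg$genetic_corr_true
  # realized genetic variances within 10% of target
  expect_lt(max(abs(diag(Sg) / diag(target) - 1)), 0.10)
  # zero-heritability trait -> exactly zero effects
  cfg0 <- sim_config(n_animals = 50, n_markers = 200, traits = c("MY", "MF"),
                     h2_true = c(0, 0.3), genetic_corr_true = diag(2),
                     trait_means = c(0, 0), trait_sds = c(1, 1),
                     missing_rate = 0, seed = 5)
  G0 <- simulate_genotypes(cfg0)
  A0 <- simulate_effects(cfg0, G0)
  expect_true(all(A0[, "MY"] == 0))
})

test_that("uncorrelated-truth effects realize near-zero genetic correlations", {
  cfg <- sim_config(n_animals = 100, n_markers = 2000, missing_rate = 0,
                    genetic_corr_true = diag(5), seed = 12)
  G <- simulate_genotypes(cfg)
  A <- simulate_effects(cfg, G)
  Sg <- genetic_covariance_draw(A, marker_variances(G))
  realized <- stats::cov2cor(Sg)
  expect_lt(max(abs(realized[upper.tri(realized)])), 0.15)
})

test_that("simulated phenotypes realize the configured heritabilities", {
  cfg <- sim_config(n_animals = 497, n_markers = 2000, missing_rate = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  expect_lt(max(abs(sim$truth$realized_h2 - cfg$h2_true)), 0.05)
  expect_equal(nrow(sim$pheno), 497)
  expect_true(all(sim$pheno$lactation_order %in% 1:3))
  expect_true(all(sim$pheno$farm %in% 1:12))
  expect_true(all(sim$pheno$dim >= 5 & sim$pheno$dim <= 360))
})

test_that("pure-noise phenotypes are uncorrelated with the genotypes", {
  cfg <- sim_config(n_animals = 497, n_markers = 100, traits = c("MY", "MF"),
                    h2_true = c(0, 0), genetic_corr_true = diag(2),
                    trait_means = c(0, 0), trait_sds = c(1, 1),
                    farm_sd_frac = 0, lactation_sd_frac = 0,
                    dim_variance_frac = 0, missing_rate = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  rs <- abs(cor(sim$pheno$MY, sim$geno[, 1:20]))
  expect_lt(max(rs), 0.15)
})

test_that("simulate_dataset is deterministic and feeds QC/io cleanly", {
  cfg <- sim_config(n_animals = 60, n_markers = 80, seed = 3)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth$effects, s2$truth$effects)
  # outputs round-trip through the file formats and pass QC with few removals
  dir <- withr::local_tempdir()
  paths <- write_sim_dataset(s1, cfg, dir)
  g_back <- read_genotypes(paths[["genotypes"]])
  expect_identical(g_back, s1$geno)
  ph_back <- read_phenotypes(paths[["phenotypes"]])
  expect_equal(ph_back$MY, s1$pheno$MY, tolerance = 1e-10)
  qc <- run_qc(s1$geno)
  expect_lt(length(qc$report$removed_animal_ids), 3)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$h2_true$MP, 0.3029)
})
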