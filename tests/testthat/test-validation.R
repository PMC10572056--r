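test_that("train/test split is exact, seeded, disjoint and exhaustive", {
  ids <- sprintf("A%03d", 1:497)
  sp <- split_train_test(ids, 400, seed = 5)
  expect_length(sp$train, 400)
  expect_length(sp$test, 97)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- split_train_test(ids, 400, seed = 5)
  expect_identical(sp, sp2)
  expect_error(split_train_test(ids, 497), "smaller")
})

test_that("accuracy is the Pearson correlation of phenotype and GEBV", {
  y <- c(2.1, 0.4, -1.3, 0.8, 1.7)
  expect_equal(accuracy(y, y), 1)
  expect_equal(accuracy(y, -y), -1)
  g <- c(1.0, 0.2, -0.9, 0.1, 1.1)
  # direct-formula oracle
  r_hand <- sum((y - mean(y)) * (g - mean(g))) /
    sqrt(sum((y - mean(y))^2) * sum((g - mean(g))^2))
  expect_equal(accuracy(y, g), r_hand)
  expect_warning(r0 <- accuracy(y, rep(1, 5)), "zero variance")
  expect_true(is.na(r0))
})

test_that("bias is the slope of phenotype regressed on GEBV", {
  g <- c(1.0, 0.2, -0.9, 0.1, 1.1)
  expect_equal(bias(2 * g, g), 2)
  expect_equal(bias(g, g), 1)
  y <- c(2.1, 0.4, -1.3, 0.8, 1.7)
  # least-squares oracle via lm
  expect_equal(bias(y, g), unname(coef(lm(y ~ g))[2]))
})

test_that("accuracy/bias respond correctly to shifting and scaling GEBVs", {
  set.seed(19)
  y <- rnorm(50)
  g <- 0.6 * y + rnorm(50, 0, 0.5)
  r0 <- accuracy(y, g); b0 <- bias(y, g)
  expect_equal(accuracy(y, g + 3), r0)   # shift invariance
  expect_equal(bias(y, g + 3), b0)
  expect_equal(accuracy(y, 2.5 * g), r0) # positive rescale: r unchanged,
  expect_equal(bias(y, 2.5 * g), b0 / 2.5)  # slope scales inversely
})

test_that("rank correlations of magnitudes handle monotone maps and ties", {
  eff <- cbind(T1 = c(0.1, -0.5, 0.3, 0.05, -0.2, 0.4),
               T2 = 2 * c(0.1, -0.5, 0.3, 0.05, -0.2, 0.4))
  rc <- marker_rank_correlations(eff)
  expect_equal(rc$rho["T1", "T2"], 1)
  # reversing the magnitude ranking gives rho = -1
  o <- order(eff[, 1]^2)
  rev_eff <- eff
  rev_eff[o, 2] <- eff[rev(o), 2]
  expect_equal(marker_rank_correlations(rev_eff)$rho["T1", "T2"], -1)
  # ties: against a brute-force average-rank oracle
  e3 <- cbind(T1 = c(1, 1, 2, 3, 3, 4), T2 = c(2, 1, 1, 4, 3, 3))
  avg_rank <- function(x) {
    sapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2)
  }
  r1 <- avg_rank(e3[, 1]^2); r2 <- avg_rank(e3[, 2]^2)
  rho_brute <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(marker_rank_correlations(e3)$rho["T1", "T2"], rho_brute)
  # invariant under any strictly monotone transform of magnitudes
  e4 <- cbind(T1 = rnorm(10), T2 = rnorm(10))
  rho_sq <- marker_rank_correlations(e4, "squared")$rho["T1", "T2"]
  rho_abs <- marker_rank_correlations(e4, "absolute")$rho["T1", "T2"]
  expect_equal(rho_sq, rho_abs)  # x^2 and |x| are monotone-linked on |x|
  expect_error(marker_rank_correlations(e4[1:2, ]), "3 markers")
})

test_that("run_validation orchestrates QC, split, fits and reports", {
  sim <- simulate_dataset(sim_config(n_animals = 80, n_markers = 150, seed = 55))
  run <- run_validation(sim$geno, sim$pheno,
                        chain = chain_config(n_iter = 400, burn_in = 100,
                                             thin = 3, seed = 99),
                        n_train = 60)
  expect_s3_class(run, "validation_run")
  expect_equal(nrow(run$results), 5)
  expect_true(all(abs(run$results$r_mt) <= 1, na.rm = TRUE))
  expect_equal(run$results$accuracy_diff,
               run$results$r_mt - run$results$r_st)
  expect_length(intersect(run$split$train, run$split$test), 0)
  expect_setequal(c(run$split$train, run$split$test),
                  setdiff(rownames(sim$geno), run$qc_report$removed_animal_ids))
  # same seed end-to-end reproduces the result exactly
  run2 <- run_validation(sim$geno, sim$pheno,
                         chain = chain_config(n_iter = 400, burn_in = 100,
                                              thin = 3, seed = 99),
                         n_train = 60)
  expect_identical(run$results, run2$results)
  expect_identical(run$params$h2, run2$params$h2)
  # CSV exports round-trip
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_validation_csv(run, p1, rank_path = p2)
  expect_equal(nrow(utils::read.csv(p1)), 5)
  expect_equal(dim(utils::read.csv(p2, check.names = FALSE))[1], 5)
})

test_that("a trait without genetic variance predicts at chance level", {
  h2 <- c(MY = 0, MF = 0.3)
  corr <- diag(2)
  cfg <- sim_config(n_animals = 150, n_markers = 300, traits = c("MY", "MF"),
                    h2_true = h2, genetic_corr_true = corr,
                    trait_means = c(0, 0), trait_sds = c(1, 1), seed = 77)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$effects[, "MY"] == 0))
  run <- run_validation(sim$geno, sim$pheno,
                        chain = chain_config(n_iter = 600, burn_in = 200,
                                             thin = 4, seed = 3),
                        traits = c("MY", "MF"), n_train = 110)
  expect_lt(abs(run$results$r_st[run$results$trait == "MY"]), 0.35)
})
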