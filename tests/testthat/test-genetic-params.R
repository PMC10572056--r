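# Minimal hand-built posterior_draws object for summary-level tests.
fake_draws <- function(alpha_array, sigma2_d, R_array, traits) {
  nd <- dim(alpha_array)[1]
  structure(list(model_tag = "MT", traits = traits, alpha = alpha_array,
                 b = NULL, d = NULL,
                 Sigma_a = array(NA, c(length(traits), length(traits), nd)),
                 R = R_array, sigma2_d = sigma2_d,
                 config = chain_config(n_iter = nd + 1, burn_in = 1, thin = 1),
                 marker_ids = dimnames(alpha_array)[[2]],
                 animal_ids = NULL, n_draws = nd),
            class = "posterior_draws")
}

test_that("per-draw genetic covariance equals the rank-1 sum definition", {
  # one marker, var 2, effect vector (1, -1)
  a <- matrix(c(1, -1), 1, 2)
  expect_equal(genetic_covariance_draw(a, 2),
               matrix(c(2, -2, -2, 2), 2, 2))
  expect_equal(genetic_covariance_draw(matrix(0, 3, 2), c(1, 2, 3)),
               matrix(0, 2, 2))
  # 3 markers x 2 traits against an independent brute-force double loop
  A <- matrix(c(0.5, -1.2, 0.3, 0.8, 0.0, -0.4), 3, 2)
  v <- c(0.48, 0.32, 0.5)
  S_brute <- matrix(0, 2, 2)
  for (i in 1:3) for (t1 in 1:2) for (t2 in 1:2) {
    S_brute[t1, t2] <- S_brute[t1, t2] + v[i] * A[i, t1] * A[i, t2]
  }
  expect_lt(max(abs(genetic_covariance_draw(A, v) - S_brute)), 1e-12)
  # PSD by construction
  set.seed(5)
  for (k in 1:10) {
    Ak <- matrix(rnorm(8 * 3), 8, 3)
    vk <- runif(8)
    ev <- eigen(genetic_covariance_draw(Ak, vk), symmetric = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("posterior genetic covariance averages the per-draw series", {
  p <- 2; t_ <- 2
  alpha <- array(0, c(2, p, t_), dimnames = list(NULL, c("m1", "m2"), c("T1", "T2")))
  alpha[1, , ] <- matrix(c(1, 0, 0, 1), p, t_)
  alpha[2, , ] <- matrix(c(0, 1, 1, 0), p, t_)
  d <- fake_draws(alpha, matrix(0, 2, t_), array(1, c(t_, t_, 2)), c("T1", "T2"))
  v <- c(1, 2)
  gc <- genetic_covariance(d, v)
  A1 <- matrix(alpha[1, , ], p, t_); A2 <- matrix(alpha[2, , ], p, t_)
  expect_equal(gc$mean, (genetic_covariance_draw(A1, v) +
                           genetic_covariance_draw(A2, v)) / 2,
               ignore_attr = TRUE)
  # constant effects: mean equals the single-draw value
  alpha[2, , ] <- alpha[1, , ]
  d2 <- fake_draws(alpha, matrix(0, 2, t_), array(1, c(t_, t_, 2)), c("T1", "T2"))
  expect_equal(genetic_covariance(d2, v)$mean,
               genetic_covariance_draw(A1, v), ignore_attr = TRUE)
})

test_that("genetic correlation normalizes by the sqrt of variance products", {
  S <- array(c(2, -2, -2, 2), c(2, 2, 1))
  expect_equal(genetic_correlation(S)$mean,
               matrix(c(1, -1, -1, 1), 2, 2), ignore_attr = TRUE)
  Sd <- array(diag(c(3, 5)), c(2, 2, 1))
  expect_equal(genetic_correlation(Sd)$mean, diag(2), ignore_attr = TRUE)
  # random PSD draw equals direct normalization, and bad draws are skipped
  set.seed(8)
  A <- matrix(rnorm(12), 4, 3)
  Sr <- crossprod(A)
  series <- array(NA, c(3, 3, 2))
  series[, , 1] <- Sr
  series[, , 2] <- matrix(0, 3, 3)  # zero diagonal -> skipped
  gc <- genetic_correlation(series)
  expect_equal(gc$mean, stats::cov2cor(Sr), ignore_attr = TRUE)
  expect_equal(gc$n_skipped, 1)
  expect_true(all(abs(gc$mean) <= 1 + 1e-12))
})

test_that("heritability is genetic over genetic + DIM + residual, per draw", {
  t_ <- 1
  alpha <- array(1, c(3, 2, t_), dimnames = list(NULL, c("m1", "m2"), "T1"))
  sg <- genetic_covariance_draw(matrix(1, 2, 1), c(1, 1))[1, 1]  # = 2
  R <- array(sg, c(1, 1, 3))        # residual equals genetic in every draw
  d <- fake_draws(alpha, matrix(0, 3, 1), R, "T1")
  gc <- genetic_covariance(d, c(1, 1))
  h <- heritability(d, gc$series)
  expect_equal(unname(h$h2), 0.5)
  expect_equal(unname(h$h2_se), 0)
  # DIM variance enters the denominator unless disabled
  d2 <- fake_draws(alpha, matrix(sg, 3, 1), R, "T1")
  h2 <- heritability(d2, gc$series)
  expect_equal(unname(h2$h2), 1 / 3)
  h3 <- heritability(d2, gc$series, include_dim = FALSE)
  expect_equal(unname(h3$h2), 0.5)
  # zero genetic variance -> h2 = 0
  alpha0 <- array(0, c(3, 2, 1), dimnames = list(NULL, c("m1", "m2"), "T1"))
  d0 <- fake_draws(alpha0, matrix(0, 3, 1), R, "T1")
  gc0 <- genetic_covariance(d0, c(1, 1))
  expect_equal(unname(heritability(d0, gc0$series)$h2), 0)
})

test_that("phenotypic correlations are pairwise-complete Pearson with t-test p", {
  ph <- data.frame(animal_id = paste0("a", 1:5),
                   MY = c(1, 2, 3, 4, 5), MF = -c(1, 2, 3, 4, 5),
                   MP = c(2.0, 1.1, 3.4, 2.2, 4.8),
                   ML = c(1.2, 0.8, 2.4, 3.0, 1.1),
                   MDM = c(NA, NA, NA, 1, 2),
                   lactation_order = 1L, farm = 1L, dim = 10)
  pc <- phenotypic_correlation(ph)
  expect_equal(pc$corr["MY", "MY"], 1)
  expect_equal(pc$corr["MY", "MF"], -1)
  # against the standard test as oracle
  ct <- cor.test(ph$MY, ph$MP)
  expect_equal(pc$corr["MY", "MP"], unname(ct$estimate))
  expect_equal(pc$p_value["MY", "MP"], ct$p.value)
  # fewer than 3 complete pairs -> undefined
  expect_true(is.na(pc$corr["MY", "MDM"]))
})

test_that("genetic_params assembles a coherent summary and CSV export", {
  sim <- simulate_dataset(sim_config(n_animals = 60, n_markers = 120, seed = 14))
  qc <- run_qc(sim$geno)
  cm <- center_markers(qc$geno)
  fr <- build_mt_model_frame(sim$pheno, cm$M, rownames(qc$geno),
                             traits = c("MY", "MF"))
  d <- fit_mt(fr, chain_config(n_iter = 400, burn_in = 100, thin = 3, seed = 2))
  gp <- genetic_params(d, marker_variances(qc$geno), pheno = sim$pheno)
  expect_true(all(gp$h2 >= 0 & gp$h2 <= 1))
  expect_true(all(gp$h2_se >= 0))
  expect_true(all(abs(gp$genetic_corr) <= 1))
  expect_equal(diag(gp$genetic_corr), c(MY = 1, MF = 1))
  # h2 point estimate lies inside the per-draw range
  expect_true(all(gp$h2 >= apply(gp$h2_series, 2, min) &
                    gp$h2 <= apply(gp$h2_series, 2, max)))
  path <- withr::local_tempfile(fileext = ".csv")
  tidy <- withr::local_tempfile(fileext = ".csv")
  write_genetic_params_csv(gp, path, tidy_path = tidy)
  tab <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), 2)
  expect_match(tab[1, "MY"], "\\+/-")
  long <- utils::read.csv(tidy)
  expect_true(all(c("h2", "genetic_corr", "phenotypic_corr") %in% long$quantity))
})
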