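# Shared fixtures and independent oracles for the test suite.

# Small centered-genotype regression fixture: y = M alpha + intercept + e.
make_ridge_fixture <- function(n = 30, p = 50, seed = 42,
                               sigma2_alpha = 0.05, sigma2_e = 1) {
  set.seed(seed)
  freqs <- runif(p, 0.1, 0.5)
  G <- matrix(rbinom(n * p, 2, rep(freqs, each = n)), n, p,
              dimnames = list(sprintf("A%03d", 1:n), sprintf("M%03d", 1:p)))
  M <- sweep(G, 2, colMeans(G), "-")
  alpha_true <- rnorm(p, 0, sqrt(sigma2_alpha))
  y <- 2 + as.vector(M %*% alpha_true) + rnorm(n, 0, sqrt(sigma2_e))
  list(G = G, M = M, y = y, alpha_true = alpha_true,
       sigma2_alpha = sigma2_alpha, sigma2_e = sigma2_e)
}

# Hand-built model frame (intercept-only fixed effects, no DIM term),
# bypassing the phenotype-table plumbing for sampler-level tests.
make_frame <- function(y, M, trait = "y") {
  n <- length(y)
  structure(list(y = y, X = matrix(1, n, 1, dimnames = list(rownames(M), "intercept")),
                 W = matrix(0, n, 0), M = M, trait = trait,
                 animal_ids = rownames(M), marker_ids = colnames(M),
                 dim_width = 30),
            class = "model_frame")
}

make_mt_frame <- function(Y, M) {
  n <- nrow(Y)
  structure(list(Y = Y, X = matrix(1, n, 1, dimnames = list(rownames(M), "intercept")),
                 W = matrix(0, n, 0), M = M, traits = colnames(Y),
                 animal_ids = rownames(M), marker_ids = colnames(M),
                 dim_width = 30),
            class = "mt_model_frame")
}

# Independent oracle: joint mixed-model-equations solve for the ridge posterior
# mean of (b, alpha) at fixed variances (flat prior on b).
ridge_mme_oracle <- function(y, X, M, sigma2_alpha, sigma2_e) {
  lambda <- sigma2_e / sigma2_alpha
  f <- ncol(X); p <- ncol(M)
  C <- rbind(cbind(crossprod(X), crossprod(X, M)),
             cbind(crossprod(M, X), crossprod(M) + diag(lambda, p)))
  rhs <- c(crossprod(X, y), crossprod(M, y))
  sol <- solve(C, rhs)
  list(b = sol[seq_len(f)], alpha = sol[-seq_len(f)])
}

# Independent oracle: GBLUP genetic values by generalized least squares with
# V = K * sigma2_a + I * sigma2_e.
gblup_gls_oracle <- function(y, X, K, sigma2_a, sigma2_e) {
  n <- length(y)
  V <- K * sigma2_a + diag(sigma2_e, n)
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  ghat <- sigma2_a * K %*% Vi %*% (y - X %*% bhat)
  list(b = as.vector(bhat), g = as.vector(ghat))
}

# Independent oracle: multi-trait GBLUP genetic values by stacked GLS with
# V = Sigma_g (x) K + R (x) I (trait-major stacking, matching vec(Y)).
mt_gblup_gls_oracle <- function(Y, X, K, Sigma_g, R) {
  n <- nrow(Y); t_ <- ncol(Y)
  V <- kronecker(Sigma_g, K) + kronecker(R, diag(n))
  Xb <- kronecker(diag(t_), X)
  yv <- as.vector(Y)
  Vi <- solve(V)
  bhat <- solve(t(Xb) %*% Vi %*% Xb, t(Xb) %*% Vi %*% yv)
  gv <- kronecker(Sigma_g, K) %*% Vi %*% (yv - Xb %*% bhat)
  matrix(gv, n, t_, dimnames = dimnames(Y))
}

# Toy QC fixture: 6 animals x 5 markers. Animal a3 is 40% missing (removed at
# the 10% threshold); marker m3 is monomorphic and marker m5's only non-ref
# allele sits on the removed a3, so both fall at MAF <= 0.05 once MAF is
# recomputed on the retained animals. Expected run_qc output: 5 x 3,
# removal counts (1 animal, 2 markers).
make_qc_fixture <- function() {
  G <- rbind(
    a1 = c(0,  1,  0, 2, 0),
    a2 = c(1,  0,  0, 1, 0),
    a3 = c(NA, NA, 0, 1, 1),
    a4 = c(2,  1,  0, 0, 0),
    a5 = c(0,  2,  0, 1, 0),
    a6 = c(1,  0,  0, 2, 0)
  )
  colnames(G) <- paste0("m", 1:5)
  G
}
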