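# Independent oracles and small utilities shared by the test files.

# Brute-force posterior moments by trapezoid quadrature on y in [-25, 25].
oracle_poisson_moments <- function(m, mu, sigma2, n_grid = 4000) {
  y <- seq(-25, 25, length.out = n_grid)
  lw <- m * y - exp(y) - (y - mu)^2 / (2 * sigma2)
  w <- exp(lw - max(lw))
  Ey <- sum(w * y) / sum(w)
  list(Ey = Ey, Vy = sum(w * (y - Ey)^2) / sum(w))
}

oracle_binomial_moments <- function(m1, m2, mu, sigma2, n_grid = 4000) {
  y <- seq(-25, 25, length.out = n_grid)
  lw <- m1 * y - (m1 + m2) * log1p(exp(y)) - (y - mu)^2 / (2 * sigma2)
  w <- exp(lw - max(lw))
  Ey <- sum(w * y) / sum(w)
  list(Ey = Ey, Vy = sum(w * (y - Ey)^2) / sum(w))
}

# Largest principal angle (radians) between the column spaces of A and B.
# Sine-based formulation: resolves angles far below the ~1.5e-8 floor of
# acos at cosines near 1.
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  resid <- qb - qa %*% crossprod(qa, qb)
  asin(min(max(svd(resid)$d), 1))
}

# Rank-based AUROC of `score` for binary `label`.
auroc <- function(score, label) {
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(rank(score)[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A random consistent model for decode/gauge/field algebra tests.
random_model <- function(G = 20, K = 3, N = 30, Q = 2, L = 0, P = 0,
                         seed = 1) {
  set.seed(seed)
  covariates <- NULL
  if (L > 0)
    covariates <- list(
      H = matrix(rnorm(L * Q), L, Q),
      R_o = matrix(rnorm(G * L), G, L),
      R_k = replicate(K, matrix(rnorm(G * L), G, L), simplify = FALSE),
      names = paste0("h", seq_len(L)))
  prior <- NULL
  if (P > 0) {
    C <- matrix(rbinom(G * P, 1, 0.2), G, P,
                dimnames = list(NULL, paste0("set", seq_len(P))))
    prior <- list(C = C,
                  A = matrix(rnorm(P * K), P, K,
                             dimnames = list(paste0("set", seq_len(P)), NULL)),
                  S_Z = N, S_A = N)
  }
  new_gedi_model(
    o_r = rnorm(G), Z_r = matrix(rnorm(G * K), G, K),
    delta_o = matrix(rnorm(G * Q, 0, 0.3), G, Q),
    delta_Z = replicate(Q, matrix(rnorm(G * K, 0, 0.3), G, K),
                        simplify = FALSE),
    B = matrix(rnorm(K * N), K, N), s = rnorm(N, 0, 0.2),
    sigma2 = 0.5, mode = "gaussian",
    sample_map = rep_len(seq_len(Q), N),
    prior = prior, covariates = covariates, fitted = TRUE)
}

# Gaussian observations lying near a planted manifold.
planted_gaussian <- function(G = 60, K = 3, N = 150, Q = 3, noise = 0.1,
                             delta_o_sd = 0, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(G * K), G, K)
  B <- matrix(rnorm(K * N), K, N)
  o <- rnorm(G)
  samp <- rep_len(seq_len(Q), N)
  d_o <- matrix(rnorm(G * Q, 0, delta_o_sd), G, Q)
  Y <- o + Z %*% B + d_o[, samp] + matrix(rnorm(G * N, 0, noise), G, N)
  list(Y = Y, Z = Z, B = B, o = o, delta_o = d_o, sample_map = samp)
}
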