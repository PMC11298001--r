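test_that("initialization is exact on noiseless low-rank data", {
  pl <- planted_gaussian(G = 40, K = 3, N = 80, Q = 1, noise = 0, seed = 31)
  obs <- gedi_observations(sample_map = pl$sample_map, Y = pl$Y)
  m <- gedi_initialize(obs, 3)
  expect_lt(max(abs((pl$Y - rowMeans(pl$Y)) - m$Z_r %*% m$B)), 1e-8)
})

test_that("initialization is deterministic and spans the SVD subspace", {
  set.seed(32)
  Y <- matrix(rnorm(100 * 300), 100, 300)
  obs <- gedi_observations(sample_map = rep(1, 300), Y = Y)
  m1 <- gedi_initialize(obs, 5)
  m2 <- gedi_initialize(obs, 5)
  expect_identical(m1$B, m2$B)
  expect_identical(m1$Z_r, m2$Z_r)

  sv <- svd(Y - rowMeans(Y), nv = 5)
  expect_lt(max_principal_angle(t(m1$B), sv$v), 1e-8)

  expect_error(gedi_initialize(obs, 150), "min\\(G, N\\)")
})

test_that("single-block updates are exact minimizers", {
  pl <- planted_gaussian(G = 30, K = 2, N = 90, Q = 3, noise = 0.2,
                         delta_o_sd = 0.5, seed = 33)
  obs <- gedi_observations(sample_map = pl$sample_map, Y = pl$Y)
  m <- gedi_initialize(obs, 2)

  # delta_o update equals the hand-derived shrunk per-sample residual mean
  m1 <- update_block(m, obs, "delta_o")
  S <- m$hyper$S_delta_o
  for (i in 1:3) {
    cells <- which(pl$sample_map == i)
    W <- m$Z_r + m$delta_Z[[i]]
    res <- pl$Y[, cells] - m$o_r - W %*% m$B[, cells] -
      rep(m$s[cells], each = 30)
    n_i <- length(cells)
    expect_equal(m1$delta_o[, i],
                 (n_i * rowMeans(res)) / (n_i + 1 / S), tolerance = 1e-10)
  }

  # A update in the vanishing-prior limit is OLS of Z_r on C
  set.seed(33)
  C <- matrix(rbinom(30 * 4, 1, 0.3), 30, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  mp <- gedi_initialize(obs, 2, prior_C = C,
                        hyper = list(S_A = 1e12, S_Z = 1))
  mp <- update_block(mp, obs, "A")
  expect_equal(unname(mp$prior$A),
               unname(qr.solve(C, mp$Z_r)), tolerance = 1e-4)

  # R_o stays zero under an all-zero covariate design
  mz <- gedi_initialize(obs, 2, covariates_H = matrix(0, 2, 3))
  mz <- update_block(mz, obs, "R_o")
  expect_equal(mz$covariates$R_o, matrix(0, 30, 2))

  # each update never increases the penalized objective
  m_cur <- m
  for (blk in c("B", "delta_o", "delta_Z", "o_r", "Z_r", "sigma2")) {
    obj0 <- gedi_objective(m_cur, obs)
    m_cur <- update_block(m_cur, obs, blk)
    expect_gte(gedi_objective(m_cur, obs), obj0 - 1e-8 * abs(obj0))
  }
})

test_that("prior-free single-sample fit recovers the PCA subspace", {
  set.seed(34)
  Y <- matrix(rnorm(120 * 250), 120, 250)
  obs <- gedi_observations(sample_map = rep(1, 250), Y = Y)
  fit <- gedi_fit(obs, k = 4, max_sweeps = 60, tol = 1e-10)
  sv <- svd(Y - rowMeans(Y), nu = 4)
  expect_lt(max_principal_angle(fit$model$Z_r, sv$u), 1e-6)
  expect_lt(max_principal_angle(fit$model$Z_r + fit$model$delta_Z[[1]],
                                sv$u), 1e-6)
})

test_that("planted per-sample translations are recovered", {
  # G >> K: the component of a planted translation lying inside the axis
  # span is exchangeable with a per-sample embedding shift, so recovery
  # loses an O(K/G) share of variance by construction
  pl <- planted_gaussian(G = 200, K = 3, N = 240, Q = 6, noise = 0.1,
                         delta_o_sd = 0.8, seed = 35)
  obs <- gedi_observations(sample_map = pl$sample_map, Y = pl$Y)
  fit <- gedi_fit(obs, k = 3, max_sweeps = 60, tol = 1e-8)
  d_fit <- fit$model$delta_o - rowMeans(fit$model$delta_o)
  d_true <- pl$delta_o - rowMeans(pl$delta_o)
  expect_gt(cor(as.numeric(d_fit), as.numeric(d_true)), 0.99)
})

test_that("exchangeable samples get matching distortions", {
  pl <- planted_gaussian(G = 40, K = 2, N = 100, Q = 1, noise = 0.05,
                         seed = 36)
  # duplicate the sample: identical cells labelled as two samples
  Y <- cbind(pl$Y, pl$Y)
  obs <- gedi_observations(sample_map = rep(1:2, each = 100), Y = Y)
  fit <- gedi_fit(obs, k = 2, max_sweeps = 50, tol = 1e-9)
  expect_lt(norm(fit$model$delta_Z[[1]] - fit$model$delta_Z[[2]], "F"), 1e-3)
  expect_lt(max(abs(fit$model$delta_o[, 1] - fit$model$delta_o[, 2])), 1e-6)
})

test_that("fits keep the objective monotone and the constraints active", {
  pl <- planted_gaussian(G = 50, K = 3, N = 150, Q = 3, noise = 0.3,
                         delta_o_sd = 0.4, seed = 37)
  obs <- gedi_observations(sample_map = pl$sample_map, Y = pl$Y)
  fit <- gedi_fit(obs, k = 3, max_sweeps = 40, tol = 1e-9)
  o <- fit$trace$objective
  expect_true(all(diff(o) >= -1e-6 * abs(o[-length(o)])))
  expect_equal(unname(rowSums(fit$model$B^2)), rep(1, 3), tolerance = 1e-8)
  Zt <- crossprod(fit$model$Z_r)
  expect_lt(max(abs(Zt[upper.tri(Zt)])) / max(diag(Zt)), 1e-8)
})

test_that("covariate effects on the centers are recovered", {
  set.seed(38)
  G <- 200; Q <- 12; L <- 2; K <- 2; N <- Q * 30
  H <- rbind(rep(c(0, 1), 6), rnorm(Q))
  R_o <- matrix(rnorm(G * L, 0, 0.7), G, L)
  pl <- planted_gaussian(G = G, K = K, N = N, Q = Q, noise = 0.1, seed = 38)
  Y <- pl$Y + (R_o %*% H)[, pl$sample_map]     # delta_o_i = R_o h_i exactly
  obs <- gedi_observations(sample_map = pl$sample_map, Y = Y)
  fit <- gedi_fit(obs, k = K, covariates_H = H, max_sweeps = 40, tol = 1e-8)
  for (l in 1:L)
    expect_gt(cor(fit$model$covariates$R_o[, l], R_o[, l]), 0.95)
})

test_that("fixed external embeddings are honored", {
  pl <- planted_gaussian(G = 30, K = 2, N = 60, Q = 2, noise = 0.2,
                         seed = 39)
  B0 <- matrix(rnorm(2 * 60), 2, 60)
  B0 <- B0 / sqrt(rowSums(B0^2))
  obs <- gedi_observations(sample_map = pl$sample_map, Y = pl$Y)
  fit <- gedi_fit(obs, k = 2, fixed_embeddings = B0, max_sweeps = 10,
                  tol = 1e-8)
  expect_equal(unname(fit$model$B), unname(B0), tolerance = 1e-12)
})

test_that("the objective matches an independent term-by-term recomputation", {
  m <- random_model(G = 12, K = 2, N = 18, Q = 3, L = 2, P = 2, seed = 40)
  m$hyper <- list(S_Z = 2, S_A = 3, S_delta_o = 0.5, S_delta_Z = 0.25,
                  S_Ro = 1.5, S_Rk = 2.5)
  m$prior$S_Z <- 2; m$prior$S_A <- 3
  set.seed(40)
  Y <- gedi_decode(m) + matrix(rnorm(12 * 18, 0, 0.3), 12, 18)
  obs <- gedi_observations(sample_map = m$sample_map, Y = Y)

  naive <- local({
    s2 <- m$sigma2; h <- m$hyper
    ll <- sum(dnorm(Y, gedi_decode(m), sqrt(s2), log = TRUE))
    pr <- 0
    for (i in 1:3) {
      mo <- drop(m$covariates$R_o %*% m$covariates$H[, i])
      pr <- pr + sum(dnorm(m$delta_o[, i], mo,
                           sqrt(s2 * h$S_delta_o), log = TRUE))
      mz <- sapply(seq_len(2), function(k)
        drop(m$covariates$R_k[[k]] %*% m$covariates$H[, i]))
      pr <- pr + sum(dnorm(m$delta_Z[[i]], mz,
                           sqrt(s2 * h$S_delta_Z), log = TRUE))
    }
    pr <- pr + sum(dnorm(m$Z_r, m$prior$C %*% m$prior$A,
                         sqrt(s2 * h$S_Z), log = TRUE))
    pr <- pr + sum(dnorm(m$prior$A, 0, sqrt(s2 * h$S_A), log = TRUE))
    pr <- pr + sum(dnorm(m$covariates$R_o, 0, sqrt(s2 * h$S_Ro), log = TRUE))
    for (k in 1:2)
      pr <- pr + sum(dnorm(m$covariates$R_k[[k]], 0,
                           sqrt(s2 * h$S_Rk), log = TRUE))
    ll + pr
  })
  expect_equal(gedi_objective(m, obs), naive, tolerance = 1e-10)
})

test_that("scaling a distortion moves the objective by its prior increment", {
  m <- random_model(G = 10, K = 2, N = 12, Q = 2, seed = 41)
  m$covariates <- NULL
  Y <- gedi_decode(m)                    # zero data residual... for model 1
  obs <- gedi_observations(sample_map = m$sample_map, Y = Y)
  m2 <- m
  m2$delta_Z[[2]] <- 2 * m$delta_Z[[2]]
  cells2 <- which(m$sample_map == 2)
  obs2 <- gedi_observations(sample_map = m$sample_map,
                            Y = gedi_decode(m2))
  S <- m$hyper$S_delta_Z
  expected_drop <- (4 - 1) * sum(m$delta_Z[[2]]^2) / (2 * m$sigma2 * S)
  expect_equal(gedi_objective(m2, obs2) - gedi_objective(m, obs),
               -expected_drop, tolerance = 1e-10)
})

test_that("different seeds land on the same decoded means", {
  pl <- planted_gaussian(G = 40, K = 3, N = 120, Q = 2, noise = 0.2,
                         seed = 42)
  obs <- gedi_observations(sample_map = pl$sample_map, Y = pl$Y)
  f1 <- gedi_fit(obs, k = 3, max_sweeps = 40, tol = 1e-9, seed = 1)
  f2 <- gedi_fit(obs, k = 3, max_sweeps = 40, tol = 1e-9, seed = 99)
  expect_lt(median(abs(gedi_decode(f1$model) - gedi_decode(f2$model))),
            1e-3)
})
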