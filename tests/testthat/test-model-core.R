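test_that("decode reproduces the affine manifold map", {
  m <- random_model(G = 3, K = 2, N = 4, Q = 1, seed = 2)
  m$o_r <- c(0, 0, 0)
  m$Z_r <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)
  m$delta_o[] <- 0
  m$delta_Z[[1]][] <- 0

  # zero embedding, zero intercept -> the center itself
  expect_equal(unname(gedi_decode(m, b = c(0, 0), sample = 1, s = 0)),
               m$o_r)
  # identity-axes arithmetic
  expect_equal(unname(gedi_decode(m, b = c(0.6, 0.8), sample = 1, s = 0.5)),
               c(1.1, 1.3, 0.5))
  # cancellation: delta_Z = -Z_r removes all b dependence
  m2 <- random_model(G = 5, K = 2, N = 4, Q = 1, seed = 3)
  m2$delta_Z[[1]] <- -m2$Z_r
  for (b in list(c(0, 0), c(1, -2), rnorm(2)))
    expect_equal(unname(gedi_decode(m2, b = b, sample = 1, s = 0.7)),
                 m2$o_r + m2$delta_o[, 1] + 0.7)
})

test_that("decode is exactly linear in b and s", {
  m <- random_model(G = 25, K = 4, N = 10, Q = 2, seed = 4)
  b1 <- rnorm(4); b2 <- rnorm(4)
  d0 <- gedi_decode(m, b = rep(0, 4), sample = 2, s = 0)
  d1 <- gedi_decode(m, b = b1, sample = 2, s = 0)
  d2 <- gedi_decode(m, b = b2, sample = 2, s = 0)
  d12 <- gedi_decode(m, b = b1 + b2, sample = 2, s = 0)
  expect_equal(d12 - d0, (d1 - d0) + (d2 - d0), tolerance = 1e-12)
  expect_equal(gedi_decode(m, b = b1, sample = 2, s = 3) - d1,
               rep(3, 25), ignore_attr = TRUE)
})

test_that("decode rejects mismatched blocks with a structured error", {
  m <- random_model()
  expect_error(gedi_decode(m, b = rnorm(7), sample = 1),
               class = "gedi_dim_error")
  expect_error(gedi_decode(m, b = rnorm(3), sample = 99),
               class = "gedi_dim_error")
})

test_that("gauge renormalization fixes B rows without moving any mean", {
  # hand example: row (3,4) becomes (0.6,0.8), the axis column absorbs 5
  m <- random_model(G = 4, K = 1, N = 2, Q = 1, seed = 5)
  m$B <- matrix(c(3, 4), 1, 2)
  z <- m$Z_r
  dz <- m$delta_Z[[1]]
  before <- gedi_decode(m)
  m2 <- renormalize_gauge(m)
  expect_equal(m2$B, matrix(c(0.6, 0.8), 1, 2))
  expect_equal(m2$Z_r, z * 5)
  expect_equal(m2$delta_Z[[1]], dz * 5)
  expect_equal(gedi_decode(m2), before, tolerance = 1e-12)

  # already unit rows: identity
  m3 <- random_model(seed = 6)
  m3$B <- m3$B / sqrt(rowSums(m3$B^2))
  expect_equal(renormalize_gauge(m3), m3)

  # random 5 x 50 case: likelihood invariance oracle via recomputation
  m4 <- random_model(G = 30, K = 5, N = 50, Q = 2, seed = 7)
  expect_lt(max(abs(gedi_decode(renormalize_gauge(m4)) - gedi_decode(m4))),
            1e-10)
  expect_equal(unname(rowSums(renormalize_gauge(m4)$B^2)), rep(1, 5))

  m4$B[2, ] <- 0
  expect_error(renormalize_gauge(m4), "degenerate")
})

test_that("orthogonalization preserves span and Frobenius norm", {
  # orthogonal input unchanged
  Z <- qr.Q(qr(matrix(rnorm(40), 10, 4))) %*% diag(c(3, 2, 1.5, 1))
  expect_equal(enforce_orthogonality(Z), Z, tolerance = 1e-12)

  # span check on the 3 x 2 example
  Z2 <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)
  O2 <- enforce_orthogonality(Z2)
  expect_lt(abs(sum(O2[, 1] * O2[, 2])), 1e-10)
  expect_lt(max_principal_angle(O2, diag(3)[, 1:2]), 1e-10)

  # random case: subspace angle oracle + norm preservation
  set.seed(8)
  Z3 <- matrix(rnorm(250), 50, 5)
  O3 <- enforce_orthogonality(Z3)
  expect_lt(max_principal_angle(Z3, O3), 1e-8)
  expect_equal(sum(O3^2), sum(Z3^2), tolerance = 1e-8)
  G3 <- crossprod(O3)
  expect_lt(max(abs(G3[upper.tri(G3)])) / max(diag(G3)), 1e-8)

  # rank-deficient input is refused with the dependent columns named
  Z4 <- cbind(Z3[, 1], Z3[, 1] * 2, Z3[, 2])
  expect_error(enforce_orthogonality(Z4), class = "gedi_rank_error")
})

test_that("ellipsoid projection satisfies both constraints", {
  # K = 1, d = 1, one cell: sign preserved, both constraints exact
  B1 <- matrix(-0.4, 1, 1)
  expect_equal(project_ellipsoid(B1, 1), matrix(-1, 1, 1))

  # feasible input unchanged
  set.seed(9)
  K <- 3; N <- 40
  B <- matrix(rnorm(K * N), K, N)
  B <- B / sqrt(rowSums(B^2))
  d <- sqrt(K * rowMeans(B^2))
  d <- d * sqrt(sum(1 / d^2) / N)
  Bf <- project_ellipsoid(B, d, tol = 1e-9, max_iter = 500)
  expect_equal(project_ellipsoid(Bf, d, tol = 1e-9), Bf, tolerance = 1e-9)

  # constraint-evaluation oracle on the projected result
  expect_lt(max(abs(sqrt(rowSums(Bf^2)) - 1)), 1e-9)
  expect_lt(max(abs(sqrt(colSums((Bf / d)^2)) - 1)), 1e-9)

  expect_error(project_ellipsoid(B, c(1, -1, 1)), "positive")
})

test_that("activities and gradients follow the prior-block algebra", {
  m <- random_model(G = 30, K = 3, N = 20, Q = 2, P = 3, seed = 10)

  # A = identity -> activities equal B
  m$prior$A <- diag(3)
  rownames(m$prior$A) <- paste0("set", 1:3)
  expect_equal(unname(activities(m)), m$B)

  # zero row -> zero activities; gradients follow
  m$prior$A[2, ] <- 0
  expect_equal(unname(activities(m)[2, ]), rep(0, 20))
  expect_equal(unname(activity_gradient(m, 2)), rep(0, 30))
  expect_equal(unname(activity_gradient(m, 1)), m$Z_r[, 1])

  # random case: naive loop oracle
  m$prior$A <- matrix(rnorm(9), 3, 3,
                      dimnames = list(paste0("set", 1:3), NULL))
  act <- activities(m)
  for (p in 1:3) for (n in c(1, 7, 20))
    expect_equal(act[p, n], sum(m$prior$A[p, ] * m$B[, n]))
  expect_equal(unname(activity_gradient(m, 3)),
               drop(m$Z_r %*% m$prior$A[3, ]))

  expect_error(activity_gradient(m, 9), "out of range")
  m$prior <- NULL
  expect_error(activities(m), "prior")
})

test_that("activities are invariant to sample transforms", {
  m <- random_model(G = 30, K = 3, N = 20, Q = 2, P = 3, seed = 11)
  a1 <- activities(m)
  m$delta_o <- m$delta_o + 5
  m$delta_Z <- lapply(m$delta_Z, function(d) d * 3)
  expect_identical(activities(m), a1)
})

test_that("the model archive round-trips", {
  m <- random_model(G = 15, K = 3, N = 12, Q = 2, L = 2, P = 2, seed = 12)
  m$seed <- 42L
  dir <- withr::local_tempdir()
  write_gedi_model(m, dir)
  m2 <- read_gedi_model(dir)
  for (fld in c("o_r", "Z_r", "delta_o", "B", "s", "sigma2"))
    expect_equal(unname(as.matrix(m2[[fld]])), unname(as.matrix(m[[fld]])),
                 tolerance = 1e-12)
  for (i in 1:2)
    expect_equal(unname(m2$delta_Z[[i]]), unname(m$delta_Z[[i]]),
                 tolerance = 1e-12)
  expect_equal(unname(m2$covariates$R_o), unname(m$covariates$R_o),
               tolerance = 1e-12)
  expect_equal(unname(m2$prior$A), unname(m$prior$A), tolerance = 1e-12)
  expect_identical(m2$mode, m$mode)
  expect_identical(m2$samples, m$samples)
  expect_identical(m2$sample_map, m$sample_map)
  expect_identical(m2$seed, m$seed)
  expect_equal(m2$hyper, m$hyper)

  # manifest is byte-stable under rewrite
  man1 <- readLines(file.path(dir, "manifest.txt"))
  dir2 <- withr::local_tempdir()
  write_gedi_model(m2, dir2)
  expect_identical(readLines(file.path(dir2, "manifest.txt")), man1)
})
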