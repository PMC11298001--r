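#' Initialize a model from observations
#'
#' Deterministic initialization used by [gedi_fit()]: cell embeddings come
#' from a truncated SVD of the mode-appropriate transform of the data
#' (gaussian: row-centered `Y`; poisson: row-centered `log1p` of
#' depth-normalized counts; binomial: row-centered
#' `logit((m1 + 0.5)/(m1 + m2 + 1))`), per-sample distortions start at
#' zero, and the cell intercept starts at the log total count in poisson
#' mode (zero otherwise). SVD signs are fixed so each axis column's
#' largest-magnitude loading is positive.
#'
#' @param observations a [gedi_observations] object.
#' @param k number of latent factors (K).
#' @param prior_C optional G x P gene-level prior matrix.
#' @param covariates_H optional L x Q sample covariate matrix (columns in
#'   sample order).
#' @param hyper prior-variance ratios; see [new_gedi_model()].
#' @param orthogonalize,ellipsoid constraint flags carried into the model.
#' @param fixed_embeddings optional externally supplied K x N embedding
#'   matrix, held fixed during fitting.
#' @return an unfitted `gedi_model`.
#' @export
gedi_initialize <- function(observations, k, prior_C = NULL,
                            covariates_H = NULL, hyper = NULL,
                            orthogonalize = TRUE, ellipsoid = FALSE,
                            fixed_embeddings = NULL) {
  d <- obs_dim(observations)
  G <- d[1]; N <- d[2]
  Q <- length(observations$samples)
  if (k < 1 || k > min(G, N))
    gedi_stop("k must be between 1 and min(G, N) = ", min(G, N))
  hyper <- utils::modifyList(default_hyper(Q, N), hyper %||% list())

  if (observations$mode == "gaussian") {
    T_ <- obs_dense(observations$Y)
    s <- rep(0, N)
    o_r <- rowMeans(T_)
  } else if (observations$mode == "poisson") {
    M <- obs_dense(observations$M)
    depth <- colSums(M)
    if (any(depth <= 0)) gedi_stop("poisson mode requires nonzero columns")
    mbar <- mean(depth)
    T_ <- log1p(sweep(M, 2, depth, `/`) * mbar)
    s <- log(depth)
    o_r <- rowMeans(T_) - log(mbar)
  } else {
    M1 <- obs_dense(observations$M1); M2 <- obs_dense(observations$M2)
    T_ <- logit((M1 + 0.5) / (M1 + M2 + 1))
    s <- rep(0, N)
    o_r <- rowMeans(T_)
  }
  X <- T_ - rowMeans(T_)

  if (is.null(fixed_embeddings)) {
    sv <- svd(X, nu = k, nv = k)
    sgn <- vapply(seq_len(k), function(j) {
      u <- sv$u[, j]
      if (u[which.max(abs(u))] < 0) -1 else 1
    }, numeric(1))
    Z_r <- sweep(sv$u, 2, sgn * sv$d[seq_len(k)], `*`)
    B <- t(sv$v) * sgn
  } else {
    B <- as.matrix(fixed_embeddings)
    if (!identical(dim(B), c(as.integer(k), as.integer(N))))
      gedi_stop("fixed_embeddings must be K x N", class = "gedi_dim_error")
    Z_r <- X %*% t(B) %*% solve(tcrossprod(B) + diag(1 / hyper$S_Z, k))
  }

  resid <- X - Z_r %*% B
  sigma2 <- max(mean(resid^2), 1e-10)

  prior <- NULL
  if (!is.null(prior_C)) {
    C <- as.matrix(prior_C)
    if (nrow(C) != G)
      gedi_stop("prior_C must have G = ", G, " rows",
                class = "gedi_dim_error")
    P <- ncol(C)
    A <- matrix(0, P, k,
                dimnames = list(colnames(C) %||% paste0("set", seq_len(P)),
                                NULL))
    prior <- list(C = C, A = A, S_Z = hyper$S_Z, S_A = hyper$S_A)
  }
  covariates <- NULL
  if (!is.null(covariates_H)) {
    H <- as.matrix(covariates_H)
    if (ncol(H) != Q)
      gedi_stop("covariates_H must have Q = ", Q, " columns",
                class = "gedi_dim_error")
    L <- nrow(H)
    covariates <- list(H = H, R_o = matrix(0, G, L),
                       R_k = replicate(k, matrix(0, G, L), simplify = FALSE),
                       names = rownames(H) %||% paste0("h", seq_len(L)))
  }

  new_gedi_model(
    o_r = o_r, Z_r = Z_r,
    delta_o = matrix(0, G, Q),
    delta_Z = replicate(Q, matrix(0, G, k), simplify = FALSE),
    B = B, s = s, sigma2 = sigma2, mode = observations$mode,
    sample_map = observations$sample_map, samples = observations$samples,
    genes = observations$genes, cells = observations$cells,
    prior = prior, covariates = covariates, hyper = hyper,
    orthogonal_axes = orthogonalize, ellipsoid = ellipsoid
  )
}

## E-step: posterior moments of the latent profile under the current model.
fit_estep <- function(model, observations) {
  d <- obs_dim(observations)
  if (observations$mode == "gaussian")
    return(list(Ey = obs_dense(observations$Y),
                Vy = matrix(0, d[1], d[2])))
  mu <- gedi_decode(model)
  if (observations$mode == "poisson") {
    e <- poisson_estep(obs_dense(observations$M), mu, model$sigma2)
  } else {
    e <- binomial_estep(obs_dense(observations$M1),
                        obs_dense(observations$M2), mu, model$sigma2)
  }
  list(Ey = matrix(e$Ey, d[1], d[2]), Vy = matrix(e$Vy, d[1], d[2]))
}

sample_index <- function(model)
  split(seq_along(model$sample_map), model$sample_map)

## Prior means of the sample distortions given covariates (zero otherwise).
prior_delta_o <- function(model, i) {
  if (is.null(model$covariates)) return(0)
  drop(model$covariates$R_o %*% model$covariates$H[, i])
}
prior_delta_Z <- function(model, i) {
  K <- ncol(model$Z_r)
  if (is.null(model$covariates)) return(matrix(0, length(model$o_r), K))
  h <- model$covariates$H[, i]
  vapply(seq_len(K), function(k) drop(model$covariates$R_k[[k]] %*% h),
         numeric(length(model$o_r)))
}

## Exact coordinate updates. Each is the minimizer of the penalized
## objective for its own block with everything else held fixed; all reduce
## to (ridge) least squares because every layer above the data is Gaussian.
update_B_block <- function(model, Ey, idx) {
  for (i in seq_along(idx)) {
    n_i <- idx[[i]]
    W <- model$Z_r + model$delta_Z[[i]]
    R <- Ey[, n_i, drop = FALSE] - (model$o_r + model$delta_o[, i])
    R <- sweep(R, 2, model$s[n_i], `-`)
    WtW <- crossprod(W)
    diag(WtW) <- diag(WtW) + 1e-10 * mean(diag(WtW))
    model$B[, n_i] <- solve(WtW, crossprod(W, R))
  }
  model
}

update_s_block <- function(model, Ey, idx) {
  for (i in seq_along(idx)) {
    n_i <- idx[[i]]
    W <- model$Z_r + model$delta_Z[[i]]
    R <- Ey[, n_i, drop = FALSE] - (model$o_r + model$delta_o[, i]) -
      W %*% model$B[, n_i, drop = FALSE]
    model$s[n_i] <- colMeans(R)
  }
  model
}

update_delta_o_block <- function(model, Ey, idx) {
  S <- model$hyper$S_delta_o
  for (i in seq_along(idx)) {
    n_i <- idx[[i]]
    W <- model$Z_r + model$delta_Z[[i]]
    R <- Ey[, n_i, drop = FALSE] - model$o_r -
      W %*% model$B[, n_i, drop = FALSE]
    R <- sweep(R, 2, model$s[n_i], `-`)
    model$delta_o[, i] <-
      (rowSums(R) + prior_delta_o(model, i) / S) / (length(n_i) + 1 / S)
  }
  model
}

update_delta_Z_block <- function(model, Ey, idx) {
  S <- model$hyper$S_delta_Z
  K <- ncol(model$Z_r)
  for (i in seq_along(idx)) {
    n_i <- idx[[i]]
    B_i <- model$B[, n_i, drop = FALSE]
    R <- Ey[, n_i, drop = FALSE] - (model$o_r + model$delta_o[, i]) -
      model$Z_r %*% B_i
    R <- sweep(R, 2, model$s[n_i], `-`)
    G_mat <- tcrossprod(B_i) + diag(1 / S, K)
    model$delta_Z[[i]] <-
      t(solve(G_mat, t(R %*% t(B_i) + prior_delta_Z(model, i) / S)))
  }
  model
}

update_o_r_block <- function(model, Ey, idx) {
  R <- Ey
  for (i in seq_along(idx)) {
    n_i <- idx[[i]]
    W <- model$Z_r + model$delta_Z[[i]]
    R[, n_i] <- R[, n_i, drop = FALSE] - model$delta_o[, i] -
      W %*% model$B[, n_i, drop = FALSE]
  }
  R <- sweep(R, 2, model$s, `-`)
  model$o_r <- rowMeans(R)
  model
}

update_Z_r_block <- function(model, Ey, idx) {
  K <- ncol(model$Z_r)
  S_Z <- model$hyper$S_Z
  RBt <- matrix(0, length(model$o_r), K)
  BBt <- matrix(0, K, K)
  for (i in seq_along(idx)) {
    n_i <- idx[[i]]
    B_i <- model$B[, n_i, drop = FALSE]
    R <- Ey[, n_i, drop = FALSE] - (model$o_r + model$delta_o[, i]) -
      model$delta_Z[[i]] %*% B_i
    R <- sweep(R, 2, model$s[n_i], `-`)
    RBt <- RBt + R %*% t(B_i)
    BBt <- BBt + tcrossprod(B_i)
  }
  M0 <- if (!is.null(model$prior)) model$prior$C %*% model$prior$A else 0
  model$Z_r <- t(solve(BBt + diag(1 / S_Z, K), t(RBt + M0 / S_Z)))
  model
}

update_A_block <- function(model) {
  if (is.null(model$prior)) return(model)
  C <- model$prior$C
  P <- ncol(C)
  lhs <- crossprod(C) / model$prior$S_Z + diag(1 / model$prior$S_A, P)
  model$prior$A[] <- solve(lhs, crossprod(C, model$Z_r) / model$prior$S_Z)
  model
}

update_R_o_block <- function(model) {
  if (is.null(model$covariates)) return(model)
  H <- model$covariates$H
  L <- nrow(H)
  ratio <- model$hyper$S_delta_o / model$hyper$S_Ro
  model$covariates$R_o <-
    model$delta_o %*% t(H) %*% solve(tcrossprod(H) + diag(ratio, L))
  model
}

update_R_k_block <- function(model) {
  if (is.null(model$covariates)) return(model)
  H <- model$covariates$H
  L <- nrow(H)
  ratio <- model$hyper$S_delta_Z / model$hyper$S_Rk
  G_inv <- solve(tcrossprod(H) + diag(ratio, L))
  for (k in seq_len(ncol(model$Z_r))) {
    Dz_k <- vapply(model$delta_Z, function(dz) dz[, k],
                   numeric(length(model$o_r)))
    model$covariates$R_k[[k]] <- Dz_k %*% t(H) %*% G_inv
  }
  model
}

## Joint (marginal) updates of a covariate-effect matrix and its sample
## distortions. The per-sweep conditional updates of (delta, R) alone mix
## extremely slowly when the distortion prior is tight (contraction
## 1/(1 + S*n) per sweep), so the fitting loop instead solves the two
## levels jointly: R is estimated from the marginal model with the
## distortions integrated out (a gene-wise generalized ridge whose
## curvature is shared across genes), then the distortions are refreshed
## conditional on R. Exact block minimization, hence still monotone.
update_center_joint <- function(model, Ey, idx) {
  if (!is.null(model$covariates)) {
    S <- model$hyper$S_delta_o
    H <- model$covariates$H
    L <- nrow(H)
    n_i <- lengths(idx)
    RS <- matrix(0, length(model$o_r), length(idx))   # per-sample row sums
    for (i in seq_along(idx)) {
      cells_i <- idx[[i]]
      W <- model$Z_r + model$delta_Z[[i]]
      R <- Ey[, cells_i, drop = FALSE] - model$o_r -
        W %*% model$B[, cells_i, drop = FALSE]
      RS[, i] <- rowSums(R) - sum(model$s[cells_i])
    }
    shrink <- 1 / (1 + S * n_i)
    gram <- H %*% (t(H) * (n_i * shrink)) + diag(1 / model$hyper$S_Ro, L)
    rhs <- (H %*% (t(RS) * shrink))                   # L x G
    model$covariates$R_o <- t(solve(gram, rhs))
  }
  update_delta_o_block(model, Ey, idx)
}

update_axes_joint <- function(model, Ey, idx) {
  if (!is.null(model$covariates)) {
    S <- model$hyper$S_delta_Z
    H <- model$covariates$H
    L <- nrow(H); K <- ncol(model$Z_r); G <- length(model$o_r)
    gram <- matrix(0, K * L, K * L)
    RHS <- matrix(0, G, K * L)
    for (i in seq_along(idx)) {
      cells_i <- idx[[i]]
      B_i <- model$B[, cells_i, drop = FALSE]
      G_i <- tcrossprod(B_i)
      Minv <- solve(diag(K) + S * G_i)
      R <- Ey[, cells_i, drop = FALSE] - (model$o_r + model$delta_o[, i]) -
        model$Z_r %*% B_i
      R <- sweep(R, 2, model$s[cells_i], `-`)
      C_i <- R %*% t(B_i) %*% Minv                    # G x K
      h <- H[, i]
      gram <- gram + kronecker(tcrossprod(h), G_i %*% Minv)
      for (l in seq_len(L))
        RHS[, (l - 1) * K + seq_len(K)] <-
          RHS[, (l - 1) * K + seq_len(K)] + C_i * h[l]
    }
    gram <- gram + diag(1 / model$hyper$S_Rk, K * L)
    vecR <- solve(gram, t(RHS))                       # KL x G
    for (k in seq_len(K))
      model$covariates$R_k[[k]] <-
        t(vecR[(seq_len(L) - 1) * K + k, , drop = FALSE])
  }
  update_delta_Z_block(model, Ey, idx)
}

## Pooled sigma^2 M-step: every prior variance is written proportional to
## sigma^2, so all quadratic forms and their dimensions pool into one MAP
## estimate.
update_sigma2_block <- function(model, Ey, Vy) {
  qf <- prior_quadforms(model)
  mu <- gedi_decode(model)
  num <- sum((Ey - mu)^2) + sum(Vy) + qf$num
  df <- length(Ey) + qf$df
  model$sigma2 <- max(num / df, 1e-12)
  model
}

## Quadratic forms and dimension counts of all sigma^2-scaled priors.
prior_quadforms <- function(model) {
  G <- length(model$o_r); K <- ncol(model$Z_r)
  Q <- length(model$delta_Z)
  h <- model$hyper
  num <- 0; df <- 0
  for (i in seq_len(Q)) {
    num <- num + sum((model$delta_o[, i] - prior_delta_o(model, i))^2) /
      h$S_delta_o
    num <- num + sum((model$delta_Z[[i]] - prior_delta_Z(model, i))^2) /
      h$S_delta_Z
  }
  df <- df + G * Q + G * K * Q
  M0 <- if (!is.null(model$prior)) model$prior$C %*% model$prior$A else 0
  num <- num + sum((model$Z_r - M0)^2) / h$S_Z
  df <- df + G * K
  if (!is.null(model$prior)) {
    num <- num + sum(model$prior$A^2) / h$S_A
    df <- df + length(model$prior$A)
  }
  if (!is.null(model$covariates)) {
    num <- num + sum(model$covariates$R_o^2) / h$S_Ro
    df <- df + length(model$covariates$R_o)
    num <- num + sum(vapply(model$covariates$R_k,
                            function(R) sum(R^2), numeric(1))) / h$S_Rk
    df <- df + length(model$covariates$R_k[[1]]) * K
  }
  list(num = num, df = df)
}

#' Penalized log-posterior of a model
#'
#' Sum of the data-layer log-likelihood (or its evidence lower bound in the
#' latent count modes) and all Gaussian prior terms, each scaled by its
#' prior-variance ratio times the model variance. This is the quantity the
#' fitting loop maximizes and monitors for convergence.
#'
#' @inheritParams loglik_observed
#' @return scalar penalized log-posterior.
#' @export
gedi_objective <- function(model, observations, posterior = NULL) {
  ll <- loglik_observed(model, observations, posterior)
  qf <- prior_quadforms(model)
  s2 <- model$sigma2
  h <- model$hyper
  G <- length(model$o_r); K <- ncol(model$Z_r); Q <- length(model$delta_Z)
  logdet <- G * Q * log(2 * pi * s2 * h$S_delta_o) +
    G * K * Q * log(2 * pi * s2 * h$S_delta_Z) +
    G * K * log(2 * pi * s2 * h$S_Z)
  if (!is.null(model$prior))
    logdet <- logdet + length(model$prior$A) * log(2 * pi * s2 * h$S_A)
  if (!is.null(model$covariates)) {
    logdet <- logdet +
      length(model$covariates$R_o) * log(2 * pi * s2 * h$S_Ro) +
      length(model$covariates$R_k[[1]]) * K * log(2 * pi * s2 * h$S_Rk)
  }
  ll - qf$num / (2 * s2) - logdet / 2
}

#' Refresh one parameter block
#'
#' Updates a single block of the model to the exact minimizer of the
#' penalized objective given all other blocks (one step of the block
#' coordinate descent). In the latent count modes the E-step posterior is
#' recomputed first.
#'
#' @param model a `gedi_model`.
#' @param observations matching `gedi_observations`.
#' @param block one of `"B"`, `"s"`, `"delta_o"`, `"delta_Z"`, `"o_r"`,
#'   `"Z_r"`, `"A"`, `"R_o"`, `"R_k"`, `"sigma2"`.
#' @return the model with the block refreshed.
#' @export
update_block <- function(model, observations, block) {
  block <- match.arg(block, c("B", "s", "delta_o", "delta_Z", "o_r", "Z_r",
                              "A", "R_o", "R_k", "sigma2"))
  e <- fit_estep(model, observations)
  idx <- sample_index(model)
  switch(block,
    B = update_B_block(model, e$Ey, idx),
    s = update_s_block(model, e$Ey, idx),
    delta_o = update_delta_o_block(model, e$Ey, idx),
    delta_Z = update_delta_Z_block(model, e$Ey, idx),
    o_r = update_o_r_block(model, e$Ey, idx),
    Z_r = update_Z_r_block(model, e$Ey, idx),
    A = update_A_block(model),
    R_o = update_R_o_block(model),
    R_k = update_R_k_block(model),
    sigma2 = update_sigma2_block(model, e$Ey, e$Vy))
}

## Change of basis making Z_r columns orthogonal while leaving every
## decoded mean unchanged: Z -> Z T, dZ_i -> dZ_i T, B -> T^{-1} B.
apply_orthogonality <- function(model) {
  Z <- model$Z_r
  K <- ncol(Z)
  if (K == 1L) return(model)
  cn <- sqrt(colSums(Z^2))
  S <- crossprod(Z)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values)) return(model)  # skip if unstable
  S_invsqrt <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  T_mat <- S_invsqrt %*% diag(cn, K)
  T_inv <- diag(1 / cn, K) %*% (e$vectors %*% (t(e$vectors) * sqrt(e$values)))
  model$Z_r <- Z %*% T_mat
  model$delta_Z <- lapply(model$delta_Z, function(dz) dz %*% T_mat)
  model$B <- T_inv %*% model$B
  model
}

## Per-sweep constraints are limited to decode-invariant (orthogonality)
## or explicitly requested projections (ellipsoid). The unit-row gauge is
## applied once after the final sweep: inside the loop it would rescale
## the axis columns against their own ridge every sweep (the B update
## re-absorbs the inverse of the axis shrinkage), producing a persistent
## scale limit-cycle that leaks a few 1e-6 of objective per sweep.
apply_constraints <- function(model, fixed_B = FALSE, final = FALSE) {
  if (fixed_B) return(model)   # externally supplied B is never touched
  if (model$orthogonal_axes) model <- apply_orthogonality(model)
  if (!final && !model$ellipsoid) return(model)
  if (model$ellipsoid) {
    ## semi-axes from the pre-gauge per-factor spread, scaled by sqrt(K)
    ## so the row and column constraint sets intersect, then rescaled so
    ## that sum(1/d_k^2) = N (the exact compatibility condition implied by
    ## unit row norms)
    K <- nrow(model$B); N <- ncol(model$B)
    d_raw <- sqrt(K * rowMeans(model$B^2))
    d <- d_raw * sqrt(sum(1 / d_raw^2) / N)
    model$B <- project_ellipsoid(model$B, d, tol = 1e-6, max_iter = 200)
    model$d <- d
  }
  renormalize_gauge(model)
}

#' Fit the model by MAP block coordinate descent / EM
#'
#' Iteratively sweeps all parameter blocks. In gaussian mode each sweep is
#' plain block coordinate descent on the penalized objective; in the count
#' modes each sweep starts with an E-step that replaces the latent profile
#' by its posterior moments (expectation-maximization). After each sweep
#' the gauge, orthogonality and (optionally) ellipsoid constraints are
#' applied. Iteration stops when the relative objective change falls below
#' `tol` or after `max_sweeps`.
#'
#' @inheritParams gedi_initialize
#' @param max_sweeps maximum number of full sweeps (default 200).
#' @param tol relative objective tolerance (default 1e-6).
#' @param seed integer seed recorded with the fit (initialization is
#'   deterministic; the seed guards any future stochastic extension).
#' @param verbose print per-sweep objective.
#' @return list with elements `model` (fitted `gedi_model`) and `trace`
#'   (data frame of per-sweep objective, update norm, and elapsed seconds).
#' @examples
#' params <- sim_params(G = 60, N = 200, Q = 4, K_arch = 3, seed = 1)
#' sim <- simulate_cohort(params)
#' obs <- gedi_observations(sample_map = sim$sample_map, M = sim$counts)
#' fit <- gedi_fit(obs, k = 3, covariates_H = params$H, max_sweeps = 10)
#' field <- vector_field(fit$model, "condition")
#' head(field$magnitudes)
#' @export
gedi_fit <- function(observations, k, prior_C = NULL, covariates_H = NULL,
                     hyper = NULL, orthogonalize = TRUE, ellipsoid = FALSE,
                     fixed_embeddings = NULL, max_sweeps = 200, tol = 1e-6,
                     seed = 1, verbose = FALSE) {
  set.seed(seed)
  model <- gedi_initialize(observations, k, prior_C = prior_C,
                           covariates_H = covariates_H, hyper = hyper,
                           orthogonalize = orthogonalize,
                           ellipsoid = ellipsoid,
                           fixed_embeddings = fixed_embeddings)
  fixed_B <- !is.null(fixed_embeddings)
  idx <- sample_index(model)
  trace <- data.frame(sweep = integer(), objective = numeric(),
                      delta_norm = numeric(), seconds = numeric())
  obj_prev <- -Inf
  for (sweep in seq_len(max_sweeps)) {
    t0 <- proc.time()[["elapsed"]]
    par_prev <- c(model$o_r, model$Z_r, model$B)
    e <- fit_estep(model, observations)
    if (!fixed_B) model <- update_B_block(model, e$Ey, idx)
    ## constraints directly after the embedding update: the orthogonality
    ## basis change leaves every decoded mean untouched but perturbs the
    ## axis priors, so all prior-bearing blocks re-minimize below before
    ## the objective is recorded (keeps the trace monotone)
    model <- apply_constraints(model, fixed_B = fixed_B)
    ## the cell intercept is a library-size term: only the poisson layer
    ## has one (a free intercept in the other modes would fold the ones
    ## vector into the axis span and break the PCA correspondence)
    if (model$mode == "poisson") model <- update_s_block(model, e$Ey, idx)
    model <- update_o_r_block(model, e$Ey, idx)
    model <- update_Z_r_block(model, e$Ey, idx)
    model <- update_A_block(model)
    model <- update_center_joint(model, e$Ey, idx)
    model <- update_axes_joint(model, e$Ey, idx)
    model <- update_sigma2_block(model, e$Ey, e$Vy)
    obj <- gedi_objective(model, observations,
                          posterior = if (model$mode == "gaussian") NULL
                                      else list(Ey = e$Ey, Vy = e$Vy))
    if (!is.finite(obj)) {
      print(utils::tail(trace))
      gedi_stop("non-finite objective at sweep ", sweep)
    }
    dn <- sqrt(sum((c(model$o_r, model$Z_r, model$B) - par_prev)^2))
    trace <- rbind(trace, data.frame(
      sweep = sweep, objective = obj, delta_norm = dn,
      seconds = proc.time()[["elapsed"]] - t0))
    if (verbose)
      message(sprintf("sweep %3d  objective %.6e  |delta| %.3e",
                      sweep, obj, dn))
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) < tol * abs(obj_prev)) break
    obj_prev <- obj
  }
  ## leave the returned model on the constraint set (decode-invariant for
  ## gauge/orthogonality), with the dependent prior blocks re-minimized
  model <- apply_constraints(model, fixed_B = fixed_B, final = TRUE)
  model <- update_A_block(model)
  model <- update_R_o_block(model)
  model <- update_R_k_block(model)
  if (!fixed_B) model <- canonicalize_factors(model)
  model$fitted <- TRUE
  model$seed <- seed
  list(model = model, trace = trace)
}
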