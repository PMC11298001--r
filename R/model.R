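#' Construct a gedi model object
#'
#' A `gedi_model` holds the complete parameter set of the shared-manifold
#' model: the reference manifold (center `o_r`, axes `Z_r`), per-sample
#' affine distortions (`delta_o`, `delta_Z`), per-cell embeddings `B` with
#' intercepts `s`, the spherical model variance `sigma2`, and the optional
#' gene-level prior block (`C`, `A`) and sample-covariate block
#' (`H`, `R_o`, `R_k`).
#'
#' The expected expression profile of cell `n` from sample `i = i(n)` is the
#' affine image
#' \deqn{\mu_n = o_r + \Delta o_i + (Z_r + \Delta Z_i) b_n + s_n 1_G.}
#'
#' @param o_r numeric length-G center of the reference manifold.
#' @param Z_r G x K matrix of reference axes (columns).
#' @param delta_o G x Q matrix of per-sample center translations.
#' @param delta_Z list of Q G x K matrices of per-sample axis distortions.
#' @param B K x N matrix of cell embeddings.
#' @param s numeric length-N vector of cell intercepts.
#' @param sigma2 positive scalar model variance.
#' @param mode one of `"gaussian"`, `"poisson"`, `"binomial"`.
#' @param sample_map integer vector length N mapping each cell to its sample
#'   (values in `1..Q`).
#' @param samples character vector of sample identifiers (length Q).
#' @param genes,cells optional identifier vectors.
#' @param prior optional gene-level prior block: a list with elements
#'   `C` (G x P), `A` (P x K), `S_Z`, `S_A`.
#' @param covariates optional covariate block: list with `H` (L x Q),
#'   `R_o` (G x L), `R_k` (list of K G x L matrices).
#' @param hyper named list of prior-variance ratios
#'   (`S_Z`, `S_A`, `S_delta_o`, `S_delta_Z`, `S_Ro`, `S_Rk`).
#' @param orthogonal_axes,ellipsoid logical flags for the axis-orthogonality
#'   and hyperellipsoid constraints.
#' @param d optional positive length-K vector of ellipsoid semi-axes.
#' @param fitted logical; marks a model as the output of [gedi_fit()].
#'
#' @return an object of class `gedi_model`.
#' @export
new_gedi_model <- function(o_r, Z_r, delta_o, delta_Z, B, s, sigma2,
                           mode = c("gaussian", "poisson", "binomial"),
                           sample_map, samples = NULL,
                           genes = NULL, cells = NULL,
                           prior = NULL, covariates = NULL,
                           hyper = default_hyper(length(delta_Z), ncol(B)),
                           orthogonal_axes = TRUE, ellipsoid = FALSE,
                           d = NULL, fitted = FALSE) {
  mode <- match.arg(mode)
  Z_r <- as.matrix(Z_r); delta_o <- as.matrix(delta_o); B <- as.matrix(B)
  model <- structure(list(
    o_r = as.numeric(o_r), Z_r = Z_r, delta_o = delta_o,
    delta_Z = lapply(delta_Z, as.matrix), B = B, s = as.numeric(s),
    sigma2 = sigma2, mode = mode,
    sample_map = as.integer(sample_map),
    samples = samples %||% paste0("sample", seq_along(delta_Z)),
    genes = genes %||% paste0("g", seq_along(o_r)),
    cells = cells %||% paste0("cell", seq_len(ncol(B))),
    prior = prior, covariates = covariates, hyper = hyper,
    orthogonal_axes = orthogonal_axes, ellipsoid = ellipsoid,
    d = d, fitted = fitted
  ), class = "gedi_model")
  validate_gedi_model(model)
  model
}

## Default prior-variance ratios. The gauge (unit-row B) puts the whole
## signal scale into the axis matrices: a factor contributing unit signal
## variance per entry has column norm ~ sqrt(N G), i.e. entries of Z_r,
## delta_Z and R_k scale like sqrt(N). Their variance ratios therefore
## carry a factor N so that the implied prior on the *reconstructed
## signal* (z b) is O(sigma^2), independent of the number of cells.
## Translation-scale blocks (delta_o, R_o) are O(1) and per-sample
## distortions shrink with 1/Q.
default_hyper <- function(Q, N) {
  N <- as.numeric(N); Q <- as.numeric(Q)
  list(S_Z = N, S_A = N, S_delta_o = 1 / Q, S_delta_Z = N / Q,
       S_Ro = 1, S_Rk = N)
}

#' @export
print.gedi_model <- function(x, ...) {
  cat(sprintf("gedi_model: G=%d genes, K=%d factors, N=%d cells, Q=%d samples\n",
              length(x$o_r), ncol(x$Z_r), ncol(x$B), length(x$delta_Z)))
  cat(sprintf("  mode=%s  sigma2=%.4g  fitted=%s\n", x$mode, x$sigma2, x$fitted))
  if (!is.null(x$prior))
    cat(sprintf("  gene-level prior: P=%d sets\n", ncol(x$prior$C)))
  if (!is.null(x$covariates))
    cat(sprintf("  sample covariates: L=%d\n", nrow(x$covariates$H)))
  invisible(x)
}

validate_gedi_model <- function(m) {
  G <- length(m$o_r); K <- ncol(m$Z_r); N <- ncol(m$B)
  Q <- length(m$delta_Z)
  if (nrow(m$Z_r) != G)
    gedi_stop("Z_r has ", nrow(m$Z_r), " rows but o_r has length ", G,
              class = "gedi_dim_error")
  if (!identical(dim(m$delta_o), c(G, Q)))
    gedi_stop("delta_o must be G x Q (", G, " x ", Q, "), got ",
              nrow(m$delta_o), " x ", ncol(m$delta_o), class = "gedi_dim_error")
  for (i in seq_len(Q))
    if (!identical(dim(m$delta_Z[[i]]), c(G, K)))
      gedi_stop("delta_Z[[", i, "]] must be G x K (", G, " x ", K, ")",
                class = "gedi_dim_error")
  if (nrow(m$B) != K)
    gedi_stop("B has ", nrow(m$B), " rows but Z_r has ", K, " columns",
              class = "gedi_dim_error")
  if (length(m$s) != N)
    gedi_stop("s has length ", length(m$s), ", expected N = ", N,
              class = "gedi_dim_error")
  if (length(m$sample_map) != N || any(m$sample_map < 1L | m$sample_map > Q))
    gedi_stop("sample_map must have length N with values in 1..Q",
              class = "gedi_dim_error")
  if (!is.null(m$sigma2) && (!is.finite(m$sigma2) || m$sigma2 <= 0))
    gedi_stop("sigma2 must be a positive finite scalar")
  if (!is.null(m$prior)) {
    if (nrow(m$prior$C) != G)
      gedi_stop("prior matrix C has ", nrow(m$prior$C), " rows, expected G = ",
                G, class = "gedi_dim_error")
    if (!identical(dim(m$prior$A), c(ncol(m$prior$C), K)))
      gedi_stop("prior coefficient matrix A must be P x K",
                class = "gedi_dim_error")
  }
  if (!is.null(m$covariates)) {
    L <- nrow(m$covariates$H)
    if (ncol(m$covariates$H) != Q)
      gedi_stop("covariate matrix H must have Q = ", Q, " columns",
                class = "gedi_dim_error")
    if (!identical(dim(m$covariates$R_o), c(G, L)))
      gedi_stop("R_o must be G x L", class = "gedi_dim_error")
    if (length(m$covariates$R_k) != K)
      gedi_stop("R_k must be a list of K matrices", class = "gedi_dim_error")
  }
  if (!is.null(m$d) && (length(m$d) != K || any(m$d <= 0)))
    gedi_stop("ellipsoid semi-axes d must be a positive length-K vector")
  invisible(m)
}

#' Decoded mean expression profiles
#'
#' Evaluates the affine decoder \eqn{\mu_n = o_r + \Delta o_{i(n)} +
#' (Z_r + \Delta Z_{i(n)}) b_n + s_n 1_G} either for cells stored in the
#' model (columns of `B`) or for an arbitrary embedding `b` in a given
#' sample.
#'
#' @param model a [gedi_model][new_gedi_model].
#' @param cells integer indices of cells to decode (default: all).
#' @param b optional K-vector or K x M matrix of embeddings; overrides
#'   `cells`.
#' @param sample sample index used with `b` (single integer).
#' @param s intercept(s) used with `b` (scalar or length M).
#' @return G x M matrix of decoded means (a plain vector if one cell).
#' @export
gedi_decode <- function(model, cells = NULL, b = NULL, sample = NULL, s = 0) {
  G <- length(model$o_r); K <- ncol(model$Z_r)
  if (!is.null(b)) {
    b <- if (is.matrix(b)) b else matrix(b, nrow = length(b))
    if (nrow(b) != K)
      gedi_stop("embedding b has ", nrow(b), " rows, expected K = ", K,
                class = "gedi_dim_error")
    if (is.null(sample)) sample <- 1L
    if (sample < 1L || sample > length(model$delta_Z))
      gedi_stop("sample index ", sample, " out of range",
                class = "gedi_dim_error")
    W <- model$Z_r + model$delta_Z[[sample]]
    mu <- (model$o_r + model$delta_o[, sample]) + W %*% b
    mu <- sweep(mu, 2, rep_len(s, ncol(b)), `+`)
    return(if (ncol(mu) == 1L) drop(mu) else mu)
  }
  cells <- cells %||% seq_len(ncol(model$B))
  mu <- matrix(0, G, length(cells))
  map <- model$sample_map[cells]
  for (i in unique(map)) {
    idx <- which(map == i)
    W <- model$Z_r + model$delta_Z[[i]]
    mu[, idx] <- (model$o_r + model$delta_o[, i]) +
      W %*% model$B[, cells[idx], drop = FALSE]
  }
  mu <- sweep(mu, 2, model$s[cells], `+`)
  dimnames(mu) <- list(model$genes, model$cells[cells])
  mu
}

#' Resolve the scale redundancy between axes and embeddings
#'
#' Each column of `Z_r + delta_Z_i` can be scaled by a constant with the
#' matching row of `B` scaled by its inverse without changing the decoded
#' means. This gauge is fixed by rescaling every row of `B` to unit L2 norm
#' and moving the norm into the corresponding axis columns (reference and
#' all per-sample distortions alike), leaving every decoded mean unchanged.
#'
#' @param model a `gedi_model`.
#' @return the model with unit-norm `B` rows.
#' @export
renormalize_gauge <- function(model) {
  r <- sqrt(rowSums(model$B^2))
  if (any(r < .Machine$double.eps * ncol(model$B)))
    gedi_stop("degenerate factor: B row ", which.min(r), " is all zero")
  model$B <- model$B / r
  model$Z_r <- sweep(model$Z_r, 2, r, `*`)
  model$delta_Z <- lapply(model$delta_Z, function(dz) sweep(dz, 2, r, `*`))
  model
}

#' Orthogonalize manifold axes
#'
#' Symmetric (Loewdin) orthogonalization of the columns of `Z`, followed by
#' rescaling so that each output column keeps the corresponding input
#' column's norm; the total Frobenius norm and the column span are
#' preserved. Symmetric orthogonalization is used (rather than
#' Gram-Schmidt) so the result does not depend on column order.
#'
#' @param Z a G x K matrix with full column rank, K <= G.
#' @return a G x K matrix with mutually orthogonal columns.
#' @export
enforce_orthogonality <- function(Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) > nrow(Z))
    gedi_stop("cannot orthogonalize: more columns (", ncol(Z),
              ") than rows (", nrow(Z), ")", class = "gedi_dim_error")
  if (ncol(Z) == 1L) return(Z)
  cn <- sqrt(colSums(Z^2))
  S <- crossprod(Z)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values)) {
    qrz <- qr(Z)
    dep <- sort(qrz$pivot[-seq_len(qrz$rank)])
    gedi_stop("rank-deficient axis matrix; dependent columns: ",
              paste(dep, collapse = ", "), class = "gedi_rank_error")
  }
  S_invsqrt <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  Zo <- Z %*% S_invsqrt                  # orthonormal columns, same span
  sweep(Zo, 2, cn, `*`)                  # redistribute original column norms
}

#' Project embeddings onto the hyperellipsoid
#'
#' Alternating projections between the unit-row-norm constraint on `B` and
#' the per-column ellipsoid constraint \eqn{\sum_k (b_{k,n}/d_k)^2 = 1},
#' iterated until both residuals drop below `tol`.
#'
#' @param B K x N embedding matrix.
#' @param d positive length-K semi-axes.
#' @param tol convergence tolerance on both constraint residuals.
#' @param max_iter iteration cap; exceeded iterations raise an error
#'   reporting the residuals.
#' @return a feasible K x N matrix.
#' @export
project_ellipsoid <- function(B, d, tol = 1e-6, max_iter = 100) {
  B <- as.matrix(B)
  d <- as.numeric(d)
  if (length(d) != nrow(B) || any(d <= 0))
    gedi_stop("d must be positive with one entry per row of B")
  for (it in seq_len(max_iter)) {
    res_row <- max(abs(sqrt(rowSums(B^2)) - 1))
    res_col <- max(abs(sqrt(colSums((B / d)^2)) - 1))
    if (res_row < tol && res_col < tol) return(B)
    B <- B / sqrt(rowSums(B^2))                      # row constraint
    B <- sweep(B, 2, sqrt(colSums((B / d)^2)), `/`)  # ellipsoid (radial)
  }
  res_row <- max(abs(sqrt(rowSums(B^2)) - 1))
  res_col <- max(abs(sqrt(colSums((B / d)^2)) - 1))
  if (res_row < tol && res_col < tol) return(B)
  gedi_stop(sprintf(paste0("ellipsoid projection did not converge in %d ",
                           "iterations (row residual %.3g, column residual ",
                           "%.3g)"), max_iter, res_row, res_col),
            class = "gedi_convergence_error")
}

#' Projected regulon/gene-set activities per cell
#'
#' With a gene-level prior block, entry (p, n) is the projected activity
#' \eqn{a_p \cdot b_n} of prior set p (e.g. a TF regulon) in cell n.
#'
#' @param model a `gedi_model` carrying a prior block.
#' @return P x N activity matrix with set identifiers as row names.
#' @export
activities <- function(model) {
  if (is.null(model$prior))
    gedi_stop("model has no gene-level prior block; fit with `prior_C`")
  act <- model$prior$A %*% model$B
  dimnames(act) <- list(rownames(model$prior$A), model$cells)
  act
}

#' Activity gradient in expression space
#'
#' The direction of steepest increase of the activity of prior set `p`,
#' mapped to expression coordinates: \eqn{Z_r a_p^\top}.
#'
#' @param model a `gedi_model` with a prior block.
#' @param p prior-set index or name.
#' @return numeric length-G gradient vector.
#' @export
activity_gradient <- function(model, p) {
  if (is.null(model$prior))
    gedi_stop("model has no gene-level prior block")
  if (is.character(p)) {
    p_idx <- match(p, rownames(model$prior$A))
    if (is.na(p_idx)) gedi_stop("unknown prior set '", p, "'")
    p <- p_idx
  }
  if (p < 1 || p > nrow(model$prior$A))
    gedi_stop("prior set index ", p, " out of range 1..", nrow(model$prior$A))
  g <- drop(model$Z_r %*% model$prior$A[p, ])
  names(g) <- model$genes
  g
}

## Reproducible factor order: columns of Z_r sorted by decreasing norm, sign
## fixed so each column's largest-magnitude entry is positive; B rows, A
## columns, delta_Z columns, R_k list and d permuted along.
canonicalize_factors <- function(model) {
  nrm <- sqrt(colSums(model$Z_r^2))
  ord <- order(nrm, decreasing = TRUE)
  sgn <- vapply(seq_len(ncol(model$Z_r)), function(k) {
    v <- model$Z_r[, k]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  model$Z_r <- sweep(model$Z_r[, ord, drop = FALSE], 2, sgn[ord], `*`)
  model$B <- model$B[ord, , drop = FALSE] * sgn[ord]
  model$delta_Z <- lapply(model$delta_Z, function(dz)
    sweep(dz[, ord, drop = FALSE], 2, sgn[ord], `*`))
  if (!is.null(model$prior))
    model$prior$A <- sweep(model$prior$A[, ord, drop = FALSE], 2, sgn[ord], `*`)
  if (!is.null(model$covariates))
    model$covariates$R_k <- lapply(ord, function(k) {
      model$covariates$R_k[[k]] * sgn[k]
    })
  if (!is.null(model$d)) model$d <- model$d[ord]
  model
}
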