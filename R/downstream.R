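#' Transcriptomic vector field of a sample-level covariate
#'
#' The decoder is affine in the covariate vector h, so the change in the
#' expected expression of a cell per unit change of covariate `l` is exact:
#' \deqn{v_n = step (R_o[,l] + \sum_k R_k[,l] b_{k,n}).}
#' Column n is the per-cell differential-expression vector of the
#' covariate at cell state \eqn{b_n}; its L2 norm is the magnitude of the
#' expression shift at that cell state.
#'
#' @param model a fitted `gedi_model` with a covariate block.
#' @param l covariate index or name.
#' @param step covariate step size (the field is exactly linear in it).
#' @return object of class `gedi_vector_field`: list with `V` (G x N),
#'   `magnitudes` (length N), `covariate`, `step`.
#' @export
vector_field <- function(model, l, step = 1) {
  if (is.null(model$covariates))
    gedi_stop("model has no covariate block; fit with `covariates_H`")
  cov <- model$covariates
  if (is.character(l)) {
    li <- match(l, cov$names)
    if (is.na(li)) gedi_stop("unknown covariate '", l, "'")
    l <- li
  }
  if (l < 1 || l > nrow(cov$H))
    gedi_stop("covariate index ", l, " out of range 1..", nrow(cov$H))
  V <- cov$R_o[, l] %*% t(rep(1, ncol(model$B)))
  for (k in seq_len(ncol(model$Z_r)))
    V <- V + outer(cov$R_k[[k]][, l], model$B[k, ])
  V <- step * V
  dimnames(V) <- list(model$genes, model$cells)
  structure(list(V = V, magnitudes = sqrt(colSums(V^2)),
                 covariate = cov$names[l], step = step),
            class = "gedi_vector_field")
}

#' Decode at an arbitrary covariate value
#'
#' Expected expression of the stored cells on the manifold implied by the
#' covariate vector `h`: center `o_r + R_o h` and axes `Z_r + [R_k h]_k`
#' (sample-specific residual distortions excluded). Useful for
#' extrapolating profiles to unobserved conditions.
#'
#' @param model fitted `gedi_model` with covariates.
#' @param h length-L covariate vector.
#' @param cells cell indices (default all).
#' @return G x length(cells) matrix.
#' @export
decode_at_h <- function(model, h, cells = NULL) {
  if (is.null(model$covariates)) gedi_stop("model has no covariate block")
  cov <- model$covariates
  h <- as.numeric(h)
  if (length(h) != nrow(cov$H))
    gedi_stop("h must have length L = ", nrow(cov$H),
              class = "gedi_dim_error")
  cells <- cells %||% seq_len(ncol(model$B))
  K <- ncol(model$Z_r)
  Zh <- model$Z_r
  for (k in seq_len(K)) Zh[, k] <- Zh[, k] + drop(cov$R_k[[k]] %*% h)
  mu <- (model$o_r + drop(cov$R_o %*% h)) +
    Zh %*% model$B[, cells, drop = FALSE]
  mu <- sweep(mu, 2, model$s[cells], `+`)
  dimnames(mu) <- list(model$genes, model$cells[cells])
  mu
}

#' Group-level summary of a vector field
#'
#' Collapses the per-cell differential-expression vectors to a per-group
#' mean vector (the cluster-level analogue of pseudobulk log-fold-changes)
#' and the per-group mean magnitude.
#'
#' @param field a `gedi_vector_field`.
#' @param labels vector of length N of group labels (e.g. cell types).
#' @return list with `mean_vectors` (G x n_groups) and `mean_magnitude`
#'   (named numeric).
#' @export
field_group_summary <- function(field, labels) {
  if (length(labels) != ncol(field$V))
    gedi_stop("labels must have one entry per cell", class = "gedi_dim_error")
  f <- if (is.factor(labels)) labels else factor(labels)
  counts <- table(f)
  if (any(counts == 0))
    gedi_stop("empty group(s): ",
              paste(names(counts)[counts == 0], collapse = ", "))
  groups <- levels(f)
  mv <- vapply(groups, function(g)
    rowMeans(field$V[, f == g, drop = FALSE]), numeric(nrow(field$V)))
  mm <- vapply(groups, function(g)
    mean(field$magnitudes[f == g]), numeric(1))
  list(mean_vectors = mv, mean_magnitude = mm)
}

#' Cosine similarity between a vector field and activity gradients
#'
#' For each prior set p and cell n, the cosine of the angle between the
#' cell's differential-expression vector and the expression-space gradient
#' of the set's activity, \eqn{Z_r a_p^\top}. Alignment near +1 means the
#' covariate moves that cell's expression in the direction of increasing
#' set activity.
#'
#' @param field a `gedi_vector_field`.
#' @param model the fitted `gedi_model` (with prior block) the field came
#'   from.
#' @return P x N matrix of cosines in [-1, 1]; entries where either vector
#'   has zero norm are 0, flagged in the `"zero_mask"` attribute.
#' @export
field_vs_gradient <- function(field, model) {
  if (is.null(model$prior))
    gedi_stop("model has no gene-level prior block")
  Grad <- model$Z_r %*% t(model$prior$A)     # G x P, column p = Z_r a_p^T
  gn <- sqrt(colSums(Grad^2))
  vn <- sqrt(colSums(field$V^2))
  num <- crossprod(Grad, field$V)            # P x N
  den <- outer(gn, vn)
  mask <- den == 0
  cs <- num / ifelse(mask, 1, den)
  cs[mask] <- 0
  cs <- pmin(pmax(cs, -1), 1)
  dimnames(cs) <- list(rownames(model$prior$A), model$cells)
  attr(cs, "zero_mask") <- mask
  cs
}

#' Sample feature matrix from the fitted distortions
#'
#' Encodes each sample by its manifold distortion parameters: row i is the
#' vectorized `delta_Z_i` in column-major order (gene index fastest within
#' each factor), optionally followed by `delta_o_i`. This featurization
#' supports sample-level embedding and classification.
#'
#' @param model fitted `gedi_model`.
#' @param include_delta_o append the center translations (default FALSE,
#'   matching the distortion-only encoding).
#' @return object of class `gedi_sample_features`: Q x F matrix with
#'   feature names `<gene>.k<factor>` / `<gene>.o`.
#' @export
sample_features <- function(model, include_delta_o = FALSE) {
  K <- ncol(model$Z_r)
  F_mat <- t(vapply(model$delta_Z, as.numeric,
                    numeric(length(model$o_r) * K)))
  colnames(F_mat) <- paste0(rep(model$genes, K), ".k",
                            rep(seq_len(K), each = length(model$genes)))
  if (include_delta_o) {
    dO <- t(model$delta_o)
    colnames(dO) <- paste0(model$genes, ".o")
    F_mat <- cbind(F_mat, dO)
  }
  rownames(F_mat) <- model$samples
  structure(F_mat, class = c("gedi_sample_features", class(F_mat)))
}

#' Residualize sample features on nuisance covariates
#'
#' Removes the least-squares projection of each feature column on the
#' nuisance design (post-hoc regressing-out of, e.g., technology), then
#' ranks the residualized features by variance.
#'
#' @param F samples x features matrix (e.g. from [sample_features()]).
#' @param nuisance samples x J design matrix of nuisance variables; an
#'   intercept column is added when absent.
#' @param top number of top-variance features to report (default 20).
#' @return list with `residuals` (same shape as `F`) and `top_features`
#'   (indices of the `top` highest-variance residual columns).
#' @export
residualize_features <- function(F, nuisance, top = 20) {
  F <- as.matrix(F) + 0
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(F))
    gedi_stop("nuisance must have one row per sample",
              class = "gedi_dim_error")
  if (ncol(nuisance) >= nrow(F))
    gedi_stop("nuisance must have fewer columns than samples")
  if (!any(apply(nuisance, 2, function(x) all(x == x[1]))))
    nuisance <- cbind(`(Intercept)` = 1, nuisance)
  qrn <- qr(nuisance)
  if (qrn$rank < ncol(nuisance))
    gedi_stop("rank-deficient nuisance design", class = "gedi_rank_error")
  res <- F - qr.fitted(qrn, F)
  v <- apply(res, 2, stats::var)
  list(residuals = res,
       top_features = order(v, decreasing = TRUE)[seq_len(min(top, ncol(F)))])
}
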