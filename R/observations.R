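#' Bundle observations for model fitting
#'
#' Collects the data matrices for one of the three observation layers:
#' \describe{
#'   \item{gaussian}{a dense G x N matrix `Y` of (log-scale) expression
#'     values observed directly;}
#'   \item{poisson}{a G x N matrix `M` of UMI counts, each entry Poisson
#'     with a log-normally distributed latent rate;}
#'   \item{binomial}{paired G x N count matrices `M1`/`M2` of success and
#'     failure counts (e.g. exon inclusion/exclusion reads, or spliced and
#'     unspliced UMIs), binomial with a logit-normal latent proportion.}
#' }
#'
#' @param sample_map factor/character/integer vector of length N assigning
#'   each cell (column) to a sample.
#' @param Y,M,M1,M2 matrices as described above; exactly the one(s) required
#'   by `mode` must be supplied. Sparse `Matrix` classes are accepted for
#'   counts.
#' @param mode observation layer; inferred from the supplied matrices when
#'   missing.
#' @param genes,cells optional identifiers; defaulted from dimnames.
#' @return an object of class `gedi_observations`.
#' @export
gedi_observations <- function(sample_map, Y = NULL, M = NULL,
                              M1 = NULL, M2 = NULL, mode = NULL,
                              genes = NULL, cells = NULL) {
  if (is.null(mode)) {
    mode <- if (!is.null(Y)) "gaussian"
            else if (!is.null(M)) "poisson"
            else if (!is.null(M1)) "binomial"
            else gedi_stop("supply one of Y, M, or M1/M2")
  }
  mode <- match.arg(mode, c("gaussian", "poisson", "binomial"))
  dat <- switch(mode,
    gaussian = {
      if (is.null(Y)) gedi_stop("gaussian mode requires Y")
      list(Y = as.matrix(Y))
    },
    poisson = {
      if (is.null(M)) gedi_stop("poisson mode requires M")
      check_counts(M, "M")
      list(M = M)
    },
    binomial = {
      if (is.null(M1) || is.null(M2))
        gedi_stop("binomial mode requires both M1 and M2")
      check_counts(M1, "M1"); check_counts(M2, "M2")
      if (!identical(dim(M1), dim(M2)))
        gedi_stop("M1 and M2 dimensions differ", class = "gedi_dim_error")
      list(M1 = M1, M2 = M2)
    })
  ref <- dat[[1]]
  G <- nrow(ref); N <- ncol(ref)
  if (length(sample_map) != N)
    gedi_stop("sample_map has length ", length(sample_map),
              " but data has N = ", N, " cells", class = "gedi_dim_error")
  f <- if (is.factor(sample_map)) droplevels(sample_map) else
    factor(sample_map, levels = unique(sample_map))
  obs <- structure(c(dat, list(
    mode = mode,
    sample_map = as.integer(f),
    samples = levels(f),
    genes = genes %||% rownames(ref) %||% paste0("g", seq_len(G)),
    cells = cells %||% colnames(ref) %||% paste0("cell", seq_len(N))
  )), class = "gedi_observations")
  obs
}

check_counts <- function(M, name) {
  v <- if (methods::is(M, "sparseMatrix")) M@x else as.numeric(M)
  if (any(v < 0) || any(v != round(v)))
    gedi_stop(name, " must contain nonnegative integer counts",
              class = "gedi_value_error")
  invisible(TRUE)
}

#' @export
print.gedi_observations <- function(x, ...) {
  d <- obs_dim(x)
  cat(sprintf("gedi_observations: mode=%s, G=%d, N=%d, Q=%d samples\n",
              x$mode, d[1], d[2], length(x$samples)))
  invisible(x)
}

obs_dim <- function(obs) {
  ref <- switch(obs$mode, gaussian = obs$Y, poisson = obs$M, binomial = obs$M1)
  dim(ref)
}

## dense numeric copy of the primary data matrix
obs_dense <- function(x) as.matrix(x) + 0
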