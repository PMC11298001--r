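## Model archive: a directory of full-precision numeric TSV tables plus a
## plain-text key=value manifest carrying dimensions, mode, hyperparameters
## and sample order. Write -> read round-trips the manifest exactly and the
## numerics to better than 1e-12 (tables are written at 17 significant
## digits, which round-trips IEEE doubles).

#' Write a model archive
#'
#' @param model a `gedi_model`.
#' @param dir target directory (created; existing files overwritten).
#' @return `dir`, invisibly.
#' @export
write_gedi_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  G <- length(model$o_r); K <- ncol(model$Z_r)
  Q <- length(model$delta_Z)
  kv <- c(
    format = "gedi-model/1",
    package_version = as.character(utils::packageVersion("gedi")),
    mode = model$mode,
    G = G, K = K, N = ncol(model$B), Q = Q,
    L = if (is.null(model$covariates)) 0 else nrow(model$covariates$H),
    P = if (is.null(model$prior)) 0 else ncol(model$prior$C),
    sigma2 = sprintf("%.17g", model$sigma2),
    orthogonal_axes = model$orthogonal_axes,
    ellipsoid = model$ellipsoid,
    fitted = model$fitted,
    seed = model$seed %||% NA,
    samples = paste(model$samples, collapse = ","),
    covariate_names = if (is.null(model$covariates)) "" else
      paste(model$covariates$names, collapse = ",")
  )
  hv <- vapply(model$hyper, function(x) sprintf("%.17g", x), character(1))
  kv <- c(kv, stats::setNames(hv, paste0("hyper.", names(model$hyper))))
  writeLines(paste0(names(kv), "=", kv), file.path(dir, "manifest.txt"))

  writeLines(model$genes, file.path(dir, "genes.tsv"))
  writeLines(model$cells, file.path(dir, "cells.tsv"))
  writeLines(as.character(model$sample_map), file.path(dir, "sample_map.tsv"))
  wt <- function(x, f, rn = NULL, cn = NULL)
    write_num_table(x, file.path(dir, f), row_names = rn, col_names = cn)
  wt(matrix(model$o_r, ncol = 1), "o_r.tsv", model$genes, "o_r")
  wt(model$Z_r, "Z_r.tsv", model$genes, paste0("k", seq_len(K)))
  wt(model$delta_o, "delta_o.tsv", model$genes, model$samples)
  wt(matrix(model$B, nrow = K), "B.tsv", paste0("k", seq_len(K)), model$cells)
  wt(matrix(model$s, ncol = 1), "s.tsv", model$cells, "s")
  dz_dir <- file.path(dir, "delta_Z")
  dir.create(dz_dir, showWarnings = FALSE)
  for (i in seq_len(Q))
    write_num_table(model$delta_Z[[i]],
                    file.path(dz_dir, paste0(archive_name(model$samples[i]),
                                             ".tsv")),
                    row_names = model$genes,
                    col_names = paste0("k", seq_len(K)))
  if (!is.null(model$d))
    wt(matrix(model$d, ncol = 1), "d.tsv", paste0("k", seq_len(K)), "d")
  if (!is.null(model$prior)) {
    wt(model$prior$C, "C.tsv", model$genes, colnames(model$prior$C))
    wt(model$prior$A, "A.tsv", rownames(model$prior$A),
       paste0("k", seq_len(K)))
  }
  if (!is.null(model$covariates)) {
    wt(model$covariates$H, "H.tsv", model$covariates$names, model$samples)
    wt(model$covariates$R_o, "R_o.tsv", model$genes, model$covariates$names)
    rk_dir <- file.path(dir, "R_k")
    dir.create(rk_dir, showWarnings = FALSE)
    for (k in seq_len(K))
      write_num_table(model$covariates$R_k[[k]],
                      file.path(rk_dir, paste0("k", k, ".tsv")),
                      row_names = model$genes,
                      col_names = model$covariates$names)
  }
  invisible(dir)
}

archive_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Read a model archive
#'
#' @param dir directory written by [write_gedi_model()].
#' @return a `gedi_model`.
#' @export
read_gedi_model <- function(dir) {
  mf <- file.path(dir, "manifest.txt")
  if (!file.exists(mf))
    gedi_stop("not a model archive (no manifest.txt): ", dir,
              class = "gedi_io_error")
  lines <- readLines(mf)
  kv <- sub("^[^=]*=", "", lines)
  names(kv) <- sub("=.*$", "", lines)
  K <- as.integer(kv[["K"]]); Q <- as.integer(kv[["Q"]])
  samples <- strsplit(kv[["samples"]], ",", fixed = TRUE)[[1]]
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  hyper_keys <- grep("^hyper\\.", names(kv), value = TRUE)
  hyper <- stats::setNames(as.list(as.numeric(kv[hyper_keys])),
                           sub("^hyper\\.", "", hyper_keys))
  rd <- function(f) read_num_table(file.path(dir, f))
  delta_Z <- lapply(samples, function(s)
    read_num_table(file.path(dir, "delta_Z",
                             paste0(archive_name(s), ".tsv"))))
  prior <- NULL
  if (as.integer(kv[["P"]]) > 0) {
    C <- rd("C.tsv"); A <- rd("A.tsv")
    prior <- list(C = C, A = A, S_Z = hyper$S_Z, S_A = hyper$S_A)
  }
  covariates <- NULL
  if (as.integer(kv[["L"]]) > 0) {
    H <- rd("H.tsv")
    covariates <- list(
      H = H, R_o = rd("R_o.tsv"),
      R_k = lapply(seq_len(K), function(k)
        read_num_table(file.path(dir, "R_k", paste0("k", k, ".tsv")))),
      names = strsplit(kv[["covariate_names"]], ",", fixed = TRUE)[[1]])
  }
  model <- new_gedi_model(
    o_r = drop(rd("o_r.tsv")), Z_r = rd("Z_r.tsv"),
    delta_o = rd("delta_o.tsv"), delta_Z = delta_Z,
    B = rd("B.tsv"), s = drop(rd("s.tsv")),
    sigma2 = as.numeric(kv[["sigma2"]]), mode = kv[["mode"]],
    sample_map = as.integer(readLines(file.path(dir, "sample_map.tsv"))),
    samples = samples, genes = genes, cells = cells,
    prior = prior, covariates = covariates, hyper = hyper,
    orthogonal_axes = as.logical(kv[["orthogonal_axes"]]),
    ellipsoid = as.logical(kv[["ellipsoid"]]),
    d = if (file.exists(file.path(dir, "d.tsv"))) drop(rd("d.tsv")) else NULL,
    fitted = as.logical(kv[["fitted"]]))
  if (!is.na(kv[["seed"]]) && kv[["seed"]] != "NA")
    model$seed <- as.integer(kv[["seed"]])
  model
}
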