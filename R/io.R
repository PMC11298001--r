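#' Read a sparse count matrix with identifier sidecars
#'
#' Reads a Matrix Market file (optionally gzipped) plus its row (gene) and
#' column (cell/barcode) identifier files, one identifier per line (a
#' first tab-separated field is used if the sidecar has several columns).
#'
#' @param mtx_path path to the `.mtx`(.gz) file.
#' @param genes_path,cells_path sidecar identifier files.
#' @return a `dgCMatrix` with dimnames set.
#' @export
read_counts <- function(mtx_path, genes_path, cells_path) {
  for (p in c(mtx_path, genes_path, cells_path))
    if (!file.exists(p)) gedi_stop("file not found: ", p,
                                   class = "gedi_io_error")
  M <- Matrix::readMM(mtx_path)
  ## symmetric/triangular MM variants are expanded to a general matrix so
  ## that gene/cell dimnames can differ
  M <- methods::as(methods::as(M, "generalMatrix"), "CsparseMatrix")
  genes <- read_ids(genes_path)
  cells <- read_ids(cells_path)
  if (nrow(M) != length(genes))
    gedi_stop("matrix has ", nrow(M), " rows but ", genes_path, " lists ",
              length(genes), " genes", class = "gedi_dim_error")
  if (ncol(M) != length(cells))
    gedi_stop("matrix has ", ncol(M), " columns but ", cells_path,
              " lists ", length(cells), " cells", class = "gedi_dim_error")
  if (anyDuplicated(genes))
    gedi_stop("duplicate gene identifiers in ", genes_path,
              class = "gedi_value_error")
  if (anyDuplicated(cells))
    gedi_stop("duplicate cell identifiers in ", cells_path,
              class = "gedi_value_error")
  if (any(M@x < 0) || any(M@x != round(M@x)))
    gedi_stop("counts must be nonnegative integers",
              class = "gedi_value_error")
  dimnames(M) <- list(genes, cells)
  M
}

read_ids <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  lines <- readLines(con)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a count matrix as Matrix Market plus sidecars
#'
#' @param M matrix (dense or sparse) with dimnames.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (`<prefix>.mtx`, `genes.tsv`,
#'   `barcodes.tsv`); genes/barcodes files are shared per directory.
#' @return the `.mtx` path, invisibly.
#' @export
write_counts <- function(M, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Ms <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  mtx <- file.path(dir, paste0(prefix, ".mtx"))
  Matrix::writeMM(Ms, mtx)
  writeLines(rownames(M) %||% paste0("g", seq_len(nrow(M))),
             file.path(dir, "genes.tsv"))
  writeLines(colnames(M) %||% paste0("cell", seq_len(ncol(M))),
             file.path(dir, "barcodes.tsv"))
  invisible(mtx)
}

#' Read gene sets into a prior matrix
#'
#' Builds the G x P gene-level prior matrix from either a GMT file (binary
#' membership) or a TSV with gene identifiers in the first column and one
#' signed-weight column per set. Genes outside the universe are dropped
#' (with a message); sets whose overlap with the universe falls below
#' `min_overlap` are dropped with a warning (regulons need a minimal
#' number of substantial interactions to be informative).
#'
#' @param path `.gmt` or `.tsv` file.
#' @param gene_universe character vector of genes (the model's G rows).
#' @param min_overlap minimum genes per set (default 10).
#' @return G x P numeric matrix, rows in `gene_universe` order.
#' @export
read_gene_sets <- function(path, gene_universe, min_overlap = 10) {
  if (!file.exists(path)) gedi_stop("file not found: ", path,
                                    class = "gedi_io_error")
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, character(1), 1L)
    C <- vapply(sets, function(g) as.numeric(gene_universe %in% g),
                numeric(length(gene_universe)))
    C <- matrix(C, nrow = length(gene_universe),
                dimnames = list(gene_universe, names(sets)))
    n_out <- sum(!unlist(sets) %in% gene_universe)
    if (n_out > 0)
      message(n_out, " gene-set entries outside the universe were dropped")
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    g <- tab[[1]]
    keep <- g %in% gene_universe
    if (sum(!keep) > 0)
      message(sum(!keep), " prior genes outside the universe were dropped")
    C <- matrix(0, length(gene_universe), ncol(tab) - 1,
                dimnames = list(gene_universe, colnames(tab)[-1]))
    C[match(g[keep], gene_universe), ] <-
      as.matrix(tab[keep, -1, drop = FALSE])
  }
  overlap <- colSums(C != 0)
  low <- overlap < min_overlap
  if (all(overlap == 0))
    gedi_stop("no gene set intersects the gene universe",
              class = "gedi_value_error")
  if (any(low)) {
    warning(sum(low), " set(s) below the minimum overlap of ", min_overlap,
            " dropped: ", paste(colnames(C)[low], collapse = ", "))
    C <- C[, !low, drop = FALSE]
  }
  if (ncol(C) == 0)
    gedi_stop("no gene set passes the minimum overlap of ", min_overlap,
              class = "gedi_value_error")
  C
}

#' Read a cell-to-sample map
#'
#' Two-column TSV (barcode, sample; header optional). The returned vector
#' follows the order of `cells`; unmapped cells are an error, not a silent
#' drop.
#'
#' @param path TSV path.
#' @param cells barcodes in data column order.
#' @return character vector of sample ids, length `length(cells)`.
#' @export
read_sample_map <- function(path, cells) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, col.names =
                             c("barcode", "sample"))
  if (identical(tolower(tab$barcode[1]), "barcode")) tab <- tab[-1, ]
  idx <- match(cells, tab$barcode)
  if (anyNA(idx))
    gedi_stop(sum(is.na(idx)), " cell(s) missing from the sample map, ",
              "e.g. ", cells[which(is.na(idx))[1]],
              class = "gedi_value_error")
  tab$sample[idx]
}

#' Read a sample covariate table
#'
#' TSV with samples as rows (first column sample id, header row names the
#' covariates). Returned transposed as the L x Q matrix the model expects,
#' columns ordered as `samples`.
#'
#' @param path TSV path.
#' @param samples sample identifiers in model order.
#' @return L x Q numeric matrix.
#' @export
read_covariates <- function(path, samples) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  idx <- match(samples, rownames(tab))
  if (anyNA(idx))
    gedi_stop("covariate table is missing sample(s): ",
              paste(samples[is.na(idx)], collapse = ", "),
              class = "gedi_value_error")
  t(as.matrix(tab[idx, , drop = FALSE]))
}

#' Read a dense expression matrix
#'
#' TSV with a header row of cell identifiers and gene identifiers in the
#' first column.
#'
#' @param path TSV path.
#' @return numeric G x N matrix with dimnames.
#' @export
read_dense <- function(path) {
  read_num_table(path)
}

#' Write a numeric matrix as TSV (9 significant digits)
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @param id_col name of the identifier column (default "id").
#' @return `path`, invisibly.
#' @export
write_dense <- function(x, path, id_col = "id") {
  x <- as.matrix(x)
  df <- data.frame(rownames(x) %||% as.character(seq_len(nrow(x))),
                   matrix(sprintf("%.9g", x), nrow(x), ncol(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(x) %||% paste0("V", seq_len(ncol(x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
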