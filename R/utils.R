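#' @keywords internal
#' @importFrom Matrix readMM writeMM Matrix
#' @importFrom methods as is
#' @importFrom stats rnorm runif rpois rbinom rlnorm rgamma rmultinom
#' @importFrom utils read.table write.table modifyList packageVersion
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

gedi_stop <- function(..., class = "gedi_error") {
  stop(structure(
    class = c(class, "gedi_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

## numerically safe log(1 + e^x)
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x < 33
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

## full-precision matrix TSV used by the model archive (round-trips to < 1e-12)
write_num_table <- function(x, path, row_names = NULL, col_names = NULL) {
  x <- as.matrix(x)
  if (!is.null(row_names)) rownames(x) <- row_names
  if (!is.null(col_names)) colnames(x) <- col_names
  df <- data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                   matrix(sprintf("%.17g", x), nrow(x), ncol(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(x) %||% paste0("V", seq_len(ncol(x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_num_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "", quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
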