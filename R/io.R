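#' Read a labeled square matrix from delimited text
#'
#' Expects tab-delimited text whose first row and first column carry the
#' region labels and whose body is numeric. Validates squareness and the
#' agreement of row and column labels.
#'
#' @param path File path.
#' @return Numeric matrix with matching dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character")
  m <- as.matrix(df)
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in %s is %d x %d, not square",
                 path, nrow(m), ncol(m)), call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop(sprintf("row/column label mismatch in %s", path), call. = FALSE)
  }
  m
}

#' Write a labeled square matrix as delimited text
#'
#' Tab-delimited, 9 significant digits, deterministic formatting: writing
#' the same matrix twice produces byte-identical files.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @param labels Labels; taken from `rownames(m)` when `NULL`, generated
#'   (`R001`, ...) when absent.
#' @param digits Significant digits (default 9).
#' @export
write_matrix <- function(m, path, labels = NULL, digits = 9) {
  m <- as.matrix(m)
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(nrow(m)))
  if (length(labels) != nrow(m)) {
    stop("length(labels) must match the matrix", call. = FALSE)
  }
  body <- apply(m, 1:2, function(v) formatC(v, digits = digits,
                                            format = "g"))
  lines <- c(paste(c("region", labels), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(labels[i], body[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write regional time series as delimited text
#'
#' First column is time in seconds, one column per region, header row of
#' region labels.
#'
#' @param series A [region_ts()].
#' @param path Output path.
#' @param digits Significant digits (default 9).
#' @export
write_timeseries <- function(series, path, digits = 9) {
  t <- series$t0 + (seq_len(ncol(series$values)) - 1L) / series$fs
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  lines <- c(paste(c("time", series$labels), collapse = "\t"),
             vapply(seq_along(t), function(k) {
               paste(c(fmt(t[k]), fmt(series$values[, k])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read regional time series written by [write_timeseries()]
#'
#' @param path File path.
#' @return A [region_ts()].
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  t <- df[[1]]
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  fs <- 1 / stats::median(diff(t))
  region_ts(vals, fs = fs, t0 = t[1], labels = colnames(df)[-1])
}

#' Write a coupling-sweep result
#'
#' Writes the correlation-versus-coupling curve as two-column delimited
#' text (`C`, `PCC`) and a JSON summary (`best_c`, `best_pcc`, grid
#' bounds) alongside it.
#'
#' @param sweep A `coupling_sweep` from [sweep_coupling()].
#' @param path Output path for the curve; the summary is written to
#'   `paste0(path, ".json")`.
#' @export
write_sweep <- function(sweep, path) {
  lines <- c("C\tPCC",
             paste(formatC(sweep$c_values, digits = 9, format = "g"),
                   formatC(sweep$pcc_values, digits = 9, format = "g"),
                   sep = "\t"))
  writeLines(lines, path)
  jsonlite::write_json(
    list(best_c = sweep$best_c, best_pcc = sweep$best_pcc,
         c_min = min(sweep$c_values), c_max = max(sweep$c_values),
         n_grid = length(sweep$c_values)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
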