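# Matrix I/O: delimited text with delimiter auto-detection. Rows are
# channels/variables, columns are samples.

#' Load a numeric matrix from delimited text
#'
#' Reads a rectangular numeric table; the delimiter is auto-detected among
#' comma, tab and whitespace. Ragged or non-numeric input is rejected with
#' the offending line number.
#'
#' @param path Path to the file.
#' @param transpose If `TRUE`, transpose after reading (for files that store
#'   samples in rows).
#' @return A numeric matrix.
#' @export
load_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  delim <- if (grepl(",", lines[1], fixed = TRUE)) ","
           else if (grepl("\t", lines[1], fixed = TRUE)) "\t"
           else "[[:space:]]+"
  rows <- strsplit(trimws(lines), delim)
  nf <- lengths(rows)
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged table in %s: line %d has %d fields, expected %d",
                 path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    bad <- which(vapply(rows, function(r) anyNA(suppressWarnings(as.numeric(r))),
                        TRUE))[1]
    stop(sprintf("non-numeric cell in %s: line %d", path, bad))
  }
  M <- matrix(vals, nrow = length(rows), byrow = TRUE)
  if (transpose) t(M) else M
}

#' Write a numeric matrix as tab-separated text
#'
#' @param X Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(X, path) {
  X <- check_matrix(X)
  utils::write.table(X, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a pipeline result to a directory
#'
#' Serializes a [run_miprest()] result: the delta table and residual matrix
#' as tab-separated text, the classification and per-rule dimensions as JSON,
#' and the parent RAICAR decomposition via [write_raicar()].
#'
#' @param fit A `miprest` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_miprest <- function(fit, dir) {
  if (!inherits(fit, "miprest")) stop("'fit' must be a miprest object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(fit$delta$delta, file.path(dir, "delta.tsv"))
  write_matrix(fit$delta$R_dec, file.path(dir, "R_decimated.tsv"))
  write_matrix(matrix(fit$delta$R0, nrow = 1), file.path(dir, "R_parent.tsv"))
  write_matrix(fit$residual, file.path(dir, "residual.tsv"))
  cls <- fit$classification
  jsonlite::write_json(
    list(labels = cls$labels, median_R = cls$median_R,
         median_abs_delta = cls$median_abs_delta,
         thresholds = as.list(cls$thresholds),
         counts = as.list(table(factor(cls$labels,
                                       c("sparse", "gaussian", "spurious"))))),
    file.path(dir, "classification.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(rule_dims = as.list(fit$eigen$rule_dims),
         consensus_dim = fit$eigen$consensus_dim,
         eigenvalues = fit$eigen$lambda,
         config = fit$config),
    file.path(dir, "dimensions.json"), auto_unbox = TRUE, digits = NA)
  write_raicar(fit$parent, file.path(dir, "parent_raicar"))
  invisible(dir)
}
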