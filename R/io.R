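#' Write a labeled numeric matrix as TSV
#'
#' The first column holds the row labels under the name given by
#' `label`; remaining columns are the matrix columns. Values are written at
#' full precision (17 significant digits) so that a write/read round trip is
#' exact to within double rounding.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output file.
#' @param label header name of the label column.
#' @export
write_matrix <- function(mat, path, label = "id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), format(mat, digits = 17, trim = TRUE,
                                         scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(label, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled numeric matrix from TSV/CSV
#'
#' Expects a header row and a leading label column. Ragged rows, duplicated
#' labels and non-numeric cells are reported as errors with coordinates.
#'
#' @param path file to read.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop_param("%s: need a header line and data", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1]]
  width <- length(header)
  lens <- lengths(cells[-1])
  if (any(lens != width))
    stop_param("%s: ragged row(s) %s (expected %d fields)",
               path, paste(which(lens != width) + 1L, collapse = ", "), width)
  body <- cells[-1]
  labels <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(labels))
    stop_param("%s: duplicated label(s): %s", path,
               paste(unique(labels[duplicated(labels)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(body, function(x) as.numeric(x[-1]), numeric(width - 1L)))
  vals <- if (width == 2L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_param("%s: non-numeric cell at row %d ('%s'), column %d ('%s')",
               path, bad[1] + 1L, labels[bad[1]], bad[2] + 1L,
               header[bad[2] + 1L])
  }
  dimnames(vals) <- list(labels, header[-1])
  vals
}

#' Write a synthetic cohort to a directory
#'
#' Layout: `X.tsv` (CpGs in rows, samples in columns, the methylation-array
#' export convention), `W.tsv` (samples in rows), `y.tsv`, `truth.tsv`
#' (`cpg`, `cell_type`, `beta`), `config.json`, and optionally `Z.tsv`
#' (the latent tensor in long layout: `sample`, `cpg`, one column per cell
#' type).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @param include_z also write the latent tensor (large; default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, include_z = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(t(cohort$X), file.path(dir, "X.tsv"), label = "cpg")
  write_matrix(cohort$W, file.path(dir, "W.tsv"), label = "sample")
  utils::write.table(
    data.frame(sample = names(cohort$y), y = cohort$y),
    file.path(dir, "y.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_table(cohort), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (include_z) {
    Zl <- do.call(rbind, lapply(seq_len(dim(cohort$Z)[3]), function(h)
      data.frame(sample = rep(rownames(cohort$X), ncol(cohort$X)),
                 cpg = rep(colnames(cohort$X), each = nrow(cohort$X)),
                 cell_type = dimnames(cohort$Z)[[3]][h],
                 z = as.vector(cohort$Z[, , h]))))
    utils::write.table(Zl, file.path(dir, "Z.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `X` (samples x CpGs), `W`, `y`, `truth` (data.frame)
#'   and `config` (plain list).
#' @export
read_cohort <- function(dir) {
  X <- t(read_matrix(file.path(dir, "X.tsv")))
  W <- read_matrix(file.path(dir, "W.tsv"))
  ytab <- utils::read.delim(file.path(dir, "y.tsv"), stringsAsFactors = FALSE)
  y <- stats::setNames(as.integer(ytab$y), ytab$sample)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  list(X = X, W = W, y = y, truth = truth, config = config)
}

#' Write an association table as TSV
#'
#' @param table an `assoc_table`.
#' @param path output file.
#' @export
write_assoc <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an association table written by [write_assoc()]
#'
#' @param path file to read.
#' @return an `assoc_table` data.frame.
#' @export
read_assoc <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}
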