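#' Read a Matrix Market count-matrix triple
#'
#' Reads the conventional sparse count-matrix layout: `matrix.mtx` holding
#' the non-zero integer counts with features in rows, plus `features.tsv`
#' (one feature id per line) and `barcodes.tsv` (one observation id per
#' line). The matrix is returned transposed to the package-wide orientation,
#' observations in rows and features in columns.
#'
#' @param dir_path Directory containing `matrix.mtx`, `features.tsv` and
#'   `barcodes.tsv`.
#' @return A `dgCMatrix` with observation ids as rownames and feature ids as
#'   colnames; integer values are preserved exactly.
#' @export
read_matrix_triple <- function(dir_path) {
  paths <- file.path(dir_path, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stopf("missing matrix triple file(s): %s", paste(missing, collapse = ", "))
  m <- Matrix::readMM(paths[[1L]])
  features <- readLines(paths[[2L]])
  barcodes <- readLines(paths[[3L]])
  if (nrow(m) != length(features))
    stopf("matrix.mtx declares %d rows but features.tsv has %d entries",
          nrow(m), length(features))
  if (ncol(m) != length(barcodes))
    stopf("matrix.mtx declares %d columns but barcodes.tsv has %d entries",
          ncol(m), length(barcodes))
  m <- as_sparse(Matrix::t(m))
  dimnames(m) <- list(barcodes, features)
  check_count_matrix(m)
}

#' Write a count matrix as a Matrix Market triple
#'
#' Inverse of [read_matrix_triple()]: the in-memory observations-by-features
#' matrix is transposed so that features are the rows of `matrix.mtx`.
#'
#' @param m Sparse observations-by-features matrix with dimnames.
#' @param dir_path Output directory (created if absent).
#' @export
write_matrix_triple <- function(m, dir_path) {
  m <- check_count_matrix(as_sparse(m))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(m), file.path(dir_path, "matrix.mtx"))
  writeLines(colnames(m), file.path(dir_path, "features.tsv"))
  writeLines(rownames(m), file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read a BED file into a genomic interval table
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Columns beyond the first three are interpreted
#' as name (-> `label`), score (ignored) and strand.
#'
#' @param path Path to a 3-6 column tab-separated BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, and optionally
#'   `label` and `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "label",
                                        "score", "strand")[seq_len(
                            max(utils::count.fields(path, sep = "\t")))],
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad))
    stopf("invalid interval (start >= end or negative) at line %d of %s",
          bad[[1L]], path)
  df$score <- NULL
  interval_set(df$chrom, df$start, df$end, label = df$label,
               strand = df$strand)
}

#' Construct a genomic interval set
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param label Optional per-interval label (peak class, cell type, motif).
#' @param strand Optional strand, one of `+`, `-`, `.`.
#' @return A validated data.frame of class `interval_set`.
#' @export
interval_set <- function(chrom, start, end, label = NULL, strand = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0)) stopf("interval coordinates must be non-negative")
  if (any(start >= end)) stopf("intervals must satisfy start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- as.character(label)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", ".")))
      stopf("strand must be one of '+', '-', '.'")
    df$strand <- strand
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Write a genomic interval set as BED
#'
#' @param intervals An interval set (see [interval_set()]).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$strand)) {
    cols <- c(cols, list(if (is.null(intervals$label))
      rep(".", nrow(intervals)) else intervals$label,
      rep(0L, nrow(intervals)), intervals$strand))
  } else if (!is.null(intervals$label)) {
    cols <- c(cols, list(intervals$label))
  }
  utils::write.table(do.call(data.frame, c(cols, stringsAsFactors = FALSE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Fixed dialect used by every stage: tab-separated, header row, full float
#' precision (15 significant digits), missing values as the literal `NA`.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @export
write_table <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         format(out[[j]], digits = 15, trim = TRUE,
                                scientific = NA))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV result table written by [write_table()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame; `NA` tokens become missing values.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Construct and validate a nucleus metadata table
#'
#' @param nucleus_id Unique nucleus barcodes.
#' @param donor_id Donor of origin.
#' @param condition Rhythm status, `"AF"` or `"SR"`.
#' @param cell_type Cell-type label.
#' @return A validated data.frame.
#' @export
nucleus_table <- function(nucleus_id, donor_id, condition, cell_type) {
  if (anyDuplicated(nucleus_id)) stopf("nucleus ids must be unique")
  if (!all(condition %in% c("AF", "SR")))
    stopf("condition must be 'AF' or 'SR'")
  df <- data.frame(nucleus_id = as.character(nucleus_id),
                   donor_id = as.character(donor_id),
                   condition = as.character(condition),
                   cell_type = as.character(cell_type),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stopf("nucleus table must not contain missing annotations")
  df
}

#' Write a fragments (Tn5 insertion) file
#'
#' BED-like layout: chrom, start, end, barcode; one row per insertion event.
#'
#' @param fragments data.frame with columns chrom, start, end, barcode.
#' @param path Output path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments[, c("chrom", "start", "end", "barcode")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a fragments file written by [write_fragments()]
#' @param path Path to the fragments TSV.
#' @return data.frame with columns chrom, start, end, barcode.
#' @export
read_fragments <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character"))
}
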