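#' Read a bulk expression table
#'
#' Reads a delimited genes x samples table (first column = gene identifiers,
#' header row = sample identifiers). Tab is the canonical delimiter, matching
#' how published signature matrices are distributed; CSV is accepted via
#' `sep`. Duplicate gene rows are collapsed by their mean (the common
#' microarray convention) with a message. Because the mixing model lives in
#' linear scale, an `unlog` switch applies `2^x` for tables stored in log2
#' units.
#'
#' @param path file path.
#' @param sep field delimiter, `"\t"` (default) or `","`.
#' @param unlog if `TRUE`, apply `2^x` to the numeric body before
#'   construction.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, sep = "\t", unlog = FALSE) {
  m <- .read_numeric_table(path, sep, what = "expression table")
  if (anyDuplicated(m$ids)) {
    dup <- unique(m$ids[duplicated(m$ids)])
    message(sprintf("collapsing %d duplicated gene id(s) by mean: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    m$values <- rowsum(m$values, group = m$ids, reorder = FALSE) /
      as.vector(table(factor(m$ids, levels = unique(m$ids))))
    m$ids <- unique(m$ids)
  }
  if (!unlog && any(m$values < 0))
    stop("negative expression values found; if the table is log2-scale, read with unlog = TRUE")
  vals <- if (unlog) 2^m$values else m$values
  expression_matrix(vals, gene_ids = m$ids, sample_ids = m$cols)
}

#' Read a signature matrix table
#'
#' Reads a delimited genes x cell-types table in the dialect used by
#' published immune signature matrices such as LM22 (tab-separated, gene
#' symbols in the first column, cell-type names in the header). A genuine
#' LM22 file reads as 547 genes x 22 cell types.
#'
#' @inheritParams read_expression
#' @return a [signature_matrix()].
#' @export
read_signature <- function(path, sep = "\t", unlog = FALSE) {
  m <- .read_numeric_table(path, sep, what = "signature table")
  if (anyDuplicated(m$ids)) {
    message("collapsing duplicated signature gene id(s) by mean")
    m$values <- rowsum(m$values, group = m$ids, reorder = FALSE) /
      as.vector(table(factor(m$ids, levels = unique(m$ids))))
    m$ids <- unique(m$ids)
  }
  vals <- if (unlog) 2^m$values else m$values
  signature_matrix(vals, gene_ids = m$ids, cell_types = m$cols)
}

#' Read a proportion matrix table
#'
#' @inheritParams read_expression
#' @param strict require simplex-valid columns (default `TRUE`).
#' @return a [proportion_matrix()].
#' @export
read_proportions <- function(path, sep = "\t", strict = TRUE) {
  m <- .read_numeric_table(path, sep, what = "proportion table")
  proportion_matrix(m$values, cell_types = m$ids, sample_ids = m$cols,
                    strict = strict)
}

.read_numeric_table <- function(path, sep, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L)
    stop(what, " must have a label column plus at least one data column: ", path)
  ids <- as.character(df[[1]])
  cols <- colnames(df)[-1]          # before subsetting: `[` uniquifies names
  body <- df[, -1, drop = FALSE]
  if (anyDuplicated(cols))
    stop(what, ": duplicated column identifiers in header: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                     !is.na(body[[j]]))[1]
      stop(sprintf("%s: non-numeric value at row %d, column '%s'",
                   what, if (is.na(bad)) 1L else bad, cols[j]))
    }
  }
  values <- as.matrix(body)
  if (anyNA(values)) stop(what, ": missing values in numeric body")
  list(ids = ids, cols = cols, values = values)
}

#' Write a matrix as a delimited table
#'
#' Writes row labels in the first column under the label `id_label`, at full
#' double precision so a write/read round trip is value-identical to well
#' below 1e-12.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @param sep field delimiter.
#' @param id_label header label of the row-identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, sep = "\t", id_label = "id") {
  m <- as.matrix(m)
  if (ncol(m) == 0L || nrow(m) == 0L) stop("refusing to write an empty matrix")
  df <- data.frame(format(rownames(m), justify = "none"),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_label, colnames(m))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a proportion matrix
#'
#' Cell types are rows, samples are columns. The matrix must be valid in raw
#' mode at minimum (entries in \[0,1\]).
#'
#' @param P proportion matrix.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(P, path, sep = "\t") {
  if (any(P < 0) || any(P > 1)) stop("proportions outside [0,1]")
  write_matrix_tsv(P, path, sep = sep, id_label = "cell_type")
}

#' @rdname write_matrix_tsv
#' @export
write_expression <- function(m, path, sep = "\t") {
  write_matrix_tsv(m, path, sep = sep, id_label = "gene")
}

#' @rdname write_matrix_tsv
#' @export
write_signature <- function(m, path, sep = "\t") {
  write_matrix_tsv(m, path, sep = sep, id_label = "gene")
}
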