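#' Construct a bulk expression matrix
#'
#' Bulk expression is a genes x samples matrix of non-negative, linear-scale
#' signal. Row names are gene identifiers, column names are sample
#' identifiers; both must be unique. The linear mixing model
#' \eqn{B = S P} is only meaningful in linear (anti-log) scale, so readers
#' and constructors refuse negative values and offer an unlog switch at the
#' I/O layer instead (see [read_expression()]).
#'
#' @param values numeric matrix (or coercible), genes in rows.
#' @param gene_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return a numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  m <- .as_labeled_matrix(values, gene_ids, sample_ids,
                          what = "expression matrix",
                          row_what = "gene", col_what = "sample")
  if (any(m < 0))
    stop("expression matrix contains negative values; expression must be linear-scale and non-negative")
  m
}

#' Construct a cell-type signature matrix
#'
#' A signature matrix holds the expected linear-scale expression of each gene
#' in each purified cell type (genes x cell types). Every column must carry
#' at least one strictly positive entry, otherwise the cell type is
#' unidentifiable.
#'
#' @param values numeric matrix, genes in rows, cell types in columns.
#' @param gene_ids,cell_types optional identifier vectors.
#' @return a numeric matrix with validated dimnames.
#' @export
signature_matrix <- function(values, gene_ids = rownames(values),
                             cell_types = colnames(values)) {
  m <- .as_labeled_matrix(values, gene_ids, cell_types,
                          what = "signature matrix",
                          row_what = "gene", col_what = "cell type")
  if (any(m < 0))
    stop("signature matrix contains negative values")
  zero_col <- colSums(m > 0) == 0
  if (any(zero_col))
    stop("signature column(s) with no positive entry: ",
         paste(colnames(m)[zero_col], collapse = ", "))
  m
}

#' Construct a proportion matrix
#'
#' Cell-type proportions form a cell types x samples matrix whose entries lie
#' in \[0, 1\]. In strict mode every column (sample) must additionally sum to
#' one, i.e. lie on the probability simplex; raw mode accepts non-normalized
#' columns (e.g. regression coefficients before finalization).
#'
#' @param values numeric matrix, cell types in rows, samples in columns.
#' @param cell_types,sample_ids optional identifier vectors.
#' @param strict enforce column sums of one (default `TRUE`).
#' @param tol tolerance on column sums in strict mode.
#' @return a numeric matrix with validated dimnames.
#' @export
proportion_matrix <- function(values, cell_types = rownames(values),
                              sample_ids = colnames(values),
                              strict = TRUE, tol = 1e-9) {
  m <- .as_labeled_matrix(values, cell_types, sample_ids,
                          what = "proportion matrix",
                          row_what = "cell type", col_what = "sample")
  if (strict) {
    v <- validate_proportions(m, tol = tol)
    if (!v$ok)
      stop("proportion matrix is not simplex-valid: ",
           paste(v$violations$message, collapse = "; "))
  } else if (any(m < 0) || any(m > 1)) {
    stop("proportion entries must lie in [0, 1]")
  }
  m
}

.as_labeled_matrix <- function(values, row_ids, col_ids, what, row_what, col_what) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L)
    stop(what, " is empty")
  if (anyNA(m))
    stop(what, " contains missing values")
  if (is.null(row_ids)) row_ids <- paste0(substr(row_what, 1, 1), seq_len(nrow(m)))
  if (is.null(col_ids)) col_ids <- paste0(toupper(substr(col_what, 1, 1)), seq_len(ncol(m)))
  if (length(row_ids) != nrow(m) || length(col_ids) != ncol(m))
    stop(what, ": identifier length does not match dimensions")
  if (anyDuplicated(row_ids))
    stop(what, ": duplicated ", row_what, " identifiers")
  if (anyDuplicated(col_ids))
    stop(what, ": duplicated ", col_what, " identifiers")
  dimnames(m) <- list(as.character(row_ids), as.character(col_ids))
  m
}

#' Validate the simplex constraints on a proportion matrix
#'
#' Checks the two constraints every valid proportion matrix must satisfy:
#' each entry lies in \[0, 1\] and each column (sample) sums to one within
#' `tol`. Rather than raising, it returns a verdict so callers can report all
#' violations at once.
#'
#' @param P cell types x samples numeric matrix.
#' @param tol tolerance on column sums (default `1e-9`).
#' @return a list with elements `ok` (logical) and `violations`
#'   (a data frame with columns `type`, `where`, `message`; empty when ok).
#' @export
#' @examples
#' validate_proportions(matrix(c(0.3, 0.7), 2, 1))$ok
validate_proportions <- function(P, tol = 1e-9) {
  P <- as.matrix(P)
  if (length(P) == 0L || ncol(P) == 0L)
    stop("proportion matrix must have at least one column")
  if (anyNA(P)) stop("proportion matrix contains missing values")
  viol <- list()
  bad <- which(P < 0 | P > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    viol[[length(viol) + 1L]] <- data.frame(
      type = "entry",
      where = sprintf("[%d,%d]", bad[, 1], bad[, 2]),
      message = sprintf("entry [%d,%d] = %g outside [0,1]",
                        bad[, 1], bad[, 2], P[bad]),
      stringsAsFactors = FALSE)
  }
  cs <- colSums(P)
  off <- which(abs(cs - 1) > tol)
  if (length(off) > 0) {
    viol[[length(viol) + 1L]] <- data.frame(
      type = "column_sum",
      where = as.character(off),
      message = sprintf("column %d sums to %.12g", off, cs[off]),
      stringsAsFactors = FALSE)
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(type = character(), where = character(),
               message = character(), stringsAsFactors = FALSE)
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Project non-negative columns onto the probability simplex
#'
#' Divides each column by its sum, so columns of non-negative estimates
#' become valid proportion columns. An all-zero column carries no
#' information about composition: it becomes the uniform distribution
#' \eqn{1/c} and its index is recorded in the `"degenerate_columns"`
#' attribute, so noisy pipelines do not abort. The operation is idempotent.
#'
#' @param values cell types x samples matrix with non-negative entries.
#' @return the column-normalized matrix, with attribute
#'   `degenerate_columns` (integer indices of all-zero input columns).
#' @export
renormalize_to_simplex <- function(values) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("cannot renormalize: missing values")
  if (any(m < 0)) stop("cannot renormalize: negative entries present")
  cs <- colSums(m)
  zero <- which(cs == 0)
  if (length(zero)) {
    m[, zero] <- 1 / nrow(m)
    cs[zero] <- 1
  }
  out <- sweep(m, 2, cs, "/")
  attr(out, "degenerate_columns") <- as.integer(zero)
  out
}

#' Match genes between a bulk and a signature matrix
#'
#' Restricts both matrices to their shared gene identifiers, in bulk row
#' order (deterministic). Warns when fewer than half the signature genes are
#' found in the bulk, and fails hard when no gene is shared.
#'
#' @param B bulk expression matrix (genes x samples).
#' @param S signature matrix (genes x cell types).
#' @return a list with `bulk` and `signature` subset to shared genes in
#'   identical order, plus `shared_genes`, `bulk_only` and `signature_only`
#'   counts.
#' @export
match_genes <- function(B, S) {
  bg <- rownames(B)
  sg <- rownames(S)
  if (is.null(bg) || is.null(sg))
    stop("both matrices need gene identifiers as row names")
  shared <- bg[bg %in% sg]
  if (length(shared) == 0L)
    stop("no shared genes between bulk and signature matrices")
  if (length(shared) < 0.5 * length(sg))
    warning(sprintf("only %d of %d signature genes found in bulk (< 50%%)",
                    length(shared), length(sg)))
  list(bulk = B[shared, , drop = FALSE],
       signature = S[shared, , drop = FALSE],
       shared_genes = shared,
       bulk_only = length(bg) - length(shared),
       signature_only = length(sg) - length(shared))
}

# Run code under a temporary RNG state so generators are seed-deterministic
# without clobbering the caller's stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}
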