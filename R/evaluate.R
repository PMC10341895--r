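#' Real-versus-estimated correlation matrix
#'
#' Entry (k, l) is the Pearson correlation across samples between true
#' proportion row k and estimated row l; the diagonal of a well-matched
#' estimate should be near 1. A constant row has no defined correlation and
#' contributes 0, with the affected rows recorded in the
#' `"constant_rows"` attribute, so a cell type absent from every sample does
#' not crash reporting.
#'
#' @param P_true true proportions (cell types x samples).
#' @param P_est estimated proportions, same samples, matched row order.
#' @return a c x c correlation matrix (rows = real, columns = estimated).
#' @export
correlation_matrix <- function(P_true, P_est) {
  P_true <- as.matrix(P_true); P_est <- as.matrix(P_est)
  if (ncol(P_true) != ncol(P_est)) stop("sample counts differ")
  if (ncol(P_true) < 3) stop("need at least 3 samples for correlations")
  ct <- nrow(P_true); ce <- nrow(P_est)
  R <- matrix(0, ct, ce,
              dimnames = list(rownames(P_true), rownames(P_est)))
  sd_t <- apply(P_true, 1, stats::sd)
  sd_e <- apply(P_est, 1, stats::sd)
  ok_t <- sd_t > 0; ok_e <- sd_e > 0
  if (any(ok_t) && any(ok_e))
    R[ok_t, ok_e] <- stats::cor(t(P_true[ok_t, , drop = FALSE]),
                                t(P_est[ok_e, , drop = FALSE]))
  attr(R, "constant_rows") <- list(true = rownames(P_true)[!ok_t],
                                   estimated = rownames(P_est)[!ok_e])
  R
}

#' Per-cell-type root mean square error
#'
#' For each cell type, the square root of the mean over samples of the
#' squared difference between true and estimated proportion, on the
#' proportion scale (0-1) — the scale on which such errors are conventionally
#' reported.
#'
#' @inheritParams correlation_matrix
#' @return named numeric vector of RMSEs.
#' @export
rmse_per_cell_type <- function(P_true, P_est) {
  P_true <- as.matrix(P_true); P_est <- as.matrix(P_est)
  if (!all(dim(P_true) == dim(P_est))) stop("matrix dimensions differ")
  ct <- rownames(P_true)
  if (is.null(ct)) ct <- paste0("C", seq_len(nrow(P_true)))
  stats::setNames(sqrt(rowMeans((P_true - P_est)^2)), ct)
}

#' Mean diagonal correlation
#'
#' The average of the diagonal of a real-versus-estimated correlation
#' matrix, the single-number accuracy summary used when comparing methods;
#' cell types in `exclude` (e.g. very specific subtypes known to be poorly
#' identifiable) are left out of the mean.
#'
#' @param corr square correlation matrix with matching row/column types.
#' @param exclude character vector of cell types to exclude.
#' @return the mean of the retained diagonal entries.
#' @export
mean_diagonal_correlation <- function(corr, exclude = character()) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop("correlation matrix must be square")
  d <- diag(corr)
  names(d) <- rownames(corr)
  keep <- !(names(d) %in% exclude)
  if (!any(keep)) stop("all cell types excluded")
  mean(d[keep])
}

#' Long-format bar-mixture table
#'
#' The data behind a bar-mixture plot: one row per (sample, cell type,
#' source), `source` being `"real"` or `"estimated"`, so each (sample,
#' source) group sums to 1.
#'
#' @inheritParams correlation_matrix
#' @return data frame with columns `sample`, `cell_type`, `source`,
#'   `proportion` (2 * c * m rows).
#' @export
bar_mixture_table <- function(P_true, P_est) {
  P_true <- as.matrix(P_true); P_est <- as.matrix(P_est)
  if (!all(dim(P_true) == dim(P_est))) stop("matrix dimensions differ")
  long <- function(P, src) data.frame(
    sample = rep(colnames(P), each = nrow(P)),
    cell_type = rep(rownames(P), times = ncol(P)),
    source = src,
    proportion = as.vector(P),
    stringsAsFactors = FALSE)
  rbind(long(P_true, "real"), long(P_est, "estimated"))
}

#' Cell-signature table for one cell type
#'
#' The paired real/estimated series across samples for one cell type,
#' annotated with that type's RMSE — the data behind a cell-signature plot.
#'
#' @inheritParams correlation_matrix
#' @param cell_type cell-type name present in both matrices.
#' @return data frame with columns `sample`, `real`, `estimated`; the RMSE
#'   is attached as attribute `"rmse"`.
#' @export
cell_signature_table <- function(P_true, P_est, cell_type) {
  P_true <- as.matrix(P_true); P_est <- as.matrix(P_est)
  if (!(cell_type %in% rownames(P_true)) ||
      !(cell_type %in% rownames(P_est)))
    stop("unknown cell type: ", cell_type)
  out <- data.frame(sample = colnames(P_true),
                    real = P_true[cell_type, ],
                    estimated = P_est[cell_type, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rmse") <- sqrt(mean((out$real - out$estimated)^2))
  out
}

#' Evaluate an estimate against known proportions
#'
#' Bundles the full comparison layer for one method: the real-versus-
#' estimated correlation matrix, per-cell-type RMSE, mean diagonal
#' correlation, and the long tables behind bar-mixture and cell-signature
#' plots. Unlabeled estimates (unsupervised methods) are first matched to
#' the reference rows via [assign_components()].
#'
#' @param P_true true proportions (cell types x samples).
#' @param fit a `"deconv"` fit or a proportion matrix.
#' @param match if `TRUE` (default) and row names differ from the
#'   reference, match components by correlation before evaluating.
#' @param exclude cell types excluded from the mean diagonal correlation.
#' @return object of class `"deconv_eval"`: list with `corr_matrix`,
#'   `rmse`, `mean_diagonal_corr`, `assignment` (or `NULL`),
#'   `bar_mixture`, `cell_signature` (list of tables per type), `method`.
#' @export
evaluate_deconvolution <- function(P_true, fit, match = TRUE,
                                   exclude = character()) {
  P_est <- if (inherits(fit, "deconv")) coef(fit) else as.matrix(fit)
  method <- if (inherits(fit, "deconv")) fit$method else "unknown"
  P_true <- as.matrix(P_true)
  assignment <- NULL
  if (!identical(rownames(P_est), rownames(P_true))) {
    if (match) {
      assignment <- assign_components(P_est, P_true)
      P_est <- assignment$relabeled
    } else if (all(rownames(P_true) %in% rownames(P_est))) {
      P_est <- P_est[rownames(P_true), , drop = FALSE]
    } else {
      stop("row names differ and match = FALSE")
    }
  }
  corr <- correlation_matrix(P_true, P_est)
  rmse <- rmse_per_cell_type(P_true, P_est)
  structure(list(
    corr_matrix = corr,
    rmse = rmse,
    mean_diagonal_corr = mean_diagonal_correlation(corr, exclude = exclude),
    assignment = assignment,
    bar_mixture = bar_mixture_table(P_true, P_est),
    cell_signature = stats::setNames(
      lapply(rownames(P_true), function(tp)
        cell_signature_table(P_true, P_est, tp)), rownames(P_true)),
    P_true = P_true, P_est = P_est, method = method),
    class = "deconv_eval")
}

#' @export
print.deconv_eval <- function(x, digits = 3, ...) {
  cat(sprintf("Deconvolution evaluation (method: %s)\n", x$method))
  cat(sprintf("  mean diagonal correlation: %.3f\n", x$mean_diagonal_corr))
  cat("  per-cell-type RMSE:\n")
  print(round(x$rmse, digits))
  invisible(x)
}

#' Corrplot-style image of a real-versus-estimated correlation matrix
#'
#' @param x a `"deconv_eval"` object.
#' @param ... unused.
#' @return invisibly, the correlation matrix drawn.
#' @export
plot.deconv_eval <- function(x, ...) {
  R <- x$corr_matrix
  cc <- nrow(R)
  pal <- grDevices::hcl.colors(101, "Blue-Red 3", rev = TRUE)
  op <- graphics::par(mar = c(6, 6, 2, 1)); on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(R)), seq_len(cc), t(R[rev(seq_len(cc)), ]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(R)), labels = colnames(R), las = 2)
  graphics::axis(2, at = seq_len(cc), labels = rev(rownames(R)), las = 1)
  graphics::title(sprintf("real vs estimated correlations (%s)", x$method))
  for (i in seq_len(cc)) for (j in seq_len(ncol(R)))
    graphics::text(j, cc - i + 1, sprintf("%.2f", R[i, j]), cex = 0.7)
  invisible(R)
}

#' Refine a reference signature to compact per-type marker sets
#'
#' Combines a reference signature matrix (e.g. an LM22-style immune
#' signature) with unsupervised simplex-corner deconvolution of the bulk to
#' select a compact marker set per major cell type. The bulk and signature
#' are first restricted to shared genes, subtype columns are collapsed to
#' major types by averaging within `lineage_map`, [linseed_deconvolve()] is
#' run on the shared genes, and each corner is assigned to the major type
#' whose signature-top genes overlap its marker set most (exact bipartite
#' matching). The refined lists are corner marker sets, hence always subsets
#' of the reference signature's genes (containment invariant).
#'
#' @param bulk expression matrix.
#' @param base_signature reference signature matrix (genes x subtypes).
#' @param lineage_map named character vector mapping each signature column
#'   (subtype) to a major cell type.
#' @param n_cell_types number of major types/corners; defaults to the
#'   number of distinct major types in `lineage_map`.
#' @param top_genes_per_type how many top signature genes per collapsed type
#'   define the overlap sets used for corner assignment.
#' @param ... passed to [linseed_deconvolve()].
#' @return object of class `"refined_signature"`: list with `markers`
#'   (named list per major type), `counts`, `shared_genes`,
#'   `collapsed_signature`, `assignment_overlap`, and the underlying
#'   `linseed` fit.
#' @export
refine_signature <- function(bulk, base_signature, lineage_map,
                             n_cell_types = length(unique(lineage_map)),
                             top_genes_per_type = 50, ...) {
  base_signature <- signature_matrix(base_signature)
  if (is.null(names(lineage_map)))
    stop("lineage_map must be a named vector: subtype -> major type")
  missing_map <- setdiff(colnames(base_signature), names(lineage_map))
  if (length(missing_map))
    stop("lineage_map missing subtype(s): ",
         paste(missing_map, collapse = ", "))
  mg <- match_genes(expression_matrix(bulk), base_signature)
  if (length(mg$shared_genes) < n_cell_types)
    stop("fewer shared genes than cell types")
  majors <- sort(unique(unname(lineage_map[colnames(base_signature)])))
  collapsed <- vapply(majors, function(mj) {
    cols <- colnames(base_signature)[lineage_map[colnames(base_signature)] == mj]
    rowMeans(mg$signature[, cols, drop = FALSE])
  }, numeric(nrow(mg$signature)))
  colnames(collapsed) <- majors
  ls_fit <- linseed_deconvolve(mg$bulk, n_cell_types, ...)
  # Top signature genes per major type: largest collapsed signal among
  # genes where that type dominates.
  top_sets <- lapply(majors, function(mj) {
    spec <- collapsed[, mj] / rowSums(collapsed)
    names(sort(spec, decreasing = TRUE))[seq_len(min(top_genes_per_type,
                                                     nrow(collapsed)))]
  })
  names(top_sets) <- majors
  cc <- length(ls_fit$marker_sets)
  if (cc > 8) stop("exact corner assignment supports at most 8 corners")
  if (cc != length(majors))
    stop("number of corners does not match number of major types")
  OV <- matrix(0, cc, cc, dimnames = list(names(ls_fit$marker_sets), majors))
  for (i in seq_len(cc)) for (j in seq_len(cc))
    OV[i, j] <- length(intersect(ls_fit$marker_sets[[i]], top_sets[[j]]))
  if (any(rowSums(OV) == 0)) {
    bad <- which(rowSums(OV) == 0)[1]
    stop("corner with zero overlap to every major type; its genes: ",
         paste(utils::head(ls_fit$marker_sets[[bad]], 10), collapse = ", "))
  }
  best <- NULL
  for (p in .permutations(cc)) {
    tot <- sum(OV[cbind(seq_len(cc), p)])
    lex <- paste(majors[p], collapse = "\r")
    if (is.null(best) || tot > best$tot ||
        (tot == best$tot && lex < best$lex))
      best <- list(p = p, tot = tot, lex = lex)
  }
  markers <- stats::setNames(ls_fit$marker_sets, majors[best$p])
  markers <- markers[majors]
  stopifnot(all(unlist(markers) %in% rownames(base_signature)))
  structure(list(markers = markers,
                 counts = vapply(markers, length, integer(1)),
                 shared_genes = mg$shared_genes,
                 collapsed_signature = collapsed,
                 assignment_overlap = OV,
                 linseed = ls_fit,
                 origin = "base_signature"),
            class = "refined_signature")
}

#' @export
print.refined_signature <- function(x, ...) {
  cat("Refined marker signature\n")
  cat(sprintf("  %d shared genes, %d total markers selected\n",
              length(x$shared_genes), sum(x$counts)))
  for (mj in names(x$markers))
    cat(sprintf("  %-14s %3d genes\n", mj, x$counts[[mj]]))
  invisible(x)
}
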