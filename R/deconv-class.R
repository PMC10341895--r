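#' @export
print.deconv <- function(x, digits = 3, ...) {
  cat(sprintf("Cell-mixture deconvolution fit (method: %s)\n", x$method))
  cat(sprintf("  %d genes x %d samples -> %d components\n",
              nrow(x$bulk), ncol(x$bulk), nrow(x$P)))
  cat("Estimated proportions (first samples):\n")
  print(round(x$P[, seq_len(min(6, ncol(x$P))), drop = FALSE], digits))
  invisible(x)
}

#' Extract estimated proportions from a deconvolution fit
#'
#' @param object a `"deconv"` fit.
#' @param ... unused.
#' @return the cell types x samples proportion matrix (simplex-valid
#'   columns).
#' @export
coef.deconv <- function(object, ...) object$P

#' @export
fitted.deconv <- function(object, ...) {
  if (!is.null(object$signature)) {
    object$signature %*% object$P[colnames(object$signature), , drop = FALSE]
  } else if (!is.null(object$S_est)) {
    object$S_est %*% object$A_est
  } else {
    NULL
  }
}

#' @export
residuals.deconv <- function(object, ...) {
  f <- fitted(object)
  if (is.null(f)) return(NULL)
  mg <- intersect(rownames(object$bulk), rownames(f))
  object$bulk[mg, , drop = FALSE] - f[mg, , drop = FALSE]
}

#' @export
summary.deconv <- function(object, ...) {
  out <- list(method = object$method,
              n_genes = nrow(object$bulk),
              n_samples = ncol(object$bulk),
              n_components = nrow(object$P),
              mean_proportions = rowMeans(object$P),
              per_sample_fit = object$per_sample_fit,
              extras = object$extras)
  class(out) <- "summary.deconv"
  out
}

#' @export
print.summary.deconv <- function(x, digits = 3, ...) {
  cat(sprintf("Deconvolution summary (method: %s)\n", x$method))
  cat(sprintf("  %d genes, %d samples, %d components\n",
              x$n_genes, x$n_samples, x$n_components))
  cat("Mean estimated proportions:\n")
  print(round(x$mean_proportions, digits))
  if (!is.null(x$per_sample_fit)) {
    cat("Per-sample fit (residual RMSD):\n")
    print(round(x$per_sample_fit, digits))
  }
  if (!is.null(x$extras$chosen_nu)) {
    cat("Chosen nu per sample:\n"); print(x$extras$chosen_nu)
  }
  if (!is.null(x$extras$outlier_flags)) {
    nf <- vapply(x$extras$outlier_flags, length, integer(1))
    cat(sprintf("Outlier genes flagged per sample: %s\n",
                paste(nf, collapse = " ")))
  }
  invisible(x)
}

#' Stacked bar-mixture plot of estimated proportions
#'
#' Draws each sample as a stacked bar of its estimated cell-type
#' proportions, the standard bar-mixture view of a deconvolution result.
#'
#' @param x a `"deconv"` fit.
#' @param col bar colors (one per component).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.deconv <- function(x, col = grDevices::hcl.colors(nrow(x$P), "Dark 3"),
                        ...) {
  graphics::barplot(x$P, col = col, border = NA, las = 2,
                    ylab = "estimated proportion",
                    legend.text = rownames(x$P),
                    args.legend = list(x = "topright", bty = "n", cex = 0.7),
                    ...)
}

#' Match unlabeled components to reference cell types
#'
#' Unsupervised deconvolution returns components in arbitrary order. This
#' finds the one-to-one assignment of estimated rows to reference rows
#' maximizing total Pearson correlation, solved exactly by enumerating
#' permutations (component counts here are small); ties are broken by
#' lexical cell-type order. Constant rows contribute correlation 0. A
#' component whose best correlation is below `confidence_threshold` is
#' flagged low-confidence.
#'
#' @param P_est estimated proportions (components x samples).
#' @param reference true proportions (cell types x samples), same sample
#'   order and count of rows.
#' @param confidence_threshold flag assignments with matched correlation
#'   below this (default 0.5).
#' @return object of class `"component_assignment"`: list with `mapping`
#'   (named character vector component -> cell type), `correlations`
#'   (matched r per component), `low_confidence` (logical), and `relabeled`
#'   (P_est with rows reordered and renamed to reference order).
#' @export
assign_components <- function(P_est, reference, confidence_threshold = 0.5) {
  P_est <- as.matrix(P_est); reference <- as.matrix(reference)
  if (nrow(P_est) != nrow(reference))
    stop("component and reference counts differ")
  if (ncol(P_est) != ncol(reference))
    stop("sample counts differ")
  cc <- nrow(P_est)
  if (cc > 8) stop("exact permutation matching supports at most 8 components")
  R <- matrix(0, cc, cc)
  for (i in seq_len(cc)) for (j in seq_len(cc)) {
    if (stats::sd(P_est[i, ]) == 0 || stats::sd(reference[j, ]) == 0) next
    R[i, j] <- stats::cor(P_est[i, ], reference[j, ])
  }
  ref_names <- rownames(reference)
  if (is.null(ref_names)) ref_names <- paste0("type", seq_len(cc))
  perms <- .permutations(cc)
  best <- NULL
  for (p in perms) {
    tot <- sum(R[cbind(seq_len(cc), p)])
    lex <- paste(ref_names[p], collapse = "\r")
    if (is.null(best) || tot > best$tot + 1e-12 ||
        (abs(tot - best$tot) <= 1e-12 && lex < best$lex))
      best <- list(p = p, tot = tot, lex = lex)
  }
  p <- best$p
  est_names <- rownames(P_est)
  if (is.null(est_names)) est_names <- paste0("C", seq_len(cc))
  mapping <- stats::setNames(ref_names[p], est_names)
  r_matched <- stats::setNames(R[cbind(seq_len(cc), p)], est_names)
  relabeled <- P_est[order(p), , drop = FALSE]
  rownames(relabeled) <- ref_names
  relabeled <- relabeled[ref_names, , drop = FALSE]
  structure(list(mapping = mapping, correlations = r_matched,
                 low_confidence = r_matched < confidence_threshold,
                 relabeled = relabeled, correlation_matrix = R),
            class = "component_assignment")
}

#' @export
print.component_assignment <- function(x, ...) {
  cat("Component-to-cell-type assignment:\n")
  for (i in seq_along(x$mapping)) {
    cat(sprintf("  %s -> %s (r = %.3f%s)\n", names(x$mapping)[i],
                x$mapping[i], x$correlations[i],
                if (x$low_confidence[i]) ", LOW CONFIDENCE" else ""))
  }
  invisible(x)
}

.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(n - 1L)) {
      r <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, r)
    }
  }
  out
}
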