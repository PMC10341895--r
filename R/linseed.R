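#' Mutual linearity graph between genes
#'
#' Genes expressed by a single cell type are mutually linear: their
#' expression profiles across samples are proportional, so their pairwise
#' squared Pearson correlation is 1. This scores every gene pair by squared
#' Pearson correlation across samples and summarizes each gene by its
#' collinearity score — the sum of its `top_k_edges` strongest edge weights.
#' Marker genes of well-represented cell types score near `top_k_edges`.
#'
#' The pairwise computation is quadratic in gene count, so the graph is
#' restricted to the `top_n_genes` genes by mean expression. Constant gene
#' rows carry no correlation information and are excluded with a message.
#'
#' @param bulk expression matrix (genes x samples), at least 3 samples.
#' @param top_n_genes restrict to this many genes by mean expression.
#' @param top_k_edges number of strongest edges summed into the
#'   per-gene collinearity score.
#' @return object of class `"mutual_linearity"`: list with `genes`,
#'   `score` (named), `r2` (symmetric matrix, zero diagonal), and
#'   `excluded_constant` (gene ids dropped as constant).
#' @export
mutual_linearity <- function(bulk, top_n_genes = 2000, top_k_edges = 10) {
  B <- as.matrix(bulk)
  if (ncol(B) < 3) stop("mutual linearity needs at least 3 samples")
  stopifnot(top_n_genes >= 2, top_k_edges >= 1)
  top_n_genes <- min(top_n_genes, nrow(B))
  ord <- order(rowMeans(B), decreasing = TRUE)[seq_len(top_n_genes)]
  X <- B[ord, , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  # relative threshold: a row whose variation is numerically negligible
  # against its mean carries no correlation information
  const <- sds <= 1e-10 * pmax(abs(rowMeans(X)), .Machine$double.xmin)
  excl <- rownames(X)[const]
  if (length(excl)) {
    message(sprintf("excluding %d constant gene row(s) from mutual linearity",
                    length(excl)))
    X <- X[!const, , drop = FALSE]
  }
  if (nrow(X) < 2) stop("fewer than 2 non-constant genes available")
  r2 <- stats::cor(t(X))^2
  diag(r2) <- 0
  k <- min(top_k_edges, nrow(X) - 1)
  score <- apply(r2, 1, function(v) sum(sort(v, decreasing = TRUE)[seq_len(k)]))
  structure(list(genes = rownames(X), score = score, r2 = r2,
                 excluded_constant = excl, top_k_edges = top_k_edges),
            class = "mutual_linearity")
}

#' Simplex-corner deconvolution with marker discovery
#'
#' LINSEED-style complete deconvolution. Under the mixing model, the
#' baseline-corrected, row-normalized profile of a cell-type-specific gene is
#' a point on the simplex spanned by the (row-normalized) cell-type
#' proportion rows; pure markers sit at the corners. The procedure:
#'
#' 1. build a [mutual_linearity()] graph and keep genes whose collinearity
#'    score is at or above `collinearity_quantile` (always keeping a minimum
#'    candidate pool of `10 * n_cell_types` top-scoring genes, so small
#'    problems are not over-filtered);
#' 2. subtract each gene's across-sample minimum (its non-specific baseline)
#'    and drop genes whose corrected row sums to ~0;
#' 3. row-normalize the kept genes (each gene becomes a point in sample
#'    space) and project the points onto the top-`c` right singular vectors;
#' 4. locate `c` corners by successive projection: repeatedly pick the point
#'    farthest from the origin and deflate along its direction;
#' 5. call genes within the `marker_distance_quantile` of distances to a
#'    corner its markers (at least `min_markers` nearest genes);
#' 6. estimate the normalized proportion rows as the mean row-normalized
#'    profile of each corner's markers;
#' 7. undo row normalization by weighting each row with its cell type's
#'    total marker signal, then renormalize each sample column to the
#'    simplex.
#'
#' The estimate is fully deterministic given the inputs and is invariant to
#' positive rescaling of `bulk`.
#'
#' @param bulk expression matrix (genes x samples), `m >= c` samples.
#' @param n_cell_types number of cell types / corners `c` (>= 2).
#' @param top_n_genes,top_k_edges passed to [mutual_linearity()].
#' @param collinearity_quantile keep genes with collinearity score at or
#'   above this quantile (default 0.9; use 0 to keep all candidates on small
#'   gene sets).
#' @param marker_distance_quantile distance quantile around each corner
#'   defining its marker set (default 0.05).
#' @param min_markers minimum marker genes per corner (default 3).
#' @return a list with `P` (finalized proportions, corners x samples),
#'   `marker_sets` (named list of gene ids per corner), `marker_distances`,
#'   `corner_genes` (the corner-defining gene of each component), `H_norm`
#'   (row-normalized proportion estimate), `X_norm`, `coords`,
#'   `projection_basis`, `kept_genes`, `dropped_zero_rows`, `graph`, and
#'   `per_sample_fit` (reconstruction RMSD of `X_norm` from `H_norm`).
#' @export
linseed_deconvolve <- function(bulk, n_cell_types,
                               top_n_genes = 2000, top_k_edges = 10,
                               collinearity_quantile = 0.9,
                               marker_distance_quantile = 0.05,
                               min_markers = 3) {
  B <- as.matrix(bulk)
  cc <- as.integer(n_cell_types)
  if (cc < 2) stop("n_cell_types must be at least 2")
  if (ncol(B) < cc) stop("need at least as many samples as cell types")
  ml <- mutual_linearity(B, top_n_genes = top_n_genes,
                         top_k_edges = top_k_edges)
  thr <- stats::quantile(ml$score, collinearity_quantile, names = FALSE)
  keep <- ml$score >= thr
  # Small problems: never filter below a working pool of 10*c genes.
  pool <- min(length(ml$score), 10L * cc)
  if (sum(keep) < pool)
    keep <- rank(-ml$score, ties.method = "min") <= pool
  kept_genes <- ml$genes[keep]
  if (length(kept_genes) < cc)
    stop("fewer candidate genes than cell types after filtering")
  X <- B[kept_genes, , drop = FALSE]
  # Baseline correction: a gene's across-sample minimum estimates its
  # non-specific (shared) signal; what remains is attributable to one type.
  X <- X - apply(X, 1, min)
  rs <- rowSums(X)
  dropped <- kept_genes[rs <= 1e-12 * max(rs)]
  if (length(dropped)) {
    message(sprintf("dropping %d gene(s) with ~zero baseline-corrected signal",
                    length(dropped)))
    X <- X[rs > 1e-12 * max(rs), , drop = FALSE]
  }
  if (nrow(X) < cc)
    stop("fewer candidate genes than cell types after filtering")
  Xn <- X / rowSums(X)
  sv <- svd(Xn, nu = 0, nv = cc)
  basis <- sv$v                                # m x cc
  coords <- Xn %*% basis                       # genes x cc
  corner_idx <- .successive_projection(coords, cc)
  corners <- coords[corner_idx, , drop = FALSE]
  comp_ids <- paste0("C", seq_len(cc))
  rownames(corners) <- comp_ids
  # Marker sets: genes close to each corner in projected space.
  marker_sets <- vector("list", cc); names(marker_sets) <- comp_ids
  marker_dist <- vector("list", cc); names(marker_dist) <- comp_ids
  for (k in seq_len(cc)) {
    d <- sqrt(colSums((t(coords) - corners[k, ])^2))
    qd <- stats::quantile(d, marker_distance_quantile, names = FALSE)
    sel <- d <= qd + 1e-12
    if (sum(sel) < min_markers)
      sel <- rank(d, ties.method = "first") <= min_markers
    marker_sets[[k]] <- rownames(Xn)[sel]
    marker_dist[[k]] <- stats::setNames(d[sel], rownames(Xn)[sel])
  }
  # Duplicate corners indicate fewer real vertices than requested.
  if (cc > 1) {
    cd <- as.matrix(stats::dist(corners))
    if (any(cd[upper.tri(cd)] < 1e-9))
      stop("duplicate simplex corners found; try a smaller n_cell_types")
  }
  # Normalized proportion rows: mean profile of each corner's markers.
  H <- do.call(rbind, lapply(marker_sets, function(g)
    colMeans(Xn[g, , drop = FALSE])))
  H <- H / rowSums(H)
  dimnames(H) <- list(comp_ids, colnames(B))
  # Undo row normalization: weight rows by total marker signal per type.
  w <- vapply(marker_sets, function(g) sum(X[g, , drop = FALSE]), numeric(1))
  raw <- H * w
  P <- .finalize_P(raw, comp_ids, colnames(B))
  # Diagnostics: express each gene point as a non-negative combination of
  # the estimated normalized proportion rows and measure the residual.
  A <- t(vapply(seq_len(nrow(Xn)),
                function(i) pracma::lsqnonneg(t(H), Xn[i, ])$x,
                numeric(cc)))
  recon_res <- sqrt(colMeans((Xn - A %*% H)^2))
  list(P = P, marker_sets = marker_sets, marker_distances = marker_dist,
       corner_genes = stats::setNames(rownames(Xn)[corner_idx], comp_ids),
       corner_coords = corners, H_norm = H, X_norm = Xn, coords = coords,
       projection_basis = basis, kept_genes = rownames(Xn),
       dropped_zero_rows = dropped, graph = ml,
       per_sample_fit = stats::setNames(recon_res, colnames(B)))
}

# Successive projection: pick the point with the largest norm, project all
# points onto the orthogonal complement of its direction, repeat.
.successive_projection <- function(coords, cc) {
  R <- coords
  idx <- integer(cc)
  for (k in seq_len(cc)) {
    norms <- sqrt(rowSums(R^2))
    idx[k] <- which.max(norms)
    u <- R[idx[k], ]
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12)
      stop("degenerate geometry during corner search; try a smaller n_cell_types")
    u <- u / nu
    R <- R - (R %*% u) %*% t(u)
  }
  idx
}
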