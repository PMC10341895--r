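#' Design a marker-block signature matrix
#'
#' Describes a synthetic signature with block marker structure: each cell
#' type owns `markers_per_type` marker genes expressed at
#' `background_level * marker_fold` in their own type and `background_level`
#' elsewhere; all remaining genes are flat background. `spillover` models the
#' overlap of gene signatures between cell populations: a fraction of each
#' marker's above-background signal leaks into one other, randomly chosen,
#' cell type.
#'
#' @param n_genes total number of genes.
#' @param cell_types character vector of cell-type names.
#' @param markers_per_type marker genes per cell type.
#' @param marker_fold marker expression over background (> 1).
#' @param spillover fraction in \[0, 1) of a marker's above-background signal
#'   leaked into one other cell type.
#' @param background_level baseline expression of every gene (> 0).
#' @param seed integer seed controlling the spillover targets.
#' @return an object of class `"signature_design"`.
#' @export
signature_design <- function(n_genes = 500,
                             cell_types = c("CellA", "CellB", "CellC",
                                            "CellD", "CellE"),
                             markers_per_type = 10,
                             marker_fold = 10,
                             spillover = 0,
                             background_level = 5,
                             seed = 1L) {
  stopifnot(n_genes >= 1, markers_per_type >= 1,
            marker_fold > 1, background_level > 0,
            spillover >= 0, spillover < 1,
            !anyDuplicated(cell_types), length(cell_types) >= 2)
  if (length(cell_types) * markers_per_type > n_genes)
    stop("cell_types * markers_per_type exceeds n_genes")
  structure(list(n_genes = as.integer(n_genes),
                 cell_types = as.character(cell_types),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold = marker_fold,
                 spillover = spillover,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "signature_design")
}

#' Design a mixture of samples
#'
#' Describes how ground-truth proportion columns are drawn and how much
#' multiplicative noise the mixed expression carries. `"gse64385_like"`
#' emulates the classic cancer/immune spike-in design: 12 samples over six
#' cell types, the first two samples pure cancer cells, the remaining ten
#' with a cancer fraction drawn from \{0.3, 0.4, 0.5\} and the remainder
#' split over the five immune types. Noise is multiplicative log-normal with
#' unit mean, parameterized by its coefficient of variation.
#'
#' @param n_samples number of samples.
#' @param proportion_mode one of `"dirichlet"`, `"explicit"`,
#'   `"gse64385_like"`.
#' @param dirichlet_alpha symmetric Dirichlet concentration for
#'   `"dirichlet"` mode.
#' @param explicit_P proportion matrix for `"explicit"` mode (must be
#'   simplex-valid).
#' @param pure_samples optional list of `list(sample = i, cell_type = name)`
#'   entries; those columns are overwritten with one-hot proportions.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise on the mixed expression (0 = noiseless).
#' @param seed integer seed.
#' @return an object of class `"mixture_design"`.
#' @export
mixture_design <- function(n_samples = 12,
                           proportion_mode = c("gse64385_like", "dirichlet",
                                               "explicit"),
                           dirichlet_alpha = 1,
                           explicit_P = NULL,
                           pure_samples = NULL,
                           noise_cv = 0.05,
                           seed = 1L) {
  proportion_mode <- match.arg(proportion_mode)
  stopifnot(n_samples >= 1, dirichlet_alpha > 0, noise_cv >= 0)
  if (proportion_mode == "explicit") {
    if (is.null(explicit_P)) stop("explicit mode requires explicit_P")
    v <- validate_proportions(explicit_P)
    if (!v$ok) stop("explicit_P is not simplex-valid")
  }
  structure(list(n_samples = as.integer(n_samples),
                 proportion_mode = proportion_mode,
                 dirichlet_alpha = dirichlet_alpha,
                 explicit_P = explicit_P,
                 pure_samples = pure_samples,
                 noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "mixture_design")
}

#' Cell types of the cancer/immune spike-in design
#' @return character vector of the six cell-type names.
#' @export
gse64385_cell_types <- function() {
  c("CancerCells", "Neutrophils", "Monocytes", "Bcells", "NKcells", "Tcells")
}

#' Generate a marker-block signature matrix
#'
#' Realizes a [signature_design()]: marker gene `i` of cell type `k` gets
#' value `background_level * marker_fold` in column `k` and
#' `background_level` elsewhere; with positive spillover,
#' `spillover * (marker - background)` is added to one other seed-chosen
#' column. Non-marker genes are flat background. Deterministic under the
#' design seed.
#'
#' @param design a [signature_design()].
#' @return a list with `S` (a [signature_matrix()]) and `markers` (named list
#'   of marker gene ids per cell type).
#' @export
generate_signature <- function(design) {
  stopifnot(inherits(design, "signature_design"))
  c_types <- design$cell_types
  c_n <- length(c_types)
  n <- design$n_genes
  mpt <- design$markers_per_type
  bg <- design$background_level
  gene_ids <- sprintf("g%05d", seq_len(n))
  S <- matrix(bg, n, c_n, dimnames = list(gene_ids, c_types))
  markers <- vector("list", c_n)
  names(markers) <- c_types
  .with_seed(design$seed, {
    for (k in seq_len(c_n)) {
      rows <- ((k - 1) * mpt + 1):(k * mpt)
      S[rows, k] <- bg * design$marker_fold
      markers[[k]] <- gene_ids[rows]
      if (design$spillover > 0) {
        for (r in rows) {
          others <- setdiff(seq_len(c_n), k)
          target <- others[sample.int(length(others), 1)]
          S[r, target] <- S[r, target] +
            design$spillover * (bg * design$marker_fold - bg)
        }
      }
    }
  })
  list(S = signature_matrix(S), markers = markers)
}

#' Generate ground-truth proportion columns
#'
#' @param design a [mixture_design()].
#' @param cell_types character vector of cell-type names. `"gse64385_like"`
#'   mode requires exactly six, the first being the cancer-cell type.
#' @return a strict [proportion_matrix()] (cell types x samples).
#' @export
generate_proportions <- function(design, cell_types) {
  stopifnot(inherits(design, "mixture_design"))
  c_n <- length(cell_types)
  m <- design$n_samples
  sample_ids <- sprintf("S%02d", seq_len(m))
  P <- .with_seed(design$seed, {
    P <- switch(design$proportion_mode,
      dirichlet = {
        g <- matrix(stats::rgamma(c_n * m, shape = design$dirichlet_alpha),
                    c_n, m)
        sweep(g, 2, colSums(g), "/")
      },
      explicit = {
        ep <- as.matrix(design$explicit_P)
        if (nrow(ep) != c_n || ncol(ep) != m)
          stop("explicit_P dimensions do not match design")
        ep
      },
      gse64385_like = {
        if (c_n != 6)
          stop("gse64385_like mode needs six cell types (cancer first)")
        if (m < 3) stop("gse64385_like mode needs at least 3 samples")
        P <- matrix(0, c_n, m)
        P[1, 1:2] <- 1
        for (j in 3:m) {
          cc <- sample(c(0.3, 0.4, 0.5), 1)
          g <- stats::rgamma(c_n - 1, shape = 1)
          P[1, j] <- cc
          P[-1, j] <- (1 - cc) * g / sum(g)
        }
        P
      })
    if (!is.null(design$pure_samples)) {
      for (ps in design$pure_samples) {
        k <- match(ps$cell_type, cell_types)
        if (is.na(k)) stop("pure sample references unknown cell type: ",
                           ps$cell_type)
        P[, ps$sample] <- 0
        P[k, ps$sample] <- 1
      }
    }
    P
  })
  proportion_matrix(P, cell_types = cell_types, sample_ids = sample_ids)
}

#' Mix a signature and proportions into bulk expression
#'
#' Computes \eqn{B = S P} and, when `noise_cv > 0`, multiplies every entry by
#' an independent log-normal factor with unit mean and coefficient of
#' variation `noise_cv`. Multiplicative noise is used because expression
#' noise scales with signal; `noise_cv = 0` returns the exact product.
#'
#' @param S signature matrix (genes x cell types).
#' @param P proportion matrix (cell types x samples).
#' @param noise_cv coefficient of variation of the noise factors.
#' @param seed integer seed for the noise draw.
#' @return an [expression_matrix()] (genes x samples).
#' @export
mix_expression <- function(S, P, noise_cv = 0, seed = 1L) {
  if (ncol(S) != nrow(P))
    stop("signature columns and proportion rows do not align")
  B <- S %*% P
  if (noise_cv > 0) {
    s2 <- log(1 + noise_cv^2)
    f <- .with_seed(seed, matrix(
      exp(stats::rnorm(length(B), mean = -s2 / 2, sd = sqrt(s2))),
      nrow(B), ncol(B)))
    B <- B * f
  }
  expression_matrix(B, gene_ids = rownames(S), sample_ids = colnames(P))
}

#' Generate a complete ground-truthed synthetic dataset
#'
#' Bundles a signature, proportions, and noisy bulk under the linear mixing
#' model. With `noise_cv = 0` the bulk equals `S_true %*% P_true` exactly.
#'
#' @param sig_design a [signature_design()].
#' @param mix_design a [mixture_design()]; `"gse64385_like"` mode requires a
#'   six-cell-type signature design.
#' @return an object of class `"deconv_sim"`: a list with `B`, `S_true`,
#'   `P_true`, `markers`, and the two designs.
#' @export
make_dataset <- function(sig_design, mix_design) {
  sig <- generate_signature(sig_design)
  P <- generate_proportions(mix_design, sig_design$cell_types)
  B <- mix_expression(sig$S, P, noise_cv = mix_design$noise_cv,
                      seed = mix_design$seed + 1L)
  structure(list(B = B, S_true = sig$S, P_true = P, markers = sig$markers,
                 sig_design = sig_design, mix_design = mix_design),
            class = "deconv_sim")
}

#' @export
print.deconv_sim <- function(x, ...) {
  cat("Synthetic cell-mixture dataset\n")
  cat(sprintf("  %d genes x %d samples, %d cell types (%s mode, noise CV %.3g)\n",
              nrow(x$B), ncol(x$B), nrow(x$P_true),
              x$mix_design$proportion_mode, x$mix_design$noise_cv))
  cat(sprintf("  markers per type: %d, fold %.3g, spillover %.3g\n",
              x$sig_design$markers_per_type, x$sig_design$marker_fold,
              x$sig_design$spillover))
  invisible(x)
}
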