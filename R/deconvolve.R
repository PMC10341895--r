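#' Deconvolve bulk expression into cell-type proportions
#'
#' Fits the linear mixing model \eqn{B = S P} by one of six first-generation
#' estimators and returns the proportion matrix \eqn{\hat P} with columns on
#' the probability simplex.
#'
#' Supervised methods (require `signature`):
#' \describe{
#'   \item{`"nnls"`}{per-sample non-negative least squares, the direct
#'     baseline solution of the per-gene linear system.}
#'   \item{`"svr"`}{linear nu-support-vector regression of each sample on the
#'     signature columns (CIBERSORT-style); the nu minimizing the
#'     reconstruction root-mean-square deviation over `nu_grid` is kept.}
#'   \item{`"rlm"`}{Huber robust linear regression (ABIS-style), optionally
#'     after multiplying each signature column by a per-cell-type
#'     mRNA-abundance factor (see [fit_mrna_scaling()]).}
#'   \item{`"alts"`}{adaptive least trimmed squares (FARDEEP-style): NNLS
#'     refit after iteratively discarding genes whose squared residual
#'     exceeds `alts_multiplier` times the median squared residual.}
#' }
#' Unsupervised methods (require `n_cell_types`, no signature):
#' \describe{
#'   \item{`"ica"`}{fixed-point independent component analysis of the bulk
#'     (DECONICA-style); mixing weights give the proportions.}
#'   \item{`"linseed"`}{mutual-linearity filtering, row normalization, and
#'     simplex-corner search (LINSEED-style); corner neighborhoods give the
#'     marker genes.}
#' }
#'
#' All methods share the same finalization: negative raw coefficients are
#' truncated to zero and each sample column is renormalized to the simplex,
#' so methods differ only in their regression/decomposition core.
#'
#' @param bulk bulk expression matrix (genes x samples), linear scale.
#' @param signature signature matrix (genes x cell types) for supervised
#'   methods; genes are matched by name via [match_genes()].
#' @param method one of `"nnls"`, `"svr"`, `"rlm"`, `"alts"`, `"ica"`,
#'   `"linseed"`.
#' @param n_cell_types number of cell types for unsupervised methods.
#' @param nu_grid nu values searched by `"svr"` (each in (0, 1\]).
#' @param cost positive SVR cost constant controlling error tolerance.
#' @param standardize z-score each gene using its signature-row mean/sd
#'   before SVR (default `TRUE`).
#' @param alphas optional [fit_mrna_scaling()] result (or named numeric) of
#'   per-cell-type mRNA-abundance factors for `"rlm"`.
#' @param alts_multiplier outlier threshold multiplier for `"alts"`
#'   (squared residual > multiplier x median squared residual).
#' @param alts_max_iter maximum trimming iterations for `"alts"`.
#' @param seed integer seed for `"ica"` initialization.
#' @param ... further method-specific arguments passed to
#'   [linseed_deconvolve()] or [ica_deconvolve()].
#' @return an object of class `c("deconv_<method>", "deconv")`; see
#'   [coef.deconv()], [summary.deconv()], [plot.deconv()].
#' @examples
#' sim <- make_dataset(signature_design(n_genes = 120, seed = 7),
#'                     mixture_design(proportion_mode = "dirichlet",
#'                                    noise_cv = 0, seed = 7))
#' fit <- deconvolve(sim$B, sim$S_true, method = "nnls")
#' round(coef(fit), 3)
#' @export
deconvolve <- function(bulk, signature = NULL,
                       method = c("nnls", "svr", "rlm", "alts", "ica",
                                  "linseed"),
                       n_cell_types = NULL,
                       nu_grid = c(0.25, 0.5, 0.75), cost = 1,
                       standardize = TRUE,
                       alphas = NULL,
                       alts_multiplier = 10, alts_max_iter = 20,
                       seed = 1L, ...) {
  method <- match.arg(method)
  cl <- match.call()
  bulk <- expression_matrix(bulk)
  if (method %in% c("nnls", "svr", "rlm", "alts")) {
    if (is.null(signature))
      stop("method '", method, "' is supervised and needs a signature matrix")
    signature <- signature_matrix(signature)
    mg <- match_genes(bulk, signature)
    B <- mg$bulk; S <- mg$signature
    if (ncol(S) > nrow(S))
      stop("more cell types than shared genes; the system is underdetermined")
    fit <- switch(method,
      nnls = .deconv_nnls(B, S),
      svr  = .deconv_svr(B, S, nu_grid = nu_grid, cost = cost,
                         standardize = standardize),
      rlm  = .deconv_rlm(B, S, alphas = alphas),
      alts = .deconv_alts(B, S, multiplier = alts_multiplier,
                          max_iter = alts_max_iter))
    fit$gene_match <- mg[c("shared_genes", "bulk_only", "signature_only")]
    fit$signature <- S
  } else {
    if (is.null(n_cell_types))
      stop("method '", method, "' is unsupervised and needs n_cell_types")
    fit <- switch(method,
      ica = ica_deconvolve(bulk, n_cell_types, seed = seed, ...),
      linseed = linseed_deconvolve(bulk, n_cell_types, ...))
  }
  fit$method <- method
  fit$call <- cl
  fit$bulk <- bulk
  class(fit) <- c(paste0("deconv_", method), "deconv")
  fit
}

# Shared finalization: truncate negatives, renormalize each sample column.
.finalize_P <- function(raw, cell_types, sample_ids) {
  raw[raw < 0] <- 0
  P <- renormalize_to_simplex(raw)
  dimnames(P) <- list(cell_types, sample_ids)
  P
}

.residual_rmsd <- function(S, p, b) sqrt(mean((S %*% p - b)^2))

.deconv_nnls <- function(B, S) {
  if (qr(S)$rank < ncol(S))
    warning("signature matrix is rank-deficient; proportions may be non-unique")
  m <- ncol(B)
  raw <- matrix(0, ncol(S), m)
  fitres <- numeric(m)
  for (j in seq_len(m)) {
    sol <- pracma::lsqnonneg(S, B[, j])
    raw[, j] <- sol$x
    fitres[j] <- .residual_rmsd(S, sol$x, B[, j])
  }
  P <- .finalize_P(raw, colnames(S), colnames(B))
  list(P = P, raw_coefficients = raw, per_sample_fit = stats::setNames(fitres, colnames(B)))
}

# Ordinary least squares with the same finalization; used as the
# non-robust comparator when assessing outlier tolerance.
.deconv_ols <- function(B, S) {
  raw <- qr.coef(qr(S), B)
  raw[is.na(raw)] <- 0
  fitres <- sqrt(colMeans((S %*% raw - B)^2))
  P <- .finalize_P(raw, colnames(S), colnames(B))
  list(P = P, raw_coefficients = raw, per_sample_fit = fitres)
}

.deconv_svr <- function(B, S, nu_grid = c(0.25, 0.5, 0.75), cost = 1,
                        standardize = TRUE) {
  stopifnot(length(nu_grid) >= 1, all(nu_grid > 0), all(nu_grid <= 1),
            cost > 0)
  m <- ncol(B); cc <- ncol(S)
  raw <- matrix(0, cc, m)
  fitres <- numeric(m)
  chosen_nu <- numeric(m)
  degenerate <- logical(m)
  # Global z-scoring (one mean/sd over all signature entries, and one over
  # the mixture column): keeps the relative structure of the signature while
  # putting mixture and signature on comparable scales. Per-gene scaling is
  # deliberately avoided — it erases the between-gene magnitude differences
  # that identify the proportion scale, leaving the shift to the intercept.
  Sz <- if (standardize) (S - mean(S)) / stats::sd(S) else S
  for (j in seq_len(m)) {
    b <- B[, j]
    bz <- if (standardize) (b - mean(b)) / stats::sd(b) else b
    best <- NULL
    for (nu in nu_grid) {
      mod <- e1071::svm(x = Sz, y = bz, type = "nu-regression",
                        kernel = "linear", nu = nu, cost = cost,
                        scale = FALSE)
      w <- as.vector(crossprod(mod$coefs, mod$SV))
      w[w < 0] <- 0
      rmsd <- sqrt(mean((Sz %*% w - bz)^2))
      if (is.null(best) || rmsd < best$rmsd)
        best <- list(w = w, rmsd = rmsd, nu = nu)
    }
    if (sum(best$w) == 0) {
      degenerate[j] <- TRUE
      best$w <- rep(1 / cc, cc)
    }
    raw[, j] <- best$w
    chosen_nu[j] <- best$nu
    p_norm <- best$w / sum(best$w)
    fitres[j] <- .residual_rmsd(S, p_norm, b)
  }
  if (any(degenerate))
    warning("degenerate SVR fit (all-zero coefficients) in sample(s): ",
            paste(colnames(B)[degenerate], collapse = ", "),
            "; uniform proportions returned")
  P <- .finalize_P(raw, colnames(S), colnames(B))
  list(P = P, raw_coefficients = raw,
       per_sample_fit = stats::setNames(fitres, colnames(B)),
       extras = list(chosen_nu = stats::setNames(chosen_nu, colnames(B)),
                     degenerate = degenerate))
}

#' Fit per-cell-type mRNA-abundance scaling factors
#'
#' Cell types differ in total mRNA content, so raw regression coefficients
#' over- or under-state the abundance of high- or low-mRNA cells. Given
#' estimates on calibration samples with known proportions, this fits, per
#' cell type, the factor \eqn{\hat\alpha_k} minimizing
#' \eqn{\sum_j (\alpha_k \hat p_{kj} - p_{kj})^2} over the bounded interval
#' `bounds` — the closed-form ratio
#' \eqn{\sum_j \hat p_{kj} p_{kj} / \sum_j \hat p_{kj}^2} clipped to the
#' bounds. It requires known proportions, so it is exposed as an explicit
#' calibration utility and never applied silently.
#'
#' @param P_est estimated proportions on calibration samples
#'   (cell types x samples).
#' @param P_true known proportions, same dimensions and dimnames order.
#' @param bounds length-2 positive bounds `c(l, u)` on each factor.
#' @return object of class `"mrna_scaling"`: list with `alpha` (named
#'   vector), `bounds`, and `undefined` (types with all-zero estimates,
#'   assigned alpha = 1).
#' @export
fit_mrna_scaling <- function(P_est, P_true, bounds = c(0.1, 10)) {
  stopifnot(all(dim(P_est) == dim(P_true)), length(bounds) == 2,
            bounds[1] > 0, bounds[2] >= bounds[1])
  ct <- rownames(P_est)
  if (is.null(ct)) ct <- paste0("C", seq_len(nrow(P_est)))
  alpha <- numeric(nrow(P_est))
  undefined <- logical(nrow(P_est))
  for (k in seq_len(nrow(P_est))) {
    denom <- sum(P_est[k, ]^2)
    if (denom == 0) {
      alpha[k] <- 1
      undefined[k] <- TRUE
    } else {
      alpha[k] <- min(max(sum(P_est[k, ] * P_true[k, ]) / denom, bounds[1]),
                      bounds[2])
    }
  }
  if (any(undefined))
    warning("alpha undefined (all-zero estimates) for: ",
            paste(ct[undefined], collapse = ", "), "; set to 1")
  structure(list(alpha = stats::setNames(alpha, ct), bounds = bounds,
                 undefined = stats::setNames(undefined, ct)),
            class = "mrna_scaling")
}

.deconv_rlm <- function(B, S, alphas = NULL, maxit = 50, acc = 1e-8,
                        huber_k = 1.345) {
  a <- rep(1, ncol(S))
  if (!is.null(alphas)) {
    av <- if (inherits(alphas, "mrna_scaling")) alphas$alpha else alphas
    if (!is.null(names(av)) && !is.null(colnames(S))) {
      if (!all(colnames(S) %in% names(av)))
        stop("alphas missing for cell type(s): ",
             paste(setdiff(colnames(S), names(av)), collapse = ", "))
      a <- av[colnames(S)]
    } else {
      stopifnot(length(av) == ncol(S))
      a <- av
    }
    if (any(a <= 0)) stop("mRNA scaling factors must be positive")
  }
  Ssc <- sweep(S, 2, a, "*")
  m <- ncol(B)
  raw <- matrix(0, ncol(S), m)
  fitres <- numeric(m)
  for (j in seq_len(m)) {
    fit <- suppressWarnings(
      MASS::rlm(x = Ssc, y = B[, j], psi = MASS::psi.huber, k = huber_k,
                maxit = maxit, acc = acc))
    rms <- sqrt(mean(stats::residuals(fit)^2))
    # rlm reports non-convergence on exactly-fitting data because the
    # residual scale collapses to zero; only a material residual is worth a
    # warning
    if (!isTRUE(fit$converged) && rms > 1e-8 * (mean(abs(B[, j])) + 1e-300))
      warning("robust fit did not converge for sample ", colnames(B)[j],
              "; using last iterate", call. = FALSE)
    raw[, j] <- stats::coef(fit)
    fitres[j] <- rms
  }
  P <- .finalize_P(raw, colnames(S), colnames(B))
  list(P = P, raw_coefficients = raw,
       per_sample_fit = stats::setNames(fitres, colnames(B)),
       extras = list(alpha = stats::setNames(a, colnames(S))))
}

.deconv_alts <- function(B, S, multiplier = 10, max_iter = 20,
                         zero_median_tol = 1e-10) {
  stopifnot(multiplier > 0, max_iter >= 1)
  m <- ncol(B); n <- nrow(B)
  raw <- matrix(0, ncol(S), m)
  fitres <- numeric(m)
  flags <- vector("list", m)
  names(flags) <- colnames(B)
  for (j in seq_len(m)) {
    b <- B[, j]
    flagged <- logical(n)
    for (it in seq_len(max_iter)) {
      sol <- pracma::lsqnonneg(S[!flagged, , drop = FALSE], b[!flagged])
      r2 <- as.vector(b - S %*% sol$x)^2
      med <- stats::median(r2[!flagged])
      # the absolute floor keeps numerically-zero residuals (noiseless
      # data) from flagging genes on floating-point dust
      thr <- if (is.finite(multiplier)) max(multiplier * med, zero_median_tol)
             else Inf
      candidates <- r2 > thr
      if (mean(candidates) > 0.5)
        stop("adaptive trimming flagged > 50% of genes in sample ",
             colnames(B)[j], "; contamination too heavy to trim")
      # Incremental schedule: trim at most a growing budget of the
      # worst-residual genes per pass. A fit still biased by heavy outliers
      # misfits clean genes too; trimming only the extreme tail first lets
      # the fit re-concentrate before milder residuals are judged.
      budget <- ceiling(n * min(0.5, 0.05 * it))
      if (sum(candidates) > budget) {
        keep_worst <- order(r2, decreasing = TRUE)[seq_len(budget)]
        new_flagged <- logical(n)
        new_flagged[keep_worst] <- candidates[keep_worst]
      } else {
        new_flagged <- candidates
      }
      if (identical(new_flagged, flagged)) break
      flagged <- new_flagged
    }
    raw[, j] <- sol$x
    flags[[j]] <- rownames(B)[flagged]
    fitres[j] <- sqrt(mean((b[!flagged] - S[!flagged, , drop = FALSE] %*% sol$x)^2))
  }
  P <- .finalize_P(raw, colnames(S), colnames(B))
  list(P = P, raw_coefficients = raw,
       per_sample_fit = stats::setNames(fitres, colnames(B)),
       extras = list(outlier_flags = flags,
                     threshold_multiplier = multiplier))
}
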