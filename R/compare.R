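#' Load files or simulate a ground-truthed bundle
#'
#' Resolves the input block of a comparison configuration: exactly one of a
#' synthetic design (`config$synthetic`) or file paths (`config$files`) must
#' be present. The synthetic branch delegates to [make_dataset()]; the file
#' branch reads the bulk (required) and optionally a signature and true
#' proportions.
#'
#' @param config a list; see [run_comparison()].
#' @return a list with `B`, `S` (or `NULL`), `P_true` (or `NULL`), and
#'   `markers` (or `NULL`).
#' @export
load_or_simulate <- function(config) {
  has_syn <- !is.null(config$synthetic)
  has_files <- !is.null(config$files)
  if (has_syn == has_files)
    stop("config must contain exactly one of 'synthetic' or 'files'")
  if (has_syn) {
    syn <- config$synthetic
    sig <- do.call(signature_design, syn$signature %||% list())
    mix <- do.call(mixture_design, syn$mixture %||% list())
    ds <- make_dataset(sig, mix)
    list(B = ds$B, S = ds$S_true, P_true = ds$P_true, markers = ds$markers)
  } else {
    f <- config$files
    if (is.null(f$bulk)) stop("files input needs a 'bulk' path")
    for (p in c(f$bulk, f$signature, f$proportions))
      if (!file.exists(p)) stop("input file not found: ", p)
    B <- read_expression(f$bulk, unlog = isTRUE(f$unlog))
    S <- if (!is.null(f$signature)) read_signature(f$signature) else NULL
    P <- if (!is.null(f$proportions)) read_proportions(f$proportions) else NULL
    if (is.null(P))
      message("no true proportions supplied; evaluation stages will be skipped")
    list(B = B, S = S, P_true = P, markers = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a comparison configuration from a YAML file
#'
#' @param path YAML file mirroring the [run_comparison()] config list.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  yaml::read_yaml(path)
}

#' Run a multi-method deconvolution comparison
#'
#' Orchestrates the full comparison: obtain data via [load_or_simulate()],
#' run every requested method on the same gene-matched inputs, match
#' unsupervised components to the reference, evaluate each method against
#' the known proportions, and summarize. One method failing is recorded and
#' does not stop the others. Fully deterministic under a fixed config and
#' seed.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{`methods`}{character subset of
#'       `c("nnls","svr","rlm","alts","ica","linseed")`.}
#'     \item{`synthetic` / `files`}{exactly one input block; `synthetic`
#'       holds `signature` and `mixture` argument lists for
#'       [signature_design()] / [mixture_design()], `files` holds `bulk`,
#'       optional `signature`, `proportions`, `unlog`.}
#'     \item{`n_cell_types`}{required when unsupervised methods run on
#'       file input.}
#'     \item{`seed`}{integer seed (default 1).}
#'     \item{`params`}{optional named list of per-method argument lists
#'       passed to [deconvolve()].}
#'     \item{`out_dir`}{optional directory; when set, writes
#'       `summary.tsv`, `P_<method>.tsv` and `corr_<method>.tsv`.}
#'     \item{`exclude`}{cell types excluded from the mean diagonal
#'       correlation.}
#'   }
#' @return object of class `"deconv_comparison"`: list with `summary`
#'   (data frame: method, mean_diagonal_corr, mean_rmse, best flags,
#'   error), `fits`, `evaluations`, `runtimes`, `data`, `config`.
#' @export
run_comparison <- function(config) {
  all_methods <- c("nnls", "svr", "rlm", "alts", "ica", "linseed")
  methods <- config$methods %||% all_methods
  unknown <- setdiff(methods, all_methods)
  if (length(unknown))
    stop("unknown method(s) in config: ", paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  data <- load_or_simulate(config)
  n_ct <- config$n_cell_types %||%
    (if (!is.null(data$P_true)) nrow(data$P_true) else NULL)
  fits <- list(); evals <- list(); runtimes <- numeric(0)
  errors <- stats::setNames(rep(NA_character_, length(methods)), methods)
  for (met in methods) {
    args <- c(list(bulk = data$B, method = met, seed = seed),
              config$params[[met]] %||% list())
    if (met %in% c("nnls", "svr", "rlm", "alts")) {
      if (is.null(data$S)) { errors[met] <- "no signature available"; next }
      args$signature <- data$S
      args$seed <- NULL
    } else {
      if (is.null(n_ct)) { errors[met] <- "n_cell_types unknown"; next }
      args$n_cell_types <- n_ct
      if (met == "linseed") args$seed <- NULL
    }
    t0 <- proc.time()[["elapsed"]]
    fit <- tryCatch(do.call(deconvolve, args), error = function(e) e)
    runtimes[met] <- proc.time()[["elapsed"]] - t0
    if (inherits(fit, "error")) {
      errors[met] <- conditionMessage(fit)
      message(sprintf("method '%s' failed: %s", met, errors[met]))
      next
    }
    fits[[met]] <- fit
    if (!is.null(data$P_true)) {
      ev <- tryCatch(
        evaluate_deconvolution(data$P_true, fit,
                               exclude = config$exclude %||% character()),
        error = function(e) e)
      if (inherits(ev, "error")) errors[met] <- conditionMessage(ev)
      else evals[[met]] <- ev
    }
  }
  summary_df <- data.frame(
    method = methods,
    mean_diagonal_corr = vapply(methods, function(m)
      if (!is.null(evals[[m]])) evals[[m]]$mean_diagonal_corr else NA_real_,
      numeric(1)),
    mean_rmse = vapply(methods, function(m)
      if (!is.null(evals[[m]])) mean(evals[[m]]$rmse) else NA_real_,
      numeric(1)),
    error = unname(errors),
    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!is.na(summary_df$mean_diagonal_corr))) {
    summary_df$best_corr <- !is.na(summary_df$mean_diagonal_corr) &
      summary_df$mean_diagonal_corr ==
        max(summary_df$mean_diagonal_corr, na.rm = TRUE)
    summary_df$best_rmse <- !is.na(summary_df$mean_rmse) &
      summary_df$mean_rmse == min(summary_df$mean_rmse, na.rm = TRUE)
  }
  out <- structure(list(summary = summary_df, fits = fits,
                        evaluations = evals, runtimes = runtimes,
                        data = data, config = config),
                   class = "deconv_comparison")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    sdf <- summary_df
    sdf$mean_diagonal_corr <- format(sdf$mean_diagonal_corr, digits = 15)
    sdf$mean_rmse <- format(sdf$mean_rmse, digits = 15)
    utils::write.table(sdf, file.path(config$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (m in names(fits))
      write_proportions(coef(fits[[m]]),
                        file.path(config$out_dir, paste0("P_", m, ".tsv")))
    for (m in names(evals))
      write_matrix_tsv(evals[[m]]$corr_matrix,
                       file.path(config$out_dir, paste0("corr_", m, ".tsv")),
                       id_label = "cell_type")
  }
  out
}

#' @export
print.deconv_comparison <- function(x, digits = 3, ...) {
  cat("Deconvolution method comparison\n")
  df <- x$summary
  df$mean_diagonal_corr <- round(df$mean_diagonal_corr, digits)
  df$mean_rmse <- round(df$mean_rmse, digits)
  print(df)
  invisible(x)
}
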