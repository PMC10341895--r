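make_P <- function(values, types, samples = paste0("S", seq_len(ncol(values)))) {
  dimnames(values) <- list(types, samples)
  values
}

test_that("correlation matrices behave under identity, anti-correlation, and scaling", {
  set.seed(61)
  P <- renormalize_to_simplex(matrix(stats::rexp(3 * 8), 3, 8))
  dimnames(P) <- list(c("A", "B", "C"), paste0("S", 1:8))
  R <- correlation_matrix(P, P)
  expect_equal(unname(diag(R)), rep(1, 3), tolerance = 1e-12)

  # two-type row-wise complement: perfect anti-correlation on the diagonal
  P2 <- P[1:2, ] / rep(colSums(P[1:2, ]), each = 2)
  R2 <- correlation_matrix(P2, 1 - P2)
  expect_equal(unname(diag(R2)), c(-1, -1), tolerance = 1e-12)

  # linear maps leave Pearson correlation at 1
  t1 <- matrix(c(0.1, 0.2, 0.3, 0.4), 1, 4)
  expect_equal(correlation_matrix(rbind(t1, 1 - t1),
                                  rbind(2 * t1, 1 - 2 * t1))[1, 1], 1,
               tolerance = 1e-12)

  # constant rows yield 0 with a flag rather than NA
  Pc <- P; Pc[2, ] <- 0.2
  Rc <- correlation_matrix(Pc, P)
  expect_equal(unname(Rc[2, ]), rep(0, 3))
  expect_identical(attr(Rc, "constant_rows")$true, "B")

  expect_error(correlation_matrix(P[, 1:2], P[, 1:2]), "3 samples")
})

test_that("per-type RMSE follows its closed form and symmetry", {
  P <- make_P(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2), c("A", "B"))
  expect_equal(unname(rmse_per_cell_type(P, P)), c(0, 0))

  # errors (+0.1, -0.1) give 0.1; errors (0.3, 0.4) give sqrt(0.125)
  E <- make_P(matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2), c("A", "B"))
  expect_equal(unname(rmse_per_cell_type(P, E)), c(0.1, 0.1))
  a <- matrix(c(0.3, 0.7, 0.4, 0.6), 2, 2)
  b <- matrix(c(0.6, 0.4, 0.8, 0.2), 2, 2)
  expect_equal(unname(rmse_per_cell_type(a, b))[1], sqrt(0.125))
  expect_identical(rmse_per_cell_type(a, b), rmse_per_cell_type(b, a))
  expect_error(rmse_per_cell_type(a, b[1, , drop = FALSE]), "differ")
})

test_that("mean diagonal correlation supports exclusion lists", {
  R <- diag(3); dimnames(R) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(mean_diagonal_correlation(R), 1)
  R2 <- R; diag(R2) <- c(0.9, 0.5, 1.0)
  expect_equal(mean_diagonal_correlation(R2, exclude = "B"), 0.95)
  # the 17-type pattern: three weak specific subtypes excluded
  d <- c(0.58, 0.23, 0.39, rep(1, 14))
  R3 <- diag(d); dimnames(R3) <- list(paste0("T", 1:17), paste0("T", 1:17))
  expect_equal(mean_diagonal_correlation(R3, exclude = c("T1", "T2", "T3")), 1)
  expect_error(mean_diagonal_correlation(R, exclude = c("A", "B", "C")),
               "excluded")
})

test_that("bar-mixture and cell-signature tables carry the plotting data", {
  P <- make_P(matrix(c(1, 0, 0.4, 0.6), 2, 2), c("CC", "T"))
  E <- make_P(matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2), c("CC", "T"))
  tb <- bar_mixture_table(P, E)
  expect_equal(nrow(tb), 2 * 2 * 2)
  sums <- tapply(tb$proportion, interaction(tb$sample, tb$source), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # pure sample: its real rows are one-hot
  real1 <- tb[tb$sample == "S1" & tb$source == "real", ]
  expect_equal(real1$proportion[real1$cell_type == "CC"], 1)
  expect_equal(real1$proportion[real1$cell_type == "T"], 0)

  cs <- cell_signature_table(P, E, "CC")
  expect_equal(nrow(cs), 2L)
  expect_equal(attr(cs, "rmse"), sqrt(mean(c(0.1, 0.1)^2)))
  expect_equal(attr(cell_signature_table(P, P, "CC"), "rmse"), 0)
  expect_error(cell_signature_table(P, E, "X"), "unknown")

  # 12-sample series produce 12 rows
  simg <- sim_gse_like()
  cs12 <- cell_signature_table(simg$P_true, simg$P_true, "CancerCells")
  expect_equal(nrow(cs12), 12L)
})

test_that("evaluation bundles match their components and round-trip TSV", {
  sim <- sim_noiseless(seed = 67)
  fit <- deconvolve(sim$B, sim$S_true, method = "nnls")
  ev <- evaluate_deconvolution(sim$P_true, fit)
  expect_equal(ev$mean_diagonal_corr, 1, tolerance = 1e-9)
  expect_true(all(ev$rmse < 1e-9))
  expect_identical(ev$corr_matrix,
                   correlation_matrix(sim$P_true, coef(fit)))

  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ev$bar_mixture, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- utils::read.table(f, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expect_equal(back$proportion, ev$bar_mixture$proportion, tolerance = 1e-12)
})

test_that("signature refinement returns contained, truth-aligned marker sets", {
  sim <- sim_noiseless(n_genes = 300, seed = 19, c_types = 3,
                       markers_per_type = 5)
  lineage <- stats::setNames(colnames(sim$S_true), colnames(sim$S_true))
  ref <- suppressMessages(
    refine_signature(sim$B, sim$S_true, lineage))
  # containment: refined genes are a subset of the base signature's genes
  expect_true(all(unlist(ref$markers) %in% rownames(sim$S_true)))
  expect_true(sum(ref$counts) <= length(ref$shared_genes))
  # on planted truth the refined sets equal the planted sets
  for (k in names(sim$markers))
    expect_setequal(ref$markers[[k]], sim$markers[[k]])

  expect_error(refine_signature(sim$B, sim$S_true,
                                stats::setNames("X", "T1")),
               "lineage_map")
})
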