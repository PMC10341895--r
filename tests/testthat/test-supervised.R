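test_that("NNLS solves exact and renormalizes inexact systems", {
  S <- tiny_S()
  B <- expression_matrix(matrix(c(1.4, 2.2), 2, 1,
                                dimnames = list(c("g1", "g2"), "s1")))
  fit <- deconvolve(B, S, method = "nnls")
  expect_equal(unname(coef(fit)[, 1]), c(0.4, 0.6), tolerance = 1e-10)

  # inexact right-hand side: raw solution (0.46, 0.58), renormalized
  B2 <- expression_matrix(matrix(c(1.5, 2.2), 2, 1,
                                 dimnames = list(c("g1", "g2"), "s1")))
  fit2 <- deconvolve(B2, S, method = "nnls")
  expect_equal(unname(fit2$raw_coefficients[, 1]), c(0.46, 0.58),
               tolerance = 1e-10)
  expect_equal(unname(coef(fit2)[, 1]), c(0.46, 0.58) / 1.04,
               tolerance = 1e-10)

  # pure sample: bulk equal to a signature column recovers one-hot
  B3 <- expression_matrix(matrix(S[, 2], 2, 1,
                                 dimnames = list(rownames(S), "s1")))
  fit3 <- deconvolve(B3, S, method = "nnls")
  expect_equal(unname(coef(fit3)[, 1]), c(0, 1), tolerance = 1e-10)

  # rank-deficient signature warns
  Sdef <- signature_matrix(matrix(c(1, 2, 2, 4), 2, 2,
                                  dimnames = list(c("g1", "g2"), c("A", "B"))))
  expect_warning(deconvolve(B, Sdef, method = "nnls"), "rank-deficient")
})

test_that("NNLS agrees with exhaustive grid search on 2-type problems", {
  set.seed(23)
  for (i in 1:8) {
    sim <- make_dataset(
      signature_design(n_genes = 50, cell_types = c("A", "B"),
                       markers_per_type = 5, seed = 300 + i),
      mixture_design(n_samples = 1, proportion_mode = "dirichlet",
                     noise_cv = 0.1, seed = 400 + i))
    fit <- deconvolve(sim$B, sim$S_true, method = "nnls")
    # raw coefficients against the non-negative-quadrant grid oracle
    oracle_raw <- grid_search_nonneg(sim$S_true, sim$B[, 1])
    expect_lt(max(abs(fit$raw_coefficients[, 1] - oracle_raw)), 2e-4)
    # finalized proportions against the renormalized oracle
    expect_lt(max(abs(coef(fit)[, 1] - oracle_raw / sum(oracle_raw))), 2e-4)
  }
})

test_that("SVR recovers proportions and records its model selection", {
  sim <- sim_noiseless(seed = 31)
  fit <- deconvolve(sim$B, sim$S_true, method = "svr")
  expect_lt(max(abs(coef(fit) - sim$P_true)), 0.02)
  expect_true(all(fit$extras$chosen_nu %in% c(0.25, 0.5, 0.75)))
  # consistency with the NNLS baseline on the same clean input
  fn <- deconvolve(sim$B, sim$S_true, method = "nnls")
  expect_lt(max(abs(coef(fit) - coef(fn))), 0.02)

  # pure sample: argmax lands on the true type
  simg <- sim_gse_like(noise_cv = 0)
  fitg <- deconvolve(simg$B, simg$S_true, method = "svr")
  expect_equal(unname(which.max(coef(fitg)[, 1])), 1L)
  expect_equal(unname(which.max(coef(fitg)[, 2])), 1L)
})

test_that("mRNA-abundance scaling factors solve the bounded ratio problem", {
  P_true <- renormalize_to_simplex(matrix(stats::rexp(8), 4, 2))
  rownames(P_true) <- paste0("T", 1:4)

  # estimates exactly 2x truth: alpha = 0.5
  sc <- fit_mrna_scaling(2 * P_true, P_true)
  expect_equal(unname(sc$alpha), rep(0.5, 4))
  # identity
  expect_equal(unname(fit_mrna_scaling(P_true, P_true)$alpha), rep(1, 4))
  # bound clipping
  sc2 <- fit_mrna_scaling(20 * P_true, P_true, bounds = c(0.1, 10))
  expect_equal(unname(sc2$alpha), rep(0.1, 4))
  # all-zero estimates: flagged, alpha = 1
  Pz <- P_true; Pz[2, ] <- 0
  expect_warning(sc3 <- fit_mrna_scaling(Pz, P_true), "undefined")
  expect_equal(unname(sc3$alpha[2]), 1)
  expect_true(sc3$undefined[2])
})

test_that("robust regression matches truth on clean data and resists outliers", {
  sim <- sim_noiseless(seed = 37)
  fit <- deconvolve(sim$B, sim$S_true, method = "rlm")
  expect_lt(max(abs(coef(fit) - sim$P_true)), 1e-6)

  # unit scaling factors leave the fit unchanged
  ones <- stats::setNames(rep(1, 5), colnames(sim$S_true))
  fit1 <- deconvolve(sim$B, sim$S_true, method = "rlm", alphas = ones)
  expect_equal(coef(fit1), coef(fit))

  # one gene inflated 100x: robust fit beats ordinary least squares
  sim2 <- sim_noiseless(n_genes = 200, seed = 43)
  B2 <- sim2$B
  B2[7, ] <- B2[7, ] * 100
  fr <- deconvolve(B2, sim2$S_true, method = "rlm")
  fo <- deconvmix:::.deconv_ols(B2, sim2$S_true)
  err_r <- sqrt(sum((coef(fr) - sim2$P_true)^2))
  err_o <- sqrt(sum((fo$P - sim2$P_true)^2))
  expect_lt(err_r, err_o)
})

test_that("adaptive trimming flags contaminated genes and matches NNLS when inert", {
  sim <- sim_noiseless(n_genes = 200, seed = 9)
  # clean data: no flags, identical to the NNLS baseline
  fit <- deconvolve(sim$B, sim$S_true, method = "alts")
  expect_true(all(lengths(fit$extras$outlier_flags) == 0))
  fn <- deconvolve(sim$B, sim$S_true, method = "nnls")
  expect_equal(coef(fit), coef(fn), tolerance = 1e-12)

  # 5% of genes inflated 50x: all contaminated genes flagged, near-exact fit
  B2 <- sim$B
  set.seed(99)
  bad <- sample(nrow(B2), 10)
  B2[bad, ] <- B2[bad, ] * 50
  fit2 <- deconvolve(B2, sim$S_true, method = "alts")
  for (fl in fit2$extras$outlier_flags)
    expect_true(all(rownames(B2)[bad] %in% fl))
  expect_lt(max(abs(coef(fit2) - sim$P_true)), 1e-3)

  # infinite multiplier never flags: identical to NNLS
  fit3 <- deconvolve(B2, sim$S_true, method = "alts", alts_multiplier = Inf)
  fn2 <- deconvolve(B2, sim$S_true, method = "nnls")
  expect_equal(coef(fit3), coef(fn2), tolerance = 1e-12)
  expect_true(all(lengths(fit3$extras$outlier_flags) == 0))
})

test_that("all supervised methods return simplex-valid proportions under noise", {
  sim <- make_dataset(
    signature_design(n_genes = 150, seed = 51),
    mixture_design(proportion_mode = "dirichlet", noise_cv = 0.2, seed = 51))
  for (m in c("nnls", "svr", "rlm", "alts")) {
    fit <- suppressWarnings(deconvolve(sim$B, sim$S_true, method = m))
    expect_simplex(coef(fit))
  }
})

test_that("fit accessors expose reconstruction and residuals", {
  sim <- sim_noiseless(n_genes = 60, seed = 3)
  fit <- deconvolve(sim$B, sim$S_true, method = "nnls")
  expect_lt(max(abs(fitted(fit) - sim$B)), 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  s <- summary(fit)
  expect_s3_class(s, "summary.deconv")
  expect_equal(s$n_components, 5)
})
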