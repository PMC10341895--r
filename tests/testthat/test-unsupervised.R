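test_that("ICA separates independent skewed sources", {
  set.seed(42)
  src <- cbind(stats::rexp(5000), stats::rexp(5000))
  A0 <- matrix(stats::runif(6, 0.2, 1), 2, 3)
  X <- src %*% A0
  dimnames(X) <- list(paste0("g", 1:5000), paste0("S", 1:3))
  d <- ica_deconvolve(X, 2, seed = 5)
  r <- abs(stats::cor(d$S_est, src))
  # each component matches exactly one source
  expect_true(all(apply(r, 1, max) >= 0.95))
  expect_true(all(apply(r, 2, max) >= 0.95))

  # determinism under fixed seed
  d2 <- ica_deconvolve(X, 2, seed = 5)
  expect_identical(d$S_est, d2$S_est)
  expect_identical(d$P, d2$P)

  # positive-skewness orientation
  expect_true(all(d$skewness > 0))
})

test_that("ICA warns on unidentifiable near-Gaussian data", {
  set.seed(7)
  X <- matrix(abs(stats::rnorm(2000 * 8, 100, 1)), 2000, 8,
              dimnames = list(paste0("g", 1:2000), paste0("S", 1:8)))
  expect_warning(ica_deconvolve(X, 3, seed = 1), "Gaussian")
  expect_error(ica_deconvolve(X, 8, seed = 1), "smaller")
  expect_error(ica_deconvolve(X, 1, seed = 1), "at least 2")
})

test_that("mutual linearity scores proportional genes 1 and orthogonal genes 0", {
  B <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8),
             g3 = c(2, 0, 2, 0) + 3)
  colnames(B) <- paste0("S", 1:4)
  ml <- mutual_linearity(B, top_n_genes = 3, top_k_edges = 1)
  expect_equal(ml$r2["g1", "g2"], 1, tolerance = 1e-12)
  # orthogonal construction: zero correlation
  B2 <- rbind(g1 = c(1, 1, -1, -1) + 5, g2 = c(1, -1, 1, -1) + 5)
  colnames(B2) <- paste0("S", 1:4)
  ml2 <- mutual_linearity(B2, top_n_genes = 2, top_k_edges = 1)
  expect_equal(ml2$r2["g1", "g2"], 0, tolerance = 1e-12)

  # planted blocks, noiseless: within-block pair scores are 1
  sim <- sim_noiseless(n_genes = 100, seed = 13, c_types = 3,
                       markers_per_type = 5)
  ml3 <- suppressMessages(mutual_linearity(sim$B, top_k_edges = 4))
  for (k in 1:3) {
    mk <- sim$markers[[k]]
    expect_true(all(abs(ml3$r2[mk, mk][upper.tri(diag(5))] - 1) < 1e-9))
    # top-4 edges of each marker are its 4 block partners
    expect_true(all(abs(ml3$score[mk] - 4) < 1e-9))
  }
  expect_true(length(ml3$excluded_constant) > 0)

  expect_error(mutual_linearity(sim$B[, 1:2]), "3 samples")
})

test_that("simplex-corner search recovers planted markers exactly", {
  sim <- sim_noiseless(n_genes = 300, seed = 19, c_types = 3,
                       markers_per_type = 5)
  fit <- suppressMessages(linseed_deconvolve(sim$B, 3))
  found <- lapply(fit$marker_sets, sort)
  planted <- lapply(sim$markers, sort)
  # each corner's marker set equals one planted set (precision = recall = 1)
  matched <- vapply(found, function(f)
    any(vapply(planted, identical, logical(1), y = f)), logical(1))
  expect_true(all(matched))
  expect_equal(anyDuplicated(unlist(found)), 0L)

  # matched proportion rows correlate essentially perfectly
  a <- assign_components(fit$P, sim$P_true)
  expect_true(all(a$correlations >= 0.999))
})

test_that("corner search agrees with exhaustive extreme-point search (c = 2)", {
  sim <- make_dataset(
    signature_design(n_genes = 40, cell_types = c("A", "B"),
                     markers_per_type = 4, seed = 8),
    mixture_design(n_samples = 6, proportion_mode = "dirichlet",
                   noise_cv = 0, seed = 8))
  fit <- suppressMessages(
    linseed_deconvolve(sim$B, 2, collinearity_quantile = 0))
  coords <- fit$coords
  # oracle: the two extreme points of a 1-simplex are the farthest pair
  D <- as.matrix(stats::dist(coords))
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  oracle <- coords[far, , drop = FALSE]
  for (k in 1:2) {
    d2 <- min(colSums((t(oracle) - fit$corner_coords[k, ])^2))
    expect_lt(d2, 1e-18)
  }
})

test_that("simplex-corner estimates are scale-invariant and sample-equivariant", {
  sim <- make_dataset(
    signature_design(n_genes = 300, cell_types = paste0("T", 1:3),
                     markers_per_type = 5, seed = 5),
    mixture_design(proportion_mode = "dirichlet", noise_cv = 0.05, seed = 5))
  f1 <- suppressMessages(linseed_deconvolve(sim$B, 3))
  f2 <- suppressMessages(linseed_deconvolve(sim$B * 7.3, 3))
  expect_identical(f1$marker_sets, f2$marker_sets)
  expect_equal(f1$H_norm, f2$H_norm, tolerance = 1e-12)
  expect_equal(f1$P, f2$P, tolerance = 1e-12, ignore_attr = TRUE)

  perm <- c(4, 1, 12, 3, 7, 2, 10, 9, 5, 11, 8, 6)
  f3 <- suppressMessages(linseed_deconvolve(sim$B[, perm], 3))
  expect_equal(f1$P[, perm], f3$P, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("unsupervised fits return simplex-valid proportions", {
  sim <- make_dataset(
    signature_design(n_genes = 200, seed = 29),
    mixture_design(proportion_mode = "dirichlet", noise_cv = 0.1, seed = 29))
  for (m in c("ica", "linseed")) {
    fit <- suppressMessages(
      deconvolve(sim$B, method = m, n_cell_types = 5, seed = 2))
    expect_simplex(coef(fit))
  }
})

test_that("component assignment recovers permutations and flags noise", {
  P <- renormalize_to_simplex(matrix(stats::rexp(3 * 10), 3, 10))
  dimnames(P) <- list(c("A", "B", "C"), paste0("S", 1:10))
  # identity
  a0 <- assign_components(P, P)
  expect_identical(unname(a0$mapping), c("A", "B", "C"))
  # row swap is inverted
  Psw <- P[c(2, 3, 1), ]
  rownames(Psw) <- c("C1", "C2", "C3")
  a1 <- assign_components(Psw, P)
  expect_identical(unname(a1$mapping), c("B", "C", "A"))
  expect_equal(a1$relabeled, P, ignore_attr = TRUE)
  # a pure-noise component gets the leftover label with low confidence
  set.seed(55)
  Pn <- P
  Pn[3, ] <- renormalize_to_simplex(matrix(stats::runif(10), 1, 10))
  rownames(Pn) <- c("C1", "C2", "C3")
  a2 <- assign_components(Pn, P)
  expect_identical(unname(a2$mapping[1:2]), c("A", "B"))
  expect_true(a2$low_confidence["C3"])
})
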