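# Fixtures are built in code so tests stay self-contained.

# Tiny two-type signature used for hand-verifiable solves.
tiny_S <- function() {
  signature_matrix(matrix(c(2, 1, 1, 3), 2, 2,
                          dimnames = list(c("g1", "g2"), c("A", "B"))))
}

# Standard noiseless five-type marker-block dataset.
sim_noiseless <- function(n_genes = 300, seed = 5, c_types = 5,
                          markers_per_type = 10) {
  make_dataset(
    signature_design(n_genes = n_genes,
                     cell_types = paste0("T", seq_len(c_types)),
                     markers_per_type = markers_per_type, seed = seed),
    mixture_design(proportion_mode = "dirichlet", noise_cv = 0, seed = seed))
}

# Cancer/immune spike-in style dataset (two pure cancer samples).
sim_gse_like <- function(noise_cv = 0.05, seed = 11) {
  make_dataset(
    signature_design(n_genes = 400, cell_types = gse64385_cell_types(),
                     markers_per_type = 10, seed = seed),
    mixture_design(proportion_mode = "gse64385_like", noise_cv = noise_cv,
                   seed = seed))
}

# Independent grid-search oracles for two-type problems.
#
# Simplex grid: minimizes ||S p - b|| over p = (t, 1 - t), t on a regular
# grid (the constrained estimator; equals the truth on noiseless data).
grid_search_simplex <- function(S, b, step = 1e-4) {
  t_grid <- seq(0, 1, by = step)
  d <- S[, 1] - S[, 2]
  e <- S[, 2]
  obj <- sum(d^2) * t_grid^2 + 2 * sum(d * (e - b)) * t_grid
  t_best <- t_grid[which.min(obj)]
  c(t_best, 1 - t_best)
}

# Non-negative quadrant grid: minimizes ||S p - b||^2 over p1, p2 >= 0 on a
# regular grid — the same objective NNLS solves. The result is identical to
# full 2-D enumeration: for fixed p1 the objective is a convex parabola in
# p2, so its minimum over the p2 grid is attained at a grid neighbor of the
# clamped vertex, which is evaluated directly.
grid_search_nonneg <- function(S, b, step = 1e-4, p_max = 2) {
  g11 <- sum(S[, 1]^2); g22 <- sum(S[, 2]^2); g12 <- sum(S[, 1] * S[, 2])
  c1 <- sum(S[, 1] * b); c2 <- sum(S[, 2] * b)
  p1 <- seq(0, p_max, by = step)
  # vertex of the parabola in p2 for each p1, clamped to the grid range
  v <- pmin(pmax((c2 - g12 * p1) / g22, 0), p_max)
  lo <- floor(v / step) * step
  hi <- pmin(lo + step, p_max)
  obj <- function(p2) g11 * p1^2 + g22 * p2^2 + 2 * g12 * p1 * p2 -
    2 * c1 * p1 - 2 * c2 * p2
  o_lo <- obj(lo); o_hi <- obj(hi)
  p2 <- ifelse(o_lo <= o_hi, lo, hi)
  o <- pmin(o_lo, o_hi)
  i <- which.min(o)
  c(p1[i], p2[i])
}

expect_simplex <- function(P, tol = 1e-9) {
  v <- validate_proportions(P, tol = tol)
  expect_true(v$ok, info = paste(v$violations$message, collapse = "; "))
}
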