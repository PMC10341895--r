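---
title: "Cell-mixture deconvolution: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-mixture deconvolution: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconvmix)
```

## The linear mixing model

A bulk expression profile is modeled as a weighted sum of cell-type
profiles:

$$B_{n \times m} = S_{n \times c} \, P_{c \times m},$$

where $B$ is the observed bulk (genes × samples), $S$ the signature matrix
(expected expression of each gene in each purified cell type), and $P$ the
proportion matrix. Each sample column of $P$ lies on the probability
simplex: $0 \le p_{kj} \le 1$ and $\sum_k p_{kj} = 1$. Equivalently, per
gene $i$ and sample $j$,
$b_{ij} = \sum_{k=1}^{c} s_{ik}\, p_{kj} + \varepsilon_{ij}$.

Two assumptions matter in practice. First, mixing is only linear in
**linear-scale** (anti-log) expression, so the whole package works in linear
scale; the readers expose an `unlog` switch (`2^x`) because public matrices
are often distributed in log2 units and rarely say so. Second, the model
assumes the signature describes the cell types actually present; a cell
type in the mixture but absent from $S$ (for instance tumor cells against
an immune-only signature) surfaces as structured residual that supervised
methods silently redistribute — one motivation for the unsupervised
estimators.

Estimated coefficient vectors are not automatically on the simplex. All six
methods share one finalization rule: negative coefficients are truncated to
zero and each sample column is divided by its sum (an all-zero column
becomes uniform $1/c$ and is flagged). Keeping finalization identical makes
the methods differ only in their estimation core, which is what a
comparison should measure.

## Supervised estimators

**Non-negative least squares** (`nnls`). Per sample, minimize
$\lVert S p - b \rVert_2$ subject to $p \ge 0$ (Lawson–Hanson active set,
via `pracma::lsqnonneg`). This is the natural baseline: exact on noiseless
data, and the reference the trimmed estimator reduces to.

**ν-support-vector regression** (`svr`). Per sample, a linear ν-SVR is fit
regressing the mixture on the signature columns; the proportion estimate is
the primal weight vector. The ε-insensitive loss ignores small residuals,
so genes with modest deviations do not pull the fit — the support vectors
are effectively the informative marker genes. Two choices are deliberate:

* *Standardization is global, not per gene.* The signature is z-scored with
  one mean and standard deviation over all its entries, and each mixture
  column with its own. Per-gene scaling (dividing each gene row by its own
  spread) is attractive but destroys identifiability on marker-block
  signatures: all marker rows of a type collapse to the same pattern, the
  intercept absorbs the overall level, and the minimum-norm solution is the
  true proportion vector minus its mean — wrong after truncation. Global
  scaling preserves relative row magnitudes, and the flat background genes
  pin the level, so the weight vector is unique.
* *Model selection.* ν controls the fraction of support vectors; it is
  chosen per sample from `nu_grid = c(0.25, 0.5, 0.75)` by minimizing the
  root-mean-square deviation between the reconstructed and observed mixture
  (computed on the standardized scale with negative weights truncated).
  The cost constant `C` defaults to 1.

**Robust linear regression** (`rlm`). Per sample, iteratively reweighted
least squares with Huber weights, tuning constant 1.345 (95% efficiency at
the Gaussian), up to 50 iterations at tolerance $10^{-8}$ (via
`MASS::rlm`). Optionally, the signature columns are first multiplied by
per-cell-type **mRNA-abundance factors** $\hat\alpha_k$: cell types differ
in total mRNA content, so equal *cell* fractions do not produce equal
*RNA* fractions. `fit_mrna_scaling()` fits
$\hat\alpha_k = \arg\min_{\alpha \in [l,u]} \sum_j (\alpha \hat p_{kj} - p_{kj})^2$
(closed-form ratio, clipped to bounds, default $[0.1, 10]$) — but this
requires samples with *known* proportions, so it is an explicit calibration
utility and is never applied silently. A cell type with all-zero estimates
has no defined ratio; it is flagged and assigned $\alpha = 1$.

**Adaptive least trimmed squares** (`alts`). The model is augmented with a
per-gene outlier term: genes whose squared residual exceeds
`multiplier × median(squared residuals)` (multiplier default 10) are
flagged and the NNLS fit is repeated without them, until the flag set is
stable. Two numerical guards:

* *Zero-median floor.* On (near-)noiseless data the median squared residual
  is floating-point dust ($\sim 10^{-30}$), and any multiple of it flags
  half the genes; the threshold is therefore floored at an absolute
  $10^{-10}$, so an exactly-fitting sample flags nothing and the estimator
  reduces to NNLS (as it should; with `multiplier = Inf` this holds on any
  data).
* *Incremental trimming schedule.* A fit still contaminated by heavy
  outliers misfits clean genes too. Flagging everything above threshold in
  one pass can remove all markers of a cell type and settle into a stable
  wrong state (the type becomes unidentifiable, the remaining genes fit
  perfectly, the flagged ones never return). Instead, at most
  $\lceil n \cdot \min(0.5,\, 0.05\,t) \rceil$ worst-residual genes are
  trimmed at pass $t$, so the extreme tail goes first and the fit
  re-concentrates before milder residuals are judged. If more than half
  the genes ever exceed the threshold the sample is declared too
  contaminated and the fit aborts with an error.

## Unsupervised estimators

**Independent component analysis** (`ica`). Treating each sample as an
observed mixture over the gene dimension, the bulk is centered per sample,
whitened to $c$ dimensions, and unmixed by the symmetric fixed-point
algorithm with the logcosh contrast (max 1000 iterations, tolerance
$10^{-6}$; random orthogonal initialization controlled by `seed`).
Marker-block structure makes the gene-loading components strongly
right-skewed, which resolves ICA's sign indeterminacy: each component is
oriented to positive loading skewness, after which the rows of the mixing
matrix track the proportion rows and are truncated/renormalized into
proportions. ICA is identifiable only for non-Gaussian sources; if all
recovered loadings are near-Gaussian (|skewness| < 0.1 and |excess
kurtosis| < 0.5) a warning states that the decomposition is not
identifiable. Per-component scale remains indeterminate: the finalization
maps mixing weights to the simplex exactly only when components carry
comparable signal, which is one reason ICA tracks *relative* composition
better than absolute levels.

**Simplex-corner search** (`linseed`). Genes expressed by a single cell
type are *mutually linear*: their profiles across samples are proportional,
with squared Pearson correlation 1. The estimator:

1. scores gene pairs by squared correlation and each gene by the sum of its
   `top_k_edges = 10` strongest edges, over the `top_n_genes = 2000` most
   expressed genes (the pairwise computation is quadratic, which is why a
   filter exists at all); genes at or above the
   `collinearity_quantile = 0.9` score quantile are kept, with a floor of
   $10c$ top-scoring genes so small problems are never filtered below a
   working pool;
2. subtracts each gene's across-sample minimum. This baseline correction
   treats the minimum as the gene's non-specific (shared) signal; what
   remains is attributable to a single type. It is what lets a marker with
   non-zero background still sit *on* the simplex spanned by the proportion
   rows, and it is why a cell type absent from some samples (e.g. immune
   cells in pure-tumor samples) is recovered at zero there. Rows with
   essentially no corrected signal are dropped with a message;
3. row-normalizes the kept genes — each gene becomes a point in
   $m$-dimensional sample space, a convex combination of the (normalized)
   proportion rows — and projects the points onto the top-$c$ right
   singular vectors;
4. finds the $c$ corners by successive projection: take the point farthest
   from the origin, deflate its direction, repeat. This is deterministic
   and checkable against exhaustive extreme-point search on small cases;
   duplicate corners (distance < $10^{-9}$) raise an error suggesting a
   smaller $c$;
5. defines each corner's marker set as the genes within the
   `marker_distance_quantile = 0.05` of distances to it (at least
   `min_markers = 3`);
6. estimates the normalized proportion row of each type as the mean
   profile of its marker set (more stable than the single corner gene under
   noise, identical without noise); and
7. undoes the row normalization by weighting each type's row with its
   total marker signal — markers are the only genes attributable to one
   type, so their summed expression is the natural estimate of that type's
   overall signal — and renormalizes sample columns to the simplex.

The whole estimate is invariant to positive rescaling of the bulk and
equivariant under sample permutation. The absolute scale of the recovered
proportions inherits a bias from step 2: what is estimated is proportional
to $p_{kj} - \min_j p_{kj}$, which compresses types that are never absent
(visible as a high RMSE for the always-present type despite near-perfect
correlation). This trade — absolute scale for robustness to unknown cell
types — is intrinsic to the unsupervised setting.

**Component labeling.** Unsupervised output rows are arbitrary.
`assign_components()` matches them to reference rows by the one-to-one
assignment maximizing total Pearson correlation, solved exactly by
permutation enumeration (component counts here are ≤ 8; ties broken by
lexical order), flagging matches with $r < 0.5$ as low-confidence.
Constant rows contribute correlation 0 rather than an error, so a type
absent everywhere cannot crash reporting.

## The synthetic-data generator

`make_dataset()` realizes the statistical structure the estimators assume,
with known ground truth:

* **Signature**: each of $c$ cell types owns `markers_per_type` marker
  genes at `background_level × marker_fold` in their own column and
  `background_level` elsewhere; all other genes are flat background.
  Defaults (`marker_fold = 10`, `background_level = 5`,
  `markers_per_type = 10`) reflect strong, microarray-scale marker
  enrichment. `spillover` adds a fraction of each marker's above-background
  signal to one other seed-chosen type — the signature-overlap phenomenon
  that plagues closely related cell populations.
* **Proportions**: symmetric Dirichlet columns (`dirichlet_alpha = 1`,
  uninformative over the simplex), explicit matrices, or the
  `"gse64385_like"` spike-in design: 12 samples over six types (cancer
  first), samples 1–2 pure cancer, samples 3–12 with the cancer fraction
  drawn from {0.3, 0.4, 0.5} and the remainder split over the five immune
  types by Dirichlet(1) — the published design states only the cancer
  fractions, so the immune split is left free.
* **Noise**: multiplicative log-normal with unit mean, parameterized by its
  coefficient of variation (`noise_cv`, default 0.05); expression noise
  scales with signal, which is why additive Gaussian noise is deliberately
  not the default. `noise_cv = 0` gives the exact product $S P$.

What the generator does **not** emulate: count sampling (shot noise at low
expression), probe-level artifacts and batch effects, correlated noise
across genes, continuous signature variation within a cell type, or
platform mismatch between signature and bulk. Passing the packaged tests
therefore demonstrates correctness of the estimators under the linear
mixing model with multiplicative noise — not performance on any real
dataset, where signature mismatch is usually the dominant error source.

## Numerical conventions and edge cases

* Truncate-then-renormalize is the uniform negativity rule; it is applied
  after, never inside, each method's core.
* "Constant" rows are detected relative to scale
  ($\mathrm{sd} \le 10^{-10}\,|\mathrm{mean}|$): on simplex-exact data a
  flat gene's values differ by rounding only.
* Proportion columns are validated to sum to 1 within $10^{-9}$ in strict
  mode; raw mode (entries in $[0,1]$ only) exists for intermediate
  estimates.
* Gene matching keeps bulk row order (deterministic), warns when fewer than
  half of the signature genes are found, and fails hard at zero overlap.
* Duplicate gene rows in input tables are collapsed by mean, the common
  microarray convention; whether input is log-scale cannot be detected
  reliably, so it is the caller's declaration (`unlog`).
* TSV is the canonical dialect (matching how reference signatures are
  distributed); writes use full double precision so round trips are
  value-identical well below $10^{-12}$.
* Every stochastic step (signature spillover targets, proportion draws,
  noise, ICA initialization) takes an explicit seed and restores the
  caller's RNG state, so pipeline runs are reproducible end to end —
  `run_comparison()` with a fixed config and seed writes byte-identical
  tables.

## Signature refinement

`refine_signature()` combines the two routes: the bulk is restricted to the
genes shared with a reference signature, subtype columns are collapsed to
major types by a user-supplied lineage map (published signatures resolve
finer subtypes than corner search should be asked for), the simplex-corner
estimator runs on the shared genes, and each corner is assigned to the
major type whose top signature genes overlap its marker set most (exact
bipartite matching; a corner overlapping nothing is reported as an error
with its genes listed). The refined per-type lists are corner marker sets,
hence by construction subsets of the reference signature's genes. The
result is a compact, data-supported signature — typically far fewer genes
per type than the reference carries.

## Problem sizes in the packaged checks

The test suite exercises the estimators at a few hundred genes, 12 samples,
and 2–6 cell types, with noise CVs from 0 to 0.2 and replicated-seed
averages where a monotonicity claim is tested; these sizes keep the full
suite fast while leaving every estimator's geometry intact (all methods are
per-sample or low-rank, so gene count beyond a few hundred changes cost,
not behavior).

## Limitations

* Supervised accuracy is bounded by signature quality and platform match;
  nothing in the package corrects batch or platform effects.
* The number of cell types $c$ is an input everywhere; no model-selection
  criterion for $c$ is provided.
* ICA proportions are relative by nature (per-component scale is
  unidentifiable); interpret levels with care.
* The corner-search baseline correction compresses the absolute scale of
  types present in every sample (see above).
* `fit_mrna_scaling()` needs experimentally known proportions; without
  calibration data the `rlm` route runs unscaled.
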