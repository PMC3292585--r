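---
title: "Reference-based sparse component analysis: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based sparse component analysis: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refsca)
```

## The mixture model of a sample

`refsca` treats every omics sample (a baseline-corrected mass spectrum over
K m/z ratios, or an expression profile over K genes) as an additive mixture
of a small number of components: groups of features that share a relative
concentration profile. Rather than factorizing the whole N×K dataset at
once, each test sample is paired with a **reference sample** — the
feature-wise average of the control group, and separately of the disease
group — to form a 2×K linear mixture model

$$\begin{bmatrix} \mathbf{x}_{\mathrm{ref}} \\ \mathbf{x} \end{bmatrix}
 = \mathbf{A}\,\mathbf{S}, \qquad
 \mathbf{A} \in \mathbb{R}_+^{2\times M},\;
 \mathbf{S} \in \mathbb{R}^{M\times K},\; M \in \{2,\dots,5\}.$$

Columns of **A** are constrained to unit ℓ2-norm (blind decompositions are
scale-indeterminate), so each column is fully described by its **mixing
angle** from the reference axis, `atan2(test coordinate, reference
coordinate)` ∈ [0°, 90°]. The working assumption is that disease-specific
features are present in prevailing concentration in disease samples and in
minor concentration in controls, and vice versa; features expressed
similarly in both classes form neutral components. Because decomposition is
local (per sample), a feature may be strongly expressed in one sample and
weakly in another yet still be allocated to the disease-specific component
of each — the thresholds are the sample's own mixing angles, not a
dataset-wide cutoff.

With a control reference, the component confining the **maximal** angle is
selected as disease-specific and the minimal-angle one as control-specific;
with a disease reference the logic is the opposite. For M = 2 no neutral
component is postulated; for M ∈ {3, 4, 5} the extra components absorb
features that do not vary across the population, making the selected
components sparser (the parsimony argument for larger M). Selection reads
only angles, never labels, which is what makes the four extracted sets —
disease- and control-specific components under each reference — usable as
classifier features.

## Two-stage decomposition

**Stage 1: mixing estimation from single-component points.** For M ≥ 3 the
2×K system is underdetermined, so recovery leans on sparseness: each feature
is assumed to belong to at most two components. At feature points where only
one component is active the observed 2-vector is collinear with one mixing
column. Such points are detected through the analytic continuation
$\tilde{\mathbf{x}} = \mathbf{x} + i\,H(\mathbf{x})$ (FFT construction:
positive frequencies doubled, negative zeroed, DC and Nyquist kept): feature
k is kept as a single-component point (SCP) when

$$\frac{\left|R(\tilde{\mathbf{x}}_k)^\top I(\tilde{\mathbf{x}}_k)\right|}
       {\lVert R(\tilde{\mathbf{x}}_k)\rVert_2\,
        \lVert I(\tilde{\mathbf{x}}_k)\rVert_2} \ge \cos(\Delta\theta).$$

The absolute value implements the requirement that real and imaginary parts
point in the same **or opposite** direction (0 or π); the printed form of
the criterion is ambiguous on this, and the directional reading is the one
consistent with the surrounding text. Δθ (degrees; grid {1, 3, 5}) trades
SCP purity against coverage and is a cross-validated parameter. Flat
features (zero-norm 2-vectors) are excluded silently.

The SCP 2-vectors are normalized, mapped to a common half-plane (sign flip
when the dominant coordinate is negative), and clustered by
**complete-linkage hierarchical clustering under cosine distance** into
exactly M clusters. Cluster centroids — arithmetic means clipped to the
non-negative quadrant and renormalized — are the mixing columns.
Hierarchical clustering is preferred over k-means because it is
deterministic: the same SCP set always yields the same mixing matrix
(k-means is available behind a flag for comparison). Centroid clipping is
the minimal projection onto the model's non-negative domain when
baseline-corrected spectra produce slightly negative coordinates.

Two numerical choices here deserve explanation:

* **SCP cap** (`max_scps`, default 500). The Hilbert transform is global, so
  on realistic data only a minority of features pass the criterion — but on
  idealized inputs nearly every feature can qualify, and complete-linkage
  clustering is quadratic in the number of points. Above the cap a
  deterministic subsample evenly spaced in angle rank is clustered instead.
  Because cluster members are near-collinear by construction, centroids are
  essentially unchanged; the cap bounds the cost of the ~10⁴ decompositions
  a cross-validation run performs.
* **Degenerate direction sets.** When the SCP directions span fewer than M
  distinct directions (common at M = 5 with Δθ = 1°: some components simply
  have no pure points in a given sample), two cluster centroids may
  coincide. This is tolerated — the extremal angles that drive selection are
  unaffected, and an extremum tie is broken toward the lowest column index
  with a warning. Only the truly degenerate case, all SCP vectors on a
  single direction, raises an error, since then no angular ordering exists
  at all.

**Stage 2: sparse source recovery.** With **A** fixed, all K columns of
**S** are estimated jointly by accelerated iterative shrinkage-thresholding
applied to

$$\min_{\mathbf{S}} \tfrac12 \lVert \mathbf{A}\mathbf{S} - \mathbf{X}
\rVert_F^2 + \lambda \lVert \mathbf{S} \rVert_1,
\qquad (\text{optionally } \mathbf{S} \ge 0),$$

with step 1/L (L the largest eigenvalue of AᵀA), per-iteration
soft-thresholding at λ/L — composed with projection onto the non-negative
orthant for gene-expression data — momentum acceleration, and a monotone
restart when the objective rises for ten consecutive iterations. λ is
specified relative to λ_max = max|AᵀX| (the smallest penalty for which
S = 0 is optimal), computed **per decomposition**, with the grid
{1e-2, 1e-4, 1e-6}·λ_max; the same multiplier is applied to each of a test
sample's two mixture models against its own λ_max. The two-stage scheme is
deliberate: because **A** is frozen during the S-step, the solver cannot
drift to an alternative, less sparse factorization.

Stopping and zeroing: iterations end at `max_iter` (default 1000) or when
the relative objective change drops below `tol` (default 1e-6); entries
smaller than `hard_zero_tol` (default 1e-10·λ_max) are snapped to exact
zero on exit. The 1e-6 tolerance marks convergence of the data-fidelity
term. Beyond it the iterates redistribute mass within the null space of the
rank-2 system at objective changes that alter component entries only at
numerically irrelevant scales — it multiplies runtime several-fold without
affecting selection or classification. When exact optima are needed (the
oracle-equivalence tests compare final objectives at 1e-6 absolute
tolerance), a tight configuration (`max_iter = 5000+, tol ≤ 1e-12`) is
passed explicitly; at such settings the solver matches an independent
duality-gap-certified coordinate-descent solver and, in the non-negative
case, an exact active-set enumeration. Note that at the smallest penalty
(1e-6·λ_max) exact support identification is a slow process for any
first-order method; the defaults recover the fidelity-converged solution,
which is what classification consumes.

## Cross-validation protocol

Performance is estimated by repeated **stratified** two-fold
cross-validation: each repetition splits the data 50/50 per class (the
stratification keeps fold class ratios within one sample — unstratified
splits can produce single-class folds on small data), and each half serves
once as training and once as test set. Extracted components are
standardized to zero mean and unit variance **across features** (per
extracted vector, the standardization direction that works markedly better
for this family of data), then classified with SVMs at C = 1; only kernel
hyper-parameters are searched (RBF variance 500–1500 by 100, polynomial
degree 2–4).

Two modes are provided because the protocol admits two readings:

* `mode = "nested"` (default): a single stratified two-fold split of the
  training half selects the configuration (M, Δθ, λ multiplier, kernel,
  component set) with the best inner accuracy; the winner is refit on the
  full training half and evaluated on the held-out half. This is the
  cheapest faithful nested protocol for hyper-parameter selection.
* `mode = "sweep"`: every configuration is evaluated on every fold and the
  best cell is reported, the analogue of a full parameter-sweep
  supplementary table. This is also the natural mode for validation studies
  in which parameters are fixed by design rather than cross-validated.

Reported numbers are the mean and standard deviation of sensitivity,
specificity and accuracy over all 2×n evaluations (evaluation-level, not
pooled counts). All randomness flows from one seed, with per-repetition
child seeds, so reports are byte-reproducible.

**Reference policy.** The protocol's literal description averages *all*
samples of a class into the reference, which leaks test-fold information
into the features. Both policies are implemented:
`reference_policy = "all"` reproduces the literal description (and is the
default of the plain fitting function, where no fold structure exists);
inside cross-validation the default is `"train_only"`, which rebuilds
references from the training fold exclusively — perturbing a test-fold
sample then provably changes neither references nor the trained classifier.
Training samples do contribute to their own reference average; no
self-exclusion is performed. A gold-standard labelled sample could replace
the average where expert knowledge exists; no procedure for choosing one is
offered.

## The simulator

`simulate_mixture()` reproduces the validation model: `n_true` = 10
orthogonal components over K = 15000 features (disjoint contiguous supports
of near-equal size; a shuffled partition is available), with component 1
disease-specific, the last control-specific and the rest neutral. Disease
samples are $\sum_m \sin^2(\theta_{nm})\,\mathbf{s}_m$ and control samples
$\sum_m \cos^2(\theta_{nm})\,\mathbf{s}_m$, so each component is split
between the two rules at an overall concentration of exactly 100%. Angles
are drawn independently per sample and per component, uniform over the
role's sector — by default [50, 89.99]° (disease), [25, 65]° (neutral),
[0.01, 40]° (control), a deliberately overlapping layout in which neutral
features frequently out-concentrate specific ones. The uniform law and the
independence across samples are the simplest choices consistent with
"concentration varies across the population"; the amplitude law on supports,
Uniform[0.5, 1.5], is likewise a choice of convenience (positive features of
comparable scale) — neither is dictated by the model.

What the simulator does **not** emulate: mass-spectrum peak shapes,
baselines, chemical noise, heteroscedastic intensity noise, or correlated
features within a component. Passing tests on simulated data therefore
demonstrate correctness of the decomposition and selection machinery under
the model's own assumptions, not robustness to real instrument artefacts.

## Problem sizes used by the tests

The shipped validation study runs at a reduced scale chosen to keep the
full factorial study comfortably reproducible on a single core: K = 3000
features, 50 + 50 samples, ten two-fold repetitions, Δθ = 3°,
λ = 1e-6·λ_max, linear SVM, for every M ∈ {2..5} (the study fixes Δθ and λ
by design — its purpose is the effect of M — so the sweep mode applies).
Unit fixtures use windowed-tone sources, whose analytic signal is nearly
support-local, giving exact single-component points with known mixing
angles; angle recovery on these is accurate to machine precision, and the
2° tolerance asserted in the tests is loose.

## Known limitations

* The model is linear; nonlinear sample formation is outside its scope.
* A reference profile must be constructible; with very few samples per
  class the average is noisy, and the method has no missing-data mechanism.
* M is never estimated from the data (no model-order selection); it is a
  cross-validated grid value.
* The Hilbert-transform construction depends on the feature ordering of the
  input file (m/z order for spectra); permuting features changes which
  points qualify as SCPs.
* Component selection assumes the extremal-angle components are meaningful;
  when a sample has no pure points for some component, its mixing column is
  interpolated by clustering and the corresponding source row is diffuse.
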