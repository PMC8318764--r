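---
title: "csmri: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{csmri: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the measurement
model and recovery theory, the solvers and their numerical choices, what
the synthetic generators emulate (and deliberately do not), and the design
decisions made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. Measurement model

An MR acquisition samples the image's spatial-frequency representation.
We model a 2D acquisition as

    B = Θ A,   Θ = Π Ω,

where `A` is the sparse object being recovered, `Ω` a sparse-mapping
matrix and `Π` the measurement matrix. Two instantiations coexist:

* **Explicit mode** (`sensing_explicit`): small dense `Θ`, used for the
  uniqueness theory and as oracle material. `Ω` defaults to the identity —
  for total-variation recovery the image itself is treated as the sparse
  object — with an orthonormal Haar option for wavelet-domain sparsity.
  Capped at N = 1024 columns; the theory operations enumerate subsets and
  need small N anyway.
* **Operator mode** (`sensing_operator`): `E = S F`, where `F` is the
  *unitary* centered 2D DFT and `S` selects masked k-space positions.
  Unitarity makes Parseval and adjoint identities exact, so the data
  residual `‖E A − C‖₂` is scale-free and the adjoint is the familiar
  zero-filled reconstruction. Conventions (documented because mask
  dialects depend on them): image index (1,1) is the top-left pixel;
  k-space is stored zero-frequency-centered.

The measurement vector is a single type whether it plays the role of the
theory's `B` or the solver's data `C`; the two symbols denote the same
observed data.

## 2. Uniqueness theory

The *spark* of `Θ` is the smallest number of linearly dependent columns.
If `spark(Θ) > 2k`, a k-sparse solution of `B = Θ A` is unique: the
difference of two k-sparse solutions is a nonzero null-space vector with
at most 2k nonzeros, which the spark condition forbids. The package
computes the spark exhaustively (it is NP-hard in general; N ≤ 16
enforced), certifies uniqueness by enumerating only subsets up to size 2k,
and, when uniqueness fails, constructs an explicit witness: a null-space
vector supported on a smallest dependent subset, split into two halves of
sparsity ≤ k with identical measurements.

Numerical choices: rank decisions use a relative singular-value tolerance
of 1e-10 (exact rational arithmetic is out of scope; the tolerance is
recorded in the certificate); the sparsity-count zero tolerance is 1e-12
and configurable; the spark of a matrix with no dependent subset at all is
reported as the sentinel `"full"` rather than an invented number such as
N + 1. `l0_decode` searches supports in increasing size and lexicographic
order, accepting the first support whose least-squares residual falls
below `1e-8 · ‖B‖`; ties at equal sparsity break by smaller residual, then
lexicographic order. A measurement no support can explain returns a
no-solution value, distinct from a solver error.

The relationship between L0 and L1 recovery is *documented, not
guaranteed*: a property test checks that basis pursuit reproduces the
unique L0 solution on at least 90 % of seeded Gaussian instances at
M = 8 ≥ 3k (k = 2, N = 12). At exactly M = 3k the empirical rate is
noticeably lower (around 75 % on the same family) — those failures are
genuine cases where the minimum-L1 point differs from the sparsest point,
not solver error; the test suite verifies feasibility and a strictly
smaller L1 norm in such cases before the rate assertion was fixed at
M = 8.

## 3. Reconstruction

### 3.1 The two program forms

The constrained form

    min_A  Σ_i η_i φ_i(A)   s.t.  ‖E A − C‖₂² ≤ λ

(`λ` = the noise pollution level) and its Lagrangian

    min_A  ½ ‖E A − C‖₂² + Σ_i η_i φ_i(A)

are both implemented, by different solvers with different contracts.

### 3.2 Constrained TV recovery: split Bregman

`reconstruct_l1_tv` solves `min TV(A) s.t. ‖E A − C‖₂ ≤ λ` by the split
Bregman scheme: the gradient field is decoupled as an auxiliary variable
`d ≈ D A` with Bregman variable `b`, giving three exact updates per
iteration:

1. a quadratic image update `(μ E'E + β D'D) A = μ E' C_k + β D'(d − b)`,
   solved *exactly* in k-space because both `E'E` (mask indicator) and the
   periodic-difference Laplacian `D'D` are diagonal there;
2. isotropic or anisotropic shrinkage of `D A + b` at threshold `η/β`;
3. `b ← b + D A − d`.

Data consistency is enforced by augmented-Lagrangian/Bregman add-back on
the measured coefficients. An earlier design sketch proposed geometric
continuation (penalty × 0.5 per outer stage); the Bregman route was chosen
instead because it reaches the same residual target without the
ill-conditioning of a vanishing penalty — this is the package's one
deliberate deviation from its initial design notes. The add-back is scaled
by `1 − target/residual` (a discrepancy principle): the residual descends
smoothly onto a target slightly *below* the user-facing constraint
(0.98 λ, or half the tolerance target when λ = 0), so a converged result
satisfies `‖E A − C‖₂ ≤ max(λ, tol · ‖C‖)` strictly, without the
freeze/unfreeze limit cycle that a hard threshold produces.

Stopping requires three conditions simultaneously: residual at target,
relative image change ≤ `tol` (default 1e-6, max 2000 iterations), and a
small splitting gap `‖D A − d‖` — the gap is exactly zero at the ADMM
fixed point and guards against declaring convergence before the shrinkage
has acted (the zero-filled warm start is a fixed point of update 1 alone).
Non-convergence is flagged on the returned result, never raised.

**Real-image restriction.** By default the solve is projected onto
real-valued images each iteration (`real_image = TRUE`). This matters
twice. First, over the complex field the *isotropic*-TV minimizer can
genuinely undercut the true image's TV by storing structure in the phase:
on the 64×64 default phantom at 30 % variable-density sampling, the
complex isotropic solution attains lower TV than the truth (the test suite
reproduces this) and ~7 % error, while the real-restricted solve recovers
the image to ~1e-5. Second, a real image can only produce
conjugate-symmetric k-space, so the conjugate-antisymmetric component of
complex noise on jointly-sampled ±f pairs is unfittable by *any* real
image: with noisy data and small λ, the real-restricted constraint set can
be empty, and the solver reports `converged = FALSE` honestly. For
complex-feasibility experiments set `real_image = FALSE`.

The internal TV weight η (default 0.05) shapes the optimization path, not
the constrained solution; solver-internal differences are periodic
(circulant), which is what diagonalizes the updates, while the exported
`tv_seminorm` uses replicate boundaries, the usual convention for image
metrics. On the zero-bordered phantoms the two coincide.

### 3.3 Minimum-variation L2 and the zero-fill identity

For `min ‖D A‖₂² s.t. E A = C` on a masked unitary Fourier system the
quadratic form is diagonal in k-space: `‖D A‖² = Σ_f w(f) |Â(f)|²` with
`w(f) ≥ 0`. Sampled coefficients are pinned by the constraint; each free
coefficient minimizes its own term at zero; the DC tie (`w = 0`), when DC
is unsampled, is broken at zero (minimum norm). The minimum-variation L2
solution is therefore *exactly* the zero-filled reconstruction — a closed
form, and the structural reason L2 recovery shows aliasing: it never
assigns energy to unmeasured frequencies. Explicit systems are solved by
null-space parametrization and tested against an independent KKT oracle.

### 3.4 Penalized (Lagrangian) solver

`reconstruct_lagrangian` minimizes the penalized objective by proximal
gradient with step 1/L (L = 1 for row-orthonormal operators; `σ_max(Θ)²`
for explicit systems; + 8η per quadratic-gradient term). Supported terms:
`tv` (prox by a dual projection method), `l1-identity` (soft threshold),
`l1-wavelet` (exact soft threshold in the orthonormal Haar domain — Haar
is hand-rolled because the deployment image ships no wavelet package),
`l2-tv` (smooth; folded into the gradient). Multiple simultaneous terms
reflect that MR images are sparse in several structures at once; their
composite prox is applied sequentially, an approximation guarded by a
monotone acceptance rule: a candidate that would increase the objective is
rejected and the solver stops, so the objective trace is non-increasing
after the first iteration *by construction*. The traced objective uses the
same periodic internal penalties the proximal steps minimize.

### 3.5 Metrics

PSNR uses the reference's dynamic range as peak and reports an infinite
sentinel for exact matches; SSIM uses the standard 11×11 Gaussian window
(σ = 1.5, K₁ = 0.01, K₂ = 0.03) with reflect boundaries; `relative_l2` is
`‖rec − ref‖/‖ref‖`.

## 4. Synthetic data: the stated world

### 4.1 Phantoms and acquisitions

The default phantom is the classic 10-ellipse head geometry with additive
intensities clipped to [0, 1] (bounded dynamic range for PSNR); the
optional lesion is a small hyperintense disk (center (0.25, 0.2), radius
0.12, +0.4), standing in for a diffusion-restricted infarct core. The
image is piecewise constant — gradient-sparse — which is precisely the
structure TV recovery assumes; rendering is deterministic and
seed-independent. Noise is circular complex Gaussian added in k-space only
(per-coefficient total sd = `noise_level`, so each real/imaginary
component has sd `noise_level/√2`), matching acquisition physics.

Mask dialects are this package's choice (undersampling geometry is
otherwise unspecified in the tradition this models): variable-density
random (radial-profile weights, central 4 % of radius always fully
sampled), golden-angle radial spokes (trimmed center-out to hit the count
exactly), and variable-density Cartesian phase-encode lines. All hit the
requested fraction within far less than 2 percentage points and are
deterministic per (dialect, fraction, seed).

What a green imaging test does establish: the solvers solve their stated
programs (verified against independent oracles), and on gradient-sparse
images with these masks L1-TV dominates L2. What it does not establish:
performance on real multi-coil, phase-perturbed, motion-affected
acquisitions — the phantom world has exactly sparse gradients, real
anatomy does not; no 3D, no DICOM, no scanner trajectories.

### 4.2 Clinical cohorts

The generator's defaults are the motivating study's published group
summaries: group sizes 36/151; age 63 ± 14 vs 61 ± 12 years; platelet
count 263 ± 39 vs 235 ± 52 ×10⁹/L (the ×10⁹/L definition is used where
the source's unit labels conflict); male 28/36 vs 114/151; hypertension
71.2 % vs 53.6 %; standard alteplase dose 58.3 % vs 50.3 %; anterior
infarct 21/36 vs 96/151; internal-carotid responsible artery 6/36 vs
10/151; occlusion status (normal/stenosis/occlusion) (0, 6, 30)/36 vs
(22, 55, 74)/151; NIHSS time-course means 12.3/19.6/13.3 (deterioration)
vs 8.4/7.2/6.8 (control) at 4 h/24 h/1 week. Where the source prints no
value, one realistic choice is fixed and not revisited: baseline and
immediately-post NIHSS means of 9 and 8.8 in both groups (the source
states the groups did not differ at those timepoints), a common score SD
of 3, and truncated-rounded normals for integer quantities.

Three END mechanisms: `group` (label = nominal group), `rule` (label =
the baseline-dependent classifier applied to the simulated trajectory;
round-trips exactly), and `logistic`
(`logit P(END) = β₀ + 0.26 · NIHSS_baseline + 2.36 · occlusion`). The
slopes anchor parameter-recovery studies near the scale of the published
multivariate fit without claiming to reproduce it (the patient-level data
were never deposited). The intercept −5.78 was calibrated once, by
numerical root-finding over the default covariate mix, so the pooled
mechanism reproduces the published END incidence of 18.36 %; it is part of
the stated world, not a tuning knob.

Trajectory scores are drawn independently around group means, so the
generator reproduces group-level summaries, not within-patient
correlation; recovery tests quantify estimator behaviour under the stated
mechanism, nothing more.

### 4.3 Source inconsistencies

The worked-example fixtures carry the source's own conflicts, flagged and
never corrected: the enrolled total 187 (= 36 + 151) is irreconcilable
with the printed denominators of 196 (36/196 = 18.36 %,
151/196 = 77.04 %); the hypertension percentages correspond to no integer
counts over 36/151 (no count fixture exists for them); the published
NIHSS confidence interval (1.023–1.254) does not contain its own odds
ratio (1.301), and neither printed OR equals `exp(B)` of its printed
coefficient; artery counts do not sum to the group sizes. Recomputation
from counts takes precedence over printed percentages; disagreements
surface as flags. Dose counts (21/15 and 76/75) are back-derived from
printed percentages and marked `derived`.

## 5. Statistical methods

The END rule is read with inclusive thresholds: END iff the 24-hour NIHSS
increase is ≥ 2 when baseline < 6, ≥ 4 otherwise; the general rule is
Δ ≥ 4 regardless. An exhaustive enumeration over all (baseline, 24 h)
pairs in [0, 42]² confirms the implication structure: the general rule
implies the baseline-dependent rule everywhere, the two coincide for
baseline ≥ 6, and they disagree exactly for baseline < 6 with 2 ≤ Δ < 4.

Group comparisons use Pearson chi-square without continuity correction
(Yates optional; an expected cell < 1 sets a warning flag rather than
failing) and two-sample t-tests for continuous covariates — the source
names only "single factor analysis", so the concrete tests are this
package's choice, stated here. Odds ratios use the cross-product with
Woolf log-normal intervals and the Haldane–Anscombe 0.5 correction on any
zero cell (flagged); a zero margin is a degenerate-table error. Logistic
regression is authored in-package as Newton/IRLS (relative tolerance 1e-8,
max 100 iterations) reporting B, SE, Wald `(B/SE)²`, OR, Wald CIs and
p-values, with separation flagged per covariate (`estimable = FALSE`)
rather than raised; `stats::glm` serves only as an independent oracle in
the tests. Univariate screening for model entry uses the conventional
p < 0.2 filter, configurable.

## 6. Serialization and the CLI

HDF5 is the canonical imaging container (`/image`, `/mask`,
`/kspace_real`, `/kspace_imag`, `/recon`, `/trace`; `/meta` attributes
carry `schema = 1`, the k-space convention, noise level, seeds, dialect).
Cohorts travel as CSV with a documented column dictionary; explicit
matrices as CSV with `a+bi` entries at full double precision;
certificates, metric reports and run configs as JSON. Images export to
8-bit min-max-scaled PNG. NIfTI export was dropped: no NIfTI-capable R
package exists in the deployment image, and vendoring one was out of
scope. One umbrella CLI (`inst/cli/csmri`) exposes the pipeline with a
single global seed fanned out to named per-module substreams
(`substream_seed`), so equal configurations produce bit-identical payload
datasets; command-line flags override JSON config-file values.

## 7. Known limitations

Exhaustive theory operations are capped at N = 16 (spark is NP-hard); the
explicit L2 solver is dense and small-scale by design. The split-Bregman
solver's iteration count grows near-inversely with the sampling fraction
at fixed tolerance. The sequential composite prox in the Lagrangian solver
is exact only for a single nonsmooth term. SSIM is implemented to the
standard constants but is not bit-compatible with any particular reference
implementation. The cohort generator draws covariates independently within
groups; it does not model covariate correlation, dropout, or measurement
error.
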