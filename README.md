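# csmri

Compressed-sensing MRI reconstruction and early-neurological-deterioration
(END) analysis for ischemic stroke, in one R package.

## The problem

Magnetic resonance imaging guides thrombolysis decisions in cerebral
ischemic stroke, but full k-space acquisition is slow. Compressed sensing
(CS) reconstructs an image from far fewer Fourier measurements than pixels
by exploiting sparsity — for MR images, sparsity of the spatial gradient
(total variation). The clinical question that motivates the imaging is
whether a patient deteriorates neurologically within 24 h of intravenous
thrombolysis (END), assessed on the NIHSS score and analysed with
contingency-table statistics and logistic regression.

`csmri` implements both halves as tested, reproducible code:

* **Measurement model.** `B = Θ A` with `Θ = Π Ω` in explicit-matrix form
  for small systems, and as a masked centered unitary Fourier operator
  `E = S F` for images (`S` the k-space sampling mask, `F` the unitary 2D
  DFT).
* **Uniqueness theory.** The spark of `Θ` (smallest number of linearly
  dependent columns) certifies uniqueness of k-sparse solutions via
  `spark(Θ) > 2k`, with exhaustive-search decoding (`l0_decode`) and
  constructed witness pairs when uniqueness fails.
* **Reconstruction.** The constrained programs
  `min TV(A) s.t. ‖E A − C‖₂ ≤ λ` (split-Bregman solver, exact k-space
  diagonal updates) and `min ‖D A‖₂² s.t. E A = C` (closed form: the
  zero-filled inverse transform), plus the penalized Lagrangian
  `min ½‖E A − C‖₂² + Σᵢ ηᵢ φᵢ(A)` with TV, entrywise-L1, orthonormal-Haar
  and quadratic-gradient terms by monotone proximal gradient.
* **Synthetic data.** Piecewise-constant head phantoms with stroke-like
  lesions, three undersampling mask dialects, k-space noise; synthetic
  thrombolysis cohorts anchored to the motivating study's published group
  summaries.
* **Clinical statistics.** The baseline-dependent END rule
  (END iff ΔNIHSS₍₂₄ₕ₎ ≥ 2 when baseline < 6, ≥ 4 otherwise), odds ratios
  with Woolf CIs, Pearson chi-square, logistic regression by IRLS, and a
  worked example that recomputes every published count-backed percentage.

## Worked example

```r
library(csmri)

img  <- render_phantom(phantom_spec(64, lesion = default_lesion()))
mask <- generate_mask(64, "vd-random", fraction = 0.3, seed = 11)
acq  <- simulate_acquisition(img, mask, noise_level = 0, seed = 11)

r_tv <- reconstruct_l1_tv(acq, lambda = 0)   # TV-regularized CS recovery
r_l2 <- reconstruct_l2(acq)                  # minimum-variation L2 baseline
evaluate_reconstruction(img, r_tv$image)$relative_l2
#> [1] 1.079682e-05
evaluate_reconstruction(img, r_l2$image)$relative_l2
#> [1] 0.4314833
```

From 30 % of k-space the TV reconstruction is essentially exact (relative
error ~1e-5) while the L2/zero-filled baseline keeps 43 % error — the
L1-vs-L2 gap that motivates CS-MRI.

```r
worked_example_report()
#> Worked example: published counts recomputed
#>   21 percentage entries, 20 matching at printed precision, 4 flagged
#>   occlusion table OR = 5.203 (2.047-13.223), chi-square = 13.876 (p = 0.0001952)
#>   enrollment note: enrolled total (187 = 36 + 151) is irreconcilable with the
#>   printed incidence denominators (36/196 = 18.36%, 151/196 = 77.04%)
```

Every percentage is recomputed from its counts (e.g. vessel occlusion in
30/36 = 83.33 % of deteriorating vs 74/151 = 49.01 % of stable patients);
source-internal inconsistencies are carried with explicit flags, never
silently corrected. The `4 flagged` entries are exactly those documented
discrepancies.

```r
ch  <- simulate_cohort(cohort_spec(385, 1615, seed = 1), mechanism = "logistic")
print(fit_logistic(ch, c("nihss_baseline", "occlusion")), digits = 3)
#>             term   beta     se  wald      or  ci_low ci_high        p estimable
#> 1    (intercept) -5.227 0.3069 290.0 0.00537 0.00294  0.0098 4.85e-65      TRUE
#> 2 nihss_baseline  0.224 0.0245  83.9 1.25123 1.19265  1.3127 5.10e-20      TRUE
#> 3      occlusion  1.936 0.1773 119.1 6.92756 4.89380  9.8065 9.73e-28      TRUE
```

A single cohort estimates the generative coefficients (0.26 per NIHSS
point, 2.36 for vessel occlusion) with sampling noise; the test suite
checks <10 % mean bias over 200 replicates and 93–97 % Wald CI coverage
over 500.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "csmri", package = "csmri"))')
Rscript $CLI phantom --size 64 --seed 1 -o p.h5
Rscript $CLI acquire --mask vd-random --fraction 0.3 --noise 0 --seed 1 -i p.h5 -o a.h5
Rscript $CLI reconstruct --method l1tv -i a.h5 -o r.h5
Rscript $CLI evaluate -i r.h5 -r p.h5 --json metrics.json
Rscript $CLI clinical worked-example --json report.json
```

Bundles are HDF5 (`/image`, `/mask`, `/kspace_real`, `/kspace_imag`,
`/recon`, `/trace`, `/meta` attributes incl. `schema=1` and the
zero-frequency-centered k-space convention); cohorts are CSV; reports and
configs are JSON.

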