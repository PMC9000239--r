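# flexmcr

Flexible trilinearity-constrained Multivariate Curve Resolution —
Alternating Least Squares (MCR-ALS) for three-way chromatographic and
spectroscopic data.

## The problem

Hyphenated techniques (LC-DAD, GC-MS, FIA-UV) produce three-way data
cubes **X**(I, J, K): elution or flow time × spectral channel × sample or
run. When every chemical component keeps the same concentration profile
shape and position across all runs, the cube follows the trilinear model

    x_ijk = Σ_n c_in · s_jn · z_kn + e_ijk

and trilinear solvers (PARAFAC, ATLD) resolve unique profiles. Real
chromatography rarely cooperates: retention times drift between runs, so
the elution peak of a component sits at a different position in each
slice, the trilinear model breaks, and strict trilinear solvers return
distorted profiles.

`flexmcr` implements MCR-ALS on the column-wise augmented matrix
`X_aug = C_aug · Sᵀ + E` with a **per-component** trilinearity constraint.
Each component n carries a code:

* **0 — bilinear**: its profile is free to differ in shape and position
  across slices;
* **1 — trilinear**: at every ALS sweep its augmented profile is folded
  to an I × K matrix, replaced by the best rank-one approximation
  (Eckart–Young, via SVD), and rebuilt as the Kronecker product z ⊗ c —
  one shape, synchronized in all slices;
* **2 — trilinear with shift correction**: per-slice peak maxima are
  detected first, all slices are shifted onto a reference position, the
  synchronized matrix is projected to rank one, and the rebuilt slice
  profiles are shifted back — one shape, individual positions.

Mixed models such as (2,2,1) — two shifting analytes over a run-invariant
background — are exactly the cases the flexible constraint exists for.

The package also provides: augmented-matrix SVD rank diagnostics that
classify a cube (trilinear / rank-deficient sample mode / shifted
non-trilinear) before modelling; SIMPLISMA-style purest-variable initial
spectra; a multi-right-hand-side active-set non-negative least squares
solver; PARAFAC and ATLD reference solvers; recovery metrics
(r = cos angle, angle in degrees, lack of fit, explained variance with
R² = 100 − lof²/100); seeded generators for the three benchmark scenarios
(shifted LC-DAD, GC-MS with varying background, FIA with pH-driven
acid–base speciation); and a command-line interface.

## Worked example

Simulate an LC-DAD-like cube (200 times × 40 wavelengths × 8 runs, three
components with peak shifts up to ±15 time points), diagnose it, and
resolve it with the shift-corrected trilinearity constraint:

```r
library(flexmcr)

sim <- simulate_lcdad(I = 200, J = 40, K = 8, N = 3, shift_range = 15,
                      seed = 1)
trilinearity_report(sim$data)
#> Augmented-mode rank diagnostics
#>   columnwise rank 3 (noise floor 0.038): 23.75 22.15 12.52 0.06527 ...
#>   rowwise    rank 17 (noise floor 0.0102): 20.07 17.29 11.87 10.49 ...
#>   slicewise  rank 0 (noise floor 3.85): 27.3 13.83 9.859 9.493 ...
#>   scenario: shifted_nontrilinear
```

Three singular values stand above the noise in the spectral
(column-wise) mode — three chemical species — while the row-wise mode
shows many more: the signature of unsynchronized elution profiles. So we
fit with code 2 for every component:

```r
fit <- fit_mcr_als(sim$data, mcr_spec(3, codes = 2))
fit
#> MCR-ALS fit: 3 components, codes (2,2,2)
#>   lof 0.756%  R2 99.99%  iterations 2 (converged)

recovery_report(fit$factors, sim$truth)
#>   component    mode r    angle flagged
#> 1         1 elution 1 0.155140   FALSE
#> 2         2 elution 1 0.230995   FALSE
#> 3         3 elution 1 0.163558   FALSE
#> 4         1 spectra 1 0.047792   FALSE
#> ...
```

The lack of fit (0.76%) sits at the simulated noise level, every
recovered profile has cosine ≈ 1 (angle below a quarter degree) with its
reference, and `fit$factors$shifts` reproduces the per-run retention-time
offsets exactly. A strict trilinear fit of the same cube
(`codes = 1`) is forced to average the shifted peaks and its lack of fit
rises above 50%.

For mixed models the codes are positional, so identify the components
first (e.g. with a bilinear run), then assign codes; see the vignette's
GC-MS walk-through.

## Command line

```sh
inst/cli/flexmcr simulate --scenario lcdad --seed 1 --out run1
inst/cli/flexmcr rankdiag --manifest run1/data/manifest.json
inst/cli/flexmcr fit --manifest run1/data/manifest.json \
    --ncomp 3 --codes 2,2,2 --out run1/fit
inst/cli/flexmcr evaluate --fit run1/fit --truth run1/truth
```

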