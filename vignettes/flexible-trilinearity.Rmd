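---
title: "Flexible trilinearity in MCR-ALS: model, constraint, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible trilinearity in MCR-ALS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexmcr)
```

## The model

A three-way cube $\mathbf{X}(I, J, K)$ — time × spectral channel ×
slice — is analyzed through its column-wise augmented matrix
$\mathbf{X}_{aug}$ ($IK \times J$, slices stacked vertically), factored
bilinearly as $\mathbf{X}_{aug} = \mathbf{C}_{aug}\mathbf{S}^T +
\mathbf{E}$ by alternating least squares under non-negativity. When the
data are trilinear, $x_{ijk} = \sum_n c_{in} s_{jn} z_{kn} + e_{ijk}$,
each component's augmented concentration profile folds into an
$I \times K$ matrix of rank one: the same elution shape $c_n$ in every
slice, scaled by the sample amounts $z_n$.

The trilinearity constraint enforces exactly this, per component and at
every ALS sweep: fold, project to the closest rank-one matrix
(Eckart–Young via SVD, keeping only the first singular triplet), rebuild
as $z_n \otimes c_n$. Because it acts column by column, each component
carries its own code:

* **0** — no projection (bilinear; the component may change shape and
  position between slices),
* **1** — rank-one projection (trilinear, synchronized),
* **2** — shift-corrected rank-one projection (trilinear shapes at
  per-slice peak positions).

Code 2 inserts a synchronization step around the projection: the peak
maximum of each slice's profile is located by argmax, every slice is
shifted (integer time steps, zero fill) onto a reference position, the
synchronized matrix is projected to rank one, and each rebuilt slice is
shifted back to its own original peak position. The shift table is part
of the returned fit.

Assumptions worth stating explicitly: peaks decay to baseline inside the
time window (values shifted out of the window are lost; the restore step
rebuilds edges from the rank-one model, so a peak pressed against the
window boundary is truncated); shifts are whole time points estimated
from peak maxima only (no subsample interpolation, no cross-correlation
refinement — components whose maxima are flat or multimodal in a slice
take the lowest-index argmax); a component essentially absent from a
slice (column maximum below `presence_tol` = 1e-9 of the global maximum)
keeps shift 0 rather than chasing noise.

## The ALS sweep

Each sweep updates, in order: (1) $\mathbf{C}_{aug}$ by NNLS given
$\mathbf{S}$; (2) the trilinearity projection of the coded columns of
$\mathbf{C}_{aug}$; (3) $\mathbf{S}$ by NNLS given the constrained
$\mathbf{C}_{aug}$; (4) column normalization of $\mathbf{S}$ to unit
norm, magnitudes carried into $\mathbf{C}_{aug}$; (5) the lack of fit
$\mathrm{lof} = 100\sqrt{\sum (d - \hat d)^2 / \sum d^2}$, with
$R^2 = 100 - \mathrm{lof}^2/100$ as the paired explained variance.
Iterations stop when the relative lof change drops below `tol`
(default 1e-3, i.e. 0.1%) or after `max_iter` (default 100) sweeps.

Hard projections do not guarantee a monotone lof, so the engine keeps
the best sweep seen and reports it if the final sweep is worse. The
$R^2$–lof identity holds for every returned fit by construction.

Before the constraint engages, the engine runs up to `warm_start`
(default 10) purely bilinear sweeps, stopped early by the same `tol`
rule. The synchronization shifts are thereby read off the optimal
bilinear decomposition of the data rather than off the raw initial
estimates. The difference matters for narrow, strongly shifted peaks:
shift estimates taken from a first crude concentration update can lock
the optimization into poor basins, while the bilinear solution — which
is cheap and well-behaved on these data — already separates the
components well enough to place every peak.

Two degenerate situations are handled rather than failed: a component
column collapsing to all-zero passes through the projection unchanged and
is flagged in the result; non-finite intermediates abort with a
diagnostic naming the sweep.

## Choosing codes: the workflow for mixed models

Constraint codes are positional, but the order in which components
emerge from an initialization is arbitrary. For mixed models — e.g. two
shifting analytes over a run-invariant background, (2,2,1) — the
intended workflow is: run bilinear `codes = 0` first, identify which
fitted component is which (by its spectrum against references, or its
elution structure), then refit with per-component codes assigned to the
identified components, initializing from the bilinear spectra. The
package's GC-MS tests follow exactly this sequence; assigning codes
blindly to unidentified components applies the wrong model to the wrong
profile and fits no better than the strict trilinear model.

## Initial estimates

`purest_rows()` implements the purest-variable (SIMPLISMA-style)
selection on the rows of the augmented matrix — each row is an observed
spectrum, and the picked rows serve as initial $\mathbf{S}$. Purity is
$\sigma_i / (\mu_i + \alpha)$ with $\alpha$ = `noise_allowance` (default
5) percent of the largest row mean; subsequent picks weight purity by
the determinant of the correlation-around-origin matrix of the candidate
with the rows already picked, so duplicates get weight zero. Rows (not
columns) are selected because the initial estimates wanted here are
spectra; ties break to the lowest row index, making the selection fully
deterministic. A seeded uniform random initializer is the fallback for
degenerate inputs, and every stochastic path takes an explicit seed.

## Rank diagnostics

`trilinearity_report()` computes the SVD of the three augmentations —
column-wise ($IK \times J$), row-wise ($I \times JK$), slice-wise
($K \times IJ$, rows = vectorized slices, time-major) — and estimates
each chemical rank as the number of singular values above
`floor_factor` (default 10) times a noise floor, taken as the median of
the trailing half of the spectrum (indices $\lceil m/2 \rceil + 1 \dots
m$; the last value when $m < 4$). The floor is additionally bounded
below by $10^{-10}$ of the leading singular value so that exactly
noiseless cubes, whose trailing singular values are numerical zeros, do
not report inflated ranks. The rule is scale-free: rescaling the cube
rescales every singular value alike.

The scenario classification follows the rank pattern: equal ranks in all
three modes → `trilinear`; column-wise = row-wise > slice-wise →
`rank_deficient_sample_mode` (linearly dependent sample amounts);
row-wise > column-wise → `shifted_nontrilinear` (unsynchronized
profiles); anything else → `indeterminate`. The FIA scenario, which
combines spectral-mode rank 6 with both row- and slice-wise deficiency,
deliberately lands in `indeterminate`: its signature is read from the
individual ranks, and the report prints all three spectra for exactly
that purpose. For smoothly decaying spectra (e.g. the slice-wise mode of
a strongly shifted cube) the median-based floor can sit high enough that
no value clears `floor_factor` × floor and the reported rank is 0 —
borderline counts are the analyst's call via `floor_factor`.

## Non-negative least squares

`nonnegative_lsq()` solves $\min \|AX - B\|_F,\ X \ge 0$ for all columns
of $B$ at once: the cross-products $A^TA$, $A^TB$ are formed once, the
unconstrained solution seeds the passive sets, columns sharing a passive
set are solved as one linear system, infeasible columns shrink their
passive sets, and optimality is certified by the dual variables
(gradient ≤ 0 on the active set). Rank-deficient $A$ falls back to the
SVD pseudoinverse (least-norm convention). The suite checks the solver
against exhaustive active-set enumeration and against an independent
single-column implementation.

## Reference solvers

`fit_parafac()` is plain ALS on the three matricized forms of the cube
(no line search or acceleration — adequate at this scale and simple to
verify), with optional NNLS non-negativity on all factors.
`fit_atld()` implements the canonical alternating trilinear
decomposition updates, each factor row the diagonal of a slice
sandwiched between SVD pseudoinverses of the other two factors, without
non-negativity. Both normalize $\mathbf{C}$ and $\mathbf{S}$ columns to
unit norm with magnitudes in $\mathbf{Z}$, and orient each component's
$c_n$ and $s_n$ positive by element sum (compensating in $z_n$) to
resolve the sign indeterminacy of unconstrained trilinear fits.

Both solvers default to their own seeded random initialization rather
than sharing the MCR purest-variable start. That is the configuration in
which such reference implementations are ordinarily run, and it keeps
the comparison honest: with a shared, highly informative start, PARAFAC
and constrained MCR collapse onto the same stationary point and the
comparison degenerates into a tie decided by stopping rules. Passing
`S_init = purest_rows(...)$spectra` restores the shared start when
wanted.

## Synthetic scenarios

The three generators emulate the structure of the benchmark experiments,
with full ground truth (per-slice profiles, spectra, sample amounts,
shift tables, and the exact noise realization) returned alongside the
cube:

* `simulate_lcdad()` — 600 × 96 × 11 by default: three Gaussian elution
  peaks (width I/40) shifted per run by integers up to ±30, smooth
  distinct UV spectra (sums of 2–3 broad Gaussians, pairwise cosine
  < 0.98), independent positive amounts in 0.3–1.
* `simulate_gcms()` — 25 × 200 × 44: two analytes with sparse mass
  spectra (5–15 channels above m/z 40) and narrow peaks (width 1.6)
  shifting by up to ±4 points, plus a background component with a broad
  run-invariant elution shape, per-run amplitude (±40% spread), and a
  sparse low-mass spectrum.
* `simulate_fia()` — 89 × 100 × 12: three acids, each an acid/base
  conjugate pair (six species), every species profile the shared
  Gaussian dispersion envelope times its Henderson–Hasselbalch fraction
  of a monotone pH 3→11 gradient (pKa defaults 4.5/7/9.5), and the two
  species of a compound sharing one sample-amount column — the
  rank-deficient sample mode is built in.

Noise is i.i.d. Gaussian at `noise_sd_rel` (default 1e-3) of the maximum
signal, clipped at zero; the clipped realization is stored so the cube
always equals truth reconstruction plus stored noise exactly. Shift
tables are stored relative to each component's tallest slice, the same
reference rule the shift detector uses, so they are recoverable exactly
from noiseless profiles.

What the generators do **not** emulate: peak-shape changes between runs
(column overloading, strong coelution tailing), heteroscedastic or
correlated detector noise, baseline drift within a run, and
exponentially modified peak shapes (a Gaussian peak is the default to
keep the ground truth analytic). Passing tests on these cubes therefore
demonstrates correctness of the algorithms under the stated structure,
not robustness to every failure mode of real chromatography.

The LC-DAD profiles of the original benchmark are published only as
figures, so recovery checks here are property-based — rank patterns,
recovery cosines, shift tables against the package's own ground truth —
rather than bit-level comparisons; only the analytic metric identities
are checked against published numbers directly.

## Numerical choices

* Reference slice for synchronization: the slice with the component's
  largest peak height (robust when a component is weak or absent in some
  runs); `reference = "mean"` or `"first"` are available alternatives.
* Argmax ties break to the lowest time index; matching permutation ties
  break lexicographically.
* SVD sign convention: the common profile is oriented so its
  largest-magnitude entry is positive, consistent with NNLS
  non-negativity.
* The arccosine argument is clamped to [−1, 1]; recovery `r` is the
  plain (not mean-centered, not squared) cosine, so anti-correlated
  profiles report negative values and 180° angles, and recoveries below
  0.9 are flagged.
* Component matching maximizes total cosine by exhaustive permutation
  search up to 8 components (720 permutations at N = 6 is still
  instant), greedy best-pair assignment beyond.
* `estimate_chemical_rank` on fewer than two singular values is an
  error; an all-zero spectrum reports rank 0, floor 0.

## Problem sizes

The test suite and the acceptance script run the full-size generators
(600 × 96 × 11, 25 × 200 × 44, 89 × 100 × 12) for rank diagnostics, and
a 200 × 40 × 8 three-component cube with shifts up to ±15 points (three
peak widths) for the solver comparison — large enough that the shifted
peaks overlap heavily and strict trilinear fits fail distinctly, small
enough that the whole suite runs in well under a minute. The oracle
checks use 200 random matrices × 1000 rank-one candidates
(Eckart–Young) and 100 random 6 × 3 systems (NNLS enumeration).

## Known limitations

Integer-grid shifts cannot align sub-sample drift; components whose
peaks leave the time window are truncated rather than wrapped; the
bilinear code 0 retains rotational ambiguity (its diagnostics
$c_n$, $z_n$ are reported from the folded profile's SVD but are not
unique); constraint codes are positional and the engine does not itself
identify components; and the scenario classifier intentionally reports
`indeterminate` for rank patterns outside its three named cases rather
than guessing.
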