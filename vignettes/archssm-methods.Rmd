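---
title: "Methods: shape-model reconstruction of the mucogingival borderline"
author: "archssm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape-model reconstruction of the mucogingival borderline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`archssm` implements a point-distribution statistical shape model (SSM)
over two corresponding dental-arch curves — the mucous–tooth borderline
(MT-BL, the gingival margin plus fixed papilla anchor landmarks) and the
mucogingival borderline (MG-BL) — and reconstructs the MG-BL of a new
jaw from its MT-BL alone. This vignette documents the model, its
assumptions, the tunable parameters, the numerical choices, and the
limits of what the accompanying synthetic-data tests establish.

## The statistical model and its assumptions

Write one subject's configuration as the stacked coordinate vector
$x \in \mathbb{R}^{3m}$ (order $x_1 y_1 z_1 \dots$, MT-BL block before
MG-BL block). After alignment the population is modeled as Gaussian:

$$x = \mu + Q\,\alpha, \qquad \alpha \sim N(0, I_k), \qquad
Q = V\,\mathrm{diag}(\sqrt{\lambda}),$$

with orthonormal principal directions $V$ and variances $\lambda$
(sample covariance, divisor $n-1$, computed by SVD of the centered data
matrix). Coefficients are therefore in per-component standard-deviation
units. Observing the MT-BL rows $x_o$ with iid noise
$N(0, \sigma^2 I)$, the coefficient posterior is Gaussian with mean

$$\alpha^* = (Q_o^\top Q_o + \sigma^2 I)^{-1} Q_o^\top (x_o - \mu_o),$$

and $\mu + Q\alpha^*$ is the exact conditional expectation of the full
shape — in particular of its latent MG-BL block. The test suite checks
this low-rank formula against a brute-force conditional-Gaussian oracle
built from the explicit joint covariance.

Assumptions worth stating plainly:

* **Point-wise correspondence across subjects.** Landmark `i` means the
  same anatomical locus everywhere. Correspondence is established by
  curve parameterization and improved by semilandmark sliding.
* **Linearity.** Shape variation is modeled as a linear (Gaussian)
  subspace. Rigid alignment residues make real populations slightly
  curved manifolds; with shape variation small relative to arch size the
  quadratic remainder is negligible.
* **Homoscedastic observation noise.** One scalar $\sigma^2$ for all
  MT-BL coordinates. Per-landmark anisotropic noise is out of scope.

## Pipeline and numerical choices

### Rigid registration (no scaling)

`rigid_fit()` solves the orthogonal Procrustes problem by the Kabsch
SVD construction; reflection solutions are corrected by flipping the
smallest singular direction, so only proper rotations are returned
(anatomical scans are same-handed). Generalized Procrustes analysis
(`generalized_procrustes()`) iterates fit-to-consensus with the
registration **restricted to the MT-BL landmarks** (semilandmarks and
papilla anchors — the "known structure"); the MG-BL is carried along and
never influences the alignment. Scaling is off by default because
errors must remain in physical millimetres; a similarity option exists
(`scale = TRUE`).

Numerical details: convergence when the RMS change of the consensus fit
coordinates drops below `tol = 1e-8` (mm), at most `max_iter = 100`
iterations (non-convergence warns and returns the last state). Because
a Procrustes consensus is only defined up to rotation, the converged
consensus is rotated into a deterministic canonical frame (principal
axes of the fit subset; axis signs fixed by coordinate skewness, with an
index-contrast fallback when the skewness is degenerate). This makes
the whole pipeline invariant — to numerical precision — under arbitrary
rigid motions of the inputs, which the acceptance suite asserts at
`1e-6` mm on every LOOCV statistic.

### Thin-plate-spline bending energy

The TPS system on a reference point set uses the 3D radial kernel
$U(r) = r$. The bending quadratic form is the upper-left $m \times m$
block of the inverted bordered matrix
$L = \begin{pmatrix} K & P \\ P^\top & 0\end{pmatrix}$,
$P = [\,1\,|\,x\,|\,y\,|\,z\,]$ — **negated**, because in 3D that block
is negative semidefinite for $U(r)=r$ (the biharmonic Green's function
is $-r$ up to constants). The sign convention makes the energy
nonnegative, zero exactly on affine images of the reference; both
properties are asserted in tests. Duplicate reference points raise a
singular-system error.

### Sliding semilandmarks

Each slide pass linearizes the curve at the current landmark positions
(central-difference tangents, one-sided at open ends; wrap-around for
closed curves) and minimizes the bending energy over per-landmark
tangential displacements $w$: with $A_{ij} = B_{ij}\,(u_i \cdot u_j)$
and $b_i = -u_i \cdot (B y)_i$, solve $A_{SS} w_S = b_S$ on the sliding
subset (fixed anchors have zero displacement; a singular system falls
back to a small ridge, then to zero displacement with a warning). Each
displacement is clamped and the point is re-projected onto the
**original observed polyline**, so downstream registration and PCA never
see off-curve coordinates. A backtracking step (halving the
displacement scale, down to no movement) guarantees the returned energy
never exceeds the input energy — important because clamping and
projection are not part of the quadratic model.

Two deliberate deviations from common defaults:

* **Step clamp.** The clamp is half the *smaller current* adjacent
  segment per landmark, not the mean original spacing. The MT-BL
  polyline contains long transverse segments at the papilla anchors
  (buccal tip to oral tip); a spacing-based clamp derived from them lets
  semilandmarks leap toward the anchors and pile up, which degrades the
  consensus spacing and blows up the bending form's conditioning. The
  neighbour-based clamp makes overshoot past a neighbour impossible.
* **Reference policy.** The default reference is the *first* GPA
  consensus, held fixed across outer iterations
  (`reference_policy = "fixed_reference"`). Refreshing the consensus
  each iteration (`"sample_mean"`, also available) refreshes the TPS
  kernel, and energies measured under different kernels are not
  comparable: empirically the per-configuration energy trace — and at
  times even its mean — can rise on a reference refresh. Under a fixed
  reference the trace is non-increasing by construction, which is the
  contract the package promises (and tests within `1e-7`).

Relaxation runs `outer_iterations = 3` rounds (interleaved with GPA),
`inner_iterations = 1` slide pass each, with early stop when the mean
energy improves by less than `1e-6` relative. MT-BL and MG-BL each
slide against their own kernel. Results are reported in each subject's
original coordinate frame: sliding only re-parameterizes points along
their own curves, fixed landmarks are returned bit-identical.

### Reconstruction and evaluation

`reconstruct_mgbl()` rigid-fits the query MT-BL to the model mean MT-BL,
computes the posterior mean, and maps the predicted MG-BL back through
the inverse transform; the query's own MT-BL is returned untouched.
`loocv()` rebuilds the entire pipeline (optional sliding, GPA, PCA) on
each fold's remaining $n-1$ subjects, so the held-out MG-BL can never
leak into its own prediction — a test poisons the held-out MG-BL with
`NaN` and asserts a bit-identical prediction.

Error is measured **from each actual MG-BL point to the predicted
curve** (asymmetric, as clinically read): either to the nearest
predicted vertex (`nearest_vertex`, default — the plainest reading of
"closest counterpart") or to the nearest point on the predicted polyline
(`nearest_on_polyline`, always pointwise ≤). Pooled statistics
concatenate all per-point distances, then report median and 10th/90th
percentiles with type-7 (linear-interpolation) quantiles; the mean is
computed only to rank best/worst cases.

### Key tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `sigma2` | `1e-4` | mm² | near-interpolating posterior: the MT-BL is a measured structure, so the prediction should almost honour it; exposed everywhere because no canonical value exists |
| `variance_to_retain` | `1.0` | — | keep all nonzero components; truncation is a user decision |
| GPA `tol` | `1e-8` | mm (RMS) | far below landmark noise; convergence is cheap |
| `outer_iterations` | 3 | — | bending-energy improvements die off quickly under the fixed reference |
| `step_clamp` | adaptive | mm | see above |
| error `mode` | `nearest_vertex` | — | sensitivity knob; the polyline variant is reported alongside where it matters |

## The synthetic world

`generate_population()` emulates what the pipeline needs from clinical
data, not gingiva biology. One subject is built as:

* a parabolic arch (population means 60 × 50 mm maxilla, 55 × 45 mm
  mandible) carrying a scalloped MT-BL (one lobe per tooth, amplitude
  1.5 mm) with 13 interdental papillae, each contributing a buccal and
  an oral fixed anchor;
* `latent_dim = 4` subject factors (arch width, depth, asymmetry,
  scallop amplitude; SDs 3, 3, 2, 1 mm) entering **linearly**. Each
  factor field is orthogonalized against the infinitesimal rigid
  motions of the mean MT-BL, so the factors encode shape rather than
  pose — otherwise MT-restricted Procrustes alignment becomes
  factor-dependent and leaks the factors into the aligned MG-BL even
  when the MG-BL is nominally independent;
* an MG-BL built on the population-mean arch plus `rho`-scaled factor
  fields, offset apically by a width field
  $w = 4.0 + \rho\,(c(u)^\top\beta) + \sqrt{1-\rho^2}\,\eta(u)$, where
  $\eta$ is a smooth low-order harmonic process (SD scale 1.0 mm).
  `rho = 1` makes the MG-BL an exact linear function of the subject
  factors (fully predictable); `rho = 0` makes it statistically
  independent of the MT-BL. This is the dial the acceptance criteria
  sweep;
* optional smooth monotone jitter of the curve parameterization
  (`param_jitter_sd`, default 0) emulating inconsistent digitization
  spacing — the disturbance sliding is designed to remove;
* iid coordinate noise (`landmark_noise_sd`, default 0.3 mm, a
  plausible annotation repeatability) and a random rigid pose (up to
  20°, ±10 mm).

Counts default to a reduced scale (140 MT-BL / 50 MG-BL semilandmarks)
for fast tests; `preset = "clinical"` restores full-size annotations
(560 / 150). Everything is deterministic per (master seed, subject
seed).

What the generator does **not** emulate: real mucosal texture and the
operator's color-based judgment of the borderline, tooth loss and
restorations, spatially correlated annotation error, and — most
importantly — the true biological covariation between the two
borderlines. `rho` is a dial, not an estimate. Consequently a green
end-to-end test establishes that the *pipeline* is correct (it recovers
what is recoverable, and degrades gracefully), never that clinical
accuracy of any particular magnitude would be achieved.

## What the acceptance suite checks, and two scope decisions

The acceptance tests assert: posterior equality with a full-covariance
conditional-Gaussian oracle (`1e-8`); in-span recovery of training
members at near-zero `sigma2` (`1e-3` mm); rigid invariance of all LOOCV
statistics (`1e-6` mm); near-exact LOOCV on a fully predictable world
(pooled median < 0.05 mm at `rho = 1`, zero noise) and statistical
equivalence with the population-mean baseline at `rho = 0` (±10% over
three seeds); monotone degradation with landmark noise; the sliding
energy/on-curve contracts; and exact percentile/nearest-counterpart
conventions. A final, non-gating check logs the pooled LOOCV error of a
clinically calibrated full-size world (n = 70, 0.3 mm noise,
`rho = 0.7`) and only asserts it is finite — it is a plausibility
indicator, not a reproduction of any clinical result.

Two scope decisions deserve their rationale here:

* **The end-to-end witness runs without sliding.** In the `rho = 1`,
  zero-noise, zero-jitter world there is no digitization inconsistency
  to remove; sliding would still move semilandmarks (bending energy
  against a consensus of *different* shapes is reducible), shifting
  vertex correspondence tangentially. The nearest-vertex error metric
  charges such shifts up to half the vertex spacing, which would swamp
  the 0.05 mm witness threshold without indicating any defect in the
  statistical machinery. The witness therefore isolates GPA + PCA +
  posterior; sliding has its own dedicated contracts and tests.
* **In-span recovery needs an informative MT-BL.** Recovery of a
  training member from its MT-BL presumes the observed-row restriction
  of the basis is injective; in degenerate worlds (zero noise and fewer
  MT factors than components) the coefficient is under-determined and
  the minimum-norm posterior legitimately drops MG-only components.
  The recovery tests use worlds with noise, where injectivity holds
  generically.

## Degenerate inputs and tie-breaks

Collinear point sets are rejected by `rigid_fit` (rank < 2); duplicate
reference points by `tps_kernel`. An identical-shapes population yields
a zero-component model whose posterior is the mean. Nearest-vertex and
nearest-segment ties resolve to the first minimizer — distances, the
quantities reported, are unaffected. Polyline projection clamps to
segment endpoints. In fcsv/mrk.json inputs a missing coordinate-system
declaration assumes LPS (the current Slicer default) with a warning.

## Known limitations

* Curve (1-DOF) sliding only; no surface semilandmarks or mesh
  registration.
* Isotropic, homoscedastic observation noise in the posterior.
* The canonical consensus orientation relies on odd moments of the
  landmark distribution; an exactly symmetric population could make the
  sign convention sensitive, though a deterministic fallback keeps runs
  reproducible.
* Cross-modality evaluation (cast vs intra-oral scan) is supported only
  via the 4-landmark rigid superimposition utility; no non-rigid
  surface matching.
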