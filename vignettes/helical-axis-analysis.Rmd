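---
title: "Measuring tooth movement from serial surface scans with finite helical axes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tooth movement from serial surface scans with finite helical axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helaxis)
```

## The measurement problem

Orthodontic treatment moves individual teeth by fractions of a millimetre
and a few degrees per observation interval. Plaster casts (or intraoral
scans) taken at successive timepoints capture the dentition's surface, but
each cast is digitized in an arbitrary scanner pose, so raw coordinates at
two timepoints are not comparable. `helaxis` turns a series of labelled 3D
point clouds into a per-tooth, per-interval movement report in a common
anatomical frame, describing each movement in the most compact way a rigid
displacement admits: as a screw.

The workflow has three stages:

1. **Series normalization.** Every scan is registered onto the first scan
   using only the points of a structure assumed anatomically stable over
   treatment (in the motivating application, the maxillary first molars
   joined by a transpalatal bar). After this step all scans share one
   coordinate frame and any residual per-tooth displacement is biological,
   not postural.
2. **Per-tooth rigid estimation.** For each analyzed tooth and each
   interval T(i) to T(i+1), the tooth's points at T(i) are registered onto
   its points at T(i+1), yielding a rotation matrix $A$ and translation
   vector $o$ with $m = A n + o$.
3. **Helical decomposition.** Each $(A, o)$ is decomposed into its finite
   helical axis: a unit direction $h$, a point $q$ on the axis, the
   rotation angle $\theta$ about the axis and the signed translation $t$
   along it.

## The screw model

By Chasles' theorem every proper rigid displacement is a rotation about a
unique line plus a translation along that line. The displacement of a
point $n$ is $p(n) = (A - K)n + o$, with $K$ the identity. Points on the
axis displace only along the axis, so there $p = A^{\mathsf T} p$;
substituting into the displacement equation gives the on-axis condition

$$(A + A^{\mathsf T} - 2K)\,n + (K - A^{\mathsf T})\,o = 0 .$$

The coefficient matrix is symmetric of rank 2 — its null space is the axis
direction — so the solution set is exactly the axis line, and it is also
the locus of minimal displacement norm. The remaining quantities follow
directly: $\theta$ from the trace identity
$\cos\theta = (\operatorname{tr} A - 1)/2$, the direction $h$ from the
skew part of $A$ (oriented by the right-hand rule, so $\theta$ can stay
unsigned in $[0^\circ, 180^\circ]$), and $t = p(q)\cdot h$, which reduces
to $o \cdot h$.

As a cross-check the package also computes the angle geometrically: take
any off-axis point $d_0$, its image $d_1 = A d_0 + o$, remove the screw
translation ($d_2 = d_1 - t\,h$), project onto the axis at the common foot
$q'$ and measure the angle between $d_0 - q'$ and $d_2 - q'$. The test
suite asserts agreement with the trace formula to $10^{-8}$ degrees over
thousands of random screws.

### Choosing the axis point

Because the on-axis system is rank 2, a convention must pick one point on
the line. The default is the **minimum-norm** least-squares solution (via
the pseudoinverse): the axis point closest to the origin. It is
coordinate-free and equally well-conditioned for every axis orientation.
The classical alternative — fix one coordinate and solve the remaining
two-unknown system — is kept as `axis_point_strategy = "fix_coordinate"`,
generalized to fix the coordinate with the *largest* axis component:
fixing a preset coordinate (say $z$) fails whenever the axis is nearly
perpendicular to that coordinate's direction. Both conventions return
points on the same line; the tests assert their difference is parallel to
$h$.

### Degeneracy and sensitivity

As $\theta \to 0$ the on-axis system loses rank and the axis position
becomes undefined. Below `degeneracy_threshold` (default $0.1^\circ$,
safely under the smallest clinically reported rotations of
$\approx 0.8^\circ$) the decomposition degrades to a pure-translation
description: $h = o/\lVert o\rVert$, $t = \lVert o\rVert$, `degenerate =
TRUE`. Between the threshold and $0.5^\circ$ the axis is defined but its
position is extremely noise-sensitive, so results carry an `unreliable`
flag. This sensitivity is quantified, not just asserted: with isotropic
0.02 mm noise the median axis-position error at $\theta = 0.2^\circ$ is
two orders of magnitude larger than at $\theta = 5^\circ$ (the acceptance
script reports the ratio). Rotation angle and screw translation remain
well-determined even when the axis position is not.

At $\theta \approx 180^\circ$ the skew part of $A$ vanishes; the axis is
then taken from the dominant eigenvector of the symmetric part
$(A + K)/2$, sign fixed so the first non-zero component is positive. This
branch is irrelevant at dental scales but keeps the decomposition total.

All angle computations clamp the $\arccos$ argument to $[-1, 1]$ to absorb
floating-point drift near $0^\circ$ and $180^\circ$. Angles are reported
in degrees and lengths in millimetres everywhere.

## Registration

The rigid fit for corresponded points is the Kabsch/SVD solution: the
proper rotation maximizing $\operatorname{tr}(A H)$ over the centered
cross-covariance $H$, with a sign flip of the smallest singular direction
so a reflection can never be returned, followed by the closed-form
translation. Its global optimality is verified in the tests against a
brute-force search over an axis-angle grid ($2^\circ$ spacing with local
refinement) — an oracle that shares no code with the SVD path.

When correspondences are unknown (the practical case), `icp_register`
alternates exact nearest-neighbour matching with the Kabsch fit:

* **Exact, deterministic matching.** Nearest neighbours are found by
  exhaustive search in compiled code with ties broken to the lowest target
  index. Determinism matters more here than asymptotics: clouds are a few
  thousand points, and an approximate index could make results depend on
  library versions.
* **Initialization is the identity.** Serial casts are digitized in one
  apparatus and the simulator reproduces comparably small pose offsets
  (up to $5^\circ$ / 5 mm); point-to-point ICP converges reliably from
  identity at that range, which the end-to-end tests exercise directly. No
  feature-based global initialization is attempted, and registration of
  nearly symmetric structures from large misalignments is out of scope.
* **Trimming.** A `trim_fraction` of the worst-matched points can be
  discarded from each fit (default 0.1 in the analysis configuration, for
  robustness to partial crown overlap; 0 in tests, where clouds overlap
  fully). The per-iteration mean fitting error is recorded and is
  non-increasing under a fixed trim policy; convergence is declared when
  it improves by less than `tol` (default $10^{-6}$ mm) and capped at
  `max_iter` (default 100). Non-convergence is reported as a flag, never
  an error.

The registration quality statistic is the **mean fitting error**: the mean
distance from each source point to its nearest target point. It is
directional (source to target) by definition; a symmetric average is
available via `symmetric = TRUE`.

## Calibration-plane check

Scanner accuracy is assessed by scanning a flat plate and fitting a plane.
"Least squares" is ambiguous here: regressing $z$ on $(x, y)$ minimizes
vertical residuals, which overstates the error of steeply tilted plates.
Since the quantity of interest is geometric distance to the plate,
`fit_plane` defaults to **orthogonal (total) least squares** — centroid
plus smallest principal direction — and reports the maximum absolute and
RMS deviations, with deviations taken as absolute before the maximum. The
regression variant is exposed for comparison; measured by geometric RMS it
can never win, and on anisotropic tilted clouds it loses distinctly.

## The synthetic scan series

No real scan series is bundled, so the generator is the ground truth for
every downstream stage. It emulates the study design, not tooth anatomy:

* **Crowns** are superellipsoid surfaces
  ($|x/a|^{2/e} + |y/b|^{2/e} + |z/c|^{2/e} = 1$, roundness $e = 0.8$,
  half-axes a few mm) — box-round solids with a closed-form implicit
  equation, so every sampled point can be verified against the surface it
  claims to lie on. Each structure uses ~1000 surface points (700 per
  reference crown), a deliberately sparse stand-in for real scans chosen
  to keep the full recovery suite fast at desk scale.
* **The arch** holds three movable teeth and a bilateral first-molar pair
  sharing one reference label — asymmetric enough for an unambiguous
  reference registration.
* **Motions** are screws with $\theta \in [0.5, 5]^\circ$ and
  $|t| \in [0.05, 0.5]$ mm per interval over five timepoints (T0–T4),
  matching the clinically reported magnitudes; axes pass within a few mm
  of the moving crown.
* **Scanner noise** is Gaussian with per-axis
  $\sigma = \text{step}/\sqrt{12}$ for steps $(0.01, 0.1, 0.01)$ mm — the
  variance-matched equivalent of uniform quantization at the scanner's
  stated axis resolutions. A pure quantization mode exists
  (`model = "quantize"`). The noise model is an assumption; the source
  hardware documents resolutions, not an error distribution.
* **Cast placement** is random: each timepoint gets a whole-scan pose
  perturbation uniform in $[0, 5]^\circ$ and $[0, 5]$ mm, which series
  normalization must remove. Note this applies to T0 as well, so reported
  axis geometry lives in T0's scanner frame; rotation angles and screw
  translations are invariant to that choice.
* **Determinism**: one global seed fans out to per-operation child seeds
  by a stable string hash of (seed, operation, label, timepoint);
  regeneration is bit-identical and generator calls never disturb the
  caller's RNG stream.

What passing recovery tests does **not** show: robustness to occlusal
anatomy and partial overlap from real segmentation, non-rigid crown wear
or restoration changes, scan-merge artifacts, or outlier structure beyond
Gaussian noise. The simulator validates the estimator chain, not the
scanner.

## Problem sizes and tolerances used by the test suite

The recovery suite decomposes 1000 random screws noise-free (machine
precision expected and asserted: $10^{-9}$ degrees/mm, axis line to
$10^{-7}$ mm); the optimality check runs 50 instances of up to 12 points
against the rotation-grid oracle; the end-to-end run uses the full
5-timepoint arch above (~4400 points per scan) with noise and pose
perturbations on, asserting every interval's $\theta$ within $0.1^\circ$
and $t$ within 0.02 mm, and the reference structure recovered as identity
within the noise floor. These sizes were chosen as the smallest that
exercise each property convincingly.

## Known limitations

* Point-to-point ICP only; no point-to-plane variant, no global
  initialization, no non-rigid registration.
* Tooth segmentation is taken from input labels; the package does not
  segment crowns.
* Instantaneous helical axes from velocity data, and smoothing/
  cross-validated axis estimators for noisy landmark trajectories, are out
  of scope — only the finite-displacement decomposition is implemented.
* Helical-axis position (not angle or translation) is intrinsically
  unreliable below about half a degree of rotation; the report flags but
  cannot repair this.

## A minimal worked run

```{r example}
layout <- arch_layout(n_points_tooth = 300, n_points_reference = 300)
sp <- screw_motion_spec(c(0, 0.3, 1), c(0, 22, 0), theta = 2.5, t = 0.15,
                        label = "central_incisor")
ser <- generate_series(layout, list(sp), n_timepoints = 2, seed = 11)
cfg <- analysis_config(c(T0 = "", T1 = ""),
                       reference_label = "first_molars",
                       tooth_labels = c("central_incisor", "canine"),
                       icp = list(trim_fraction = 0))
run_pipeline(cfg, scans = ser$scans)
```

The central incisor's row recovers the simulated $2.5^\circ$ /
$0.15$ mm screw; the unmoved canine is reported as degenerate (no
resolvable rotation) with a translation at the noise floor.
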