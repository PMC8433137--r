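---
title: "Registration-free navigation: models, simulator and accuracy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration-free navigation: models, simulator and accuracy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regfreenav)
```

## The problem

Intra-operative navigation in craniofacial surgery needs a rigid transform
$T_{reg}$ linking physical (tracker) space to pre-operative image space.
Conventionally $T_{reg}$ is measured in the operating room, by point-based
registration of bone-anchored fiducial screws or by surface matching of the
skin. Every such procedure costs time, is user dependent, and its error
propagates into every navigated measurement.

The registration-free workflow removes the intra-operative measurement
altogether. A splint seated on the maxillary dentition carries the dynamic
reference frame (DRF) in a pose that is fixed by design. Because the splint
is designed on the dentition extracted from the patient's own CT, the DRF
pose in image space is known *pre-operatively*:

$$T_{SPL \to BL} \;=\; T_{IPS \to BL}\, T_{SPL \to IPS},$$

where $T_{SPL \to IPS}$ is the designed DRF pose in the planning system's
image space and $T_{IPS \to BL}$ converts planning image coordinates (RAS)
into the navigation system's DICOM patient coordinates (LPS). Once the
splint is seated, $T_{SPL \to BL}$ *is* the registration.

## Coordinate frames and the header transform

All objects in the package carry a frame tag (`PATIENT`, `DRF`,
`IPS_IMAGE`, `BL_IMAGE`, `VOXEL`, or user-defined), and every composition,
inversion or application checks that frames chain before any numeric work.
Rigidity is enforced at construction ($\lVert R^\top R - I\rVert_\infty <
10^{-9}$, $\det R = 1$); the voxel-to-patient map is the one deliberately
affine transform, built from the DICOM plane equation (Image Position
Patient, Image Orientation Patient, pixel and slice spacing). Slice spacing
is taken from consecutive slice positions when a series is available;
Slice Thickness is only a single-file fallback, because it does not
reliably describe the reconstruction geometry.

For $T_{IPS \to BL}$ the package adopts the convention that the planning
frame is the RAS millimetre space anchored at the position of the first
voxel, giving

$$p_{BL} = \mathrm{IPP} + \operatorname{diag}(-1,-1,1)\, p_{IPS},$$

which reduces to the pure RAS/LPS flip when the volume origin coincides
with the patient origin. The $3\times3$ block of the flip is a proper
rotation (180° about $z$), so the chain stays rigid. Planning systems that
anchor their frame differently can inject their own convention by composing
`ras_lps_flip()`, `voxel_to_patient()` and a translation; nothing downstream
depends on the particular choice.

## Correcting the mandatory pre-registration

Navigation systems refuse to acquire coordinates without *some*
registration, so the workflow performs a throwaway pre-registration
$T_{reg}$ and corrects it afterwards. Acquired coordinates $c$ are mapped
back to the DRF,

$$c' = T_{reg}^{-1} c, \qquad c'' = T_{SPL \to BL}\, c',$$

and $c''$ is compared against the true target positions $l$ to give the
target registration error (TRE), the Euclidean distance per target. The
correction is implemented as the closed-form rigid inverse
$(R^\top, -R^\top t)$. A description of this correction as a matrix
*transpose* is only equivalent for a pure rotation — the transpose of a
homogeneous matrix with non-zero translation is not a transform at all —
and the package treats the inverse as the operative meaning; the
coincidence of the two readings at zero translation is unit-tested.

The central algebraic property, verified end-to-end in the tests, is that
$c''$ does not depend on $T_{reg}$: with exact seating and localization the
recalculated TRE is identically zero for *any* rigid pre-registration.
Whatever error the pre-registration carries cancels exactly.

## Baseline registrations

*Point-based*: the closed-form least-squares rigid fit (SVD of the
cross-covariance with determinant correction) of the five maxillary
fiducial screws, reported with its RMS fiducial registration error (FRE).
The determinant correction means mirrored inputs yield the best *proper*
rotation, never a reflection. The solution is checked in the test suite
against an independent numerical minimizer over the rotation group.

*Surface-based*: point-to-surface ICP. Correspondences are closest points
on mesh triangles (not nearest vertices, which bias toward coarse-mesh
vertices); the rigid update re-fits the original probe points to the
matched correspondences with the same closed-form solver, which makes the
RMS trace provably non-increasing. Iteration stops when the RMS change
drops below `tol` (default $10^{-6}$ mm) or at `max_iterations` (default
200); non-convergence is reported in the result rather than thrown,
because a partially converged pose is still a usable diagnostic.
Equidistant closest points resolve to the lowest face index for
determinism. An initial pose must be supplied: commercial systems seed
their surface matching in undocumented ways, and a generic global search
would claim more than the data support.

## The synthetic study

No cadaver data ship with the package, so a generator reproduces the
*structure* of the accuracy experiment: five specimens, two tracking
techniques (optical, electromagnetic), bone-anchored/surface-based/
registration-free arms (surface-based under EM only), two observers, five
repetitions, fourteen targets — 3500 potential records, of which four
registration-free acquisitions are dropped as missing (a fixed,
deterministic list, so the bookkeeping is reproducible), leaving 3496 with
1396 registration-free.

Each phantom places five fiducial screws in a $\sim$40 × 22 mm maxillary
patch with under 5 mm of craniocaudal spread — deliberately near-coplanar,
as clinical screw placement along the alveolar process is — and fourteen
targets at the named cranial landmarks with lever arms of roughly 40–180 mm
from the splint centroid (arithmetic mean of the splint vertices). Small
seeded jitter emulates specimen variation. The skin for ICP is an ellipsoid
with Gaussian protrusions (nose, brows, chin, one ear, plus low-amplitude
texture); the protrusions are what make surface matching well conditioned,
and the mesh claims nothing anatomical beyond scale and asymmetry.

Noise enters through four configurable sources, all isotropic Gaussians:
per-technique fiducial/surface localization (defaults 0.25 mm optical,
0.30 mm EM per axis), splint seating (0.2° / 0.3 mm per axis, applied in
the DRF frame), pointer-tip localization at targets (0.15 mm per axis), and
the coarse ICP starting pose (2° / 2 mm). The study these defaults emulate
reports only end-to-end error, so the decomposition is configuration, not
inference; the defaults were fixed once so that end-to-end TRE lands in the
1–2 mm range typical of craniofacial navigation, and they are not fitted to
any published table. Randomness is stratified: each session's stream is
seeded by a stable hash of its metadata tuple, so datasets are identical
regardless of enumeration order and observers get genuinely independent
substreams.

```{r, eval = FALSE}
study <- simulate_study(study_design(), phantom_seeds = 1L, noise_model())
nrow(study)                                    # 3496
proportion_above(study, 2)                     # fraction of TRE > 2 mm
```

What passing tests on this generator do and do not show: they verify the
transform algebra, the cancellation property, the registration solvers and
the statistical pipeline on data with exactly known truth. They cannot
validate the noise magnitudes against real tissue, tracker distortion, or
splint mechanics — the simulated group differences are properties of the
configured error budget, not findings about hardware.

## TRE theory as an oracle

For point-based registration with isotropic fiducial localization error
(FLE), the expected squared TRE at target $r$ follows the standard
first-order result

$$E[\mathrm{TRE}^2(r)] = \frac{\mathrm{FLE}^2}{N}\left(1 + \frac{1}{3}
\sum_{k=1}^{3} \frac{d_k^2}{f_k^2}\right),$$

with $d_k$ the target's distance from the $k$-th principal axis of the
fiducial configuration and $f_k$ the RMS fiducial distance from that axis.
`predict_tre_point_based()` implements it, and the simulator is required to
reproduce it within 3% over 2000 Monte-Carlo sessions at five lever arms.
That comparison is run at a localization SD of 0.15 mm per axis: the
formula is a first-order expansion, so its role as an oracle is in the
regime where the FLE is small against the fiducial spread (here the
craniocaudal spread is only a few mm — exactly the near-coplanarity that
makes TRE grow with distance from the fiducial centroid, the mechanism the
check exercises).

## The accuracy model

TRE distributions are right-skewed; their square root is close to normal
(the package's distribution summaries report skewness on both scales). The
analysis therefore models

$$\sqrt{\mathrm{TRE}} \sim \mathrm{distance} \times \mathrm{technique}
\times \mathrm{method} + (1 \mid \mathrm{cadaver}),$$

fit by REML with lme4, reference category bone-anchored registration under
optical tracking. The distance covariate is each target's distance to the
splint centroid, centered at the mean distance of the infraorbital-rim
targets, so the intercept is the expected $\sqrt{\mathrm{TRE}}$ *at the
infraorbital rim* — a clinically meaningful anchor — rather than at the
splint. Surface-based registration exists only under EM tracking, so the
full-interaction model matrix is rank deficient; the aliased columns are
dropped and named in the result instead of silently estimated. The source
study does not state its random-effects structure or estimator, so the
package defaults to the natural grouping (random intercept per specimen,
REML) and exposes crossed observer/target intercepts and ML as options
rather than presenting either choice as ground truth; t-values are
estimate/SE without small-sample correction, matching the columns such
studies report.

`derive_group_lines()` recalculates the fixed-effects table into one
intercept/slope line per technique-method cell by summing the applicable
terms — an exactly linear readout, so it applies equally to a fitted model
and to a published estimate table. The package ships the published
estimates of the cadaver accuracy study
(`published_study_estimates()`); feeding them through the readout
reproduces the study's reported group intercepts (0.97, 1.16, 0.91, 1.10,
0.84 $\sqrt{\mathrm{mm}}$) at their printed precision, while slopes are
only recoverable to ±0.001 because the published distance terms are
rounded to three decimals.

```{r}
derive_group_lines(published_study_estimates())
```

## Numerical choices and degenerate inputs

* Rigidity tolerance $10^{-9}$, direction-cosine tolerance $10^{-6}$;
  rigid inverses computed as $(R^\top, -R^\top t)$, never by generic
  inversion.
* Point-based registration demands $\geq 3$ fiducials and rejects collinear
  configurations (second singular value $\leq 10^{-6}$ of the first);
  collinearity, not coplanarity, is the degeneracy — coplanar fiducials
  registrate fine, they just extrapolate badly, which is the study's
  distance effect.
* A constant response short-circuits the mixed model to its degenerate
  answer (intercept = the constant) instead of letting the optimizer chew
  on a zero-variance problem.
* Histogram bins by Freedman–Diaconis, KDE bandwidth by Silverman's rule;
  groups of one record report no density. Threshold proportions use strict
  inequality and never fabricate a zero for an empty group.
* Simulated ICP sessions stop at $\Delta\mathrm{RMS} < 10^{-5}$ mm within
  100 iterations: with 0.3 mm localization noise the residual plateau sits
  orders of magnitude above the solver's default $10^{-6}$ tolerance, and
  past the plateau further iterations only slide tangentially. The solver
  itself keeps the stricter default for noise-free use.
* Problem sizes in the test suite (2000 Monte-Carlo sessions for the theory
  check, the full 3496-record study for parameter recovery, 100 random
  problems for the registration oracle) were chosen as the smallest sizes
  at which the stochastic tolerances (3%, 3 SE) are comfortably resolved.

## Known limitations

* The simulator's error budget is plausible, not estimated; in particular
  it contains no mechanism for the large optical-tracking error the
  physical study observed with splint-borne reference frames (material
  flexion is not modeled), so simulated optical and EM registration-free
  arms differ only through their configured localization noise.
* One splint/DRF design is shared by both simulated techniques.
* The planning-frame convention of a specific vendor may differ from the
  documented RAS-at-first-voxel choice; the construction is exposed so it
  can be swapped.
* ICP is plain point-to-point with optional trimming; no point-to-plane
  acceleration, no global initialization.
* DICOM support is header-only, explicit-VR little-endian, geometry tags
  only — enough for the transform chain, not a general DICOM reader.
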