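---
title: "Measuring and comparing molar macrowear: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing molar macrowear: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molarwear)
```

## The problem

During the occlusal portion of the chewing cycle (the *power stroke*),
opposing molars slide past one another in near contact, first closing
upward and medially toward maximum intercuspation (phase I), then moving
medially and away from it (phase II). Abrasive particles trapped between
the surfaces polish planar *wear facets* at specific sites on the crown.
The geometry of those facets — how much area each power-stroke phase
occupies and how steeply each facet is inclined — is a durable record of
how an individual chewed. Comparing facet-area compositions, facet dip
angles and overall occlusal relief between groups of individuals therefore
tests whether their masticatory kinematics differed, for example between
populations eating coarse versus heavily processed staple foods.

`molarwear` implements that comparison end to end on triangle meshes of
lower-molar crowns: the static measurements, a simplified timestep
collision simulation of the power stroke, the compositional statistics, and
synthetic-data generators that make every stage testable without scan data.

## Static measurements

**Coordinate frame.** All measurements are made in an occlusal frame: the
*cervical reference plane* is the total-least-squares ("gaussian best-fit")
plane through mesh vertices within ±0.2 mm of a user-supplied polyline
traced around the tooth cervix; its normal, oriented toward the crown bulk,
becomes +z, and a mesio-distal hint direction becomes +x. Total least
squares is computed from the eigen-decomposition of the vertex covariance;
this is the standard metrology meaning of a gaussian best-fit plane, and it
is invariant to rigid motions (tested to 1e-8).

**Facet areas and composition.** Wear facets are supplied as per-face
labels (`face_index,facet_label` CSV, 0-based on disk). A *facet catalog*
maps labels to power-stroke phase classes: buccal phase I (BPI), lingual
phase I (LPI), phase II (PII), and tip-crush areas. The default catalog
follows the conventional molar facet numbering (1–4 → BPI, 5–8 → LPI,
9–13 → PII) and ships as an overridable JSON data file, because the
numbering is conventionally cited rather than printed and projects may remap
it. Tip-crush areas are produced by vertical puncture-crushing rather than
guided sliding, so they are measured but excluded from the
(BPI, LPI, PII) composition. Because larger teeth have larger facets at the
same wear stage, areas enter the analysis only as proportions of the total
facet area; the composition is invariant to uniform scaling of the mesh
(tested at 1e-6).

**Dip angle.** A facet's dip is the angle between its own best-fit plane
and the cervical plane, folded into [0°, 90°]. Per-phase tooth means are
unweighted means over the phase's facets; an area-weighted variant is
available behind a flag (`area_weighted_dips`), since the literature does
not state which was used — the unweighted default is the conservative
reading of "mean dip angle for each wear facet type".

**Occlusal relief index (ORI).** The cervical plane is translated along
its normal to the deepest point of the central fossa, the crown is cut
there, and ORI is the 3D surface area above the cut divided by the 2D
cross-section area at it (1.0 = perfectly flat table; a hemisphere gives
exactly 2). The 2D area is evaluated by Stokes' theorem as the
plane-projected signed area of the clipped above-plane surface, which
equals the area enclosed by the cut contour for consistently oriented
meshes and remains exact when the cut passes exactly through boundary
vertices (e.g. a dome cut at its open equator). The contour is still
assembled by chaining intersection segments at 1e-6 mm tolerance, and an
unclosed chain is a hard error naming the gap — silent hole-dropping would
bias areas.

**Fossa auto-detection.** When no fossa point is given, the detector takes
the lowest vertex among occlusally-facing faces, excluding vertices within
0.3 mm (in-plane) of the crown outline so the cervical margin can never be
selected. This heuristic is appropriate for molar-like crowns with an
interior basin; for open primitives such as a hemisphere the caller passes
the fossa point explicitly, which always wins.

## The power-stroke simulation

The dynamic module advances the lower mesh along a waypoint trajectory in
steps of at most 0.05 mm (the canonical timestep for this kind of
simulation), detecting contacts with the upper model at every step.

* **Contact.** A lower face is in contact when its centroid's signed
  distance to the upper surface is below ε = 0.02 mm; interpenetration
  deeper than 0.005 mm triggers resolution. Neither tolerance is published
  for the original software; these defaults sit well below facet dimensions
  (~1 mm) and above mesh discretisation noise, and both are configurable.
* **Signed distances** use an exact closest-point query (compiled C++)
  with angle-weighted pseudonormals at edges and vertices, so the
  inside/outside decision is stable at creases. A closest point on an open
  mesh boundary means the query point is beyond the surface's silhouette,
  where a one-sided sign is meaningless; such points are reported outside.
* **Resolution.** If a step penetrates beyond tolerance, the advance is
  bisected back along the step direction to 80% of the tolerance (the 20%
  headroom prevents a pose resting exactly at the tolerance from
  deadlocking), then one tangential slide is attempted: the leftover motion
  projected onto the mean plane of the faces that actually blocked the step
  (faces merely within the contact threshold do not steer the slide). This
  is a documented simplification of full multi-contact rigid-body
  deflection; rotation is out of scope. A step that cannot move at all
  without violating tolerance is flagged `jammed`; a contact step that
  makes no progress is flagged `stalled`; either ends the current waypoint
  segment but never aborts the run.

The simulation is deterministic: identical inputs give bit-identical
timelines, and halving the step length changes the integrated contact-area
trace by less than 5% on the synthetic test pair.

## Synthetic data: the stated world

**Crown meshes.** `make_synthetic_molar()` builds a height field over a
disk: an occlusal table, four Gaussian cusps, a central-basin depression,
and a rim that ramps to an exact z = 0 collar at the cervix (the collar
guarantees that a fossa-height cross-section can never exit through the
open mesh boundary). Facets are carved as planar disk patches of known
strike, dip and radius; grid vertices near a patch rim are snapped onto the
rim circle so the labeled faces tile the patch disk up to an
inscribed-polygon error of order (h/r)². Ground truth (analytic dip,
patch area πr²/cos dip) accompanies every mesh; mesh-measured areas agree
within 2% at the default 120×120 resolution and within 0.5% at double
resolution.

**Antagonist pairs.** `make_antagonist_pair()` does *not* build a full
complementary upper crown. A rigid offset-complement cannot execute phase
II at all — every non-facet region collides by construction — and its
concave pockets make one-sided signed distance ill-defined. Instead the
upper model consists of the *antagonist counterpart facets*: each lower
facet patch duplicated at a 0.005 mm normal gap with its normal facing the
lower tooth. This mirrors the anatomical fact that every wear facet has a
matching facet in the opposing arch, and it makes contact timing exactly
predictable: during a straight approach at angle φ the normal gap of a
facet of dip θ closes at rate sin(φ − θ) per mm, so the pose of first
contact is known in closed form and is asserted in the tests. The
preindustrial trajectory style approaches 3° above the BPI dip (long,
lateral, slow-closing) and appends an extended phase II slide along the PII
facet plane; the industrial style approaches 20° above the BPI dip (short,
steep) with a brief phase II. The pair's molar uses a two-cusp schematic
with lifted facet planes so that no crown relief crosses a facet plane
along the trajectory — the contrasts between the two styles (longer
timeline, more exclusively-phase-II steps for the preindustrial style) are
then properties of the constructed kinematics, not accidents of meshing.

What a green dynamic test establishes is therefore that the simulator
reproduces *constructed* contact sequences faithfully; it does not certify
equivalence with the original closed-source collision engine, whose
resolution algorithm is unpublished.

**Cohorts.** `sample_cohort()` draws per-individual records with the
statistical structure the analysis assumes: compositions ilr-normal around
a group center, dips and ORI normal, covariates multinomial, all fully
seeded. The defaults are the study's scale: groups of 130 (pre-industrial)
and 103 (industrial), the published group mean compositions
(30.88/39.84/29.27% and 26.25/34.05/39.69%), the published per-phase dip
and ORI summaries, and demography frequencies from the published tables.
The ilr noise is diagonal with σ = 0.47 per coordinate. This value is
calibrated once, from the reported PERMANOVA partition: a residual sum of
squares of ~101.6 on 231 degrees of freedom over two ilr coordinates
implies a per-coordinate residual SD of √(101.6/231/2) ≈ 0.47, which in
turn places the simulated R² near the reported 0.08. (A larger σ of 0.65,
considered during design, yields R² ≈ 0.04 and is inconsistent with the
reported partition.) The generator emulates the *distributional* shape of
real data, not its biology: no within-group covariance structure, no
wear-stage dependence, no inter-facet correlation — so cohort-level green
tests validate the statistical pipeline, not anatomical realism.

## Statistics

* **ilr transform.** Compositions are mapped to R² with the orthonormal
  balance basis of the sequential binary partition {BPI} | {LPI, PII},
  then {LPI} | {PII}. Because the ilr is an isometry between Aitchison
  and Euclidean geometry (tested against a direct clr-distance oracle at
  1e-10), all distance-based results are independent of the basis choice,
  so it does not matter that the original analysis never printed its basis.
  Zero components are replaced multiplicatively at 0.1% of the smallest
  observed nonzero share before any log-ratio, with a logged message.
* **PERMANOVA.** One-way, from first principles: total and within-group
  sums of squared inter-point distances, pseudo-F, and a label-permutation
  p-value with the add-one estimator (1 + #{F ≥ F_obs})/(1 + n_perm),
  counting ties as exceedances (conservative). The permutation loop is
  vectorised through one BLAS multiply per group. Correctness is checked
  three ways: against `vegan::adonis2` on the observed statistic, against
  exhaustive enumeration of all 70 assignments at n = 4+4, and by a type-I
  calibration (500 null replicates land in [0.03, 0.07] at α = 0.05).
* **Dispersion homogeneity.** Principal-coordinate embedding (with the
  standard real/imaginary correction for negative eigenvalues), distance of
  each point to its own group centroid — centroids, not spatial medians —
  one-way F on those distances, permutation p. Verified against
  `vegan::betadisper(type = "centroid")`.
* **Pairwise PERMANOVA** over all group pairs, Benjamini–Hochberg adjusted
  by default (configurable to Bonferroni or none).
* **Welch t-tests** accept raw vectors or (mean, SD, n) summaries and give
  identical results either way, so printed summary tables can be re-analysed
  directly. Cohen's d uses the pooled SD; its 95% CI uses the large-sample
  normal approximation se(d) = √((n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂−2))), which
  reproduces the reported intervals to two decimals. Shapiro–Wilk (base R's
  implementation of the standard published algorithm) and a median-centered
  Levene test are provided as advisories and never gate the t-test.

One reported value resists recomputation: the phase II Welch degrees of
freedom print as 195.23 where the rounded printed summaries imply ≈197.5.
Rounding of the SDs is the presumed cause; the package reports its computed
value and the acceptance suite asserts t and d (stable under rounding) but
not that df.

## Numerical choices and degenerate inputs

* Mesh cleaning at load merges vertices within 1e-6 mm and drops zero-area
  faces, reporting counts; all downstream math assumes non-degenerate
  triangles.
* Cross-sections treat faces within 1e-9 (scaled) of the plane as above it,
  so a flat plate cut at its own height has ORI exactly 1.
* A plane entirely above the mesh yields zero areas with a warning, not an
  error; an unclosed intersection contour is an error.
* Boundary compositions (a zero part) are flagged on measurement and
  replaced only at the log-ratio step.
* Every stochastic routine takes an explicit seed and records it in its
  result object; generators are bit-reproducible under a fixed seed.

## Limitations

* No automatic facet segmentation: facets are inputs, as in the manual
  workflow the measurements mirror.
* The collision model is translation-only with a single-contact-plane
  deflection heuristic; jaw rotation, TMJ constraints, force modelling and
  wear propagation are out of scope.
* Curvature-based topographic metrics (DNE, OPCR), scan registration and
  mesh repair beyond basic cleaning are out of scope.
* The supplementary per-individual dataset of the source study is not
  shipped; study-scale claims are validated on the calibrated synthetic
  cohort instead, and the external-CSV column-mapping loader is provided
  for users who obtain such data.
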