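# molarwear

Occlusal fingerprint analysis of molar macrowear in R.

`molarwear` is for bioarchaeologists, dental anthropologists and
morphometricians who study chewing behaviour from the wear facets on molar
crowns. During the masticatory power stroke, opposing teeth slide in near
contact: phase I (closing toward maximum intercuspation) and phase II
(medial movement after it) each polish planar wear facets at characteristic
sites. The relative areas of buccal phase I (BPI), lingual phase I (LPI)
and phase II (PII) facets, their dip angles against the cervical reference
plane, and the occlusal relief index (ORI) of the crown together summarise
how an individual chewed — and differ systematically between groups eating
coarse versus heavily processed diets.

The package implements, from triangle meshes to final tables:

* **Mesh geometry** — STL/PLY/OBJ I/O, total-least-squares ("gaussian
  best-fit") plane fitting, occlusal-frame alignment from a cervical band
  (±0.2 mm), surface areas, and plane cross-sections (3D area above the
  plane and the 2D area enclosed by the cut contour).
* **Static measurements** — phase-classified facet areas (tip-crush areas
  excluded from the composition), wear-area compositions, facet dip angles
  folded to [0°, 90°], and ORI = 3D occlusal area above the central fossa
  plane ÷ 2D crown cross-section there.
* **Dynamic simulation** — a timestep collision simulation of the power
  stroke: the lower mesh advances 0.05 mm per step along a waypoint
  trajectory, contacts are detected by signed closest-point distance
  (compiled C++, pseudonormal sign test), interpenetration is resolved by
  bisection plus a tangential slide, and per-phase contact areas are
  recorded as a timeline.
* **Compositional statistics** — isometric log-ratio transform (balance
  basis {BPI}|{LPI,PII}, {LPI}|{PII}), compositional centers, ternary
  coordinates, one-way and pairwise PERMANOVA (9999 permutations,
  add-one p), permutation test of multivariate dispersion homogeneity,
  Welch t-tests with pooled Cohen's d and its CI, Shapiro–Wilk and Levene
  advisories, Bonferroni-adjusted α. For a two-group composition dataset
  with groups `g`:

  F = (SS_between / (a−1)) / (SS_within / (N−a)),  R² = SS_between / SS_total

  computed on Euclidean distances of the ilr coordinates.
* **Synthetic data** — parametric four-cusp molar crowns with carved
  planar facets of known dip and area, antagonist pairs with closed-form
  contact timing, and seeded cohort tables at the published study scale
  (n = 130 pre-industrial vs 103 industrial, group centers
  30.88/39.84/29.27% and 26.25/34.05/39.69%).

## Worked example

```r
library(molarwear)

# a synthetic labeled molar: mesh + per-face facet annotation + ground truth
sm <- make_synthetic_molar(molar_spec())
pa <- phase_areas(sm$mesh, sm$annotation, default_facet_catalog())
round(pa$class_totals, 2)
#>       BPI       LPI       PII TIP_CRUSH
#>      4.12      4.44      2.69      0.63
round(wear_composition(pa), 4)
#>    bpi    lpi    pii
#> 0.3665 0.3946 0.2389

cerv <- plane3d(c(0, 0, 1), 0)          # cervical plane in the occlusal frame
ori <- occlusal_relief_index(sm$mesh, cerv)
# ORI = 1.580 at the auto-detected fossa (0.00, 0.00, 0.81)

# study-scale cohort and the group comparison
tab <- sample_cohort(cohort_spec(seed = 1L))
y   <- ilr_transform(as.matrix(tab[, c("bpi_pct", "lpi_pct", "pii_pct")]) / 100)
permanova_oneway(dist(y), tab$group, n_perm = 9999, seed = 1)
#> One-way PERMANOVA
#>   SS between 8.1955 (df 1), SS within 100.5372 (df 231)
#>   pseudo-F = 18.8305, R2 = 0.0754, p = 0.0001 (9999 permutations)

# printed summary tables can be re-analysed directly
welch_t_test(c(mean = 29.81, sd = 9.59, n = 103),   # industrial BPI dips
             c(mean = 22.79, sd = 7.18, n = 130))   # pre-industrial
#> Welch two-sample t-test
#>   t = 6.182, df = 184.02, p = 3.981e-09
#>   Cohen's d = 0.843, 95% CI [0.573, 1.112]
```

The PERMANOVA pseudo-F ≈ 18.8 with R² ≈ 0.075 says that period membership
explains ~7.5% of the compositional variance — a highly significant but
modest group separation, as expected from the generator's calibration. The
Welch test reproduces the published buccal phase I comparison (t = 6.19,
df = 183.97, d = 0.84) from its printed summaries alone.

A power-stroke simulation of a synthetic antagonist pair:

```r
pair <- make_antagonist_pair("preindustrial")
tl <- simulate_power_stroke(pair$lower, pair$upper, pair$annotation,
                            default_facet_catalog(), pair$trajectory,
                            simulation_config())
timeline_summary(tl)$exclusive_pii_steps   # 12 exclusively-phase-II steps
```

The preindustrial-style trajectory (long, lateral approach; extended
phase II) produces 35 timesteps with 12 exclusively-phase-II contact steps;
the industrial style (short, steep) produces 13 and 2.

## Command line

```sh
exec/molarwear synth cohort --seed 1 --out cohort.csv
exec/molarwear stats --metrics cohort.csv --group group --seed 1 \
    --permutations 9999 --out-dir results
exec/molarwear synth pair --style preindustrial --out-dir pairdir
exec/molarwear simulate --pair-dir pairdir --out-dir simout
```

External metrics CSVs with different headers are ingested via
`--column-map map.json` (a JSON object mapping the package's column names
to the file's).

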