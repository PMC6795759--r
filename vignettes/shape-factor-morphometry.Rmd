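---
title: "Shape-factor muscle morphometry: model, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-factor muscle morphometry: model, phantoms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmorph)
```

## The measurement model

A muscle segmented in transverse MRI slices is represented as a *contour
stack*: on each slice at axial position $z$ (millimetres along the shank
axis, increasing distal → proximal) one or more simple polygons outline
the muscle boundary, with optional hole polygons for excluded interior
structures (vessels, aponeuroses). The anatomical cross-sectional area
(ACSA) on a slice is the sum of outer polygon areas minus hole areas,
each computed by the shoelace formula. From the resulting ACSA profile
$A(z)$ the pipeline derives:

* **muscle length** $L$ — the axial distance between the two marginal
  segmented slices (no extrapolation beyond them: the segmentation is
  assumed to cover the muscle);
* **measured volume** $V = \int A(z)\,dz$ by the composite trapezoidal
  rule over the sampled slices. The trapezoid is exact for constant and
  linear profiles and second-order accurate otherwise; at the working
  2 mm slice interval its error is orders of magnitude below segmentation
  uncertainty. Non-uniform slice grids are accepted;
* **ACSA\_max and its position** — the raw maximum over sampled slices
  (no smoothing or sub-slice interpolation, since no such procedure is
  part of the protocol this mirrors), with ties resolved to the most
  distal tied slice, and the position expressed as percent of shank
  length from the calcaneal tuberosity (0%) to the tibial plateau
  (100%);
* **shape factor** $p = V/(A_{\max} L)$ — equivalently the mean-to-max
  ratio of the ACSA profile. A cylinder has $p = 1$, a cone $1/3$, a
  spheroid $2/3$; real triceps-surae muscles fall near $0.48$–$0.57$.

The simplified volume assessment inverts this definition with a
population-mean factor: $V_{\text{est}} = \bar p \times A_{\max} \times
L$. Built-in tables provide the older-adult factors
(SOL 0.484, GM 0.556, GL 0.568) and the young-adult reference factors
(0.496, 0.592, 0.569).

Internally all coordinates are millimetres; reported morphology uses cm,
cm², cm³. Self-intersecting polygons are rejected rather than repaired:
silent repair could corrupt areas, and a failed validation points at the
offending slice.

## Synthetic phantoms

Because per-subject segmentation data of the motivating cohort are not
publicly deposited, validation rests on phantoms whose ground truth is
known by construction.

**Analytic solids.** `make_analytic_solid()` builds cylinders, cones and
prolate spheroids as stacks of regular polygons whose vertex radius is
corrected so each polygon's area equals the analytic section area
*exactly* — the in-plane discretization therefore contributes no error,
and the axial discretization is the only approximation the oracle tests
probe. Sections that vanish analytically (cone apex, spheroid poles) are
kept as minimal 0.01 mm² polygons, contributing under 0.1 mm³ to any
realistic volume.

**Parametric muscles.** Real triceps-surae ACSA profiles are smooth and
unimodal with muscle-specific peak positions. The generator models the
profile along the normalized muscle axis $t \in [0,1]$ as a beta kernel,

$$A(t) \propto t^{\alpha-1}(1-t)^{\beta-1}, \qquad \alpha, \beta > 1,$$

the minimal two-parameter unimodal family in which the mode
($\frac{\alpha-1}{\alpha+\beta-2}$) and the mean-to-max ratio (the
continuous shape factor) are independently controllable — precisely the
two quantities the pipeline must recover. This is a modelling choice, not
a claim about muscle physiology. Given a target $(p, \text{mode})$,
`solve_profile_parameters()` walks the line $\alpha = 1 + s\,m$,
$\beta = 1 + s(1-m)$ (which pins the mode at $m$ exactly) and solves for
$s$ by 1-D root finding: along that line the mean-to-max ratio
$B(\alpha,\beta) / \left(m^{\alpha-1}(1-m)^{\beta-1}\right)$ decreases
monotonically from 1 to 0, so any $p \in (0,1)$ is attainable and
infeasible requests fail loudly rather than being clipped.

Sections are circles of the prescribed area: since only areas enter every
measured quantity, in-plane realism is irrelevant and is not attempted.
The sampled profile is rescaled so the *sampled* maximum equals the
requested ACSA_max and the extent equals the requested length, so length
and ACSA_max are recovered exactly and the shape factor to well within
0.01 at 2 mm spacing. One consequence of reading the raw sampled maximum:
the ~10⁻⁵ residual in the recovered factor is not monotone under grid
refinement (the grid phase relative to the mode shifts), although it
shrinks on average; the tests therefore assert the documented tolerance at
each spacing rather than strict monotonicity.

## Cohort generation

`make_cohort()` draws per-subject muscle length, ACSA_max, shape factor
and peak position independently from truncated normal distributions
(truncation at ±3 SD and at feasibility bounds, rejection sampling with
bounded retries). The built-in `preset_older_female_ts()` uses the
cohort means ± SDs of a 21-subject older-female study population:

| muscle | L (cm) | ACSA_max (cm²) | p | peak (% shank) |
|---|---|---|---|---|
| SOL | 30.8 ± 0.7 | 24.0 ± 4.4 | 0.484 ± 0.027 | 59.3 ± 3.5 |
| GM  | 24.7 ± 1.4 | 13.1 ± 2.3 | 0.556 ± 0.028 | 75.0 ± 4.3 |
| GL  | 21.2 ± 2.1 | 7.6 ± 1.2 | 0.568 ± 0.049 | 80.6 ± 5.1 |

Only marginal moments are published, so no covariance is imposed; a
consequence is that the cohort mean volume approximates the product of
the means (e.g. GM: $0.556 \times 13.1 \times 24.7 \approx 179.9$ cm³,
within half a percent of the reported mean measured volume).

Geometric placement is the one genuinely open design area. The shank
frame defaults to 380 mm (a representative calcaneal-tuberosity-to-
tibial-plateau distance for women of ~165 cm stature). The soleus —
anatomically the deep, distally extending muscle — has its distal end
fixed at 5% shank; both gastrocnemii end proximally at the tibial
plateau. The profile mode is then whatever places the drawn peak
position at its drawn percent of shank length; across the preset's ±3 SD
ranges every draw yields a feasible interior mode. All randomness flows
from the single explicit seed, and the caller's RNG state is restored
afterwards.

### What the phantoms do and do not show

Passing phantom-based tests demonstrates that the geometry, integration
and statistics are implemented correctly and that parameter recovery is
unbiased at the precision stated. The phantoms do **not** emulate
segmentation error, partial-volume effects, inter-rater variability,
non-circular or lobulated cross-sections, or correlations between muscle
size and shape — so agreement statistics computed on synthetic cohorts
characterize the method under the stated distributional assumptions, not
the full error budget of a real MRI study. In particular, the published
relative RMS differences between measured and estimated volume (4.5–7.9%
within-cohort) depend on within-subject covariances that the independent
draws cannot reproduce, and are deliberately not asserted.

## Statistical conventions

* **Relative RMS difference** (default): RMS of per-subject relative
  differences, $100\sqrt{\tfrac1n \sum ((V_e - V_m)/V_m)^2}$. The
  alternative normalization (RMS of absolute differences over the cohort
  mean) is available via `method = "pooled"`; the published percentages'
  exact normalization is not recoverable, so neither is claimed to
  reproduce them.
* **R²**: squared Pearson correlation. This scale-invariant definition is
  the one under which swapping one cohort's mean factor for another's
  leaves R² unchanged — the behaviour reported for the two estimation
  variants, which share per-subject ACSA_max and length.
* **Normality**: the Kolmogorov–Smirnov check is applied to the paired
  differences with the Lilliefors correction (`nortest::lillie.test`),
  the standard applied reading when the normal's parameters are estimated
  from the sample. The Lilliefors statistic needs n ≥ 5; below that the
  normality p is reported as `NA`.
* **Paired test**: two-sided paired t test at α = 0.05 (default);
  constant differences are reported as degenerate rather than tested.
* **ANOVA**: fixed-effects one-way ANOVA with muscle as factor and
  Bonferroni-adjusted pooled-SD pairwise t tests. Muscles measured in the
  same subjects are strictly repeated measures; the independent-groups
  analysis is retained deliberately for comparability with the
  conventional analysis in this literature, and every report carries a
  note saying so. Sample (n−1) SDs are used throughout, and cohort
  factors are unweighted arithmetic means of individual factors.

## Numerical choices and degenerate inputs

* Winding is normalized to counter-clockwise on ingestion; normalization
  never changes absolute area. Polygons with repeated closing vertices
  are accepted; degenerate (zero-area) and self-intersecting polygons
  are errors naming the slice.
* Tied ACSA maxima resolve to the most distal slice, making the peak
  position deterministic.
* `mask_to_contours()` traces label boundaries by marching squares at the
  0.5 iso-level in physical coordinates (voxel-centre z positions
  $(k-\tfrac12)\,dz$), pads slices so regions touching the array edge
  close, classifies nested boundaries by point-in-polygon parity, and
  matches voxel-count areas to within 2% for convex regions of ≳100
  voxels with error decreasing as voxels shrink.
* The profile-parameter solver brackets its root in $s$ and refuses
  infeasible $(p, \text{mode})$ pairs; `make_cohort()` redraws infeasible
  parameter combinations up to 100 times before failing.
* Problem sizes in the shipped tests were chosen to keep the full suite
  in the minutes range: closure checks run on 21-subject cohorts,
  distribution-recovery checks on a 1000-subject cohort (Monte-Carlo SE
  of the mean factor ≈ 0.0009, comfortably inside the ±0.01 recovery
  band), and the cross-age comparison on 100 independent 21-subject
  cohorts.

## Known limitations

* The young-vs-older comparison at n = 21 has ~50% power for the soleus
  (printed effect 0.012 vs SD 0.027) and essentially none for GL (effect
  0.001 vs SD 0.049) — the GL sign is a coin flip at this sample size, so
  Monte-Carlo mirrors of the cross-age result are reliable only for GM.
* Muscle length is the axial marginal-slice distance, not a curved
  centroid path; for the shank muscles considered the difference is
  negligible, but the measure would understate strongly curved muscles.
* No DICOM ingestion, no registration, no automatic segmentation, and no
  pennation/fascicle/PCSA computation — contours are the interface.
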