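---
title: "Methods: the arcial construction and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the arcial construction and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The construction

A lateral cephalometric radiograph (LCR) is digitized into named 2-D
landmarks. After magnification calibration against a 10-mm ruler and
averaging of non-superimposed bilateral points, all coordinates are
expressed in a standardized frame: sella (S) at the origin, the +x axis
along the "true horizontal" (the S–N line rotated 7.0° clockwise, so
nasion sits 7° above the x axis), +y superior, units mm. The 7° constant
is the conventional inclination of the anterior cranial base relative to
the true horizontal; it is a parameter of `build_frame()`.

Four "horizontal" planes are built in this frame:

* **mandibular (MdP)** — through gonion (Go) and menton (Me);
* **occlusal** — through the midpoint of the upper/lower central incisor
  edges (U1, L1) and the midpoint of the upper/lower first-molar mesial
  cusps (U6, L6). The source analysis names the four tooth landmarks but
  not the fitting rule; we use the functional bisected occlusal plane
  because it degrades gracefully to the ideal closed-occlusion case
  (U1 = L1, U6 = L6);
* **palatal** — through the anterior and posterior nasal spines (ANS,
  PNS);
* **basal** — the anterior cranial base proxy: the S→N direction anchored
  at Si, the most inferior point of the sella turcica. "Parallel to the
  axis of the upper contour of the anterior cranial base and tangent to
  the inferior border of the sella" is operationalized as a direction
  (S–N) plus a single digitizable tangent-contact point (Si).

In a well-proportioned face the four planes converge at a single point O
posterior to the occiput. Two circles centered at O — the *anterior arc*
with radius O–ANS and the *posterior arc* with radius O–Sp — then pass
through pogonion (Pog), U1, ANS and N, and through Go and Sp,
respectively. Real faces never converge exactly, so a theoretical O is
used. The commercial software behind the original analysis derives O from
"an averaged angle of the four marked horizontal planes" without
disclosing the algorithm; this package therefore offers two explicit,
documented surrogates and records which was used:

* `least_squares` (default): the point minimizing the sum of squared
  perpendicular distances to the four planes, via closed-form 2×2 normal
  equations. It coincides with the exact point under concurrency, is
  unique whenever the planes are not all parallel, and its rms residual
  is a natural "non-convergence" score that is invariant under rigid
  motion of the input.
* `pairwise_mean`: the centroid of all pairwise plane intersections
  (pairs within 10⁻⁷ degrees of parallel are skipped), offered for
  sensitivity analysis.

The `mean_direction()` kernel (circular mean of undirected directions via
angle doubling) is also exported, since the "averaged angle" wording
suggests the proprietary rule may involve it.

### Estimating Go and Pog

The estimated Go is the intersection of the posterior arc with the MdP;
the estimated Pog the intersection of the anterior arc with the MdP.
A line through a circle has up to two roots. Because O lies far posterior
to the face and the arc radii are comparable to the O-to-face distance,
the MdP passes close to the circle *center*, so the two roots are nearly
a diameter apart: one at the mandible and one hundreds of millimetres
behind the head. We therefore restrict candidates to the anterior side of
O (the sector between the basal and mandibular planes where the arcs are
actually drawn) and then take the more posterior candidate (smaller frame
x) for Go and the more anterior (larger x) for Pog, with ties broken away
from Me and away from Go respectively. Tangency (center-to-line distance
within 10⁻⁹·r of the radius) yields a single root; if an arc misses the
MdP entirely the estimate is reported as missing together with the radial
shortfall, and the subject is flagged rather than dropped.

Differences are reported as estimated − traced per axis, and as the
Euclidean gap. A structural property follows directly from the geometry:
the traced Pog sits above the MdP (Pog is superior to Me, which defines
the plane), while the estimated Pog lies *on* the MdP — so the estimate
is systematically inferior to the tracing in y. The acceptance suite
verifies this bias holds in 100% of synthetic subjects meeting the
condition.

### Missing-mandible mode

When the mandible is absent (forensic/archaeological reconstruction) the
MdP cannot be derived from Go–Me. Estimating its vertical position from
cranial landmarks is an open problem, so `run_missing_mandible()`
*refuses to guess*: the caller must supply the plane inclination, and
either an explicit anchor point or a chin-height line (the plane is then
anchored where a provisional anterior arc, built from the three cranial
planes, crosses that height). The regression prediction of Go–Me length
from SN (below) is reported alongside as an independent check, and every
report carries the caveat that vertical positioning was supplied, not
inferred.

## Validation statistics

* **Bland–Altman**: mean difference, sample sd (n−1), limits at
  mean ± 2·sd. The 2·sd multiplier (not 1.96) matches the convention of
  the reference analysis; it is a parameter.
* **ICC(3,k)**: two-way mixed-effects, average-measures, *consistency*
  intraclass correlation, (MS_subject − MS_error)/MS_subject, with a 95%
  CI from the F ratio on (n−1) and (n−1)(k−1) df. The reference analysis
  names the two-way mixed model but not consistency-vs-absolute
  agreement; consistency is the standard formulation of that phrase.
* **Ryan–Joiner**: correlation between the ordered sample and normal
  scores Φ⁻¹((i−3/8)/(n+1/4)); rejection against the published
  critical-value polynomials in 1/√n and 1/n at α ∈ {0.10, 0.05, 0.01}
  (a Monte-Carlo critical value may be substituted). This gate decides
  which summary (mean vs median/IQR) is *emphasized*; both are always
  computed, since gap distributions are typically right-skewed.
* **Gap summaries**: mean plus quartiles under the (n+1)p order-statistic
  convention (`quantile type 6`), the convention of the statistics
  package used in the reference analysis; the convention is a parameter.
* **Spearman correlation**: average-rank rho; 95% CI via Fisher z with
  the rank-correlation standard error 1.03/√(n−3); p from the t
  approximation. Published rank-correlation CIs are not exactly
  reproducible from a rounded rho, so the CI method is documented and
  configurable rather than treated as exact.
* **Regression**: ordinary least squares of Go–Me on SN. The reference
  predictive equation Go–Me = 22.65 + 0.5426·SN (mm) ships as the default
  of `predict_gome_from_sn()`.
* **Shape association**: Pearson chi-squared (no continuity correction —
  the printed per-cell contributions of the reference table confirm the
  uncorrected statistic) with expected counts and per-cell contributions;
  one-vs-rest collapse to 2×2; Fisher's exact test, two-sided by the
  point-probability rule with a 10⁻⁷ relative tie tolerance (the
  convention of the cited software family); Bonferroni correction with
  m = 9 for the nine one-vs-rest collapses. The collapsed table is laid
  out with the palate category on the rows and the mandible category on
  the columns, the orientation in which the convex-vs-oblique comparison
  is conventionally printed.
* **Heuristic shape labels**: the reference labels were assigned
  visually, so external labels are the primary path. The heuristic
  (mainly for synthetic data) thresholds the palatal-vault deviation from
  the ANS–PNS chord (t = 0.05 of chord length, inferior positive →
  convex) and the MdP-to-basal divergence angle (< 22° horizontal,
  > 32° oblique/hyperdivergent, else curved); boundary values fall in the
  non-extreme class. All three thresholds are parameters.

## The synthetic cohort generator

No landmark data are publicly deposited, so validation runs on synthetic
cohorts with known ground truth. The ideal template is built directly in
frame coordinates from point O, four plane directions, and two radii;
every landmark is then *derived* so the membership relations hold
exactly: planes concurrent at O, ANS/N/U1/Pog on the anterior arc, Go/Sp
on the posterior arc, Pog on the MdP. Defaults (chosen once, from
anatomy): O = (−248, −33.45) mm, plane directions +7° (basal), −3°
(palatal), −7.5° (occlusal), −11° (mandibular), r_anterior = 321.2 mm
(giving |SN| ≈ 71 mm, the operating point of the predictive equation),
r_posterior = 242.5 mm (placing Sp just behind sella). All derived
landmarks land at anatomically plausible positions.

Cohorts emulate the reference study conditions: n = 100 with a 28/26/46
skeletal class I/II/III mix; class II/III as a −/+6 mm sagittal shift of
Go, Me and Pog (a moderate discrepancy; a synthetic convention, not an
anatomical claim); traced Pog lifted 4 mm above the MdP (its anatomical
position superior to menton — this is what produces the systematic
inferior bias of the estimate); a per-subject isotropic scale with sd
0.05 about sella so that SN and Go–Me co-vary; independent isotropic
Gaussian digitization jitter (default sd 0.5 mm, a typical intra-examiner
landmark error) on every landmark; shape labels drawn from the reference
joint distribution; repeat digitizations for the agreement table emulated
by re-jittering 12 subjects. All randomness flows from one explicit seed
and cohorts are bit-reproducible.

What the generator does *not* emulate: population covariance of
craniofacial form (all subjects share one template geometry), growth,
sex/ethnicity structure, and correlated digitization errors. Passing
validation on these cohorts demonstrates geometric and statistical
correctness of the pipeline, not clinical accuracy on real radiographs —
the published per-landmark agreement values cannot be reproduced without
the original images.

## Numerical choices

Angles are degrees throughout, matching the 0.1° reporting precision of
digitizing software; lines are stored as anchor + direction so vertical
planes are representable. Two lines are "parallel" below 10⁻⁷ degrees of
direction difference — far below measurement precision. Line–circle
tangency uses a 10⁻⁹·r band. Full precision is kept internally; rounding
to 0.1 mm / 0.1° belongs to the reporting layer. Landmark CSVs declare
their raw axis orientation in a header (digitizers differ in facing) and
are normalized to anterior = +x, superior = +y on read; coordinates are
written with round-trip-safe `%.17g` formatting.

## Problem sizes used in the checks

The shipped test-and-acceptance runs use: the 3×3 reference table
(n = 100) for the association statistics; 150 random ideal templates and
10⁴ random line–circle cases against a parametric-sweep root-finding
oracle for geometric closure; exhaustive Fisher-vs-enumeration checks
over all 2×2 margin classes with N ≤ 60 (modulo the row/column/transpose
symmetry group, whose invariance is asserted separately); 500 replicates
of n = 100 for regression parameter recovery; and 1000 replicates of
n = 100 for the association type-I error. These sizes give sampling error
well inside each check's tolerance.
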