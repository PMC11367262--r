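---
title: "Monitoring VMAT plan complexity and expected PSQA outcome"
author: "vmatqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring VMAT plan complexity and expected PSQA outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatqa)
```

## The problem

Volumetric modulated arc therapy (VMAT) delivers dose while the gantry
rotates, with the multileaf collimator (MLC), dose rate and gantry speed all
changing dynamically. Before treatment, each modulated plan undergoes
patient-specific quality assurance (PSQA): the dose calculated by the
treatment planning system (TPS) is compared against a measurement at the
linac, and agreement is scored by the gamma passing rate (GPR). Measuring
every plan is expensive, and failures have become rare, so clinics
increasingly want a *targeted* PSQA program: flag the few plans likely to
fail, and streamline the rest.

`vmatqa` implements the decision-support pipeline for that workflow:

1. **Measure** — parse DICOM RT Plan control points and compute ten per-arc
   complexity metrics.
2. **Analyze** — derive per-treatment-site specification limits as the
   5th/95th percentiles of a historical baseline.
3. **Improve** — train a gradient-boosted regressor that predicts per-arc
   GPR from 19 plan features, with additive per-feature attribution.
4. **Control** — flag outlier arcs, apply defect / at-risk rules, and run an
   automated end-of-day scan ("Poka Yoke") that writes risk reports for
   plans expected to fail.

A synthetic VMAT generator makes the whole pipeline testable without
clinical data; a gamma-index engine with a brute-force oracle covers the
measurement-analysis side.

## The ten complexity metrics

All metrics are computed per arc from the jaw-clipped aperture geometry of
each control point. A leaf pair counts as *open* when its clipped gap
exceeds 0.5 mm — the threshold is not standardized anywhere, and 0.5 mm
suppresses the dosimetrically inert gap of closed-but-not-touching pairs; it
is a parameter (`minGap`) on every metric.

| metric | definition | direction of complexity |
|---|---|---|
| `q1_mlc_gap`, `median_mlc_gap` | 25th/50th percentile of all open gaps pooled over control points | low |
| `sas10` | fraction of open gaps < 10 mm | high |
| `mean_tgi` | MU-weighted mean of S/(S+G), S = exposed adjacent-leaf step length, G = total gap length | high |
| `mcs` | MU-weighted mean of AAV x LSV (aperture-area and leaf-sequence variability) | low |
| `mi_total` | integral over f in [0, 2] of the weighted fraction of leaf-speed/acceleration samples exceeding f standard deviations | high |
| `bi` | MU-weighted mean of perimeter^2 / (4 pi area) | high |
| `bm` | 1 - (MU-weighted mean area) / (union aperture area) | high |
| `edge_metric` | MU-weighted mean of (side steps + end caps) / area | high |
| `lt_al` | mean leaf travel / gantry arc length | high |

### MU weighting and split invariance

Segment *k* runs from control point *k* to *k+1* and carries meterset
fraction `dw_k`. Every MU-weighted metric evaluates its per-control-point
quantity at the segment *start* and weights it by `dw_k` (a left-endpoint
Riemann rule). This was a genuinely open design point: the common
alternative averages the two endpoint values per segment. The left-endpoint
rule was chosen because it makes all weighted metrics *exactly* invariant
under two operations that should never change a physical summary of the
delivery: re-normalizing the meterset weights, and splitting a control point
into two identical machine states that share its segment MU. Endpoint
averaging breaks the second invariance at first order in `dw`; the two rules
otherwise differ only at O(dw^2) for smoothly varying apertures, i.e. well
below the arc-to-arc variability the monitoring rules act on. Only
ordering/direction of the metrics is relied upon downstream.

### Geometry conventions

Coordinates are IEC 61217: leaves travel along x (bank A left, bank B
right), leaf pair *i* covers the y-strip between consecutive leaf
boundaries. The open region of a control point is a union of jaw-clipped
rectangles, so its boundary decomposes exactly into vertical leaf-end
segments, adjacent-leaf *steps* (the symmetric difference of consecutive
exposed intervals), and *end caps* against closed pairs or the field edge.
The tongue-and-groove term S counts only steps between two open pairs; the
edge metric counts steps plus caps (both are MLC side edges).

One geometric fact worth recording: a staircase of thin leaves inscribing a
disc does *not* approach the irregularity of a disc (BI = 1). Its perimeter
converges to the taxicab perimeter 8r, so BI converges to 16/pi^2 = 1.62
from below; the unit tests assert this limit rather than the naive one.
A square aperture gives BI = 4/pi exactly.

The gantry arc length accumulates absolute segment deltas with
shortest-path wrap at the 0/360 seam, so a full arc from 181 deg to 179 deg
through 0 deg measures 358 deg, not 2 deg.

### Timing model

`mi_total` and the delivery features need segment durations. These come from
the limiting axis: `dt_k = max(|d gantry| / maxGantrySpeed, dMU /
maxDoseRate)` with TrueBeam-class defaults (25 mm/s leaf speed, 6 deg/s
gantry, 600 MU/min) in `machineLimits()`. Leaf speeds are per-segment
displacements over `dt`; accelerations difference consecutive speeds over
the midpoint duration. The exceedance curve Z(f) is integrated by trapezoid
on a 0.01 grid; a refinement test checks agreement with a 1e-4 grid to
1e-3.

## Gamma analysis

`gammaMap()` implements the global gamma index: for every reference point at
or above the low-dose cutoff (10% of the reference maximum by default), the
gamma value is the minimum over nearby evaluated positions of
`sqrt(dist^2/dta^2 + doseDiff^2/tol^2)`, with the dose tolerance a
percentage (3% by default) of the *reference* maximum. The reference is the
TPS-calculated grid: normalization and cutoff both key off it, and gamma <=
1 counts as passing against a 90% action limit.

The production engine searches a square lattice of sub-pixel offsets
(bilinear interpolation) within three distance-tolerances of each point,
scanning offsets in order of increasing distance so the distance term alone
prunes the search exactly. The lattice step defaults to 0.05 mm: on
rigid-shift fields dense with gamma ~ 1 borderline points a 0.1 mm lattice
still disagreed with the exhaustive oracle by up to ~1 pp, while 0.05 mm
brings agreement within ~0.05 pp at negligible cost. `gammaBruteForce()` is
the validation oracle: an exhaustive search over the whole evaluated grid
upsampled 10-fold, with no locality assumption. The two engines are
cross-checked on twenty random grid pairs in the test suite. One caveat is
inherent: when a dose-matched rigid shift has magnitude exactly equal to the
distance tolerance, the continuous gamma is exactly 1 over the whole
steep-gradient region, and *any* finite lattice flips borderline points both
ways; the tests sample shifts away from that knife edge.

Grids are planar (EPID portal dosimetry is planar) and travel as a
three-line-header text format (`readDoseGrid()` / `writeDoseGrid()`); DICOM
RTDOSE is not parsed — the package's minimal DICOM codec is scoped to the
RT Plan module.

## Specification limits and the monitoring rules

`buildLimits()` computes, per treatment site and metric, the 5th and 95th
percentiles (type-7 linear interpolation, like every quantile in the
package) of a baseline cohort; strata under 20 arcs are kept but marked
unusable. Values strictly outside [low, high] are outliers — a value exactly
on a limit is in spec. Each metric carries a fixed complexity direction
(`complexityDirections()`): an outlier is *high-complexity* when it falls on
the complex side (low gaps, low MCS; high everything else).

The rules, with strict boundaries throughout:

* an arc is a **defect** when more than five of ten metrics are outside the
  limits (six or more);
* an arc is **at risk** when more than five metrics are high-complexity
  outliers;
* a plan is **at risk** when a *strict majority* of its arcs are at risk, or
  the mean predicted GPR over its arcs falls below the 90% action limit.
  An exact tie (one of two arcs) does not trigger the complexity clause —
  the conservative reading of "most of its arcs" for even counts; the GPR
  clause is the safety net. The per-plan GPR is the simple (unweighted)
  mean over arcs.

`dpmo()` uses the conventional one-sided definition with a 1.5-sigma
long-term shift, under which six sigma corresponds to 3.4 defects per
million opportunities; `compareGPRDistributions()` wraps the two-sided
Mann-Whitney test (`stats::wilcox.test`) and reports
"median [first, third] quartile" summaries.

Unknown treatment sites are an error by default; with
`unknownSitePolicy = "pool"` the pooled envelope over all baseline strata is
used instead.

## GPR prediction

`assembleFeatures()` produces a fixed 19-vector: the ten metrics plus total
MU, MU per degree, mean gantry speed, mean dose rate, dose-rate standard
deviation, equivalent-square side of the union aperture, number of control
points, arc length, and MU-weighted mean aperture area. The exact
composition of the nine delivery features is this package's documented
choice; the contract (complexity + plan parameters, 19 numbers, fixed
order) is what downstream code relies on, and prediction refuses mismatched
feature sets.

`trainGPRModel()` fits a gradient-boosted tree ensemble (xgboost,
squared-error objective) with modest defaults: eta 0.05, depth 6, 400
rounds, subsample/colsample 0.9, single-threaded for bit-reproducibility.
Predictions are clipped to [0, 100]. `featureAttribution()` exposes the
ensemble's TreeSHAP contributions: 19 signed scores plus a baseline that sum
to the raw (unclipped) prediction — the additive contract is asserted in the
tests. Serialization embeds the booster bytes with the feature list and
training metadata in one JSON file; a round trip reproduces predictions
bit-for-bit.

Evaluation reports MAE plus failure-detection sensitivity/specificity at the
action limit; with no failing case in the test set the sensitivity is
undefined and reported as NA rather than silently 1.

## The synthetic generator

`generateArc()` emulates a single full arc: 178 control points over a
358-degree sweep (181 deg to 179 deg through 0 deg), 40 leaf pairs of 5 mm,
uniform meterset, 2 MU per control point, 600 MU/min. A modulation dial m in
[0, 1] controls realism of a different kind at each end:

* m = 0: a static rectangular field conformal to the target's bounding box —
  by construction MCS = 1, MeanTGI = 0, BM = 0, LT/AL = 0 exactly, the
  anchor for the metric unit tests;
* as m grows the leaf tips blend to the conformal ellipse outline (complete
  by m = 0.3), the gap scale shrinks by up to 60%, and a growing fraction
  (15% + 75% m) of leaves picks up smooth two-harmonic excursions of
  amplitude 12m mm. The growing *fraction* matters: it is what makes the
  modulation index rise with the dial, since that metric is standardized by
  the arc's own speed spread and is insensitive to pure amplitude scaling.

Every directed metric tracks the dial with rank correlation >= 0.7 over 200
arcs; that ordering, not absolute metric scales, is what the monitoring
rules consume.

`simulateGPRLabels()` stands in for EPID measurements: label = 70 + 30 *
logistic((a0 - sum w_j z_j) / tau) + N(0, noiseSD), clipped to [0, 100],
where z_j are the standardized metrics oriented toward complexity. The
frozen defaults (w = 0.15 each, a0 = 3.4, tau = 1.2, noise 2 pp) were
calibrated once so that a default cohort shows roughly 6% of arcs below the
90% action limit — the strong imbalance that makes real GPR prediction
hard — while the bulk of labels spreads over roughly 93–99% rather than
saturating at the logistic plateau, mirroring the quartile spread seen in
clinical expected-GPR distributions. The scale tau exists because those two
goals pull against each other: without it, 94% of labels compress into a
1-pp band where measurement noise destroys all ranking signal. Model
recovery is therefore scored two ways in the tests: ranking against the
noiseless generative signal (Spearman >= 0.8 at n = 2000 training arcs),
and MAE against the noisy labels (within 20% of E|N(0,2)| = 1.6 pp, the
irreducible floor).

What the generator does **not** emulate: fluence or dose realism (labels
come from the logistic model, not a dose calculation), machine log files,
inter-site anatomical differences (sites differ only through the dial
distribution), interplay or delivery errors. Passing tests therefore
demonstrate the pipeline's internal correctness and statistical behavior
under a controlled generative model — not clinical performance on real
plans, which requires an institutional baseline and measured GPRs.

## Degenerate inputs and numerical corners

* A fully closed aperture is a valid control point (zero area, no gaps); an
  arc with *no* open control point errors on every metric with the metric
  named.
* Zero-duration segments (no gantry motion and no MU) make `mi_total` error
  with the segment index.
* Meterset weights are re-normalized to [0, 1] on DICOM read; non-monotone
  weights are a validation error, as are static (non-DYNAMIC) beams and
  beams without an MLC position sequence — each error names the beam.
* Leaf/jaw positions omitted at a control point are carried forward from the
  previous one, per DICOM RT convention.
* `sd` of a single-segment dose-rate vector is NA-free by construction
  (arcs require >= 2 control points; `mi_total` requires >= 3).

## Problem sizes

The test-suite and acceptance-script study sizes are the package's choices:
cohorts of 1650 synthetic plans (~3000 arcs) with 2000 training rows for
model recovery; 200 arcs for the dial-monotonicity study; 500 arcs for
metric range bounds; 20 random 50x50 grid pairs for gamma oracle
equivalence; 10,000 baseline arcs for the self-flag rate; 200,000 simulated
arcs for the binomial defect-rate check; a 10-plan directory (one
constructed high-complexity plan) for the end-to-end monitor run. Smaller
fixtures use 48-control-point arcs where only geometry, not the label
distribution, is exercised.

## Known limitations

* The DICOM codec reads/writes Explicit VR Little Endian only, with the RT
  Plan tags this pipeline needs; it is not a general conformance layer.
* Gamma analysis is 2D global-normalization only; no absolute calibration,
  EPID image prediction, or 3D gamma.
* Metric absolute scales follow this package's operationalization of the
  one-line literature definitions; cross-package comparisons should use
  rankings, or recalibrate limits on a common baseline.
* The at-risk machinery inherits whatever biases the baseline cohort has;
  limits built from under-20-arc strata are flagged unusable, but the
  quality of the percentiles with a few dozen arcs is still poor.
* E-mail dispatch is out of scope by design: at-risk reports land in an
  outbox directory (and the monitor exit code signals a scheduler), where a
  clinical mail hook can pick them up.
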