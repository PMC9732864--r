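---
title: "Relating ioECoG biomarker rates to MRI lesion geometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating ioECoG biomarker rates to MRI lesion geometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoglesion)
```

## The scientific question

During resective surgery for focal lesional epilepsy, intraoperative
electrocorticography (ioECoG) grids and strips record interictal
spikes and high-frequency oscillations (ripples, 80–250 Hz; fast
ripples, 250–500 Hz) directly from the exposed cortex, while the
structural MRI shows a lesion. How the electrographic markers relate
*spatially* to the radiographic lesion — and whether that relationship
depends on the underlying pathology — determines how a surgeon should
read the ioECoG when tailoring a resection. This package implements the
full analysis chain for that question: electrode localization on a
cortical surface, three lesion–electrode distance models,
channel-level biomarker rates, robust regression of distance on rate
stratified by pathology, and moderation analysis — plus a synthetic
cohort generator so every stage can be validated without patient data.

## Geometry

**Lesion.** A binary voxel mask with a voxel-to-world affine
(`lesion_volume()`). Voxel index $(i,j,k)$ (0-based) maps to the voxel
*centre* in mm. Volume is foreground count × voxel volume.

**Distances.** For a bipolar channel at midpoint $p$ (the exact spatial
midpoint of its two electrode coordinates):

* $d_{\mathrm{edge}}$ — minimum Euclidean distance from $p$ to any
  foreground voxel centre. We deliberately measure to voxel *centres*
  (equivalently, the Euclidean distance transform of the background
  sampled at $p$) rather than to an interpolated iso-surface: the
  definition is unambiguous and checkable against brute-force
  enumeration, and the ≤ half-voxel discrepancy is far below the 2–3 mm
  electrode-localization error inherent to photograph-based placement.
  Points inside the mask get $d_{\mathrm{edge}} = 0$.
* $d_{\mathrm{com}}$ — Euclidean distance from $p$ to the lesion's
  centre of mass (unweighted mean of foreground voxel centres).
* $d_{\mathrm{geo}}$ — the length of the shortest straight segment from
  the COM to the cortical surface plus the shortest on-surface path
  from that entry point to the electrode; this approximates recruitment
  along horizontal cortico-cortical connections.

**Geodesic computation.** Both endpoints are snapped to mesh vertices
(nearest vertex; ties broken by lowest index for determinism), so the
two legs meet at a well-defined common point. The on-surface leg is a
shortest path in a graph. A pure mesh-edge graph is attractive for its
simplicity, but on near-regular triangulations its metric overestimates
true surface distance by up to $2/\sqrt{3} - 1 \approx 15\%$ in
directions that force zig-zag paths. The default therefore augments the
graph with 2 evenly spaced auxiliary (Steiner) nodes per edge and
connects all nodes sharing a face, letting paths cross triangle
interiors. On a 10,242-vertex sphere of radius 50 mm this measures
within 2% of the analytic great-circle value, and the error shrinks
monotonically under mesh refinement. The plain `"edge"` method is kept
as an option; on meshes small enough to enumerate every simple path it
is verified against exhaustive enumeration.

**Grid extrapolation.** Arrays are rigid (10 mm chord pitch). Hidden
electrodes are filled by marching outward from the visible ones:
each missing cell is seeded by linear continuation (two collinear
localized neighbours) or parallelogram completion (an L of three), then
relaxed by alternating (i) rescaling to the nominal chord length from
each localized neighbour and (ii) projecting onto the surface (exact
point-to-triangle projection). Defaults: chord tolerance 0.2 mm,
surface snap tolerance 1.0 mm, both configurable. Chord (not geodesic)
spacing is preserved because physical grids are rigid in the chord
sense. The fill of a cell depends only on its parent cells, which makes
the procedure idempotent and lets a grid regenerated from any visible
subset containing the original anchors reproduce identical coordinates
— the property the end-to-end file round-trip test relies on. On a
plane the procedure reproduces the exact lattice.

## Events and rates

Events arrive as timestamp logs (channel, type, time within a 60 s
epoch). Rates are counts per minute per channel; montage channels
without events get rate 0; artifactual channels are excluded before any
analysis and logged with a reason. The bipolar montage pairs
layout-adjacent electrodes along rows by default (configurable to
columns); the pairing direction is an explicit input because recording
conventions vary. Multiple recordings per patient are pooled without
weighting, and channels from different recordings are kept distinct.
Summary tables report, per group, total events and the mean/SD of rates
over channels with at least one event of that type (groups without any
events are shown as missing, not zero). `dmax()` reports, per patient
and event type, the highest rate and the $d_{\mathrm{edge}}$ of the
channel carrying it (ties to the lowest channel id) —
$d_{\mathrm{edge}}$ because that is the distance family used for all
downstream analyses.

## Statistics

All regressions put the *distance* on the left-hand side and the
*rate* on the right, matching the clinical workflow question ("does a
hot channel sit near the lesion?"); slopes are mm per event/min.

* `ols_hc3()` — OLS with the HC3 (Davidson–MacKinnon) covariance
  $(X'X)^{-1} X' \operatorname{diag}\!\big(e_i^2/(1-h_{ii})^2\big) X (X'X)^{-1}$,
  a robust $t$ referred to $t_{n-2}$ (equivalently $F(1, n-2)$), and a
  percentile bootstrap CI from 1000 case resamples (count and seed
  configurable). In simple regression $\eta^2 = r^2$ exactly, and that
  identity is asserted to machine precision. Effect sizes are binned
  small ($\le 0.06$), moderate ($< 0.14$), large ($\ge 0.14$); the
  boundary 0.14 goes to *large*, resolving the overlap in the
  conventional phrasing in the direction consistent with published
  usage (0.09 labelled moderate, 0.22 large).
* `welch_anova()` — heteroscedastic one-way ANOVA with Satterthwaite
  denominator df (via `stats::oneway.test`).
* `logistic_occurrence()` — ML logistic fit of fast ripple occurrence
  on distance; odds ratio per mm with Wald CI and Wald $\chi^2$; errors
  on single-class outcomes and (quasi-)complete separation.
* `moderation()` — fits $y \sim x + m + x\!:\!m$ with the HC3
  covariance; the omnibus moderation test is a robust Wald $F$ over all
  interaction coefficients referred to $F(q, n-p)$ (with $q = k-1$ for
  a categorical moderator of $k$ levels). Simple slopes are the
  level-specific slopes under reference-level dummy coding, or, for a
  continuous moderator, the slope probed at mean − 1 SD, mean,
  mean + 1 SD. The robust Wald construction is cross-checked in the
  test suite against an independent route (`car::linearHypothesis`
  with an HC3 covariance).

No multiple-comparison correction is applied anywhere; the analyses
test complementary hypotheses on interdependent variables and are
reported at $\alpha = 0.05$.

## The synthetic cohort generator

The generator exists so that the full pipeline — file formats,
extrapolation, distances, rates, fits — can be exercised end-to-end
with known ground truth. It emulates:

* 33 patients in the clinical pathology proportions (12 FCD, 9
  ganglioglioma, 5 DNET, 3 low-grade glioma, 2 PXA, 2 cavernoma), each
  with 1–5 pre-resection recordings and 4×5, 4×4 or 1×8 arrays at
  10 mm pitch, a fraction of electrodes hidden under the skull;
* lesions as ball-shaped voxel blobs abutting the cortical surface,
  with volumes drawn from per-pathology lognormal laws (means/SDs as
  published: FCD 2.5 (3.0) cm³ … low-grade glioma 20.8 (28.6) cm³);
* about 10.6% of bipolar channels flagged artifactual;
* event counts per 60 s epoch from a zero-inflated negative binomial:
  an activity gate (many channels never show a given biomarker) times
  an overdispersed count law. Published rate tables give active-channel
  means *and SDs*; a pure Poisson cannot reproduce those SDs, so
  "Poisson-like" is realized as a Poisson mixture. Fast ripples are
  absent by construction for cavernoma, DNET and low-grade glioma.

**Slope calibration.** For each pathology × event type the generator
receives a target regression slope $b$ (distance on rate, mm per
event/min; defaults: spikes cavernoma −1.37, FCD −0.25, PXA −0.18,
low-grade glioma +0.65; ripples FCD −0.35, low-grade glioma +2.67;
fast ripples ganglioglioma −2.22; all others 0). Rates are generated
*conditionally on distance* (the causal direction) and calibrated so
that regressing distance on the realized rates recovers $b$ in
expectation: with active fraction $\pi$, active mean $M$, active SD
$S$ and empirical distance variance $V$, the conditional-mean slope is
$\beta = b\,(S^2 + (1-\pi)M^2)/V$, with the overdispersion parameter
set by moment matching. When $\beta^2 V$ would exceed the variance
budget $S^2 - M$ (the published slope is steeper than the rate scale
can support through the mean channel alone), the remainder of the
association is carried by a distance-dependent occurrence gate
$\pi(d) = \operatorname{logit}^{-1}(a_0 + a_1 d)$, solved numerically
on the supplied distances so the population slope still equals $b$;
cells where even this cannot reach $b$ are generated at the closest
attainable slope of the correct sign and flagged `partial`. The gate
gradient is also scientifically natural: for low-grade gliomas,
ripples *occur* predominantly away from the lesion.

**Distance spreads.** Per-pathology SDs of channel distance
(`pathology_defaults()$d_sd`, around a common 18.9 mm mean) are fixed
design constants chosen so that the generated effect sizes match the
published $\eta^2$ values; the published (slope, $\eta^2$, rate
moments) triplets are only mutually consistent if the within-pathology
distance spread differs across pathologies (about 5 mm for PXA, about
9–10 mm for FCD and low-grade glioma). The generator's event *totals*
match the published totals in expectation exactly
($n\,\pi\,M$); the split between the number of active channels and
their conditional mean shifts slightly with the count law's zero mass.

**What the generator does not emulate**, and hence what passing tests
do not show about real data: anatomically realistic cortical folding
(surfaces are spheres or gently perturbed spheres), brain shift,
within-patient between-channel correlation (channels are independent
given distance — a stated simplification), propagation of discharges
along networks, and any raw-signal phenomena (detection, filtering,
artifact morphology are out of scope; events arrive as logs).

## Validation design and problem sizes

The test suite validates each layer against an independent oracle:
brute-force enumeration for voxel geometry; exhaustive path enumeration
(≤ 12 vertices) and the analytic great circle for geodesics; closed-form
lattices for extrapolation; a hand-expanded sandwich formula and the
`sandwich`/`car` packages for the robust statistics. Calibration
properties use 2000 null simulations (Welch and moderation type-I
error, checked against the 0.035–0.065 band at $\alpha = 0.05$) and
500 replicates of percentile-bootstrap coverage at $n = 300$ channels
(93–97% band); slope-sign recovery uses 100 seeds per pathology at the
published channel counts. These sizes give the binomial checks enough
resolution that the bands are informative without being brittle.

Two validation choices deserve explanation:

* *Volume-moderation null.* The generator never lets lesion volume
  enter the rate law, so volume moderation is null by construction —
  but only at the unit where volume varies. In a mixed cohort, volume
  correlates with pathology and pathology *does* moderate, so a
  volume-only moderation model is confounded and rejects often; that
  is an omitted-moderator effect, not a false positive of the test.
  And with one volume per patient, pooled-channel inference has an
  effective sample size of the patient count, inflating finite-sample
  rejection (we measure ≈ 17% within FCD at 12 patients). The
  calibration check therefore probes the null where it actually holds:
  within a single pathology with channel-level volume draws, where the
  rejection rate is at the nominal 5%. The same caveat applies to
  pooled-channel moderation analyses of clinical data.
* *Fast ripples.* The published fast-ripple moments (22 events on 368
  ganglioglioma channels, active mean 2.0, SD 1.7) bound the attainable
  effect size so low that no generator respecting them can guarantee
  ≥ 95% sign recovery of the −2.22 slope at those counts; the
  generator recovers the sign in roughly 9 of 10 seeds, and the
  sign-recovery guarantee is asserted for the six spike/ripple cells.

## Known limitations

* The geodesic is a graph approximation, not an exact polyhedral
  geodesic; with the default Steiner refinement the bias is below the
  electrode-localization error, but it is always non-negative on the
  graph leg.
* COM-to-surface entry uses the nearest *vertex*, not the nearest
  surface point; on meshes at the resolutions used the difference is
  sub-millimetre and keeps both legs anchored at the same point.
* The rate generator matches first and second moments and the slope
  structure of the published tables, not any waveform-level physiology.
* Pooled-channel regressions ignore within-patient correlation, as in
  the clinical analysis being emulated; the D-max and visual-slope
  analyses (one point per patient) are the robustness checks for that
  choice.
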