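---
title: "Feature-based DR grading, progression and evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based DR grading, progression and evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscreen)
```

This vignette is the package's account of its science: the grading
model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, the numerical choices,
and the design decisions taken where the design was genuinely open.

## The model

### Lesions, not pixels

The unit of analysis is a *lesion annotation*: a type from a closed
15-label enumeration, a centroid in pixel coordinates, an area in
pixels and a detector confidence in [0, 1]. Where those annotations
come from — human experts, a segmentation network, or the bundled demo
blob detector — is outside the model. The consequence worth stating
plainly: every grade this package produces is explainable as "these
lesions, at these locations, fired this rule", and the same lesion set
can be regraded under a different scheme by swapping a JSON file. The
trade-off is that grading quality is bounded by annotation quality;
the noise model in the synthetic module exists precisely to study that
coupling.

`ARTEFACT` is a first-class label that contributes to no grade: real
detectors report dust, reflections and co-pathology, and the
evaluation machinery needs those detections to exist without polluting
severity.

### Geometry: the disc-diameter metric

All distances are expressed in units of the optic-disc diameter (DD),
measured from the fovea, so pixel scale and camera field of view
cancel. The disc diameter and both landmark positions are taken as
given in the annotation; estimating them from pixels is deliberately
out of scope (the demo detector also receives them as inputs).

Two partitions are derived from the landmarks:

* **Regions** 1–5: concentric fovea-centred annuli with outer bounds
  1, 1.5, 2 and 3 DD, region 5 being everything beyond. Boundaries are
  *upper-edge inclusive* (a point at exactly 1.0 DD is region 1): the
  region definition gives no open/closed detail, and the inclusive
  convention makes the five regions a total partition of the plane —
  which the tests verify by direct enumeration.
* **Quadrants** 1–4: the four half-plane intersections of the
  horizontal and vertical axes through the fovea, numbered 1 =
  upper-right then counter-clockwise as displayed. Points exactly on
  an axis join the lower-numbered adjacent quadrant, and the fovea
  itself is quadrant 1 — an arbitrary but total and documented
  tie-break. Quadrants are not part of the region definition; they
  exist because the ICDRS severe-NPDR ("4-2-1") rule counts lesions
  per quadrant.

Lesion location is always the *centroid*. Boundary-based assignment
could shift borderline maculopathy calls for large exudates near the
1 DD radius; with typical exudate radii of 3–6 px against a 180 px
disc diameter the shift is below 0.04 DD, but it is a real limitation
for confluent lesions.

### Decision tables

A grading scheme is an ordered level ladder plus rules, each rule a
disjunction of predicates over the lesion summary (presence, counts,
per-quadrant counts, areas, fovea distances). Rules are evaluated
highest severity first; the first satisfied rule wins; the empty
summary reaches the lowest level. Both shipped tables live in
`inst/extdata/` and every threshold is data, not code:

| Parameter | Default | Where | Why |
|---|---|---|---|
| haemorrhages per quadrant (4-2-1) | 20 | icdrs.json | published severe-NPDR criterion |
| beading quadrants (4-2-1) | 2 | icdrs.json | published severe-NPDR criterion |
| IRMA quadrants (4-2-1) | 1 | icdrs.json | published severe-NPDR criterion |
| MA mild ceiling | unlimited | icdrs.json | mild is "MAs only", any count |
| blot haemorrhages for R2 | 5 | nsc.json | "multiple" blot haemorrhages; no published count |
| maculopathy radius | 1.0 DD | both | standard M1 exudate criterion |
| referable cut-off | ICDRS ≥2 / NSC ≥R2, or maculopathy | both | common screening practice; the referral threshold is policy, not biology, so it is config |
| confidence threshold θ | 0.5 | argument | detector operating point; 0.5 is the neutral default |

Two deliberate departures from a minimal reading of the published
level descriptions, both recorded here because they change grades:

* ICDRS moderate includes `VENOUS_BEADING` (in a single quadrant).
  Moderate is defined as "more than just MAs but less than severe";
  without this, one beading would grade ICDRS 0 while grading NSC R2,
  breaking the cross-scheme concordance the package promises (ICDRS 0
  ⇔ R0 at the ladder extremes).
* NSC R1 includes `BLOT_HAEMORRHAGE` below the R2 count threshold —
  blot haemorrhages are haemorrhages; 1–4 of them are background
  retinopathy, not absence of disease.

`SCAR` carries no grading weight under either default table: neither
scheme's published criteria name retinal scarring as level-defining.
It is accepted, stored and reported, and a custom table may use it.

### Maculopathy and referability

Maculopathy (M1 / the DMO flag) is assessed from exudate proximity to
the fovea alone: true iff any exudate lies within the configured
radius. This is a two-dimensional colour-fundus surrogate — it cannot
see retinal thickening, so it under-detects oedema without exudates
and the flag should be read as "exudative maculopathy". Referability
is a pure lookup on (level, maculopathy) under the configured policy.

### The ensemble path

The probabilistic grading stage is a bagged ensemble of CART trees
(Gini impurity, `mtry` random candidate features per node, bootstrap
resampling) trained on a deterministic 98-long feature vector: for
each of the 14 DR lesion types, total count, log(1 + total area) and
the five per-region counts. The tree grower is written in the package
because no tree package is available in the supported environment;
its contract is what matters: per-class probabilities that sum to 1,
training fully deterministic given the seed, and argmax ties broken
toward the *lower* severity — conservative against severity
inflation, which is the dominant error mode of lesion-based graders.
The decision table remains the reference path; on noiseless synthetic
cohorts the ensemble agrees with it on ≥99% of images (verified at
n = 2,000), and the residual disagreements are rare feature
combinations (e.g. a venous loop as the only lesion) that the
bootstrap may under-sample. The feature vector deliberately excludes
quadrant counts, so the 4-2-1 rule is only approximately learnable
from totals and regions — a faithful reproduction of the information
actually given to such a classifier.

## Progression

Registration uses only the two anatomical landmarks. Two point pairs
determine the 4-degree-of-freedom similarity transform in closed form
(complex ratio), which exists whenever disc and fovea are distinct in
both images and is exact by construction — the tests require recovery
of random transforms to 1e-9 per parameter. Vessel-based refinement
is out of scope on purpose: advanced pathology (beading,
neovascularisation, pre-retinal haemorrhage) degrades exactly the
vessel features such refinements rely on. The cost is that
non-similarity distortion (eye rotation out of plane, lens effects)
becomes matching error; the matching radius absorbs it.

Matching is greedy nearest neighbour per lesion type (an MA never
matches a haemorrhage), in increasing distance order, within
τ = 0.25 DD, ties broken by lower lesion id. Greedy rather than
optimal assignment: with well-separated lesions the two coincide, and
greedy is deterministic, auditable and O(n²) per type at worst.

A matched pair is `GROWN` when the follow-up/baseline area ratio
exceeds 1 + δ, `SHRUNK` below 1 − δ, otherwise `STABLE`; δ defaults
to 0.2. The size-change threshold is this package's construct (the
clinical sources say only "smaller or bigger"), hence a parameter.
Note the literal form is not perfectly symmetric under swapping the
two visits: ratios in (1/(1−δ), 1+δ) ≈ (1.25, 1.2)… i.e. the band
(1.2, 1.25) classifies as GROWN forward but STABLE backward. The
synthetic generator plants factors 2.0 and 0.5, far outside the band,
so the swap-symmetry property holds on every planted scenario; an
application needing exact symmetry should set δ such that
1 − δ = 1/(1 + δ) (log-symmetric deadband).

Event regions are attributed in the *follow-up* frame — the
clinically current image. Conservation holds by construction:
baseline lesions = matched + RESOLVED, follow-up lesions = matched +
NEW.

## Evaluation

The confusion outcomes are *feature-conditioned*, matching screening
validation practice rather than plain threshold confusion: any strict
severity over-call is FP (even when both grades are on the same side
of the referral threshold); on a task-positive ground truth, a
task-positive prediction is TP and a task-negative one FN; a
task-negative image with only task-negative findings is TN. The
overlap case — prediction exceeds a positive ground truth — is
resolved as FP, following the explicit over-call clause; the ordered
evaluation makes the function total, which the tests verify over
every level pair of both schemes. `conventional = TRUE` switches to
plain confusion counting for comparison.

Confidence intervals default to the Wilson score method: well-behaved
at proportions near 0 and 1 (where screening sensitivities live) and
standard in the screening literature; Clopper–Pearson is available
where an exact interval is required. Metrics with empty denominators
are reported as absent, never as 0. Quadratic weighted kappa uses the
standard O/E contingency form; the degenerate case (both raters
constant and identical) has a zero chance-disagreement denominator
and raises an error rather than silently returning 1. ROC curves
sweep the unique scores descending (positive ⇔ score ≥ threshold),
AUC is trapezoidal and equals the Mann–Whitney statistic to 1e-12.
Operating points maximise the free metric subject to a floor on the
other; an infeasible floor returns the nearest feasible point flagged
`feasible = FALSE`. Prevalence subsampling keeps all negatives and
downsamples positives, reaching the target within one record.

The ordinal score used for rule-based ROC analysis is
`level_index − 1 + 0.5 · maculopathy`: any referable image scores
strictly above any non-referable one under the default policies,
which is the property the ROC needs; the ensemble's referable
probability is the natural score when the probabilistic path is used.

## The synthetic world

`synthesise_for_level` inverts the decision tables: the output
satisfies the target rule and provably fails every higher rule
(checked predicate-by-predicate in the tests). Counts are drawn from
modest ranges (e.g. 1–10 MAs for mild; 20–24 haemorrhages per
quadrant for the 4-2-1 branch; 5–9 blots for the R2 count branch),
positions uniformly within region annuli, with explicit quadrant-wise
sampling where the rule demands it. Cohort levels are drawn from a
prevalence configuration; the three presets encode the published
compositions of real national screening datasets (row sums 15,000,
10,026 and 28,680), so simulated cohorts reproduce realistic class
imbalance — rare severe disease is the stress case for screening
statistics. Per-level maculopathy rates rise with severity (0.15 at
the first feasible level to 0.35 at proliferative disease) and are 0
where the tables make maculopathy infeasible (ICDRS 0/1, NSC R0 — an
exudate would already exceed the level); these rates are this
package's choice of a plausible screening mix, made once and not
fitted to anything.

The noise model has four channels — per-type Bernoulli misses,
per-type Poisson false alarms (including artefacts), Gaussian
centroid jitter in DD, log-normal area jitter — plus Beta-distributed
confidences. The default is zero noise, under which grading a cohort
reproduces its ground truth exactly; that property anchors the
round-trip tests, so a green round-trip establishes correctness of
the table inversion and grader, *not* realism of the detector. What
the generator does not emulate: spatial correlation of lesions,
type-confusion between lesion classes (exposed as a parameter shape
but with no published rates to default to), ungradable images, and
co-pathology.

Longitudinal pairs apply a camera perturbation (similarity), plant
scripted events, and return the exact change log. Planted NEW lesions
are kept at least `min_separation_dd` (default 0.5 DD = 2τ) from
every same-type lesion, so the matcher cannot alias a planted lesion
with an unrelated one — the condition under which 100% planted-change
recovery is a theorem rather than a probability.

Phantoms are flat-background rasters with hard-disc blobs, a bright
disc, a dark foveal patch and random-walk vessels, exchanged as
plain-text PGM; the demo detector is thresholding plus 8-connected
components with a size-based type heuristic. Its purpose is to close
the pixels-to-grade loop in tests, not to model photography.

## Numerical and format choices

* All seeded functions save and restore the caller's RNG state; child
  seeds are derived arithmetically and stay below 2^31.
* CSV/JSON writers use 6-significant-digit float formatting and fixed
  column orders, so identical inputs give byte-identical outputs
  (verified in the CLI tests); annotation JSON keeps full double
  precision for lossless round trips.
* Region boundaries inclusive-upper; quadrant axis ties to the lower
  number; matching ties to the lower id; ensemble argmax ties to the
  lower severity — every tie-break is total and stated.
* Degenerate inputs fail loudly: coincident landmarks, single-class
  training cohorts, unreachable prevalence targets, constant-rater
  kappa, single-class ROC labels.

## Known limitations

* DMO is exudate-proximity only; maculopathy without exudates is
  invisible.
* The graders see centroids, so a lesion straddling a region boundary
  is wholly attributed to its centroid's region.
* Registration is similarity-only; strong projective distortion
  between visits will surface as unmatched lesions.
* The synthetic world is independent-lesion and noise-stationary;
  performance numbers measured on it characterise the machinery, not
  any real detector or population.
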