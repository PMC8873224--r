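# drscreen

Feature-based diabetic retinopathy (DR) grading, progression analysis and
screening evaluation in R.

Automated DR screening systems increasingly predict a severity grade
directly from the whole fundus image. `drscreen` implements the
complementary, feature-based route used by human graders: detected
lesions (microaneurysms, haemorrhages, exudates, cotton wool spots,
venous abnormalities, IRMA, neovascularisation, ...) with their sizes
and locations are mapped to a severity level by an explicit, auditable
decision table. Because the grade is derived from features, the same
lesion set can be graded under any scheme without retraining — the
package ships tables for the two schemes most widely used in screening
programmes, and both are plain JSON that can be edited without touching
code. The package is aimed at screening-programme analysts and
methods researchers who need a transparent grader, a lesion-level
progression report, or the standard screening statistics with
reproducible synthetic cohorts.

## What it computes

**Grading.** A lesion set is summarised (per-type counts, areas,
fovea-centred regions and quadrants; detections below a confidence
threshold and artefacts are dropped) and pushed through a decision
table, highest severity first:

* **ICDRS** (International Clinical Diabetic Retinopathy Severity
  Scale), levels 0–4: proliferative lesions (NVD, NVE, pre-retinal
  haemorrhage, fibrosis) ⇒ 4; the 4-2-1 rule (≥20 haemorrhages in each
  of 4 quadrants, venous beading in ≥2 quadrants, or any IRMA) ⇒ 3;
  other non-MA lesions ⇒ 2; MAs only ⇒ 1; nothing ⇒ 0.
* **UK NSC**, levels R0–R3 plus maculopathy M0/M1: proliferative
  lesions ⇒ R3; venous abnormalities, IRMA or ≥5 blot haemorrhages ⇒
  R2; any background lesion ⇒ R1.

Maculopathy (a 2-D surrogate for diabetic macular oedema) is flagged
when an exudate lies within 1 disc diameter (DD) of the fovea.
Referability is a policy lookup (defaults: ICDRS ≥2 or DMO; NSC ≥R2 or
M1). A seeded bagged-tree ensemble trained on lesion feature vectors
provides the probabilistic grading path; the decision table is the
reference.

**Geometry.** All distances are in disc diameters, so pixel scale
cancels. The retina is partitioned into five fovea-centred regions
(≤1 DD, 1–1.5, 1.5–2, 2–3, >3) and four quadrants.

**Progression.** Baseline and follow-up visits of the same eye are
registered by the closed-form similarity transform through the two
anatomical landmarks (disc centre, fovea centre) — robust when
pathology obscures the vessels — and lesions are matched per type by
greedy nearest neighbour within 0.25 DD. Each lesion becomes one event:
`NEW`, `RESOLVED`, `GROWN`, `SHRUNK` (area ratio outside a ±20%
deadband) or `STABLE`, attributed to a region of the follow-up frame.

**Evaluation.** The feature-conditioned confusion outcomes used in
screening validation (an over-call is FP even on the same side of the
referral threshold; "only MAs on a mild image" is TN), sensitivity /
specificity / PPV / NPV with Wilson (or Clopper–Pearson) 95% CIs,
quadratic weighted kappa

&kappa;<sub>qw</sub> = 1 − &Sigma; w<sub>ij</sub> O<sub>ij</sub> / &Sigma; w<sub>ij</sub> E<sub>ij</sub>, &nbsp; w<sub>ij</sub> = (i−j)² / (k−1)²,

ROC curves with AUC and dual (high-sensitivity / high-specificity)
operating points, prevalence subsampling, and the workload-reduction
statistic (TN+FN)/n of a pre-screening filter.

**Synthetic cohorts.** `synthesise_for_level()` inverts the decision
tables (the output satisfies the target level's predicate and no higher
one), `sample_cohort()` draws graded cohorts at configurable
prevalences — presets encode three published national screening
compositions (15,000 / 10,026 / 28,680 images) — with a detector noise
model (misses, false alarms, jitter), and `synthesise_pair()` plants
longitudinal change events with exact ground truth. A raster phantom
renderer plus threshold/connected-component demo detector closes the
loop from pixels.

## Worked example

```r
library(drscreen)
g <- default_fundus_geometry()          # 2000x2000 px, 180 px disc, fovea centred
rec <- image_record("eye-042-baseline", g,
  lesion_frame(type = c("MA","MA","MA","HAEMORRHAGE","EXUDATE"),
               x = c(1080, 940, 1110, 760, 1120), y = c(950, 1060, 1150, 820, 1010),
               area = c(6, 8, 5, 70, 45)))
grade_record(rec, grading_table("icdrs"))
#> <grade_result> ICDRS 2 + maculopathy [referable] (rule: moderate)
grade_record(rec, grading_table("nsc"))
#> <grade_result> NSC R1 + maculopathy [referable] (rule: background)
```

The same lesion set grades moderate under ICDRS and R1 under NSC; the
exudate 0.67 DD from the fovea raises the maculopathy flag, which makes
both grades referable. A follow-up visit (camera shifted, the
haemorrhage doubled in area, one new haemorrhage):

```r
rep <- compare_visits(rec, followup)
rep
#> <progression_report> ICDRS 2 -> 2 (delta +0); NEW=1 RESOLVED=0 GROWN=1 SHRUNK=0 STABLE=4
rep$events
#>     kind lesion_type region baseline_id followup_id area_ratio
#> 1 STABLE          MA      1           1           1   1.000000
#> 4  GROWN HAEMORRHAGE      3           4           4   2.285714
#> 6    NEW HAEMORRHAGE      3          NA           6         NA
```

Screening evaluation of a noisy synthetic cohort (10% misses, 0.2
spurious detections per image per type):

```r
co <- sample_cohort("china", 200, noise_model(miss_prob = 0.1,
                                              false_alarm_rate = 0.2), seed = 1)
grades <- grade_cohort(co, grading_table("nsc"))
evaluate_cohort(grades, co$truth, grading_table("nsc"))$REFERABLE
#> <eval_summary> n=200 TP=18 TN=127 FP=53 FN=2 (wilson 95% CI)
#>   sensitivity  90.00% (69.90-97.21%)
#>   specificity  70.56% (63.52-76.73%)
#>   ppv          25.35% (16.68-36.55%)
#>   npv          98.45% (94.52-99.57%)
#>   accuracy     72.50% (65.93-78.22%)
```

Sensitivity stays high while the false-alarm channel (spurious lesions
read as higher grades) costs specificity — the characteristic error
mode of lesion-based graders, here visible directly in the FP count.

A command-line interface covers the same pipeline
(`simulate`, `grade`, `progress`, `evaluate`, `roc`):

```sh
Rscript -e 'drscreen::drscreen_cli()' simulate --preset kenya --n 500 --seed 3 --out run/
Rscript -e 'drscreen::drscreen_cli()' grade --annotations run/annotations.json --scheme icdrs --out run/
Rscript -e 'drscreen::drscreen_cli()' evaluate --grades run/grades_icdrs.csv --truth run/truth.csv --out run/
```

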