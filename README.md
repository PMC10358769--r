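# atcprofiles

Medication-profile clustering and longitudinal cluster tracing for type 2
diabetes cohorts built from free-text electronic medical records (EMR).

## What it does

Clinicians' visit notes carry a patient's prescription history as plain
text. `atcprofiles` turns a registry of such notes into a longitudinal
picture of how medication burden evolves with age:

1. **Extraction** — drug mentions are resolved to ATC level-5 codes
   (`A10BA02` = metformin) through a surface-form lexicon, exploiting the
   ATC hierarchy: truncating a code gives its therapeutic class
   (`A10BA02 → A10`, drugs used in diabetes).
2. **Cohort filter** — the inclusion cascade of a diabetes-clinic study:
   reject O24 (gestational diabetes) patients; keep records reporting an
   E11-branch diagnosis; keep notes longer than 100 characters; keep
   patients with ≥ 10 visits inside a 10-year window; reject patients
   younger than 30. Every stage is audited.
3. **Profiles** — per patient and 10-year age group (30–39 … 80+), the
   binary vector over ATC level-2 classes ever prescribed in that group.
   Medication *diversity* is the number of distinct classes,
   `n_distinct_lv2`.
4. **Clustering** — Ward-linkage agglomerative clustering of each age
   group's profiles on Euclidean distances, cut at a fixed merge height
   (default 16); clusters are labeled C1…Cn by ascending mean diversity.
5. **Tracing** — clusters of adjacent age groups are linked one-to-one by
   greedy ascending centroid distance; a linked cluster inherits its
   predecessor's profile identity, an unlinked one opens a new identity.
6. **Flows** — patients followed across a group boundary contribute
   transitions, classified **Not Worse** (same identity, or a
   lower-or-equal-diversity cluster) or **Worse**, with per-pair odds
   `n_worse / n_not_worse` (Sankey-ready tables exported).
7. **Reporting** — ATC usage shares per age group (levels 1/2/4),
   diversity order statistics, per-cluster prescription frequencies, and
   Kruskal–Wallis/ANOVA comparisons of laboratory values (glucose,
   cholesterol, triglycerides, eGFR) across clusters.

Real cohorts of this kind are access-restricted, so the package includes
a seedable synthetic EMR generator (`generate_cohort()`) with planted
medication archetypes, planted filter decoys and planted lab shifts —
every downstream stage is testable against exact ground truth, and
user-supplied tables in the same schema drop straight in.

## Worked example

```r
library(atcprofiles)

cfg <- cohort_config(600, seed = 901, visits_per_year = 0.5,
  archetype_mix = default_archetype_mix(), archetype_persistence = 0.7,
  frac_non_e11 = 0.1, frac_o24 = 0.05, frac_short_text = 0.05)
cohort <- generate_cohort(cfg)
res <- run_pipeline(cohort)

res$audit
#> <filter_audit>
#>               stage records_removed patients_removed records_left patients_left
#>               input               0                0        10459           600
#>        o24_patients             628               36         9831           564
#>         e11_records            1051               61         8780           503
#>  short_text_records             617               36         8163           467
#>     sparse_patients               0                0         8163           467
#>  under_age_patients               0                0         8163           467

res$solutions[["60-69"]]
#> <cluster_solution> [60-69] 217 profiles -> 2 clusters (ward linkage, cut at 16, euclidean metric)
#>   C1: n = 90, mean distinct LV2 = 2.21
#>   C2: n = 127, mean distinct LV2 = 7.46

res$odds
#> <transition_stats> (odds mode)
#>  from_group to_group n_not_worse n_worse       odds proportion_worse
#>       30-39    40-49          91       0 0.00000000       0.00000000
#>       40-49    50-59          69      43 0.62318841       0.38392857
#>       50-59    60-69         107      11 0.10280374       0.09322034
#>       60-69    70-79         121       9 0.07438017       0.06923077
#>       70-79      80+         117       0 0.00000000       0.00000000
```

Reading the output: the audit drops the planted decoys exactly (36 O24
patients, 61 without E11, 36 with only short notes); the 60–69 group
splits into a low-medication cluster (C1, mean 2.2 distinct level-2
classes) and a polypharmacy cluster (C2, mean 7.5); worsening odds are
lowest at the youngest and oldest transitions and highest in midlife,
where the archetype mix shifts fastest. `res$diversity` shows mean
diversity rising from 2.4 (30–39) to 5.3 (60–69), and
`res$usage_lv2` ranks A10 (antidiabetics) first, prescribed to every
patient in every age group.

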