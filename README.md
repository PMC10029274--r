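# darshape

Geometric categorization of animal **diel activity routines (DARs)** from
high-frequency relocation data.

A DAR is the movement path of one individual over one 24-hour diel window
(here 10:00 to 10:00 local time) — for a nocturnal central-place forager,
one roost-to-roost night. darshape is aimed at movement ecologists with
second-to-minute resolution telemetry (reverse-GPS/ATLAS arrays, modern GPS
tags) who want to classify what *kind* of night an animal had — local
wandering, a commute, a large excursion, a one-way move — and compare those
routine types across individuals, sexes, ages, seasons and places.

## The method

Each quality-filtered, diel-segmented night is reduced to four scalar
whole-path metrics (all in km):

| metric | definition | captures |
|---|---|---|
| net displacement | distance between averaged start and end points | openness |
| max displacement | farthest distance from the start point | reach |
| max diameter | largest pairwise distance; its segment is the *diameter line* | extent |
| max width | sum of the largest perpendicular offsets on either side of the diameter line | elongation |

These are insensitive to relocation frequency (unlike step-length or
turning-angle statistics), which makes them robust descriptors at the
whole-night scale. The z-scored metrics are clustered by Ward linkage
(`ward.D2`), with the number of clusters k chosen from the
within-sum-of-squares curve via the relative slope change
f(k) = (s(k−1) − s(k))/s(k−1), s(k) = wss(k+1) − wss(k). A correlation PCA
of the same matrix yields an all-positive first component — a composite
**extent** (size) factor — plus an **openness** (PC2) and an **elongation**
(PC3) factor. Group comparisons use chi-squared contingency tests of
type-by-group tables and a linear mixed model
`sqrt(size) ~ sex + age + (1 | individual) + (1 | night)`.

A synthetic trajectory generator emulating seven archetypal night
geometries (five closed types of increasing scale, one of them transverse;
one partially open; one wide open) makes every stage testable without field
data.

## Worked example

Simulate a 7-individual cohort (one archetype each, 35 nights, ~1.1 M raw
fixes) and run the full pipeline — filtering, diel segmentation, night
quality, flight/stop segmentation, endpoint averaging, 5-min subsampling,
metrics, Ward clustering at k = 7, PCA:

```r
library(darshape)
res <- run_all(simulate = TRUE, cohort_spec = archetype_cohort_spec(35),
               config = dar_config(seed = 7))

res$report$n_dars
#> [1] 245

truth <- res$truth$archetype[match(names(res$labels),
          paste(res$truth$individual_id, res$truth$night_date, sep = "_"))]
adjusted_rand_index(res$labels, truth)
#> [1] 0.9902973

head(res$k_candidates, 3)      # elbow candidates, ranked by f(k)
#>   k         f
#> 4 7 0.6809736
#> 1 2 0.6390168
#> 3 6 0.5651399

round(res$pca$variance_fraction, 3)
#> [1] 0.741 0.198 0.060 0.000
```

All 245 complete nights survive extraction; cutting the Ward tree at k = 7
recovers the generating archetypes almost perfectly (adjusted Rand index
0.99), and the elbow heuristic's top candidate is the true k = 7. PC1
carries 74% of the variance with all-positive loadings (net displacement
smallest), PC2 is dominated by net displacement — the extent/openness
pattern expected when most routines are closed.

The per-cluster summary reproduces the archetype regimes, e.g. the
transverse cluster (mean diameter 3.6 km, mean width 0.70 km — ratio below
1/4) and the wide-open cluster (mean net displacement 4.1 km):

```r
res$summary[, c("cluster", "n", "net_displacement_mean", "max_diameter_mean",
                "max_width_mean", "openness", "transverse")]
#>   cluster  n net_displacement_mean max_diameter_mean max_width_mean       openness transverse
#> 1       1 35            0.11229707         0.8136899      0.3386262         closed      FALSE
#> 2       2 35            0.10443073         1.7561436      0.7486738         closed      FALSE
#> 3       3 36            0.40198269         2.4542570      1.2519484 partially open      FALSE
#> 4       4 35            0.15234476         3.6250534      0.6952486         closed       TRUE
#> 5       5 34            0.09233816         3.5086394      1.8932164         closed      FALSE
#> 6       6 34            0.15548727         6.0543762      2.0263670         closed      FALSE
#> 7       7 35            4.09059338         4.8972860      1.7507813      wide open      FALSE
```

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/darshape.R run --simulate --nights 50 --seed 1 --out outdir/
```

which writes `metrics.csv`, `labels.csv`, `wss_curve.csv`,
`pca_loadings.csv`, `cluster_summary.csv`, `cohort_records.csv` and a JSON
run report.

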