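# cptriage

Triage of cytotoxic and nuisance compounds from cell-painting morphological
profiles and companion cell-health readouts.

High-content morphological profiling (cell painting) is a powerful,
target-agnostic way to annotate compound libraries — but many of the "hits"
it produces act through undesirable mechanisms: nonspecific electrophiles,
redox cyclers, aggregators, and outright cytotoxins. These compounds tend to
produce strong, stereotyped "gross injury" morphologies together with reduced
cell numbers. `cptriage` implements the analysis pipeline used to
characterize such compounds in concentration-response (qHTS) screens, so that
new screening hits can be compared against reference cellular-injury
phenotypes and prioritized or discarded accordingly.

Who it is for: screening groups and chemical biologists with well-level
feature tables (e.g. CellProfiler output aggregated per well), plate maps,
live-cell imaging time courses, and glutathione plate readouts.

## The method

Given a wells × features matrix with plate/compound/concentration/replicate
metadata:

1. **Normalization.** Per plate and feature, robust z-scores against the
   vehicle (DMSO) wells: `z = (x − median_veh) / (1.4826 · MAD_veh)`.
   Redundant features are removed greedily until no pair has
   `|Pearson r| > 0.9` (threshold configurable).
2. **Activity score.** For each compound × concentration, replicate wells
   are stacked with all vehicle wells; PCA (scaled, uncentered) keeps the
   first *q* components explaining ≥ 90% of variance; the two groups'
   covariances are pooled with sample-size weights,
   `Σ = (n_t Σ_t + n_c Σ_c) / (n_t + n_c)`, and the activity score is the
   Mahalanobis distance between group centroids,
   `D = sqrt((μ_t − μ_c)ᵀ Σ⁻¹ (μ_t − μ_c))`.
3. **Activity cutoff.** Vehicle wells are partitioned into seeded
   pseudo-treatment groups and scored the same way; the cutoff is
   `mean + 3·SD` of these null distances (strict inequality).
4. **Phenotype clustering.** Active treatment profiles (replicate-averaged,
   reduced feature set) are clustered with `1 − Pearson r` distances and
   Ward linkage, cut at k = 9; the phenotype of a cluster is the feature-wise
   mean of its members. External profiles are matched to cluster signatures
   by Pearson correlation over shared features (HC / NC / intermediate
   calls), and per-compound concentration trajectories ("rainbow plots")
   report the assigned cluster at each dose.
5. **Cell health.** Live-cell time courses (confluence, caspase-3/7,
   membrane integrity; 0–60 h every 4 h) are background-corrected with
   reagent-free wells and summarized as trapezoid AUCs. Glutathione
   luminescence plates are quantified through a 10-point standard curve
   (6.4 µM → 13 nM, 2-fold), with `GSH = total − 2·GSSG`, the GSH:GSSG
   ratio, and outlier flags (GSSG > 200% of vehicle; ratio withheld when
   computed GSH < 0).

A seeded synthetic-screen generator (`synth_config()`, `generate_screen()`,
`generate_timecourses()`, `generate_glutathione_plate()`) emits all of these
inputs with ground-truth labels, and is what the test suite uses to verify
recovery of planted phenotypes end to end.

## Worked example

```r
library(cptriage)

cfg    <- synth_config(n_features = 100, n_compounds_per_cluster = 2,
                       n_inert_compounds = 3, n_vehicle_wells_per_plate = 24,
                       seed = 42)
screen <- generate_screen(cfg)
print(screen$profiles)
#> <well_profiles> 696 wells x 100 features [raw]
#>   plates: 4  roles: positive_control=96 treatment=504 vehicle=96

norm  <- robust_z_normalize(screen$profiles)
red   <- reduce_redundant_features(norm$profiles, threshold = 0.9)
length(red$reduction$retained)
#> [1] 22

scored <- score_screen(norm$profiles, seed = 42)
round(scored$threshold$cutoff, 2)
#> [1] 3.54
```

The activity table for one compound shows the expected concentration
response — the score climbs past the 3-SD vehicle cutoff while the relative
cell number falls (the inverse activity/cell-count relationship typical of
injury compounds):

```r
scored$results[scored$results$compound_id == "CPD001",
               c("concentration_um", "activity_score", "active",
                 "relative_cell_number")]
#>  concentration_um activity_score active relative_cell_number
#>             0.625           1.85  FALSE                 94.1
#>             1.250           3.36  FALSE                 89.4
#>             2.500           5.10   TRUE                 71.3
#>             5.000           9.85   TRUE                 51.6
#>            10.000          13.73   TRUE                 43.5
#>            20.000          13.57   TRUE                 41.6
```

Clustering the active treatments and reading one compound's trajectory:

```r
prof  <- treatment_profiles(red$profiles)
keys  <- with(scored$results,
              paste(compound_id, concentration_um, sep = "@"))[scored$results$active]
prof  <- prof[rownames(prof) %in% keys, ]
model <- ward_cluster(correlation_distance_matrix(prof, ids = rownames(prof)), k = 9)
print(model)
#> <cluster_model> 100 profiles, k = 9 (ward.D2 linkage)
#> cluster
#>  1  2  3  4  5  6  7  8  9
#> 18  9 11 10 13  7 14  9  9

cluster_trajectory(scored$results, model$labels, "CPD001")
#>  concentration_um activity_score active cluster
#>             0.625       1.854426  FALSE      NA
#>             1.250       3.362235  FALSE      NA
#>             2.500       5.104176   TRUE       2
#>             5.000       9.847846   TRUE       2
#>            10.000      13.731188   TRUE       2
#>            20.000      13.570211   TRUE       2
```

Inactive doses carry no cluster label; once active, this compound sits
stably in one phenotype cluster across doses.

## Pipeline / CLI

The whole analysis runs as seeded, manifest-logged stages writing CSV
artifacts:

```r
run_pipeline("all", config = list(), outdir = "run", seed = 1)
```

or from the shell via `inst/cli/cptriage.R`:

```sh
Rscript inst/cli/cptriage.R all --outdir run --seed 1
```

Stages: `simulate`, `normalize`, `score`, `cluster`, `match`, `health`,
`report`. Re-running with the same config and seed reproduces byte-identical
tables.

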