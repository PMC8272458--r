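# mpdascreen

Multi-parametric analysis (MPDA) and hit calling for image-based
high-content compound screens in 384-well plates.

## The problem

High-content screens read out each well not as a single intensity but as a
microscope image of a phenotype — here, fluorescent reporter-positive
stem-cell colonies. Each plate carries **active control** wells (AC: the
desired phenotype maintained — many compact, bright colonies) and
**negative control** wells (NC: the phenotype collapsed — sparse, small,
dim debris). A compound is a *hit* when its well resembles the active
controls even though the maintaining stimulus was withdrawn.

`mpdascreen` quantifies that resemblance:

1. **Segmentation & features** — objects are segmented per field (Otsu
   threshold with a robust background floor), measured (area,
   circumference, diameter, circularity 4πA/P², anisometry, compactness;
   mean/median/total/max/min intensity), and aggregated per well into a
   fixed **112-feature** profile (9 statistics × 11 measures + 6
   shape–intensity covariances + 7 well scalars).
2. **Plate QC & feature selection** — the Z′-factor,
   `Z' = 1 − 3(σ₊+σ₋)/|μ₊−μ₋|`, ranks features by their AC-vs-NC window;
   the top features (default ≤ 10, Z′ ≥ 0) are retained.
3. **Mahalanobis scoring** — AC and NC control populations are modelled
   per plate as multivariate normals with shrunk covariance
   `Σ = (1−λ)S + λ·tr(S)/d·I`; every well receives distances
   `MHD(x) = sqrt((x−μ)ᵀΣ⁻¹(x−μ))` to both models (Cholesky solves, no
   explicit inverse). Plate QC is the Z′ between the AC and NC wells'
   MHD-to-AC distributions.
4. **Triage & hit calling** — wells are triaged (`dead`, `disparate`,
   `ac_like`, `nc_like`); a compound is a final hit when, in **every**
   duplicate run, its MHD-to-AC is more than 1 SD below the NC wells'
   mean MHD-to-AC and it stays `ac_like`. Dose-range validation and
   target-class summaries (MEK1, TNKS, PKC, …) complete the pipeline.

Because no raw screen images are publicly deposited, the package includes
a seeded synthetic screen generator — both rendered 16-bit well images
with ground truth and a fast feature-space simulator — calibrated once so
the default pipeline reproduces the plate-performance regime of a
well-behaved screen (mean plate Z′ ≈ 0.6).

## Worked example

Simulate a duplicate-run 384-well screen in feature space, score each
replicate, and call hits:

```r
library(mpdascreen)

cfg <- screen_sim_config()              # documented defaults
sim <- simulate_screen_tables(cfg, seed = 42)

score_rep <- function(tb) {
  feats <- setdiff(names(tb), c("well", "role", "compound_id", "replicate"))
  x <- as.matrix(tb[, feats]); rownames(x) <- tb$well
  ps <- score_plate(x, tb$role)
  sc <- triage_wells(ps$scores)
  sc$compound_id <- tb$compound_id
  list(scores = sc, zprime = ps$zprime, subset = ps$subset)
}
reps <- lapply(sim$tables, score_rep)

reps[[1]]$zprime
#> Z' = 0.7019  (n+ = 16, n- = 16)
reps[[1]]$subset
#> feature_subset: 6 features
#>   area_mean                    Z' = 0.334
#>   area_median                  Z' = 0.295
#>   area_sum                     Z' = 0.234
#>   area_sd                      Z' = 0.193
#>   area_max                     Z' = 0.156
#>   area_min                     Z' = 0.039

hits <- call_hits(lapply(reps, `[[`, "scores"))
sum(hits$final_hit)                     # 18 hits out of 352 compounds
intersect(hits$compound_id[hits$final_hit],
          sim$truth$compound_id[sim$truth$is_active])  # all 18 planted actives
```

The first replicate plate shows an excellent assay window (plate
Z′ = 0.70 on the Mahalanobis scores); per-feature selection picked six
area statistics whose individual windows are modest (Z′ 0.04–0.33) —
multivariate scoring is what turns them into a clean separation. All 18
planted actives are recovered with no false positives.

The same pipeline runs from images on disk:

```r
cfg <- run_config(seed = 7, sim = list(n_compound = 10, n_ac = 6, n_nc = 6,
                                       image_size = 96, fields_per_well = 1),
                  min_controls = 6)
run_simulate(cfg, "my_run")   # TIFFs + plate maps + truth table
run_analyze(cfg, "my_run")    # scores, QC, hits, report.md
```

A thin CLI wrapping these functions is installed at
`system.file("cli", "mpda", package = "mpdascreen")` with subcommands
`simulate`, `extract`, `analyze`, `report`.

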