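# favmeta

Fuzzy-logic analysis of species distributions on atlas grids: fit
prevalence-corrected **favorability** models to gridded presence/absence
data, delimit favorable habitat **patches**, decide whether a species'
distribution has a **metapopulation** structure, and map the
**connectivity** of the inter-patch matrix from a least-cost friction
analysis.

The package is aimed at biogeographers and landscape ecologists working
with atlas-style occurrence data (e.g. 10 × 10 km UTM grids): one row per
grid cell per species, plus environmental predictor layers on the same
grid.

## The method

**Favorability.** A logistic regression gives each cell an occurrence
probability *P*. Probability confounds local environmental quality with
how common the species is, so it is transformed to favorability

> F = (P/(1−P)) / (n₁/n₀ + P/(1−P))

where n₁ and n₀ are the numbers of presence and absence cells. F is a
fuzzy membership degree in \[0, 1\]: F = 0.5 exactly where *P* equals the
species' prevalence n₁/(n₁+n₀), so maps of different species share one
scale. Variables enter the model through univariate logistic screening
under Benjamini–Hochberg FDR control (q < 0.05), forward–backward
stepwise selection by AIC, and Wald-significance trimming (α = 0.05).
Models are evaluated by CCR, sensitivity, specificity, under- and
over-prediction rates and Cohen's kappa at the F = 0.5 threshold, the
rank-based AUC, and the Hosmer–Lemeshow index with 10 equal-count bins.

**Metapopulation structure.** Contiguous cells with F ≥ 0.8 form
favorable patches (queen adjacency by default); a patch containing at
least one recorded presence is occupied in its entirety, and empty
patches are kept — they are the recolonizable habitat. A distribution is
classified a metapopulation when the favorable area is patchy (≥ 2
patches) and more than half of the recorded presences fall in
high-favorability cells.

**Connectivity.** The matrix (F < 0.8) opposes movement with friction
1 − F. Least cost to reach each cell from any patch is accumulated by
multi-source Dijkstra over the 16-cell knight's neighborhood (step cost =
step length × mean friction of the two endpoint cells; lengths 1, √2, √5).
Costs become connectivity via
`1 − (cost − min cost)/(max cost − min cost)`, rescaled to \[0, 0.9\] on
the matrix — 0.9 at the patch border, 0 at the maximum cost — with patch
interiors set to 1, and graded into eighteen 0.05-wide levels for
mapping.

A synthetic landscape generator (spatially autocorrelated predictor
fields, species drawn from a known logistic model, multi-nucleus
"fragmented" scenarios) provides ground truth for every stage.

## Worked example

```r
library(favmeta)

favorability(0.3, n1 = 30, n0 = 70)   # at prevalence -> 0.5
#> [1] 0.5
favorability(0.5, n1 = 20, n0 = 80)   # odds/(r + odds) -> 0.8
#> [1] 0.8

cfg <- generator_config(seed = 42, n_rows = 55, n_cols = 55,
                        n_predictors = 6, autocorr_scale = 4,
                        target_prevalence = 0.15)
scenario <- make_fragmented_scenario(cfg)   # two favorable nuclei, known truth
fit <- favorability_fit(scenario$occurrence, scenario$landscape)
summary(fit)
#> favorability model 'fragmented' (glm fit)
#>   n1 = 470 presences, n0 = 2555 absences (prevalence 0.155)
#>   variables: blob
#>   AIC 630.60
#>
#> Coefficients:
#>         term estimate std_error      z    p_value
#>  (Intercept)   -3.016    0.1363 -22.13 1.786e-108
#>         blob    4.121    0.1984  20.78  7.209e-96
#>
#> univariate screening (FDR q = 0.05): 5 of 9 predictors accepted
#>   accepted: env01, env03, env04, env05, blob

evaluate_model(fit)
#> classification @ F >= 0.50: CCR 0.946, sens 0.919, spec 0.951,
#>   UPR 0.081, OPR 0.223, kappa 0.810
#> discrimination: AUC 0.976 (outstanding)
#> calibration: HL 3.41, p 0.906 (well-calibrated)

report <- run_species(scenario$occurrence, scenario$landscape)
report
#> species report 'fragmented'
#>   model: blob (AIC 630.60)
#>   AUC 0.976 (outstanding); category metapopulation (2 patches, 2 occupied)

scenario$truth$n_true_patches   # the generative truth the fit recovered
#> [1] 2
```

The fitted model recovers the planted `blob` predictor (true slope 4 on
the standardized scale, estimated 4.12 ± 0.20), classifies the species'
distribution as a metapopulation, and finds the same two patches present
in the true favorability surface. `run_species(..., out_dir = )` writes
the favorability, probability, patch-label and (binned) connectivity
surfaces as ESRI ASCII grids plus a JSON report; `run_panel()` processes
a list of species and tabulates structure categories, AUC classes and
calibration verdicts.

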