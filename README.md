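# cytoscreen

Mechanistic analysis of mass cytometry (CyTOF) immunophenotyping cohorts
with a dichotomous clinical outcome — built for the oral-immunotherapy
setting in which participants who pass an allergen challenge after a period
of avoidance (**SU**, sustained unresponsiveness) are contrasted with those
who react (**DS**, desensitized), but applicable to any two-arm,
batch-structured single-cell study. The intended users are computational
immunologists and trial biostatisticians who need every step of such an
analysis to be scripted, seeded and testable.

The pipeline covers:

* **Preprocessing** — arcsinh transform (`asinh(x / 5)`), CD127 exclusion
  from the lineage set, landmark density alignment across samples
  (monotone piecewise-linear warps of KDE modes), 50,000-live-cell
  subsampling, extreme-outlier screening by Tukey fences (`coef = 3.0`).
* **Gating** — a declarative YAML gating tree (26 shipped PBMC
  populations) producing subset frequencies and median signal intensities.
* **Clustering** — self-organizing map (10×10, seeded, Rcpp) with
  average-linkage metaclustering to a fixed cluster count (30).
* **Differential testing** — per-feature likelihood-ratio χ²(1) tests
  between nested mixed models (group fixed effect, batch random
  intercept, ML fits), Benjamini–Hochberg FDR within each analysis family,
  significance rule `p < 0.05 & q < 0.1`; Wilcoxon/Mann–Whitney paths for
  analyte data.
* **Stability selection** — the core statistic: simulate the baseline
  table R times, fit a cross-validated elastic-net logistic regression per
  replicate, score features 0–100 by max-scaled standardized
  coefficients, and report per feature the **cumulative importance**

  $$\mathrm{CumulativeImportance}_j \;=\; \frac{\sum_{i=1}^{R} \delta_{ij}}{R}\times 100,
  \qquad \delta_{ij} = \mathbf{1}\{\,\mathrm{score}_{ij} > 80\,\},$$

  together with ensemble AUC / sensitivity / specificity from out-of-fold
  predictions.
* **Serology screening** — Spearman correlations of features against
  peanut-specific IgE, Ara h 2-specific IgE and IgG4/IgE ratios, gated at
  `|ρ| > 0.4` and raw `p < 0.001`, with OLS line + 95% band for reporting.
* **Synthetic cohorts** — a fully seeded generator (participants, events,
  feature tables, serology) with known ground truth, so every stage above
  is testable without any data download.

See `vignettes/methods.Rmd` for the models, assumptions and design
decisions in detail.

## Worked example

Simulate the 46-participant baseline (20 SU vs 26 DS, 123 features, two
truly discriminative features at standardized shift 1.5), run a
50-iteration stability ensemble, and screen the serology:

```r
library(cytoscreen)

cfg <- cohort_config(seed = 42, n_su = 20, n_ds = 26,
                     n_informative = 2, effect_size = 1.5)
cohort   <- generate_cohort(cfg)
baseline <- generate_feature_table(cohort, cfg)
cohort_truth(baseline)$informative_features
#> # A tibble: 2 × 2
#>   feature  effect
#>   <chr>     <dbl>
#> 1 feat_081    1.5
#> 2 feat_055   -1.5

ens <- run_ensemble(baseline,
                    simulation_strategy("per_feature_jitter"),
                    ensemble_config(iterations = 50, seed = 42))
ens
#> Stability-selection ensemble: 50 iterations, 123 features
#> mean AUC 0.819 | mean sensitivity 0.864 | mean specificity 0.616
#> top features by cumulative importance:
#> # A tibble: 5 × 3
#>   feature  cumulative_importance mean_score
#>   <chr>                    <dbl>      <dbl>
#> 1 feat_055                    92       95.0
#> 2 feat_081                    48       70.5
#> 3 feat_078                     4       35.2
#> 4 feat_112                     2       31.9
#> 5 feat_047                     2       24.6
```

Both planted features head the cumulative-importance ranking: `feat_055`
exceeded the score-80 cut in 92% of the 50 simulate-and-refit iterations,
`feat_081` in 48%, and no noise feature reached 5%. The ensemble separates
the arms with mean out-of-fold AUC 0.82 across replicates. The same two
features — and no others — come out of mixed-effects differential testing
(`differential_analysis(baseline)`: q = 0.004 and 0.043), and the
generator's planted serology links pass the correlation screen:

```r
sero <- generate_serology(cohort, baseline)
dplyr::filter(screen_serology(baseline, sero), passes_screen)
#> # A tibble: 2 × 8
#>   feature  serology        n   rho        p passes_screen slope intercept
#>   <chr>    <chr>       <int> <dbl>    <dbl> <lgl>         <dbl>     <dbl>
#> 1 feat_081 peanut_sIgE    46 0.510 0.000294 TRUE          0.160      2.11
#> 2 feat_081 arah2_sIgE     46 0.520 0.000210 TRUE          0.132      3.05
```

The observed Spearman ρ of 0.51/0.52 sits close to the planted targets
(0.45/0.47). `autoplot(ens)`, `autoplot(differential_analysis(baseline))`
and `plot_correlation(baseline, sero, "feat_081", "peanut_sIgE")` give the
standard figures; `tidy()`/`glance()` return the tables. The full
orchestrated run — events, alignment, gating, clustering, testing,
stability, correlation, with a reproducibility manifest — is
`run_pipeline(pipeline_config(seed = 1))`.

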