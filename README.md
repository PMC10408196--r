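# microresist

Is a person's gut microbiome going to budge when they change diet, start
exercising, or take antibiotics? Longitudinal metagenomics shows wide
person-to-person differences: some communities are plastic, others resist
restructuring. `microresist` is an R package for analysts of longitudinal
microbiome studies that quantifies this, end to end:

* **Stability** of diversity indexes, taxa and pathways as intraclass
  correlation coefficients — the two-way random-effects, absolute-agreement,
  mean-of-k-ratings form
  `ICC(A,k) = (MS_R − MS_E) / (MS_R + (MS_C − MS_E)/n)`
  on transformed measurements, with subject-level bootstrap CIs; ICC ranges
  from 0 (no stability) to 1 (perfect stability), values above 0.5 are
  called stable.
* **Responder classification**: the day-to-day Bray–Curtis fluctuation of
  no-intervention cohorts (sample pairs 1–2 days apart) yields cutoffs
  mean + SD and mean + 2·SD; each intervention subject is scored at the
  first peak of their Bray–Curtis trajectory from baseline and labeled
  non-responder (< mean + SD), partial responder ([mean + SD, mean + 2SD]),
  or responder (> mean + 2SD).
* **Biomarkers of responsiveness**: PERMANOVA on baseline dissimilarities,
  proportional-odds ordinal regression across the three ordered groups,
  Wilcoxon tests with log2 fold changes, chi-square enrichment, Spearman
  species–pathway association, stratified contribution linking, and SparCC
  co-abundance networks with degree/closeness centrality comparisons.
* **Prediction**: a gradient-boosting classifier of responder vs
  non-responder from the baseline microbiome alone, with recursive feature
  elimination to 30 features, grid-tuned by LOOCV/k-fold, evaluated over 100
  stratified 80/20 splits, plus external-cohort evaluation.

A synthetic-study generator (logistic-normal + multinomial, with closed-form
true stability `rho = sigma_b2/(sigma_b2 + sigma_w2)`, planted responders
and planted discriminative taxa) makes the whole pipeline testable without
any sequence data. Readers/writers are included for merged taxonomic tables
(pipe-delimited lineages, percent or proportion dialects), stratified
functional tables (`PWY|g__X.s__Y` rows, CPM), metadata TSVs and Newick
trees.

## Worked example

```r
library(microresist)

# an undisturbed control cohort, and its daily-fluctuation cutoffs
ctl <- simulate_control_cohort(simulation_config(n_subjects = 40, seed = 42))
baseline <- estimate_daily_fluctuation(study_species_table(ctl), ctl$metadata)
baseline
#> fluctuation_baseline: mean 0.3866, sd 0.0525 (cutoffs 0.4391 / 0.4916; 40 pairs, gap <= 2 d)

# an intervention cohort with planted responders, classified at first peak
int <- simulate_intervention_cohort(
  simulation_config(n_subjects = 50, timepoints = c(0, 14), seed = 42))
assessment <- classify_cohort(study_species_table(int), int$metadata, baseline)
table(assessment$label)
#>     non_responder partial_responder         responder
#>                20                 5                25
head(assessment, 3)
#>   subject_id selected_day bc_value         label
#> 1   INT_S001           14  0.79792     responder
#> 2   INT_S002           14  0.80502     responder
#> 3   INT_S003           14  0.39762 non_responder

# per-species stability of the control cohort
prof <- feature_icc_profile(study_species_table(ctl), ctl$metadata,
                            n_boot = 200, seed = 42)
sprintf("species ICC: mean %.2f, %d/%d stable (ICC > 0.5)",
        mean(prof$icc[prof$valid]), sum(prof$icc[prof$valid] > 0.5),
        sum(prof$valid))
#> "species ICC: mean 0.73, 97/100 stable (ICC > 0.5)"
```

The cutoffs say: an undisturbed gut drifts by Bray–Curtis ≈ 0.39 ± 0.05 from
one day to the next, so only subjects displaced beyond 0.49 are called
responders. Half of the intervention arm was planted as responders
(post-intervention log-abundance shifts on 30% of taxa) and the
classification recovers them; the control community itself stays stable
(mean species ICC 0.73, matching the Spearman–Brown value 0.8 of the planted
`rho = 2/3` up to the arcsine-square-root attenuation discussed in the
vignette).

`run_stability_analysis()` and `run_response_pipeline()` orchestrate the
full flow (diversity → ICC → classification → differential abundance →
networks → ML) and write per-stage TSVs plus a JSON manifest of file
digests; see the methods vignette
(`vignettes/microbiome-stability-methods.Rmd`) for the models, defaults and
numerical decisions.

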