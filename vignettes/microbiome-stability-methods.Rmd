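---
title: "Quantifying gut-microbiome stability and responsiveness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gut-microbiome stability and responsiveness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microresist)
```

# The scientific problem

Longitudinal shotgun metagenomics shows that some people's gut communities
barely move under a dietary, exercise, or even antibiotic intervention, while
others are restructured wholesale. `microresist` implements a complete
analysis chain for this phenomenon:

1. **Stability** — how reproducible is a microbiome measurement across
   repeated visits of the same subject? Quantified by the intraclass
   correlation coefficient (ICC).
2. **Responsiveness** — did an intervention move a subject's community more
   than the day-to-day fluctuation of an undisturbed gut would? Quantified by
   Bray-Curtis displacement against control-cohort cutoffs.
3. **Biomarkers** — which taxa and functions differ, at baseline, between
   people who respond and people who resist? Ordinal regression, rank tests,
   enrichment tests, species-pathway correlation, and SparCC co-abundance
   networks.
4. **Prediction** — can the baseline community alone predict who will
   respond? Gradient-boosted classifiers with recursive feature elimination
   over repeated train/test splits.

Because the real cohorts behind such analyses are thousands of deposited
metagenomes, the package ships a synthetic-study generator with known ground
truth so that every stage is testable end to end on a desktop.

# The synthetic-study generator

The generator uses a **logistic-normal + multinomial** law. For subject $i$
and species $j$:

$$ m_{ij} \sim N(\mu_j, \sigma_b^2), \qquad
   y_{ijt} = m_{ij} + \varepsilon_{ijt}, \quad
   \varepsilon_{ijt} \sim N(0, \sigma_w^2) $$

The visit composition is $\mathrm{softmax}_j(y_{ijt})$ and counts are
multinomial at the configured depth. The additive decomposition on the log
scale gives every species the same closed-form intra-visit correlation

$$ \rho = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2}, $$

which is the package's ground truth for parameter-recovery tests. A
Dirichlet law would not give this closed form; that is why logistic-normal
was chosen.

Default conditions, chosen once as a realistic undisturbed gut:

| parameter | default | meaning |
|---|---|---|
| `sigma_b2` | 1 | between-subject log-abundance variance |
| `sigma_w2` | 0.5 | visit-to-visit variance ($\rho = 2/3$: stable controls) |
| `mu_sd` | 1 | spread of species means (~2 orders of magnitude rank-abundance) |
| `depth` | 50000 | multinomial reads per sample |
| `effect_size` | 5 | post-intervention log shift on affected taxa of responders |
| `affected_fraction` | 0.3 | taxa shifted per responder (community-wide displacement without single-taxon artifacts) |
| `responder_fraction` | 0.5 | planted responders per intervention arm |
| `informative_offset` | 2 | baseline offset of planted discriminative taxa (2x the between-subject SD: a strong biomarker effect) |

Intervention cohorts additionally plant `n_informative` species whose
*baseline* means differ between (future) responders and non-responders, so
the machine-learning stage has a recoverable signal, and shift a random 30%
of taxa by $\pm$`effect_size` in each responder's post samples. Pathway
tables are exact weighted sums of contributing species' relative abundances,
re-expressed per sample as copies per million, with one stratified row per
contributor.

**What the generator does not emulate:** subject-specific species pools
(presence/absence turnover), realistic phylogenies (the emitted tree is a
random coalescent, only there to exercise UniFrac), batch effects across
cohorts, and read-level artifacts. Passing tests therefore demonstrate the
statistical machinery, not robustness to those real-data features.

# Stability: the intraclass correlation

Per-feature relative abundances are arcsine-square-root transformed;
diversity measurements are gaussianized with the rank-based inverse-normal
transform (Blom offsets, ties sharing mean ranks — deterministic and
distribution-free, unlike automatic transform selectors). The ICC is the
**two-way random-effects, absolute-agreement, mean-of-k-ratings** form,

$$ \mathrm{ICC}(A,k) =
   \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}, $$

from the subjects-by-occasions ANOVA mean squares. Negative estimates are
truncated to 0 because the stability scale runs from 0 (no stability) to 1
(perfect stability); values above 0.5 are called stable (strict inequality,
exposed as an argument). Confidence intervals are percentile bootstrap over
*subjects* — the exchangeable unit of a repeatability design — with 1000
resamples by default. Estimates are non-valid when fewer than 3 complete
subjects remain, when k < 2, or when total variance is zero (e.g. a species
absent from the whole cohort).

For $k$ exchangeable visits, the estimator converges to the Spearman-Brown
reliability of the truth, $k\rho / (1 + (k-1)\rho)$. Two numerical caveats
are documented because they are intrinsic, not bugs:

* **Transform attenuation.** The arcsine-square-root transform is nonlinear;
  at large log-scale variance (e.g. $\sigma_b^2 = \sigma_w^2 = 1$ and
  beyond) the per-species Pearson correlation of transformed proportions
  falls below $\rho$, in the manner of the classical lognormal correlation
  attenuation $(e^{\rho s^2}-1)/(e^{s^2}-1)$. At the package's default noise
  the effect is within 0.05 of the closed form; estimator-recovery tests on
  direct two-variance-component data are exact.
* **Chao1 degeneracy at saturating depth.** With 50k reads and ~100 species,
  every taxon is observed in every sample, observed richness is constant,
  and the chao1 ICC is rightly non-valid or near zero. Subject-level
  richness signal appears at moderate depth with a wide rank-abundance
  spread, which is how the high-stability demonstration cohort is
  configured.

```{r icc-demo}
ctl <- simulate_control_cohort(simulation_config(n_subjects = 30, seed = 1))
prof <- feature_icc_profile(study_species_table(ctl), ctl$metadata,
                            n_boot = 50, seed = 1)
summary(prof$icc[prof$valid])
2 * (2/3) / (1 + 2/3)   # Spearman-Brown value of the planted rho
```

# Responsiveness: fluctuation cutoffs and first-peak selection

The day-to-day fluctuation of an undisturbed gut is estimated from all
control-subject sample pairs 1-2 days apart (window configurable); the
pooled Bray-Curtis values' mean and SD give two cutoffs, mean + SD and
mean + 2SD. An intervention subject's trajectory of Bray-Curtis distances
from baseline is reduced to its **first peak** — the earliest local maximum,
with runs of equal values compressed and a qualifying plateau reported at
its first day (this earliest-day rule also covers trajectories that end on a
plateau). Labels follow

* non-responder: below mean + SD,
* partial responder: in the closed interval [mean + SD, mean + 2SD],
* responder: above mean + 2SD,

so that under pure fluctuation the expected label proportions are the normal
tail masses 84.1% / 13.6% / 2.3%. Pooling pairs across subjects (rather than
averaging per subject first) matches how dissimilarity distributions are
usually displayed per cohort and weights subjects by their pair counts.

# Group statistics

**PERMANOVA** uses the pseudo-F on among/within sums of squared distances
with free label permutation and $p = (1 + \#\{F^\ast \ge F\}) / (1 +
n_{perm})$; on Euclidean distances it reduces exactly to the coordinate
one-way ANOVA F, which the tests verify to 1e-8 together with agreement with
`vegan::adonis2`.

**Ordinal differential abundance** fits the proportional-odds model
$P(Y \le j) = \mathrm{logistic}(\theta_j - \beta x)$ per feature on
arcsine-square-root abundances (no covariate adjustment), by Newton
iteration with step halving on a standardized covariate; the converged
gradient is below 1e-8 and the fit matches `MASS::polr` to ~1e-5 in the
tests. Wald p-values come from the observed information; monotone separation
(diverging slope) is detected and flagged, with a likelihood-ratio fallback
p-value. $\beta > 0$ means enriched in responders. Significance thresholds
differ per analysis in practice (species q < 0.2, pathways and KOs q < 0.1)
and are therefore arguments, not constants; all adjustment is
Benjamini-Hochberg.

**Wilcoxon tests** (normal approximation with tie correction) compare
responders against non-responders per feature with
$\log_2\mathrm{FC} = \log_2((\bar{x}_R + \epsilon)/(\bar{x}_{NR} +
\epsilon))$, where $\epsilon$ is half the smallest nonzero value of the
table — a pseudo-count tied to the data scale, since CPM and relative tables
differ by $10^6$. Chi-square enrichment is the 2x2 Pearson statistic without
continuity correction, warning when an expected count drops below 5.
Species-pathway association is Spearman's rho with t-approximation p-values
and BH across the whole matrix. Stratified contribution linking calls a
species a contributor to a pathway when its stratified row is nonzero in at
least 10% of samples, and reports the mean stratified/community fraction.

# SparCC co-abundance networks

Basis correlations are solved from the log-ratio variation matrix
$T_{ij} = \mathrm{var}(\log x_i / x_j)$ under the sparsity assumption, with
up to 20 rounds of excluding the strongest pair above |rho| = 0.1 (both
configurable); a pseudo-count of 0.5 precedes the log-ratios. The desk-scale
implementation uses the pseudo-count point estimate rather than averaging
over Dirichlet resamples. Null p-values resample each feature's values
independently across samples — breaking cross-feature association while
keeping marginals — and count how often the null |rho| reaches the observed
one. Networks keep edges with BH-adjusted p below 0.1, nodes without edges
remain as isolates, and centralities are computed on the binarized graph:
degree, and component-normalized closeness $(c-1)/\sum d$ with isolates at
0. On a known-correlation logistic-normal basis (50 taxa x 200 samples) the
estimator's RMSE against the true correlations is ~0.02, well inside the
0.12 the tests require.

# The response classifier

Features are baseline abundances; partial responders are excluded. Per
train/test split (stratified 80/20, 100 repeats by default):

1. near-zero-variance filter (frequency ratio > 95/5 and unique fraction
   < 10%) and z-scoring, both fit on the training part only;
2. recursive feature elimination with the boosting learner's gain
   importance — subset sizes halve until at most twice the 30-feature
   target, then step by one ("halve" mode goes straight down, used for
   large repeated runs);
3. grid search over interaction depth, tree count, learning rate and
   minimum node size, scored by cross-validated AUC — leave-one-out up to 60
   training samples, stratified k-fold beyond;
4. held-out AUC, sensitivity and specificity at probability 0.5 (the
   operating point is an argument).

The learner is gradient-boosted trees via xgboost; the minimum-node-size
grid axis is specified in observations and internally rescaled to xgboost's
hessian units (~0.25 per observation under the logistic loss). The final
model refits selection and tuning on all data; external cohorts are joined
by terminal clade name with absent features imputed as zero *before* the
training scaling — never re-standardized on themselves.

One behavior worth knowing when interpreting permutation nulls: with ~100
subjects and hundreds of features, a *single* fixed label permutation
retains random overlap with the true labels and carries its own chance
feature associations, so its repeated-split mean AUC can sit anywhere around
0.38-0.6. Unbiasedness (mean AUC 0.5) emerges across fresh permutations,
which is how the package's null checks are constructed.

# Orchestration and reproducibility

`run_stability_analysis()` and `run_response_pipeline()` wire the stages
together from in-memory cohorts, write per-stage TSVs plus a JSON manifest
of MD5 digests, log feature/sample counts per stage, and skip gracefully
(with an explicit notice) when a stage's preconditions fail — e.g. fewer
than 5 subjects per class for the classifier, or a single response group for
PERMANOVA. Every stochastic stage consumes a seed derived deterministically
from one master seed, so identical runs produce identical manifests. YAML
configurations are validated against the known key set; unknown keys are
errors because silent typos corrupt analyses.

# Problem sizes used by the shipped checks

The test-suite and the acceptance script run entirely on synthetic studies:
control cohorts of 60 subjects x 2 visits, intervention cohorts of 100
subjects (baseline + day 14), 100 species / 25 genera / 30 pathways,
SparCC at 50 taxa x 200 samples, 500-replicate type-I simulations for
PERMANOVA, 400 fully-null replicates for the ordinal-regression FDR check,
and 100-model repeated-split evaluations for the classifier. These sizes
were chosen so each property is measured with useful precision while the
whole suite stays desk-scale.

# Known limitations

* ICC variants are fixed to the two-way absolute-agreement family; no
  REML/mixed-model repeatability with covariates, no >2-level designs.
* No compositional differential-abundance methods (ALDEx2/ANCOM style); the
  ordinal and rank tests operate on (transformed) relative abundances.
* Rarefaction and phylogenetic alpha diversity are out of scope; UniFrac is
  included solely as a beta metric.
* The generator's planted effects are calibration choices — the magnitudes
  of real intervention effects are not estimated from data.
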