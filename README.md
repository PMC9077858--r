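# pedsep

Computable 24-hour phenotypes of pediatric severe sepsis: derivation,
bedside assignment, and downstream epidemiology, as a tested R package.

## The problem

Pediatric severe sepsis is heterogeneous: beneath one admission diagnosis
sit subgroups with mortality ranging from ~2% to ~34% and sharply
different propensities to develop thrombocytopenia-associated multiple
organ failure (TAMOF), macrophage activation syndrome (MAS),
immunoparalysis (IPMOF) and sequential liver failure (SMOF). A
*computable phenotype* is a subgroup definition a computer can evaluate
from bedside data alone within the first 24 PICU hours — the prerequisite
for enrolling the right children into early, phenotype-targeted trials.

`pedsep` implements the full derivation pipeline:

* **Synthetic cohort generation** calibrated to the reference cohort of
  404 children (four latent phenotypes, PedSep-A/B/C/D, at 34/25/27/14%),
  with per-phenotype clinical marginals, day-1 organ-failure rates,
  subsequent-MOF rates, mortality, length of stay and therapy exposure as
  exact simulation parameters (`sim_config()`, `generate_cohort()`).
* **A clinical rule engine**: the organ failure index (OFI, 0–6), SIRS
  count against age-banded references, and the empirical MOF phenotypes —
  e.g. MAS = ferritin > 500 ng/mL with platelets < 100 K/mm³, INR > 1.5,
  ALT > 100 U/L and bilirubin > 1 mg/dL on one day (`rule_set()`,
  `ofi_score()`, `mof_labels()`).
* **Variable screening**: most-abnormal-in-window day-1 feature
  extraction, the < 20% missingness / < 60% correlation screen that takes
  52 candidate variables to 25, median/mode imputation, and a stored
  log/z transform (`screen_variables()`, `transform_standardize()`).
* **Consensus k-means** with resampling: for each k, the consensus matrix
  M(k) holds the fraction of subsampled k-means runs co-clustering each
  patient pair; the area A(k) under the CDF of consensus values and its
  relative change Δ(k) = (A(k) − A(k−1))/A(k−1) select the number of
  phenotypes (largest k with Δ(k) ≥ 0.1), and an average-linkage cut of
  1 − M yields final labels and centroids (`consensus_cluster()`).
* **Bedside assignment**: nearest centroid in the stored standardized
  space, with median imputation for missing inputs and reference outcome
  annotation (`assign_phenotype()`, `risk_annotation()`).
* **Statistics**: Kruskal–Wallis / chi-square / Fisher group comparisons
  with Benjamini–Hochberg adjustment, unadjusted and covariate-adjusted
  odds ratios, non-nested daily organ-failure and mortality curves, chord
  links, biomarker log-ratios (`compare_groups()`, `adjusted_or()`, ...).
* **Treatment-interaction screening**: univariable therapy selection,
  elastic-net logistic models over 14 therapies and their 91 pairwise
  combinations (105 cells), OR < 0.1 flagging, and logistic confirmation
  of flagged interactions (`elastic_net_grid()`, `confirm_interaction()`).

## Worked example

```r
library(pedsep)

cfg    <- sim_config()                       # calibrated defaults, n = 404
cohort <- generate_cohort(cfg, seed = 1)
cohort
#> Synthetic sepsis cohort: 404 patients, 4712 patient-day rows
#> latent_phenotype
#>   A   B   C   D
#> 141  91 116  56

# 52 candidate variables -> 25 retained
cand   <- make_candidate_table(cohort)
screen <- screen_variables(cand)
screen
#> Variable screening: 25 of 52 candidates retained

feats <- impute_features(cand[, c("patient_id",
                                  screen$variable[screen$retained])])
cmx   <- transform_standardize(feats)
model <- consensus_cluster(cmx, n_iterations = 200, seed = 1)
model
#> Consensus k-means model
#>   k range 2-6, 200 iterations, subsample 0.80
#>   chosen k = 4
#>   delta area: k=2 0.432, k=3 0.312, k=4 0.237, k=5 0.055, k=6 0.063
#>   cluster sizes:
#> PedSep-A PedSep-B PedSep-C PedSep-D
#>      140      115      126       23

# bedside assignment of a new patient
new_patient <- extract_day1_features(generate_cohort(cfg, seed = 99))[7, ]
assign_phenotype(new_patient, model)[, c("label", "n_missing_inputs")]
#>      label n_missing_inputs
#> 1 PedSep-B                0
risk_annotation("D")[, c("phenotype", "mortality_pct", "tamof_pct", "mas_pct")]
#>   phenotype mortality_pct tamof_pct mas_pct
#> 1  PedSep-D          33.9        50    33.9
```

The chosen k = 4 recovers the four latent phenotypes; the delta-area
curve collapses after k = 4 (little statistical gain from a 5- or 6-class
model). The per-phenotype risk annotation reports the reference outcome
rates (e.g. PedSep-D: 33.9% mortality, 50% TAMOF, 33.9% MAS).

A thin command-line front end is installed with the package
(`inst/scripts/pedsep.R`): subcommands `simulate`, `rules`, `screen`,
`cluster`, `assign`, `all` map one-to-one onto the exported functions.

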