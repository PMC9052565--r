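# crpcnet

Stability-selected partial-correlation networks and survival subgroups
for synthetic castration-resistant prostate cancer (CRPC) cohorts.

## The problem

Registry studies of docetaxel-refractory CRPC treated with cabazitaxel
have linked overall survival (OS) to baseline factors (visceral
metastases, ECOG performance status) and, intriguingly, to on-treatment
neutropenia — but the patient-level data behind such analyses are closed
to public access, so the machine-learning workflow itself cannot be
inspected, stress-tested, or reused. `crpcnet` rebuilds that workflow as
a tested R package and pairs it with a synthetic cohort generator whose
dependency structure is *planted* (known), so every stage can be
validated end to end and its edge recovery scored against ground truth.

The package is aimed at biostatisticians and methods researchers who
want to study — or reuse — this class of registry analysis: 660
patients, 91 explanatory variables, three response variables (OS,
time-to-treatment-failure TTF, PSA response), one-year administrative
censoring.

## The methods core

* **Graphical-Markov stage.** Conditional independence of variables
  *i*, *j* given a set *S* is tested with the Fisher-z
  partial-correlation test, `z = atanh(r)`,
  statistic `sqrt(n - |S| - 3) |z|`, where `r` comes from the inverse of
  the correlation submatrix (ridge-stabilised when ill-conditioned;
  degenerate tests signal "incomputable" and never interrupt the run).
  A PC-stable skeleton search (conditioning sets up to size 3) runs in
  each of B resampling iterations; a pair is retained when present in
  strictly more than B/2 iterations (the \>500-of-1000 rule), with a
  sign call from its final surviving partial correlation.
* **Consensus clustering.** The retained graph (edge weight = stability
  frequency) is partitioned by seven community-detection algorithms
  (edge betweenness, leading eigenvector, fast-greedy, Louvain, label
  propagation, walktrap, infomap); a factor is associated with a
  response when they co-cluster in ≥ 4 of 7 models, and an association
  is called positive when its positive-direction frequency is ≥ 0.8.
* **Survival stage.** Kaplan–Meier curves with Greenwood errors and
  Brookmeyer–Crowley median CIs, log-rank tests, and univariate Cox
  hazard ratios (Efron ties) for six pre-specified subgroups.
* **Scoring.** `recovery_metrics()` compares any selected edge set with
  the planted graph: precision, recall, sign accuracy.

The methods vignette (`vignettes/crpcnet-methods.Rmd`) derives the
generative model, documents every tunable parameter, and explains a
statistical point central to the design: majority-vote stability over
*bootstrap* resamples of a single dataset cannot remove dataset-level
false positives (a null pair's selection frequency is about
`pnorm(|z| - z_alpha)`), whereas over *re-simulated* cohorts false-edge
frequencies concentrate binomially near alpha. Both regimes are
implemented in `stability_run()`.

## Worked example

```r
library(crpcnet)

# twenty calibrated cohorts, pooled (13,200 patients)
cohorts <- lapply(1:20, function(s) generate_cohort(default_config(), s)$cohort)
s <- summarize_cohort(do.call(rbind, cohorts))
s$km
#>   endpoint events median lcl ucl
#> 1       OS   6947    316 303 326
#> 2      TTF  10782    114 111 119
subset(s$binary, variable == "neutropenia")$percent
#> [1] 58.14394

# recover the planted graph: stability selection over 200 re-simulated cohorts
cfg  <- default_config()
sim  <- generate_cohort(cfg, seed = 1)
enc  <- encode_table(sim$cohort, sim$dictionary)
refresh <- function(seed) {
  x <- generate_cohort(cfg, seed)
  encode_table(x$cohort, x$dictionary)$matrix[, colnames(enc$matrix)]
}
acfg <- analysis_config(alpha = 0.05, iterations = 200, min_count = 100,
                        seed = 7)
res  <- stability_run(enc$matrix, acfg, refresh = refresh)
sel  <- select_stable_edges(res, acfg)
nrow(sel)
#> [1] 20
subset(sel, var1 == "OS" & var2 == "TTF")
#>   var1 var2 selection_count frequency positive_fraction     sign
#> 4   OS  TTF             200         1                 1 positive
unlist(recovery_metrics(sel, sim$graph)[c("precision", "recall", "sign_accuracy")])
#>     precision        recall sign_accuracy
#>     0.9500000     0.8636364     1.0000000

# confirmatory subgroup analysis on one cohort
sg <- subgroup_analysis(sim$cohort)
sg$liver_metastasis$hazard_ratio$hr   # > 1: liver metastasis, worse OS
#> [1] 2.598557
sg$neutropenia$hazard_ratio$hr        # < 1: neutropenia, better OS
#> [1] 0.3602107
```

The pooled KM medians (316 and 114 days), the neutropenia incidence
(58.1%), and the subgroup hazard-ratio directions match the published
cohort summaries the generator was calibrated to; the recovery metrics
show that stability selection over re-simulated cohorts finds 19 of the
22 planted edges with one extra edge and every sign correct.

## The analysis workflow

Numbered drivers under `analysis/` rerun the whole study narrative and
write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate the default cohort, planted graph, baseline summary |
| `02_gm_stability.R` | bootstrap stability selection at alpha 0.05 and 0.01 (B = 1000) |
| `03_consensus.R` | seven-model clustering and the ≥ 4-of-7 consensus vote |
| `04_survival.R` | KM subgroup tables, log-rank tests, hazard ratios |
| `05_recovery.R` | re-simulation stability run scored against the planted graph |

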