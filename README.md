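# pdoresponse

Chemotherapy-response classification for gastric-cancer organoid drug
screens, and transfer of the response groups to external expression
cohorts.

Patient-derived organoids (PDOs) screened against combination chemotherapy
give a sample × regimen viability matrix. This package implements the
analysis chain around that matrix:

1. **Screen classification** — viabilities are normalized to untreated
   controls, replicates averaged, regimens annotated by mechanism of action
   (taxane-containing → *anti-microtubule*; otherwise *anti-replication*),
   and the matrix bi-clustered (Euclidean/Ward). The three sample clusters
   are named from their MOA-class centroids: `double_sensitive` (lowest
   anti-replication viability), `not_sensitive` (highest anti-microtubule
   viability), `single_sensitive` (the remainder), with a loud failure when
   the rules collide. Samples with viability > 0.75 under the
   5-fluorouracil + oxaliplatin reference regimen carry a *resistant* flag.
2. **Signatures and markers** — gene-set scores are mean per-gene z-scores;
   score–viability correlations flag resistance programs; per-group marker
   panels come from one-vs-rest Wilcoxon tests (BH, q < 0.05, positive
   effect, top 25 by effect, disjoint across groups).
3. **Transfer** — external cohorts are scored against the panels
   (z-scored within the cohort); label = argmax panel, `undefined` when the
   best panel's mean z is not significantly positive (one-sided t across
   panel genes). A clustering-based mode is available for comparison.
4. **IC50 imputation** — ridge regression (closed form via SVD, penalty
   from 10^(−3..4) by seeded 10-fold CV) trained on cell-line expression
   after quantile homogenization, predicting per-drug log10 IC50 that is
   z-scaled and compared across the groups (Kruskal–Wallis + one-sided
   pairwise rank tests).
5. **Outcome association** — Kaplan–Meier / log-rank (median-split markers,
   O/E hazard ratio) and per-group somatic-mutation enrichment
   (Fisher exact, Haldane–Anscombe odds ratios, BH within group).

A synthetic-data generator (`sim_config()`, `gen_*()`) emulates every input
at the study geometry — 19 samples (groups 7/9/3), 5 regimens, 3 replicates,
latent-factor cell-line expression — with planted truth serialized beside
the data, so every claim the pipeline makes is checked by recovery.

## Worked example

```r
library(pdoresponse)

cfg <- sim_config(seed = 3)                 # study-geometry defaults
scr <- gen_viability_screen(cfg)
cls <- classify_screen(scr$screen, cfg$regimens)
table(cls$assignment$group)
#> double_sensitive    not_sensitive single_sensitive
#>                7                3                9
round(cls$centroids, 2)
#>                  anti_microtubule anti_replication
#> double_sensitive             0.44             0.55
#> single_sensitive             0.45             0.86
#> not_sensitive                0.86             0.83
cls$separation
#> [1] 10.19454
```

The centroid table reads directly as the group definitions: the
double-sensitive row is killed by both regimen classes (viability ≈ 0.45
and 0.55 against a 0.85 baseline), the single-sensitive row only by
anti-microtubule regimens, the not-sensitive row by neither. The
separation statistic (smallest centroid gap over within-cluster spread)
is ~10, i.e. the split is unambiguous; values near or below 2 mean the
naming should not be trusted.

The full chain — simulate → classify → markers → transfer → impute →
compare → survival/mutations — runs as numbered drivers:

```sh
Rscript analysis/01_simulate.R        # writes results/data/ + truth sidecar
Rscript analysis/02_classify_screen.R
Rscript analysis/03_signatures_markers.R
Rscript analysis/04_transfer.R
Rscript analysis/05_impute_ic50.R
Rscript analysis/06_survival_mutations.R
Rscript analysis/99_report.R          # only stage that reads the truth
```

Stage 5, for example, prints the group means of scaled IC50 and recovers
the planted pattern — the anti-microtubule-like drug low in the double- and
single-sensitive groups, the anti-replication-like drug low only in the
double-sensitive group:

```
     drug              moa mean_double mean_single mean_not    kruskal_p
  drug_mt anti_microtubule  -0.5803002 -0.72363191 1.109468 1.043603e-22
 drug_rep anti_replication  -0.9959092  0.07078777 1.136871 1.358605e-25
```

`run_pipeline(pipeline_config(seed = 1))` performs the same chain in one
call, writing artifacts plus a manifest of file hashes; two runs with the
same seed are byte-identical.

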