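# mirisk

Differential expression and risk scoring for serum circulating miRNA
case-control studies.

Small "extreme case-control" designs — e.g. diabetic-retinopathy (DR) cases
with short diabetes duration vs non-retinopathy (NDR) controls with long
duration — can surface large miRNA expression differences from ~20 serum
samples, but only if the analysis handles three things honestly: counts are
overdispersed, group is confounded with age by design, and any classifier
evaluated on its own discovery samples is optimistic. `mirisk` implements
that analysis end to end, with the statistics it relies on validated against
brute-force oracles and simulations at the actual study size.

## The model

Counts for miRNA *i* in sample *j* are negative binomial,

    K_ij ~ NB(mu_ij, alpha_i),   mu_ij = s_j * q_i * 2^(beta_i x_j + gamma_i a_j)

with size factor `s_j` (median-of-ratios), case indicator `x_j`, age `a_j`,
and `beta_i` the log2 fold change (LFC). Per-miRNA dispersions are Cox–Reid
adjusted profile-ML estimates; the group coefficient gets a Wald test and
Benjamini–Hochberg correction; DE calls use raw p ≤ 0.01 and |LFC| ≥ 2
(screening rule for small n). The polygenic risk score of sample *j* is the
LFC-weighted sum of log-FPM values over the DE panel,

    S_j = sum_i LFC_i * log2(FPM_ij + 1)

evaluated by midrank Mann–Whitney AUC, DeLong confidence interval and
Youden-optimal cutoff. Validated target genes of the panel are tested for
pathway over-representation with the hypergeometric upper tail against an
explicit background (default N = 20,000). A seeded simulator generates
NB count matrices with the same design (10 vs 11 samples, 756 abundant
miRNAs, age confounded with group) so the whole pipeline runs and is tested
without any external data. See `vignettes/serum-mirna-methods.Rmd` for the
full methods account.

## Worked example

The `analysis/` scripts run the workflow on simulated data:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_risk_score.R
Rscript analysis/04_enrichment.R
```

Step 02 prints (abridged):

```
abundance filter: 754 of 756 miRNAs retained
9 DE miRNAs at raw p <= 0.01 and |LFC| >= 2:
        mirna base_mean   lfc    se   pvalue     padj
 sim-miR-0022      61.5 -3.46 0.695 6.40e-07 1.61e-04
 sim-miR-0167     144.2 -4.91 0.909 6.57e-08 4.95e-05
 ...
planted-truth check: sensitivity 4/5, observed FDR 0.56
```

i.e. 4 of the 5 planted effects are recovered, and the raw-p screening rule
admits false positives at this sample size — the observed FDR is printed,
not hidden. Step 03 then reports

```
AUC = 0.936, 95% DeLong CI [0.833, 1.000] (direction case_high; in-sample, optimistic)
Youden-optimal cutoff -225.034: sensitivity 1.000, specificity 0.818
```

where `in-sample` flags that the LFC weights and the evaluation share the
same 21 samples, and step 04 finds the planted 4-of-11 pathway overlap at
raw p = 1.66e-08 (Bonferroni 6.74e-06 over 405 sets). Functions can equally
be called directly; `run_pipeline(pipeline_config(counts, samples, ...))`
executes read → merge → filter → normalize → DE → score → enrich in one call
and writes TSV/JSON outputs.

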