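---
title: "Methods: negative-binomial differential expression and polygenic risk scoring for serum miRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: negative-binomial differential expression and polygenic risk scoring for serum miRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirisk)
```

## The problem and the model

Circulating miRNAs in serum are candidate minimally invasive biomarkers.
The design this package targets is a small extreme case-control study:
diabetic-retinopathy cases (DR) selected for short diabetes duration against
non-retinopathy controls (NDR) with long duration, which enriches for genuine
susceptibility differences at the price of strong confounding between group
and age. The analysis must therefore adjust for age while working with
10-vs-11 samples — too few for asymptotics to be taken on faith, which is why
the package ships a simulator and calibration checks alongside the estimators.

Counts for mature miRNA $i$ in sample $j$ are modelled as negative binomial,

$$K_{ij} \sim \mathrm{NB}\big(\mu_{ij},\ \alpha_i\big), \qquad
\mu_{ij} = s_j\, q_i\, 2^{\beta_i x_j + \gamma_i a_j}, \qquad
\mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2,$$

with $s_j$ the library size factor, $x_j$ the case indicator, $a_j$ age, and
$\beta_i$ the log2 fold change (LFC) reported throughout. Fitting is a
log-link GLM by iteratively reweighted least squares with offset $\log s_j$;
coefficients and standard errors (inverse observed Fisher information) are
converted to log2 units. The group coefficient is tested with a Wald test,
$z = \hat\beta/\widehat{\mathrm{se}}$ against the standard normal, and
corrected across miRNAs by Benjamini–Hochberg.

### Dispersion

Each miRNA's dispersion is estimated by maximizing the Cox–Reid-adjusted
profile likelihood — the NB log-likelihood at the fitted coefficients minus
$\tfrac12 \log\det(X^\top W X)$ — over $\alpha \in [10^{-8}, 10]$ on the log
scale. The adjustment counteracts the downward bias of plain ML when three
coefficients are estimated from 21 samples. Deliberately, there is **no
empirical-Bayes shrinkage** toward a mean–dispersion trend: with a single
small data set the per-gene estimator keeps the procedure transparent and
self-contained, at the cost of noisier dispersions than trend-shrinkage
pipelines produce; DE calls on real data will not match such pipelines
gene-for-gene, and the package does not claim they should. If the profile
likelihood cannot be evaluated, a method-of-moments estimate on normalized
counts is substituted and flagged (`dispersion_method = "mom"`).

### Normalization

Size factors are median-of-ratios: over features positive in all samples,
$s_j = \mathrm{median}_i\, K_{ij} / (\prod_l K_{il})^{1/n}$, rescaled to
geometric mean 1. FPM ("normalized fragments per million") is the
size-factor-normalized count rescaled so the *mean* per-sample total is
$10^6$: $\mathrm{FPM}_{ij} = 10^6 (K_{ij}/s_j) / m$ with
$m = \mathrm{mean}_j \sum_i K_{ij}/s_j$. The log transform defaults to base 2
with pseudocount 1 — base 2 coheres with the LFC units, and the pseudocount
keeps zero counts finite. Both are configurable; nothing in the downstream
mathematics depends on the choice except the absolute scale of risk-score
cutoffs, which is why a cutoff value learned under one convention is not
transferable to another.

### DE calling on raw p-values

A miRNA is called DE when raw $p \le 0.01$ **and** $|\mathrm{LFC}| \ge 2$
(both thresholds inclusive, configurable). The raw-p rule is intentional: at
$n = 21$ with ~750 tests, BH-adjusted values rarely clear conventional
thresholds even for large, consistent effects, and the joint raw-p/effect-size
rule is the established screening practice for such designs. The cost is a
high false-discovery proportion among calls, which the pipeline reports
against planted truth in simulation rather than hiding. Non-converged fits
are excluded from the BH denominator (only tested hypotheses are counted)
and logged.

### Abundance filter and ordering of steps

Features with total count (over all samples) below 200 are removed *after*
merging precursor-level counts to mature miRNAs and *before* size-factor
estimation, so every downstream quantity is a function of retained features
only; `size_factors_on = "all"` switches the basis to the unfiltered matrix.
The boundary is retained: a total of exactly 200 stays in. Merging sums
counts of precursors sharing a mature ID and conserves per-sample totals
exactly; feature order is first-appearance order, never hash order.

## The polygenic risk score

For the DE panel with weights $w_i$ (the LFCs), each sample's score is
$S_j = \sum_i w_i L_{ij}$ over log-FPM $L$. With one panel miRNA and unit
weight this is just that miRNA's log-FPM, so single-marker ROC analyses are
the same code path. Evaluation: midrank Mann–Whitney AUC (ties count half),
an empirical ROC with thresholds at midpoints between distinct scores (its
trapezoidal area equals the midrank AUC exactly, ties included), a DeLong
structural-components confidence interval (bootstrap available), and the
Youden-optimal cutoff $\max(sens + spec - 1)$ with ties broken toward higher
sensitivity (screening-motivated) and then the lower cutoff.

Two honesty features are built in rather than optional. First, orientation:
with predominantly negative LFC weights, cases score *low*; instead of
silently flipping the sign, `roc_curve(..., direction = "auto")` records
which orientation was used. Second, circularity: weights estimated on the
same samples that are then classified inflate the AUC; the pipeline marks
the result `in_sample = TRUE` and the workflow scripts print the caveat.
The value of the cutoff depends on the log base/pseudocount convention, so
cutoffs are only comparable within one configuration.

## Target-gene enrichment

Validated targets of the DE panel are pooled (union, deduplicated after
whitespace/case normalization) and each gene set is tested by the
hypergeometric upper tail $P(X \ge k)$ with $k$ the overlap, $K$ the set
size, $n$ the query size and $N$ the background. $N$ is an explicit,
required parameter (default 20,000, the approximate protein-coding count)
because web enrichment tools pin it to unpublished annotation versions;
results are reported with both Bonferroni (headline, matching how corrected
enrichment p-values in this literature scale with the number of sets tested)
and BH corrections. Query genes outside a declared universe are excluded
from $n$ and logged.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws from exactly the NB model above. Defaults, chosen
once to mirror the target study design:

| parameter | default | rationale |
|---|---|---|
| group sizes | 10 vs 11 | the case-control design |
| features | 756 | abundant miRNAs after filtering |
| baseline abundance $q_i$ | log-normal, meanlog $\log 50$, sdlog 1.5, floor 15 | right-skewed serum profile; floor keeps the default stratum abundant |
| dispersion $\alpha_i$ | log-normal, median 0.3, sdlog 0.6 | moderate biological overdispersion for serum counts |
| size factors | log-normal sd 0.3, geomean 1 | realistic library-size spread |
| DE fraction | 5/756 | a handful of true signals |
| planted $|\beta|$ | Uniform(2, 4.26), negative w.p. 0.8 | the reported effect-size span; 4 of 5 reported effects were down |
| ages | N(47.10, 6.45²) cases, N(63.45, 4.25²) controls, truncated [18, 90] | reproduces the group–age confounding so the adjustment path is exercised |
| age effect $\gamma_i$ | 0 | no per-gene age effect sizes are reported; a confounded alternative is one parameter away |

Age is centred inside the mean model, so $q_i$ keeps its meaning as baseline
abundance when $\gamma_i \neq 0$ (a reparameterization, not a change of
model). `simulate_low_abundance_mix()` adds a low-abundance stratum whose
rows are guaranteed below the filter threshold (rows that cross it by
sampling noise are proportionally thinned back) so that contracts like
"fraction = 1 leaves nothing" hold deterministically; at fraction 0.7 of
2588 features it reproduces the 2588 → ~770 retention scale.
`make_target_fixture()` constructs a target table and pathway with an exact
55-gene union, 41 genes unique to the first panel miRNA, and a 4-of-11
pathway overlap, padded with decoy sets (default 404, giving 405 tested)
drawn from a disjoint synthetic background.

The simulator does **not** emulate: sequencing-depth-dependent technical
noise beyond the size factor, correlated miRNA modules, hemolysis artefacts,
a mean–dispersion trend, batch structure, or real miRNA identifiers. Passing
tests therefore demonstrate that the estimators recover the model they
assume at this sample size — not that the model captures everything in real
serum data.

## Calibration results the package itself verifies

The test suite (not this vignette) computes: unbiasedness of the LFC
estimator at planted LFC = 3 ($n$ = 10 vs 11, $\alpha$ = 0.2, 500
replicates, mean within 3 ± 0.25); a raw-p rejection rate on 2,000 null
genes with age confounding inside [0.005, 0.03] at the 0.01 threshold (the
NB Wald test is mildly anti-conservative at this $n$ — the band documents
it); dispersion recovery ($\alpha$ = 0.5, 100 per group, 90% of estimates in
[0.3, 0.7]); and exact agreement of BH, hypergeometric tail, trapezoid-AUC
and Youden maximization with brute-force oracles. Problem sizes (500
replicates, 2,000 null genes, 200 dispersion replicates) were chosen so
Monte-Carlo error is small relative to the bands being checked.

## Numerical choices and degenerate inputs

* IRLS: linear-predictor clamped to ±30, convergence at max coefficient
  change $<10^{-10}$, 100 iterations; fits with $|\beta|$ > 25 on the
  natural-log scale are flagged non-converged (separation guard) and get NA
  statistics.
* Dispersion search: `optimize()` on $\log\alpha$ over $[\log 10^{-8}, \log 10]$,
  tolerance $10^{-4}$; clamped at the bounds.
* Size factors with zeros everywhere: hard error by default, `poscounts`
  pseudo-reference on request; a sample with zero total count is always an
  error.
* ROC with tied scores: thresholds at midpoints between *distinct* values
  keep ties on one side, which is what makes trapezoid = midrank AUC an
  identity rather than an approximation.
* Degenerate AUC (0 or 1) at tiny $n$: DeLong variance collapses to 0; the
  interval is flagged `widened` instead of pretending certainty.
* All randomness is seeded; the generator pins the RNG kind so fixed seeds
  are reproducible across platforms.

## Known limitations

Per-gene Cox–Reid ML without shrinkage is noisy at $n = 21$; raw-p DE
calling trades FDR control for sensitivity and must be read as screening;
in-sample AUC is optimistic by construction; the enrichment background
$N$ materially changes p-values and must be stated with any result; and the
simulator's independence assumptions make power estimates optimistic
relative to correlated real profiles.
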