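---
title: "Methods: the susceptibility-gene screen and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the susceptibility-gene screen and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(susceptigene)
```

## The screening model

The package implements a three-stage funnel for nominating genes whose
loss selectively impairs one cancer type and whose overexpression marks
poor prognosis.

**Stage 1 (differential dependency).** Input is a gene × cell-line matrix
of CRISPR dependency scores (dimensionless; negative = knockout depletes
the cells) with a two-level grouping of cell lines into the target type
and the background. For each gene we compute the arithmetic mean score in
each group (`group_mean_scores()`; "average" is read as the mean, with a
median switch for sensitivity analysis) and select genes with
`mean_target < -0.5` and `mean_other > -0.2`
(`select_susceptibility_candidates()`). Both inequalities are strict —
the thresholds are worded as "below" and "higher than" — and a
`strict = FALSE` switch includes the boundary. Missing scores are dropped
from the averages; a minimum-observation gate (`min_obs`, default 1 per
group) controls eligibility. The selection is monotone in both
thresholds and invariant under gene reordering, and both properties are
tested.

**Stage 2 (expression enrichment).** Stage-1 passers are filtered on
tumor-versus-reference TPM: fold change > 3 and tumor-group mean
TPM > 10, again strict. The default fold dialect is linear,
`(mean_t + c)/(mean_r + c)` with pseudocount `c = 1`; because public
expression portals often work on `log2(TPM + 1)`, a second dialect takes
the difference of group means on that scale and reports `2^difference`,
so the same thresholds apply. Neither dialect is asserted to be "the"
original one; both are exposed and the default is stated. With
`pseudocount = 0` a zero reference mean yields an undefined (infinite)
fold, which is flagged and excluded from selection rather than passed.

**Stage 3 (survival).** For each remaining gene, samples are stratified
into the top and bottom expression quartiles
(`stratify_by_quantile()`, `q = 0.25`; `q = 0.5` gives a median split
covering all samples). Quantiles use R's default (type 7) definition;
samples exactly at a cut join the extreme group (inclusive cuts) so the
split is deterministic, with a strict-cut switch. The high-versus-low
contrast is scored twice:

* `cox_hr()` — univariate Cox proportional hazards, maximising the
  partial likelihood by Newton–Raphson from `beta = 0`, Breslow handling
  of tied event times by default (Efron optional), convergence when the
  update falls below `1e-8` or after 50 iterations, and a 95 % Wald
  interval from the observed information. A monotone likelihood
  (complete separation, e.g. all events in one group — detected when
  `|beta|` exceeds 15) is returned as a flagged non-converged result
  with infinite interval bounds, never as an exception, so a per-gene
  screen continues.
* `logrank_test()` — the standard two-group log-rank statistic: at each
  distinct event time the observed events in one group are compared with
  their hypergeometric expectation under the pooled risk set; the squared
  summed difference over the summed variance is referred to chi-square
  with 1 df.

`km_estimate()` implements the product-limit estimator for display and
checking; with no censoring it equals the empirical survival function
exactly. All three are written from first principles — they are the core
of the method — and are cross-checked in the tests against an
established survival library on random datasets (agreement to 1e-6) and
against hand-computed closed forms.

A gene is a final candidate if it passes stages 1–2 and has `hr > 1`
with `logrank_p < 0.05` (`run_screen()`). The source procedure ranks by
hazard ratio without a printed cut, so this cut is an explicit package
default, not a claim about the original analysis; both knobs are
arguments. Stages are strictly nested by default (each filter sees only
the previous stage's passers), which makes the funnel
`universe ≥ stage1 ≥ stage2 ≥ candidates` monotone by construction; a
non-nested mode scores every gene at every stage for exploration.

## Regulatory and downstream analyses

Interval tables follow BED conventions (0-based half-open); overlap means
sharing at least one base pair on the same chromosome, strand-agnostic —
the minimal standard reading, since the source rule states no minimum
overlap. `classify_peaks()` partitions peaks into promoter and
non-promoter peaks (the partition property is asserted on every random
fixture). `overlap_peaksets()` counts shared peaks from both sets'
perspectives separately because many-to-many overlap makes the two counts
differ; they are reported, not collapsed. `genomic_distribution()`
assigns each peak to the highest-precedence overlapping category
(promoter > exon > intron > intergenic by default) and compares against
the genome's base-pair composition under the same precedence.
`promoter_signal_rank()` aggregates peak signal per gene over its
promoters — maximum by default, because "highest promoter level" most
naturally reads as the strongest site; a `sum` mode exists — sorts
descending with deterministic `gene_id` tie-breaks, and returns the
top-n set (default 200) for enrichment testing. Internally these
operations run on GenomicRanges; the tests re-derive every result with
naive all-pairs scans.

The differential-expression stage is deliberately a *stand-in*: counts
are normalised by raw median-of-ratios size factors, shifted by a
pseudocount of 1, log2-transformed, and compared per gene with a Welch
t-test; the log2 fold change is the difference of condition means on the
transformed scale. It is not a negative-binomial GLM and does not claim
to be one — the filter (`de_filter()`: |fold| ≥ 2 inclusive, p < 0.01
strict, raw p by default with an optional BH mode) also accepts
externally computed (gene, log2fc, p) tables so any engine can sit
upstream. Degenerate convention: zero variance in both groups gives
p = 1 for equal means and p = 0 otherwise. The stand-in's null
calibration is checked by simulation (type-I error at p < 0.01 within
[0.005, 0.02] over 10,000 null negative-binomial genes).

`enrichment_score()` / `gsea_preranked()` implement preranked GSEA from
scratch: hits increment the running sum by `|metric|^p` (default
`p = 1`, the standard weighting) normalised over in-set weights, misses
decrement by `1/(N - k)`; the ES is the extremum of larger magnitude,
with exact magnitude ties resolved to the positive side. Ranking ties
keep stable input order; the permutation stream is governed only by the
seed. The null randomises set membership over the ranked universe
(gene-label permutation — the only option when the input is already a
ranked list), and both the nominal p and the NES are sign-stratified:
`p = (1 + #{|null ES| ≥ |ES|, same sign}) / (1 + #{same-sign null})` and
`NES = ES / mean |same-sign null ES|`. A consequence worth knowing: with
`n_perm` permutations the attainable p bottoms out near
`1/(n_perm/2 + 1)`, not `1/(n_perm + 1)`, because only same-sign nulls
enter the denominator; if no null shares the observed sign the p is
reported at its resolution bound and flagged. `run_integrative()` chains
promoter-signal ranking into a one-set preranked test on the
knockout-versus-control fold changes; a negative ES with small p says the
strongly promoter-bound genes sit among the downregulated ones.

## The synthetic-data generators

`sim_config()` fixes all generator conditions in one validated object;
identical configs give bit-identical outputs, and each generator draws
from its own substream of the seed so adding one never perturbs another.
Defaults mirror the study design the package emulates: 13 target-type
versus 345 background cell lines, a 173-sample tumor cohort with 70
reference samples, four replicates per RNA-seq condition; the original
screen covered 17,670 genes, and 2,000 is the desk-scale default
universe.

Distributional choices, each the simplest family consistent with the
data type: dependency noise is Normal(0, `noise_sd = 0.15`) around 0
(non-essential genes in public dependency data are approximately
centred at 0 with a spread of this order); expression background is
log-normal (gene-level `sdlog = 1` around `meanlog = log 10` TPM,
sample-level `sdlog = 0.5`), matching the heavy right tail of TPM;
counts are negative-binomial with dispersion 0.1 (0 = Poisson) and
log-normal gene means; survival baselines are exponential with rate
0.02 per month (median ≈ 35 months; a Weibull option exists), because
the exponential admits closed-form sanity checks; censoring is
independent Uniform(0, b) with b solved numerically so the expected
censored fraction under the baseline hazard equals `censoring_rate`
(approximate once planted hazard effects shift the rates).

Two benchmark-design choices deserve emphasis:

* **Planted overexpressed genes get the population-typical baseline**
  (`meanlog = log 10`) before the fold is applied. A fold planted on a
  gene whose random baseline is near zero would be undetectable by any
  method and would poison sensitivity estimates; pinning the baseline
  makes the planted fold identifiable ground truth. Background genes
  keep the full baseline lottery.
* **Planted prognostic genes form a co-expressed signature.** One latent
  high-risk quartile of tumor samples is drawn and upregulated by
  `risk_fold = 4` in every prognostic gene, and the hazard is multiplied
  by `prognostic_hr` once for that group. Multiplying hazards
  independently per gene would compound to absurd rates
  (`2.5^30` for thirty planted genes) and, conversely, attenuate every
  gene's *marginal* high-versus-low hazard ratio below the declared
  truth. The signature construction keeps each planted gene's marginal
  HR equal to `prognostic_hr`, and reduces to the literal per-gene rule
  when a single gene is planted. Biologically this mimics prognostic
  signature genes co-expressed in the same high-risk patients.

What the generators do **not** emulate: real DepMap/TCGA marginal
distributions beyond the stated families, copy-number artefacts,
batch structure, gene–gene correlation outside the planted signature,
isoform effects, or read-level data. Passing tests therefore demonstrate
correctness of the algorithms and calibration under the stated models,
not performance on any particular public dataset — whose headline counts
depend on dataset versions and are deliberately not asserted anywhere in
the package.

## Validation design and problem sizes

The test suite validates every operation against an independent oracle
(brute-force loops, hand calculations, exhaustive enumeration for tiny
GSEA instances, or an established library), and the acceptance checks
run the full pipeline on planted data. Simulation sizes are chosen so
that the binomial/Monte-Carlo standard error of each checked rate sits
well inside its acceptance band: 1,000 replicates for Cox recovery at
true HR 2 (n = 500 per replicate, mean HR checked in [1.9, 2.1] and CI
coverage in [0.93, 0.97]); 10,000 null genes for DE type-I; 600
repetitions with 500 permutations each for the GSEA and integrative
null-rejection rates (band [0.03, 0.07], standard error ≈ 0.009); 20
seeds for the end-to-end screen.

The end-to-end check plants 30 genes (dependency effect −1, 8-fold
overexpression, true HR 2.5) among 2,000 and requires the candidate set
to equal the planted set exactly. Exactness makes per-gene power
multiply across 30 genes, so the survival cohort for this configuration
is 500 samples — the same size used for the Cox recovery simulations —
where per-gene log-rank power is high enough (roughly 200 events in the
quartile contrast) for the joint event to be routine. At the 173-sample
realism default, per-gene power at HR 2.5 is around 0.97, which no
implementation could turn into reliable 30-gene exact recovery; the
cohort size is therefore a property of this benchmark configuration,
not a tuning of the method.

One calibration subtlety: in the integrative null check, each repetition
draws a fresh null fold-change vector *and* a fresh signal shuffle.
Reusing one metric draw across repetitions would let the chance
enrichment of the peak-bearing genes in that single draw bias all
repetitions coherently, inflating the apparent rejection rate — the
repetitions would measure one dataset's conditional bias, not the
test's calibration.

## Known limitations

* Stage thresholds are consumed as given; no multiplicity control is
  applied across the screen (the source procedure applies none).
* The Cox model is univariate with no proportionality diagnostics,
  competing risks or interval censoring.
* The DE stand-in has no dispersion shrinkage and modest power at small
  counts compared to NB-GLM engines; use the filter-only mode on
  external results when that matters.
* GSEA reports nominal p (optionally BH across sets), not the
  phenotype-permutation FDR of the original desktop tool.
* Peak analyses are peak-level; no base-pair-level Venn counting, peak
  calling or motif analysis.
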