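---
title: "Methods: cross-cohort pathway consensus analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cohort pathway consensus analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathconsensus)
```

## The problem and the model

Given several cohorts of log2 expression values comparing tumor tissue to
normal controls, the package asks which *pathways* shift consistently, and
answers with the intersection of two independent lines of evidence.

**Track 1 — per-cohort permutation gene-set analysis.** After
preprocessing, each gene in a cohort receives the classical equal-variance
two-sample Student's $t$ (tumor mean minus normal mean, $df = n_T + n_N -
2$). A pathway $S$ is scored by the arithmetic mean of its member genes'
$t$ statistics. Significance comes from a sample-label permutation null:
group labels are shuffled preserving group sizes, all gene $t$ statistics
are recomputed, and every pathway is rescored. This treats the genes of a
pathway as a unit while preserving inter-gene correlation, which a
gene-permutation null would destroy. Pathways with permutation $p \le
0.05$ in the same direction in *every* cohort form the common set.

**Track 2 — gene-level meta-analysis and over-representation.** Per-cohort
two-sided $t$-test p-values $P^i$ are combined with Fisher's method,
$X^2 = -2\sum_{i=1}^{k}\ln P^i \sim \chi^2_{2k}$ (natural logarithm). Genes
with combined $p < 0.05$ are tested for pathway over-representation with a
one-sided hypergeometric test against the background of pathway-annotated,
actually-tested genes.

A pathway present in both tracks with agreeing direction is a consensus
pathway; its meta-significant member genes, sorted by combined $p$, are the
key genes of the report.

### Assumptions

* Expression values are already normalised, on the log2 scale, with
  approximately Gaussian noise; the equal-variance $t$ presumes
  homoscedasticity between groups.
* The unpaired test is used even when pair labels exist. Pairing is read
  and stored but deliberately ignored by the statistics, matching the
  analysis tradition this pipeline reimplements; with positive within-pair
  correlation this is conservative.
* Fisher's method assumes the per-cohort p-values are independent, which
  holds when cohorts share no samples.
* Direction labels for enriched pathways are a majority vote over member
  genes' mean $t$ signs — an explicit convention, since over-representation
  itself is direction-blind.

## Preprocessing

The reduction runs restrict → filter → collapse, in that order:

1. **Restrict** to probes whose gene symbol is in the pathway-annotated
   universe (the union of all gene-set members); unannotated probes drop.
2. **Filter** probes with interquartile range below 0.5 across all samples
   of the cohort (both groups pooled). Quartiles interpolate linearly
   between order statistics (the type-7 convention, the default of the
   analysis environment this workflow is native to). "Below 0.5" is strict:
   a probe at exactly IQR = 0.5 is kept.
3. **Collapse** multiple probes per gene to the one with maximal IQR; equal
   IQRs break the tie toward the lexicographically smallest probe id, so
   the operation is deterministic and idempotent.

Computing the IQR filter after the pathway restriction (rather than before)
follows from the filter being described as acting on "the remaining genes";
since the IQR of a probe does not depend on which other probes are present,
the order only affects which probes are *reported* as filtered, not the
final matrix.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `iqr_cutoff` | 0.5 | log2 IQR below which a probe is dropped |
| `n_permutations` | 1000 | label shuffles per cohort |
| `gsea_alpha` | 0.05 | per-cohort pathway level, boundary **included** (`<=`) |
| `meta_alpha` | 0.05 | combined-p gene level, **strict** (`<`) |
| `enrich_alpha` | 0.05 | enrichment level, strict (`<`) |
| `ease` | `FALSE` | overlap-minus-one (EASE-style) enrichment variant |
| `seed` | 1 | master seed; per-cohort shuffle seeds derive from it |

The asymmetric boundary conventions (inclusive at the permutation stage,
strict at the meta and enrichment stages) mirror the thresholds of the
workflow being reimplemented and matter only for p-values landing exactly
on 0.05 — common for permutation p-values, which live on a lattice.

## Numerical choices

* **Plus-one permutation estimator.** $p_{up} = (1 + \#\{s^* \ge s\}) /
  (B + 1)$, so no pathway ever reports $p = 0$; the attainable minimum is
  $1/(B+1)$. With `exhaustive = TRUE` all $\binom{n}{n_T}$ assignments
  (identity included) are enumerated instead and p-values are exact
  proportions.
* **One shared shuffle stream** scores all pathways, for speed and
  cross-pathway comparability; per-pathway independent streams would be
  equally valid.
* **Score comparison tolerance.** Observed and permuted scores travel
  different (algebraically identical) arithmetic paths; exceedance is
  counted with a relative tolerance of $10^{-9}$ so the identity
  relabelling always counts, keeping p-values conservative.
* **Degenerate genes.** Zero pooled variance with zero mean difference
  gives $t = 0$, $p = 1$; zero variance with a nonzero difference is
  unscorable and the gene is excluded with a warning.
* **Fisher domain.** $p = 0$ is a domain error; `run_meta()` floors
  underflowed per-cohort p-values at the smallest positive double before
  combining. Genes absent from some cohorts keep a reduced $k$ (standard
  Fisher treatment of unbalanced availability) rather than being dropped.
* **Direction ties.** A pathway significant in both directions goes to the
  smaller p-value, an exact tie excludes it; an enrichment direction vote
  that ties falls back to the sign of the summed mean $t$, and a still-tied
  pathway is `UNDEFINED`.
* **Zero-overlap pathways** are omitted from enrichment output:
  $P(X \ge 0) = 1$ carries no evidence.

## The synthetic study generator

`simulate_study()` emulates the three-cohort paired design this pipeline
targets: 7/7, 10/10 and 23/23 tumor/normal samples by default, one shared
gene universe, probe map and pathway collection across cohorts. Pathways
own disjoint consecutive gene blocks; planted pathways shift every member
gene's tumor mean by $\pm\delta$ (default 1 log2 unit), identically in all
cohorts — the simplest structure under which "up-regulated pathway" is well
defined and cross-cohort consistency holds by construction. Noise is
Gaussian, homoscedastic, independent across samples; decoy genes get a
0.05-SD near-constant profile (expected IQR $\approx 0.07$) to exercise the
variability filter. Generation is a pure function of the config, so
identical configs give bit-identical studies.

What the generator does **not** model — and what passing tests therefore do
not demonstrate about real data: within-pair correlation, batch and
platform effects, intensity-dependent variance, probe cross-hybridisation,
overlapping pathway membership, and heavy-tailed noise. The validation
shows the pipeline implements its stated rules correctly and is calibrated
under its own model, not that the model captures microarray reality.

`expected_detectable_power()` gives an independent Monte-Carlo estimate
(via `stats::t.test`, not the package's own code paths) of single-gene
power in the smallest cohort, used to set expectations in validation.

## Validation problem sizes

The test suite exercises: exact 3v3/4v4 enumeration (20 and 70 label
assignments) against a brute-force oracle; a 2,000-gene, 200-pathway,
three-cohort null study (1,000 permutations) for gene-, pathway- and
enrichment-level calibration; and the default planted study (50 pathways
× 15 genes, 10 up + 10 down, $\delta = 1$) for end-to-end recovery. These
sizes give stable Monte-Carlo bands (3 binomial SE) while keeping a full
test run in the tens of seconds.

## Known limitations

* Mean-$t$ is one of several defensible pathway aggregators (median,
  maxmean, weighted KS are others); it is the classic category-style
  statistic and makes the permutation null straightforward, but is
  sensitive to a few extreme member genes in small sets.
* No multiple-testing correction is applied at any stage by default — raw
  0.05 thresholds are part of the reimplemented workflow. `run_meta()`
  output contains everything needed to apply `p.adjust()` downstream.
* Probe maps are taken as user input; cross-platform probe harmonisation is
  out of scope, and cohorts on different chips simply contribute whatever
  genes their maps cover (reduced $k$ in the meta-analysis).
* An empty consensus is a valid outcome, not an error: with weak effects,
  the intersection logic is intentionally strict.
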