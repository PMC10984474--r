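---
title: "Deriving stromal gene signatures and evaluating their prognostic impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving stromal gene signatures and evaluating their prognostic impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromascape)
```

## The problem

The tumor microenvironment (TME) of colorectal cancer — cancer-associated
fibroblasts (CAF), tumor-associated endothelia (TAE), cytotoxic T
lymphocytes (CTL), myeloid cells (TAMC) and their subpopulations — shapes
patient prognosis, but bulk tumor expression profiles mix the epithelial
and stromal compartments. stromascape implements a two-dataset design that
separates the two questions:

1. **Where does a gene live?** Paired laser-microdissected cancer-stroma
   and epithelium profiles from the same tumors (on the order of 13 tumors,
   tens of thousands of probes) let us measure each probe's
   *stroma specificity* and its *co-expression* with canonical TME marker
   genes within the stromal compartment.
2. **Does it matter clinically?** A bulk-tumor cohort with overall-survival
   follow-up (on the order of 232 patients) lets us test each candidate
   gene's prognostic impact.

Gene identity bridges the two datasets by symbol; on a probe-level cohort
the most abundant probe of a symbol stands for the gene, mirroring the
anchor-probe rule below.

## The model, step by step

### Housekeeping normalization

Microarray signal intensities are put on comparable per-sample units by a
*single housekeeping probe*: each value becomes
$100 \times \mathrm{signal} / \mathrm{signal}_{GAPDH}$ of the same sample.
All abundance thresholds downstream are stated in these units. The probe id
is a configuration value (`A_23_P13899` on Agilent 4x44K, `212581_x_at` on
Affymetrix U133 Plus 2.0 are the documented platform defaults), never
hard-coded. The transform is idempotent and cancels any per-sample scale
factor; both properties are tested. Inputs are treated as linear
intensities; if a source matrix is log-scaled it must be unlogged before
loading (the loaders do not guess).

### Stroma specificity: the cS/E ratio

For each probe, the cancer-stroma/epithelium ratio is the quotient of its
mean normalized expression over all stromal samples and over all epithelial
samples, classified with inclusive boundaries:

* **High**: cS/E $\ge$ 10
* **Middle**: 5 $\le$ cS/E $<$ 10
* **Low**: cS/E $<$ 5

We use the *ratio of compartment means* as the default aggregation rather
than the mean of per-tumor ratios: a single near-zero epithelial
measurement in one tumor would otherwise dominate the statistic. The
alternative is available as `compute_cse(mode = "mean-of-ratios")` for
sensitivity analysis. Probes with an exactly zero epithelial mean get an
infinite-ratio sentinel and are excluded from signature filters (with a
warning): an infinite ratio would trivially pass any specificity threshold,
which is not evidence of specificity but of a degenerate denominator.

### Expression amount

Abundance is read off a single designated *reference stromal sample*
(flagged `is_reference` in the sample metadata): a probe's normalized value
in that sample. This mirrors reading amounts off one deeply profiled case
rather than averaging across tumors, and makes the abundance filter
reproducible from one column of the matrix.

### Signature derivation: the R-index rule

A signature is anchored on a marker gene (SPARC for CAF, PECAM1 for TAE,
CD8A for CTL, CD14 for TAMC, and six further markers in the default
panel). The *R-index* of a probe is its Pearson correlation with the
anchor probe across the **stromal samples only** — co-expression is
evaluated in the compartment where the TME lives, not across compartments
where the stroma/epithelium contrast would dominate every correlation.
Membership requires all three inclusive filters:

* R-index $\ge$ 0.9 with the anchor probe,
* cS/E $\ge$ 10,
* expression amount $\ge$ 40 normalized units in the reference sample.

Choices made here, and why:

* **Pearson on normalized linear values.** The R-index is a linear
  association measure on the scale the thresholds are stated in;
  `method = "spearman"` is offered as a robustness flag.
* **Single anchor probe per marker, the most abundant one** (deterministic
  lexicographic tie-break). Cross-probe correlation ranges between probe
  sets of one gene are diagnostics, not membership criteria; the
  multi-probe concordance property (probes of one gene generated from one
  latent signal stay within a tight correlation band) is tested on
  synthetic data.
* **An anchor may fail its own specificity filter.** Immune markers such
  as CD8A sit near cS/E 4.7 — Low class — yet their associated genes can be
  highly stroma-specific. The anchor then defines the axis without being a
  member; the package warns instead of erroring.
* **Probes with zero variance** across stromal samples have no defined
  correlation; their R-index is recorded as missing and they cannot become
  members.
* The correlation universe is all probes with finite variance; no
  expression pre-filter is applied before the three membership filters.

Member probes collapse to unique symbols ordered by each symbol's best
probe amount, and the top-n symbols (default 76) proceed to prognostic
analysis. Overlaps between signatures are cross-tabulated per symbol, with
CAF-signature members subclassified as *fibrosis* (collagen-family symbols,
`^COL`, plus SPARC and TAGLN as collagen-induction genes — the set is
configurable) versus *non-fibrosis*.

### Prognostic evaluation

Per gene, in the bulk cohort with overall survival as sole endpoint:

1. **AUC for death prediction** as the Mann–Whitney rank statistic (ties
   1/2) on the death indicator — equal to the trapezoidal area under the
   empirical ROC curve, which the tests verify to 1e-10.
2. **Best optimized cutoff**: the threshold among midpoints of consecutive
   sorted unique values maximizing the Youden index
   $J = \mathrm{sens} + \mathrm{spec} - 1$. Orientation is automatic: when
   AUC $<$ 0.5 the gene is protective and J is computed with the direction
   reversed, so the dichotomization stays meaningful. Ties break toward
   more balanced groups, then the smaller cutoff. A group-size floor of
   10% of the cohort per side prevents degenerate 1-vs-(n-1) splits. The
   alternative `cutoff_mode = "minp-logrank"` (cutoff minimizing the
   log-rank p) is provided because "best optimized" admits both readings;
   neither is asserted as canonical.
3. **Kaplan–Meier / log-rank / Cox** on the dichotomized groups, through
   the standard survival machinery (Efron approximation for ties, the
   default of modern survival software). The hazard ratio of the
   high-expression group and the log-rank p yield the **direction call**:
   *negative* (high expression, worse survival) when p $<$ 0.05 and HR
   $>$ 1, *positive* when p $<$ 0.05 and HR $<$ 1, *ns* otherwise.
4. Genes are ranked by AUC (descending, id tie-break), and no
   multiple-testing correction is applied by default — per-gene raw p
   values are reported; `p.adjust` can be applied downstream by users who
   want FDR control.

**The measured, not nominal, type-I level.** Optimizing the cutoff on the
same data that is then tested inflates the false-positive rate of the
direction call well above the nominal alpha. `measure_type1_level()`
quantifies this on simulated null genes — around 15–25% at alpha = 0.05
for a 232-patient cohort — and the package reports this measured level
rather than pretending the nominal 5% holds. Interpret single-gene
significance accordingly; the planted-effect recovery rates below are the
quantity the pipeline is validated on.

### Two-gene combined stratification

`combined_stratification()` asks whether gene B stratifies prognosis
conditionally on gene A: the cohort splits at A's full-cohort cutoff, and
within each A-stratum patients are dichotomized by B's full-cohort cutoff
and compared by log-rank. The motivating pattern is a CTL marker that
separates survival only when the strongest negative-prognostic collagen
gene is low — immune effects that cannot overcome a fibrotic stroma. A
stratum with a single B-group, fewer than two patients per group, or no
events is reported as not evaluable rather than failing.

## The synthetic-data generator

The generator plants ground truth at the scale of the motivating study
design so every stage is testable without downloads: 13 tumors with paired
stroma/epithelium samples, a few thousand probes, and a linked 232-patient
cohort.

* **Co-expression factors**: per factor, a log-normal latent signal
  (sdlog 0.6) across stromal samples; member probes are
  `loading x latent x (1 + noise)` with relative Gaussian noise
  (default sd 0.05). Log-normal latents keep all signals positive, as
  intensities must be. Loadings are calibrated so each probe's normalized
  reference-sample value hits a planted amount drawn from the factor's
  range.
* **Specificity by construction**: epithelial values are scaled copies of
  each probe's stroma mean, so the realized ratio-of-means cS/E equals the
  planted value exactly at zero noise — specificity and co-expression are
  independently controllable dials.
* **Per-sample scale factors** multiply every raw column (housekeeping
  probe included); housekeeping normalization must cancel them, and a test
  confirms it does.
* **Survival cohort**: per gene, a standard-normal latent z per patient;
  expression is the monotone transform `50 * exp(0.6 z)`; the hazard is
  `h0 * exp(sum(beta_g z_g))` with exponential event times, independent
  exponential censoring calibrated to the target censoring fraction, and
  simple clinical covariates. The optional interaction block activates
  gene B's log-hazard only below the median of gene A's latent, with a
  main effect on A so that A's data-driven cutoff tracks the true stratum
  boundary.

Defaults (13 + 13 samples, 2,000 probes, 232 patients, baseline hazard
0.02/month, 40% censoring, planted effect beta = 0.7) reflect the scale of
the paired-microdissection and bulk-cohort designs the package targets.
What the generator does **not** emulate: platform-specific noise spectra,
probe sequence effects, batch structure, missing values, or correlated
censoring. Passing tests on synthetic data therefore demonstrate that the
algorithms recover what they are defined to recover under the stated noise
model — not that any particular biological claim holds on real arrays.

## Numerical choices and degenerate inputs

* Correlations, AUC and cutoffs are exact rank/arithmetic computations; no
  iterative optimization outside the Cox partial likelihood.
* Inclusive thresholds exactly at the stated boundaries (10, 5, 0.9, 40);
  boundary behavior is pinned by exact tests.
* Missing values in the signal block are rejected at load time because
  every downstream statistic assumes complete per-probe vectors.
* Zero housekeeping signal, zero-variance anchors, single-class outcomes,
  empty compartments and single-patient strata all raise informative
  errors or sentinels as documented on each function.
* Test problem sizes: property simulations run 100 seeds at the study's
  own design scale (200–2,000 probes, 232–300 patients), completing in
  seconds per block.

## Known limitations

* Membership uses a single anchor probe; genes whose probes disagree with
  the chosen anchor probe's behavior can be missed (cross-probe ranges are
  reported as diagnostics).
* The cS/E scalar hides per-tumor heterogeneity; no per-tumor trajectories
  are computed.
* Direction calls inherit the inflated type-I level discussed above.
* Symbol-level bridging between platforms ignores probe-level isoform
  specificity.
* No differential-expression testing between compartments, no batch
  correction, no competing risks or time-dependent covariates.
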