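# stromascape

Stromal compartment gene signatures and their prognostic impact in
colorectal tumors.

## The problem

Bulk tumor expression profiles mix cancer epithelium with the tumor
microenvironment (TME) — cancer-associated fibroblasts (CAF), endothelia,
and immune infiltrates. stromascape implements a two-dataset workflow that
untangles them:

1. From **paired micro-dissected cancer-stroma/epithelium profiles** it
   measures each probe's stroma specificity (the cS/E ratio, classified
   High ≥ 10 / Middle 5–<10 / Low < 5) and derives **anchor-marker
   co-expression signatures**: all probes with Pearson R-index ≥ 0.9
   against a marker probe (SPARC for CAF, PECAM1 for endothelia, CD8A for
   cytotoxic T cells, CD14 for myeloid cells, ...) across the stromal
   samples, filtered to cS/E ≥ 10 and expression amount ≥ 40 normalized
   units (signal/GAPDH × 100) in a designated reference stromal sample.
2. In a **bulk survival cohort** it evaluates each signature gene:
   Mann–Whitney AUC for death prediction, the best optimized expression
   cutoff (Youden index over all candidate thresholds), Kaplan–Meier
   curves, log-rank tests, Cox proportional hazards, a
   negative/positive/ns prognostic direction call, AUC ranking, and
   two-gene combined stratification (does a T-cell marker still stratify
   survival when a collagen gene is high?).

A seeded synthetic-data generator plants co-expression factors, designed
specificity, and log-linear hazards, so the whole pipeline is testable and
reproducible without external downloads. See the methods vignette
(`vignettes/stromascape-methods.Rmd`) for the model and every numerical
choice.

## Worked example

```r
library(stromascape)

cfg <- synthetic_config(n_probes = 1000, seed = 7)
gen <- generate_compartment_dataset(cfg)

nm   <- normalize_by_housekeeping(gen$matrix, gen$hk_probe)
prof <- compute_cse(nm)
caf  <- derive_signature(nm, prof, "SPARC", name = "CAFG")
caf
#> <SignatureDefinition> CAFG (anchor SPARC / P_00001)
#>   thresholds: R >= 0.9, cS/E >= 10, amount >= 40
#>   members: 31 probes (19 symbols); 31 probes associated at R >= 0.9
```

The signature recovered 31 probes (19 gene symbols) passing all three
inclusive filters — exactly the probes the generator planted on the
SPARC-anchored factor. Evaluating the anchor gene in the linked
232-patient cohort (where it was planted with log-hazard slope 0.7):

```r
sv  <- generate_survival_cohort(cfg, extra_genes = collapse_to_symbols(caf))
res <- evaluate_gene(sv$cohort$expression["SPARC", ],
                     sv$cohort$clinical$time, sv$cohort$clinical$event,
                     id = "SPARC")
res
#>     id    auc cutoff n_high n_low logrank_p hr_high_vs_low direction
#>  SPARC 0.6274  47.35    139    93  1.01e-14          4.187  negative
```

High SPARC expression predicts death with AUC 0.63; the optimal cutoff
(47.35 normalized units) splits the cohort 139 vs 93, the high group has
4.2-fold hazard, and the gene is called a negative prognostic factor —
matching the planted ground truth. `run_full_pipeline()` chains all stages
(normalization → cS/E → signatures per marker panel → overlap table with
fibrosis subclassing → per-gene prognosis → AUC ranking → combined
stratification) and writes per-stage TSVs plus a reproducibility manifest.

A thin CLI lives at `inst/scripts/stromascape` (`simulate` and `run`
subcommands).

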