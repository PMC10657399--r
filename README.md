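# her2landscape

Tools for asking whether HER2-low breast cancer (IHC 1+, or 2+ with
negative in situ hybridization) is genomically distinct from HER2-0
disease, using tumor-only targeted panel sequencing. The package is aimed
at cancer-genomics analysts working with panel cohorts (clinical table +
MAF-dialect mutation calls + SEG-dialect copy-number segments) who need the
full methodological chain as tested, reusable functions rather than a
one-off script.

## What it implements

* **Germline filtering for tumor-only calls.** A variant is removed when it
  is present in gnomAD or ClinVar unless seen more than once in COSMIC:
  retained ⇔ `(!gnomad & !clinvar) | cosmic_count ≥ 2`. Database hits are
  consumed as precomputed columns; no live queries.
* **Oncogenicity rules.** Mutation oncogenic ⇔ curated label ∈ {oncogenic,
  likely, predicted} ∨ (LOF class ∈ {nonsense, frameshift, splice} in a
  TSG). CNV oncogenic ⇔ high amplification (> 6 copies) of an oncogene ∨
  two-copy deletion of a TSG; everything else is VUS.
* **TMB and hypermutation.** TMB = filtered mutations / panel Mb; the
  hypermutation threshold is the inflection of the sorted log1p(TMB) curve
  found by an exact two-segment least-squares (two-line) changepoint fit,
  with a 15 mut/Mb fallback for degenerate cohorts.
* **Purity-corrected ERBB2 copy counts.** With purity *p* and segment log2
  ratio *L*: copies = (2·2^L − 2(1−p)) / p — the exact inverse of the
  contamination model r = (pC + 2(1−p))/2; categorized as < 1.5 deletion,
  1.5–2.5 no change, > 2.5 gain. Outputs are relative copy counts (no
  ploidy correction).
* **Per-gene enrichment.** Logistic regression of each gene's events on
  HER2 class + ER group + background burden (hypermutation status for
  mutations; leave-one-out dichotomized CNV count for CNVs), Wald OR/CI/p,
  likelihood-ratio gate vs the intercept-only null, BH-FDR within mutation
  and CNV families, non-convergence and separation reported per gene.
* **ER-stratified statistics.** Generalized Cochran–Mantel–Haenszel test
  (general-association, 2 × K × S, hypergeometric covariance; ordinal
  variant for ordered categories) and a stratified Kruskal–Wallis
  (van Elteren-type) rank test, plus conventional baseline tests.
* **Synthetic cohort generator** with planted ground truth (HER2/ER joint
  distribution, purity, TMB mixture, ERBB2 copy shift, germline
  contamination), so the entire pipeline is testable end-to-end without
  any restricted-access data.

## Worked example

```r
library(her2landscape)
cohort <- generate_cohort(sim_config(n_samples = 400, seed = 11))
res <- run_full_analysis(cohort)
res
#> HER2-low vs HER2-0 analysis
#>   samples analyzed: 400 (subset: all)
#>   hypermutation threshold: 17.08 mut/Mb (two_segment_linear)
#>   ERBB2 median copies [her2_0]: 1.75 (n=158)
#>   ERBB2 median copies [her2_low]: 2.09 (n=150)
#>   CMH (copy category ~ HER2 | ER): p = 2.74e-05
#>   enrichment models converged: 29
res$copy_summary
#>   her2_class   n median_copies single_copy_deletion no_change allelic_gain
#> 1     her2_0 158      1.746785             0.335443 0.5506329    0.1139241
#> 2   her2_low 150      2.089596             0.160000 0.5666667    0.2733333
```

Reading the output: the generator plants true ERBB2 copy-number means of
2.05 (HER2-low) vs 1.79 (HER2-0), and the pipeline recovers medians of
2.09 vs 1.75 after purity correction; the HER2-0 arm shows roughly double
the hemideletion rate (33.5% vs 16.0%); the Cochran–Mantel–Haenszel test on
the 2 × 3 category table, stratified on ER status, confirms the shift
(p ≈ 3e-05). Because the default generator plants no per-gene HER2 effect,
the enrichment table yields no gene with q < 0.05 — the expected null
result. Sensitivity subsets (`subset = "metastatic_only"` or
`"ihc2_vs_0"`) rerun the same chain on the restricted cohort.

A thin command-line wrapper is installed at
`inst/scripts/her2landscape-cli.R` (`simulate` and `run-all` subcommands).

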