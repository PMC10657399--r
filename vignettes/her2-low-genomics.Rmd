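---
title: "Comparing the genomic landscape of HER2-low and HER2-0 breast tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the genomic landscape of HER2-low and HER2-0 breast tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2landscape)
```

## The scientific question

HER2-low breast cancer (IHC 1+, or 2+ with a negative in situ hybridization)
has become clinically actionable, which raises the question of whether it is
a distinct molecular entity or simply the low end of a continuum within
HER2-negative disease. Answering that from tumor-only targeted panel
sequencing requires a chain of methodological steps, each of which this
package implements as a reusable, tested unit:

1. **Germline filtering** of tumor-only variant calls, since no matched
   normal is available to subtract inherited variation.
2. **Oncogenicity classification** of the surviving mutations and of
   copy-number events.
3. **Tumor mutational burden** (TMB) and a cohort-derived hypermutation
   threshold.
4. **Purity-corrected ERBB2 copy counts** from segmented log2 ratios.
5. **Per-gene enrichment modeling** between HER2-low and HER2-0 arms with
   covariate adjustment and false-discovery-rate control.
6. **ER-stratified cohort statistics**, because estrogen-receptor status is
   strongly imbalanced between the arms and confounds every naive
   comparison.

Because the motivating patient-level data are access-restricted, the package
ships a synthetic cohort generator whose defaults emulate the joint
structure of such a cohort; every downstream stage is exercised end-to-end
against planted ground truth.

## The germline filter and oncogenicity rules

A variant is presumed germline and removed when it appears in gnomAD or
ClinVar — unless it has been recorded more than once in COSMIC, in which
case somatic recurrence outweighs the population-database hit:

```r
retained <- (!gnomad_present & !clinvar_present) | cosmic_count >= 2
```

"More than once" is read literally: a COSMIC count of 1 does not rescue.
The rescue overrides gnomAD and ClinVar presence jointly, since both
removals form a single step. The ClinVar clause is implemented as a bare
presence flag; whether upstream pipelines restrict it to benign/germline
assertions is a property of the input files, not of this package.

A filtered mutation is **oncogenic** when a curated knowledge-base label
says so (`oncogenic`, `likely_oncogenic`, `predicted_oncogenic`), or when
it is a loss-of-function event (nonsense, frameshift, splice) in a tumor
suppressor gene. Synonymous variants are retained by the filter — they
count toward TMB — but are never oncogenic. Copy-number events are
oncogenic only as high amplifications (more than 6 called copies) of
oncogenes or two-copy deletions of TSGs; everything else is a VUS.
Successive versions of a targeted panel differ in gene content, so all
comparative analyses are restricted to genes present on every version.

## TMB and the hypermutation threshold

TMB is the filtered mutation count divided by the panel footprint in
megabases. Footprints per panel version are configuration values (defaults
`v1 = 0.8`, `v2 = 0.9`, `v3 = 1.2` Mb — targeted panels of a few hundred
genes are of this order; the true footprints are assay properties the user
should supply when known). TMB therefore scales exactly inversely with the
configured footprint, which is one of the test invariants.

Hypermutated tumors form a sparse high tail. The threshold separating them
is placed at the inflection of the sorted TMB curve: an exact two-segment
least-squares fit on sorted `log1p(TMB)`, scanning all admissible
breakpoints with a minimum segment occupancy of 2% of the cohort (at least
3 points). Each segment carries its own regression line; a linear — rather
than constant — segment model is essential, because a two-means split of a
unimodal body plus a small tail prefers to cut the body near its center
(the bulk dominates the variance), landing far below the real inflection,
while the two-line fit tracks the curvature and lands between body and
tail. On the default mixture (lognormal body with median about 7.4 mut/Mb,
7% tail uniform on 20–60) the detected threshold sits at 14–18 mut/Mb,
consistent with the 15 mut/Mb fallback that is also the shipped default for
degenerate inputs (fewer than 20 samples, or constant TMB). The
hypermutation call itself is strict: a sample exactly at the threshold is
not hypermutated.

## The ERBB2 copy-count model

A specimen with tumor purity $p$ whose tumor cells carry $C$ copies of a
locus yields the expected depth ratio

$$ r = \frac{pC + 2(1-p)}{2}, $$

so with an observed segment value $L = \log_2 r$ the purity-corrected
estimate is

$$ \hat C = \frac{2 \cdot 2^{L} - 2(1-p)}{p}. $$

At $L = 0$ this returns exactly 2 for every purity. The estimate is the
exact algebraic inverse of the forward model, which the synthetic generator
uses to produce observed log2 ratios — so parameter recovery is well-posed,
and the round-trip identity is asserted to $10^{-9}$ over
$C \in [0.5, 12]$, $p \in [0.2, 1]$. A published rendering of this formula
is typographically ambiguous between $2^{L+1}$ and $2^{L}+1$ in the
numerator; both readings agree at $L = 0$, but only the first inverts the
contamination model, so it is the default and the second is available as
`model = "plus_one"` for comparison. Negative estimates are floored at
zero. Without a matched normal there is no ploidy correction; outputs are
*relative* copy counts and the run manifest records this caveat.

Estimates are categorized as single-copy deletion (< 1.5 copies), no change
(1.5–2.5, read as a closed interval: gains require strictly more than 2.5)
or allelic gain. When a gene spans several segments, their log2 ratios are
combined by an overlap-length-weighted mean — deterministic and
order-independent. Samples are excluded from copy-count comparisons, with
an enumerated reason, when purity is unrecorded, no segment covers the
locus, or the IHC value was recorded as "Not Otherwise Specified" under 2+.

## Enrichment modeling

For each gene and event class (any mutation, oncogenic mutation, oncogenic
CNV) a logistic regression of the per-sample event indicator is fit on:

* HER2 class (the coefficient of interest, reported as an odds ratio with
  Wald 95% CI and two-tailed Wald p);
* ER group — ER-low (1–9% staining) is merged into ER-positive, and samples
  without recorded ER are excluded from modeling;
* a categorical background-burden covariate: hypermutation status for
  mutation models, and for CNV models a dichotomized count of high
  amplifications plus deep deletions, cut at a changepoint-detected
  threshold.

The CNV burden covariate is computed **leave-one-out**: the focal gene's
own event is subtracted from the count before dichotomizing. With only a
handful of commonly amplified genes, an as-is covariate would make every
event imply "high burden", quasi-separating every model; leave-one-out
removes that leakage while preserving the background-rate adjustment.

Fits are capped at 500 iterations; non-convergence, boundary fits and the
degenerate standard errors of complete separation are reported as
non-converged rows that carry no estimates and are listed (with reasons) in
the run output — never silently dropped. Penalized (Firth-type) regression
would be an alternative for separated genes but is deliberately not the
default. Each model is additionally screened by a likelihood-ratio test
against the intercept-only null; whether the covariates-only null would be
preferable is an open modeling choice, and the intercept-only convention is
used because the screen is meant to ask whether the model explains anything
at all. Mutations and CNVs form separate BH-FDR families (they are separate
analyses); within a family, LL p-values are BH-adjusted and gated at
q < 0.05, and coefficient p-values are BH-adjusted across the same family.
Whether reported per-gene p-values should be Wald or LRT is not fixed by
convention; Wald is used for coefficients, with the LRT reserved for the
model gate. The BH step-up itself is implemented from its definition
(`bh_fdr()`), handles missing values by exclusion and reinsertion, and is
tested against a brute-force evaluation of the definition and against
`p.adjust`.

## Stratified statistics

ER status differs strongly between HER2-low and HER2-0 arms, so unadjusted
comparisons of anything correlated with ER are confounded. Two stratified
tests are provided:

* **Generalized Cochran–Mantel–Haenszel test** of general association for
  2 × K × S tables (e.g. copy-count category by HER2 class, stratified on
  ER). The statistic pools, over strata, the first group's category counts
  centered at their hypergeometric expectation, with the exact
  finite-population covariance (denominator $n_s - 1$), and refers the
  quadratic form to chi-square with $K-1$ df. With one stratum and two
  categories it reduces to the Mantel–Haenszel chi-square without
  continuity correction (no continuity corrections are used anywhere). The
  general-association flavor treats categories as nominal — appropriate for
  the 2 × 3 copy-category design; an ordinal (correlation-type, 1 df)
  variant with integer scores is exposed for ordered axes such as
  IHC 0 / 1+ / 2+, since which flavor a given published analysis used is
  rarely stated. Zero-margin strata are dropped with a warning.
* **Stratified Kruskal–Wallis (van Elteren-type) rank test**: within-stratum
  midranks, centered per stratum, pooled into a quadratic form against the
  within-stratum permutation covariance, chi-square with groups − 1 df.
  With a single stratum it equals the tie-corrected Kruskal–Wallis
  statistic exactly, and its two-group single-stratum p-value equals the
  two-sided normal-approximation Wilcoxon rank-sum p-value.

Both are validated against independent oracles: closed-form hand
calculations, `mantelhaen.test`/`kruskal.test`/`wilcox.test`, and a
within-stratum permutation null. For the permutation comparison the tables
carry expected cell counts around 12 — the regime the chi-square reference
is meant for; on sparser tables the approximation error itself reaches
0.03–0.05 and the discrete permutation distribution has tie atoms, so the
permutation p is compared under the mid-p convention (half weight on ties),
the standard way to compare a discrete null with a continuous reference.

Baseline cohort description uses the conventional tests: chi-square for
categorical variables, Welch t for continuous ones, Wilcoxon rank-sum for
durations.

## The synthetic cohort generator

The generator draws, per sample: HER2 class (46.9% HER2-low), IHC score
within the HER2-low arm (43% 2+), ER status from per-arm triples
(ER-positive/low/negative ≈ 77/4/20% in HER2-low vs 61/4/35% in HER2-0 —
the confounding backbone), tumor purity as
$0.2 + 0.8 \cdot \mathrm{Beta}(2, 2)$ (histologic review enforces at least
20% cellularity, hence the floor), specimen type, and panel version. Latent
TMB is a lognormal body (median ≈ 7.4 mut/Mb, sdlog 0.55) with a 7%
hypermutated tail uniform on 20–60 mut/Mb; the uniform tail gives the
changepoint detector a genuine inflection to find. True ERBB2 copy numbers
are truncated normal (≥ 0.5) with means 2.05 (HER2-low) and 1.79 (HER2-0)
and SD 0.5 — the SD is a stated assumption, as within-group spread is not
something cohort-level summaries pin down; these means and spread reproduce
hemideletion rates of roughly 15% vs 30% between arms. Observed log2 ratios
come from the forward contamination model plus Gaussian noise (SD 0.1), and
about 10% of samples get the locus split across two segments to exercise
the length-weighted merge.

Driver mutations are Bernoulli per gene with ER-dependent baselines
(TP53-dominated ER-negative disease; PIK3CA/CDH1/GATA3/ESR1 enriched in
ER-positive) and a planted HER2 log-odds that defaults to **zero for every
gene** — the generator's default landscape is the null in which the arms
share one genomic background and ER is the only systematic difference.
Passenger counts make the filtered per-sample total match the latent TMB;
germline contaminants are added at a configurable rate (default 0.3), carry
gnomAD/ClinVar flags, and are COSMIC-rescued with probability 0.2. ER-low
is generated as its own category with an ER percentage in 1–9 so grouping
rules are testable. Rates for IHC-NOS recording (13%), missing purity (8%)
and missing segmentation (5%) yield roughly a quarter of samples ineligible
for copy-count analysis, matching the attrition scale such cohorts report.

What the generator does **not** emulate: read-level noise, sequencing
error, subclonality, mutational signatures, gene–gene co-occurrence
structure, and panel-version differences in per-gene sensitivity. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated generative assumptions, not robustness to every artifact of real
panel data.

## Numerical choices and degenerate inputs

* Changepoint scans are exact (every breakpoint evaluated), so results are
  deterministic and order-independent; prefix sums make the scan O(n).
* Quadratic forms use a generalized inverse and the matrix rank as df, so
  structurally singular covariances (e.g. an empty category) degrade to the
  correct reduced test instead of failing.
* All-identical TMB, constant outcomes, all-zero tables, single-observation
  strata and missing-ER samples each have a defined, tested behavior
  (fallback with a flag, non-converged with reason, degenerate-input error,
  dropped with warning, excluded with count).
* Cohort generation is a deterministic function of the configuration
  including its seed; writing a cohort or an analysis twice produces
  byte-identical files.

## Problem sizes used in the shipped checks

The test-suite simulations use cohorts of 786–5000 samples, 20 seeds for
the copy-count recovery study, 1000 null replicates for the rank-test
type-I error, 100 replicates of 100 null genes for FDR control, and 10^5
permutation draws for the CMH cross-check — sizes chosen so each check has
the statistical resolution its tolerance needs.

## A worked example

```{r example}
cohort <- generate_cohort(sim_config(n_samples = 400, seed = 11))
res <- run_full_analysis(cohort)
res
res$copy_summary
subset(res$tmb_tests, select = c(comparison, statistic, df, p_value))
```

The copy-count medians separate by construction (2.05 vs 1.79 planted),
the hemideletion rate is higher in the HER2-0 arm, the CMH test on the
category distribution is significant after ER stratification, and — with
the default null landscape — TMB does not differ and no gene survives
FDR correction.

## Known limitations

* Oncogenicity is consumed from precomputed labels; the package does not
  reimplement a knowledge-base evidence engine, and database snapshots are
  the caller's responsibility (their versions belong in file metadata).
* Copy counts are relative to tumor ploidy; no allele-specific or
  whole-genome ploidy inference is attempted.
* The enrichment default is plain maximum likelihood; genes with complete
  separation are reported, not rescued.
* The CMH and rank tests are asymptotic; exact conditional versions are out
  of scope, and very sparse tables deserve a permutation p instead.
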