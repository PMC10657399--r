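#' Derive HER2 class from IHC score and ISH result
#'
#' IHC 0 is HER2-0; IHC 1+, or 2+ with a negative (or unavailable) ISH, is
#' HER2-low. IHC 3+ or a positive ISH means HER2-positive disease, which is
#' outside the cohort definition and rejected at load.
#'
#' @param ihc_score Character vector: `"0"`, `"1+"`, `"2+"`, `"3+"`.
#' @param ish_positive Logical vector (NA = not done).
#' @return Character vector `her2_0` / `her2_low`.
#' @export
derive_her2_class <- function(ihc_score, ish_positive = NA) {
  ish_positive <- rep_len(ish_positive, length(ihc_score))
  if (any(ihc_score == "3+" | (!is.na(ish_positive) & ish_positive), na.rm = TRUE)) {
    stop_her2("HER2-positive sample(s) (IHC 3+ or ISH-positive) are outside the cohort",
              class = "her2_argument_error")
  }
  ifelse(ihc_score == "0", "her2_0",
         ifelse(ihc_score %in% c("1+", "2+"), "her2_low", NA_character_))
}

#' Subset a clinical table for the sensitivity analyses
#'
#' `all` is the identity. `metastatic_only` keeps samples collected from
#' metastatic disease with a recorded ER status. `ihc2_vs_0` compares the
#' IHC 2+/non-amplified part of the HER2-low arm against HER2-0 (IHC 0),
#' dropping IHC 1+ and NOS samples, again requiring recorded ER.
#'
#' @param clinical Clinical table with `specimen_type`, `ihc_score`,
#'   `er_status`.
#' @param mode One of `"all"`, `"metastatic_only"`, `"ihc2_vs_0"`.
#' @return The subset of `clinical`.
#' @export
apply_subset <- function(clinical, mode = c("all", "metastatic_only", "ihc2_vs_0")) {
  mode <- match.arg(mode)
  er_recorded <- !is.na(clinical$er_status) & clinical$er_status != "unknown"
  switch(mode,
    all = clinical,
    metastatic_only = clinical[clinical$specimen_type == "metastasis" &
                                 er_recorded, , drop = FALSE],
    ihc2_vs_0 = clinical[clinical$ihc_score %in% c("0", "2+") & er_recorded, ,
                         drop = FALSE]
  )
}

#' @keywords internal
#' @noRd
freq_by_group <- function(events, clinical, genes) {
  er_group <- er_group_from_status(clinical$er_status)
  cells <- interaction(clinical$her2_class, ifelse(is.na(er_group), "er_unknown",
                                                   er_group), sep = ".")
  mat <- build_alteration_matrix(events, clinical$sample_id, genes)
  out <- lapply(levels(cells), function(cl) {
    ix <- which(cells == cl)
    data.frame(cell = cl, gene = genes,
               n = length(ix),
               frequency = if (length(ix)) colMeans(mat[ix, , drop = FALSE]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @keywords internal
#' @noRd
oncoprint_matrix <- function(onc_mut, onc_cnv, clinical, genes) {
  m_mut <- build_alteration_matrix(onc_mut, clinical$sample_id, genes)
  m_cnv <- build_alteration_matrix(onc_cnv, clinical$sample_id, genes)
  lab <- matrix("", nrow(m_mut), ncol(m_mut), dimnames = dimnames(m_mut))
  lab[m_mut & !m_cnv] <- "MUT"
  lab[!m_mut & m_cnv] <- "CNV"
  lab[m_mut & m_cnv] <- "MUT;CNV"
  data.frame(sample_id = rownames(lab), as.data.frame(lab, optional = TRUE),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full HER2-low versus HER2-0 comparison
#'
#' Orchestrates every analysis stage on an in-memory cohort: optional
#' sensitivity subsetting; restriction of all events to genes on every panel
#' version; the germline filter cascade; oncogenicity classification of
#' mutations and CNVs; per-sample TMB with changepoint hypermutation
#' calling; purity-corrected ERBB2 copy counts with CMH tests of the
#' category distribution (stratified on ER) both by HER2 class and, as an
#' ordinal test, by IHC score; covariate-adjusted per-gene enrichment with
#' BH-FDR; TMB group comparison (Kruskal-Wallis, plain and ER-stratified)
#' and a hypermutation chi-square; HER2-by-ER frequency tables and an
#' OncoPrint-style sample-by-gene export; and a manifest recording every
#' threshold, exclusion and count, with a samples-in = excluded + analyzed
#' ledger per stage. Given the same cohort and arguments the result is
#' deterministic, and written output files are byte-identical across runs.
#'
#' @param cohort A `her2_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param subset Sensitivity subset mode, see [apply_subset()].
#' @param freq_threshold Mutation-frequency threshold for enrichment.
#' @param hm_fallback Fallback hypermutation threshold (mut/Mb).
#' @param panel_sizes_mb Named megabase footprints per panel version.
#' @param copy_model Copy-count model, see [estimate_copy_count()].
#' @param outdir Optional directory; when given, all tables are written as
#'   TSV and the manifest as JSON.
#' @return A list of class `her2_analysis`: `clinical`, `tmb`,
#'   `copy_counts`, `copy_summary`, `cmh_copy_her2`, `cmh_copy_ihc`,
#'   `tmb_tests`, `enrichment`, `frequencies`, `oncoprint`, `baseline`,
#'   `manifest`.
#' @export
run_full_analysis <- function(cohort,
                              subset = c("all", "metastatic_only", "ihc2_vs_0"),
                              freq_threshold = 0.04, hm_fallback = 15,
                              panel_sizes_mb = c(v1 = 0.8, v2 = 0.9, v3 = 1.2),
                              copy_model = c("doubling", "plus_one"),
                              outdir = NULL) {
  stopifnot(inherits(cohort, "her2_cohort"))
  subset <- match.arg(subset)
  copy_model <- match.arg(copy_model)
  manifest <- list(subset = subset, freq_threshold = freq_threshold,
                   hm_fallback = hm_fallback,
                   panel_sizes_mb = as.list(panel_sizes_mb),
                   copy_model = copy_model)

  ## stage: subset -----------------------------------------------------------
  clin_all <- cohort$clinical
  clinical <- apply_subset(clin_all, subset)
  manifest$stage_subset <- list(samples_in = nrow(clin_all),
                                samples_excluded = nrow(clin_all) - nrow(clinical),
                                samples_analyzed = nrow(clinical))
  ids <- clinical$sample_id

  ## stage: common-gene restriction ------------------------------------------
  ann <- cohort$gene_annotation
  var_in <- cohort$variants[cohort$variants$sample_id %in% ids, , drop = FALSE]
  cnv_in <- cohort$cnv_calls[cohort$cnv_calls$sample_id %in% ids, , drop = FALSE]
  variants <- restrict_to_common_genes(var_in, ann)
  cnv <- restrict_to_common_genes(cnv_in, ann)
  manifest$stage_common_genes <- list(
    variants_in = nrow(var_in), variants_dropped = nrow(var_in) - nrow(variants),
    cnv_in = nrow(cnv_in), cnv_dropped = nrow(cnv_in) - nrow(cnv))

  ## stage: germline filter + oncogenicity -----------------------------------
  filtered <- filter_germline(variants)
  manifest$stage_germline_filter <- list(
    variants_in = nrow(variants),
    variants_removed = nrow(variants) - nrow(filtered),
    variants_retained = nrow(filtered))
  filtered <- classify_mutation_oncogenic(filtered, ann)
  cnv <- classify_cnv_oncogenic(cnv, ann)

  ## stage: TMB / hypermutation ----------------------------------------------
  tmb <- hypermutation_table(filtered, clinical, panel_sizes_mb,
                             fallback = hm_fallback)
  fit <- attr(tmb, "threshold_fit")
  manifest$hypermutation <- list(threshold = fit$threshold,
                                 method = fit$method,
                                 degenerate = fit$degenerate,
                                 n_hypermutated = sum(tmb$hypermutated))

  ## stage: ERBB2 copy counts -------------------------------------------------
  cc <- erbb2_copy_counts(clinical, cohort$segments, model = copy_model)
  manifest$stage_copy_counts <- list(
    samples_in = nrow(cc), samples_excluded = sum(!cc$eligible),
    samples_analyzed = sum(cc$eligible),
    exclusion_reasons = as.list(table(cc$reason[!cc$eligible])),
    note = "relative copy counts (no ploidy correction)")
  her2_cc <- clinical$her2_class[match(cc$sample_id, clinical$sample_id)]
  erg_cc <- er_group_from_status(
    clinical$er_status[match(cc$sample_id, clinical$sample_id)])
  ok <- cc$eligible & !is.na(erg_cc)
  copy_summary <- do.call(rbind, lapply(split(which(ok), her2_cc[ok]), function(ix) {
    data.frame(her2_class = her2_cc[ix][1], n = length(ix),
               median_copies = stats::median(cc$copies[ix]),
               single_copy_deletion = mean(cc$category[ix] == "single_copy_deletion"),
               no_change = mean(cc$category[ix] == "no_change"),
               allelic_gain = mean(cc$category[ix] == "allelic_gain"),
               stringsAsFactors = FALSE)
  }))
  rownames(copy_summary) <- NULL
  cmh_copy_her2 <- if (sum(ok) && length(unique(her2_cc[ok])) == 2) {
    cmh_general_association(group = her2_cc[ok],
                            category = factor(cc$category[ok],
                                              levels = c("single_copy_deletion",
                                                         "no_change", "allelic_gain")),
                            stratum = erg_cc[ok])
  } else NULL
  ihc_cc <- clinical$ihc_score[match(cc$sample_id, clinical$sample_id)]
  ok_ihc <- ok & ihc_cc %in% c("0", "1+", "2+")
  cmh_copy_ihc <- if (sum(ok_ihc) && length(unique(ihc_cc[ok_ihc])) >= 2) {
    # ordinal in the copy-count category, scored across ordered IHC strata?
    # No: IHC is the grouping of interest; keep HER2 dichotomy for the group
    # axis and test IHC ordinally as categories against copy category.
    cmh_ordinal_ihc(cc$copies[ok_ihc], ihc_cc[ok_ihc], erg_cc[ok_ihc])
  } else NULL

  ## stage: enrichment ---------------------------------------------------------
  mut_any <- filtered[filtered$variant_class != "synonymous", , drop = FALSE]
  mut_onc <- filtered[filtered$oncogenic, , drop = FALSE]
  cnv_onc <- cnv[cnv$oncogenic, , drop = FALSE]
  genes <- ann$gene
  hm_cov <- factor(ifelse(tmb$hypermutated, "hypermutated", "non_hypermutated"))
  cnv_counts <- as.integer(table(factor(cnv_onc$sample_id, levels = ids)))
  cnv_cutoff <- attr(cnv_burden_category(cnv_counts), "cutoff")
  manifest$cnv_burden_cutoff <- cnv_cutoff
  matrices <- list(
    mutation = list(events = build_alteration_matrix(mut_any, ids, genes),
                    burden = hm_cov, family = "mutation"),
    mutation_oncogenic = list(events = build_alteration_matrix(mut_onc, ids, genes),
                              burden = hm_cov, family = "mutation"),
    cnv_oncogenic = list(events = build_alteration_matrix(cnv_onc, ids, genes),
                         burden_counts = cnv_counts, burden_cutoff = cnv_cutoff,
                         family = "cnv", frequency_filter = FALSE)
  )
  enr <- run_enrichment(matrices, clinical, freq_threshold = freq_threshold)
  excl <- attr(enr, "excluded")
  manifest$enrichment <- list(
    n_models_converged = nrow(enr),
    n_models_excluded = nrow(excl),
    excluded = if (nrow(excl)) excl else "none",
    n_er_missing = sum(is.na(er_group_from_status(clinical$er_status))))

  ## stage: TMB comparison ------------------------------------------------------
  her2_t <- clinical$her2_class
  erg_t <- er_group_from_status(clinical$er_status)
  kw_plain <- stratified_kruskal_wallis(tmb$tmb, her2_t)
  ok_t <- !is.na(erg_t)
  kw_strat <- stratified_kruskal_wallis(tmb$tmb[ok_t], her2_t[ok_t], erg_t[ok_t])
  hm_tab <- table(her2_t, tmb$hypermutated)
  hm_chisq <- if (all(dim(hm_tab) == c(2, 2))) {
    ct <- suppressWarnings(stats::chisq.test(hm_tab, correct = FALSE))
    her2_test_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
                     "chi_square", 1L)
  } else NULL
  tmb_tests <- rbind(
    cbind(comparison = "tmb_kruskal_wallis", kw_plain),
    cbind(comparison = "tmb_stratified_er", kw_strat),
    if (!is.null(hm_chisq)) cbind(comparison = "hypermutated_chi_square", hm_chisq)
  )
  tmb_medians <- tapply(tmb$tmb, her2_t, stats::median)
  manifest$tmb <- list(median_her2_low = unname(tmb_medians["her2_low"]),
                       median_her2_0 = unname(tmb_medians["her2_0"]),
                       hypermutated_fraction = mean(tmb$hypermutated))

  ## descriptive outputs ---------------------------------------------------------
  frequencies <- list(
    mutation_oncogenic = freq_by_group(mut_onc, clinical, genes),
    cnv_oncogenic = freq_by_group(cnv_onc, clinical, genes))
  oncoprint <- oncoprint_matrix(mut_onc, cnv_onc, clinical, genes)
  baseline <- baseline_tests(clinical,
                             categorical = c("er_status", "specimen_type",
                                             "panel_version"),
                             continuous = "purity")

  out <- structure(
    list(clinical = clinical, tmb = tmb, copy_counts = cc,
         copy_summary = copy_summary, cmh_copy_her2 = cmh_copy_her2,
         cmh_copy_ihc = cmh_copy_ihc, tmb_tests = tmb_tests,
         enrichment = enr, frequencies = frequencies, oncoprint = oncoprint,
         baseline = baseline, manifest = manifest),
    class = "her2_analysis")
  if (!is.null(outdir)) write_analysis(out, outdir)
  out
}

#' @keywords internal
#' @noRd
cmh_ordinal_ihc <- function(copies, ihc, er_group) {
  # ordinal association between IHC score (0 < 1+ < 2+) and copy category,
  # ER-stratified; IHC plays the "category" axis with integer scores, the
  # copy category is dichotomized around the modal no_change state per tail.
  # Simpler and standard: correlation-type CMH of IHC score vs copy count
  # category scores within ER strata.
  cat3 <- factor(categorize_copy_count(copies),
                 levels = c("single_copy_deletion", "no_change", "allelic_gain"))
  ihc_f <- factor(ihc, levels = c("0", "1+", "2+"))
  strata <- factor(er_group)
  U <- 0; V <- 0; used <- 0L
  for (s in levels(strata)) {
    ix <- which(strata == s)
    if (length(ix) < 2) next
    r <- as.integer(ihc_f[ix]); cscore <- as.integer(cat3[ix])
    n_s <- length(ix)
    if (length(unique(r)) < 2 || length(unique(cscore)) < 2) next
    U <- U + sum(r * cscore) - sum(r) * sum(cscore) / n_s
    vr <- sum(r^2) - sum(r)^2 / n_s
    vc <- sum(cscore^2) - sum(cscore)^2 / n_s
    V <- V + vr * vc / (n_s - 1)
    used <- used + 1L
  }
  if (used == 0 || V <= 0) {
    return(her2_test_result(0, 1L, 1, "cmh_ordinal_ihc", used, "degenerate"))
  }
  stat <- U^2 / V
  her2_test_result(stat, 1L, stats::pchisq(stat, 1, lower.tail = FALSE),
                   "cmh_ordinal_ihc", used)
}

#' Write an analysis bundle to a directory
#'
#' Emits every table as TSV and the manifest as JSON with stable formatting,
#' so repeated runs on the same cohort produce byte-identical files.
#'
#' @param analysis A `her2_analysis` from [run_full_analysis()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_analysis <- function(analysis, outdir) {
  stopifnot(inherits(analysis, "her2_analysis"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(analysis$tmb, file.path(outdir, "tmb.tsv"))
  write_tsv(analysis$copy_counts, file.path(outdir, "copy_counts.tsv"))
  write_tsv(analysis$copy_summary, file.path(outdir, "copy_summary.tsv"))
  write_tsv(analysis$tmb_tests, file.path(outdir, "tmb_tests.tsv"))
  write_tsv(as.data.frame(analysis$enrichment),
            file.path(outdir, "enrichment.tsv"))
  write_tsv(analysis$frequencies$mutation_oncogenic,
            file.path(outdir, "frequencies_mutation.tsv"))
  write_tsv(analysis$frequencies$cnv_oncogenic,
            file.path(outdir, "frequencies_cnv.tsv"))
  write_tsv(analysis$oncoprint, file.path(outdir, "oncoprint.tsv"))
  write_tsv(analysis$baseline, file.path(outdir, "baseline_tests.tsv"))
  if (!is.null(analysis$cmh_copy_her2)) {
    write_tsv(analysis$cmh_copy_her2, file.path(outdir, "cmh_copy_her2.tsv"))
  }
  jsonlite::write_json(analysis$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.her2_analysis <- function(x, ...) {
  cat("HER2-low vs HER2-0 analysis\n")
  cat(sprintf("  samples analyzed: %d (subset: %s)\n", nrow(x$clinical),
              x$manifest$subset))
  cat(sprintf("  hypermutation threshold: %.2f mut/Mb (%s)\n",
              x$manifest$hypermutation$threshold,
              x$manifest$hypermutation$method))
  if (!is.null(x$copy_summary) && nrow(x$copy_summary)) {
    for (i in seq_len(nrow(x$copy_summary))) {
      cat(sprintf("  ERBB2 median copies [%s]: %.2f (n=%d)\n",
                  x$copy_summary$her2_class[i], x$copy_summary$median_copies[i],
                  x$copy_summary$n[i]))
    }
  }
  if (!is.null(x$cmh_copy_her2)) {
    cat(sprintf("  CMH (copy category ~ HER2 | ER): p = %.3g\n",
                x$cmh_copy_her2$p_value))
  }
  cat(sprintf("  enrichment models converged: %d\n", nrow(x$enrichment)))
  invisible(x)
}
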