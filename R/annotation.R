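ONCOGENIC_LABELS <- c("oncogenic", "likely_oncogenic", "predicted_oncogenic")
LOF_CLASSES <- c("nonsense", "frameshift", "splice")

#' Germline filtering cascade for tumor-only variant calls
#'
#' Tumor-only panels cannot subtract a matched normal, so presumed germline
#' variants are removed by population-database lookup: a variant is dropped
#' when it is present in gnomAD or ClinVar, unless it has been observed more
#' than once in COSMIC (recurrence in a somatic cancer database rescues it).
#' A variant is retained iff
#' `(!gnomad_present & !clinvar_present) | cosmic_count >= 2`.
#' The output is a subsequence of the input; order is preserved and the
#' operation is idempotent.
#'
#' @param variants Data frame with logical columns `gnomad_present`,
#'   `clinvar_present` and integer `cosmic_count` (as from [read_maf()] or
#'   [generate_cohort()]).
#' @return The retained rows of `variants`.
#' @examples
#' v <- data.frame(sample_id = "S1", gene = "TP53",
#'                 gnomad_present = c(TRUE, FALSE), clinvar_present = FALSE,
#'                 cosmic_count = c(2L, 0L))
#' filter_germline(v) # both retained: COSMIC rescue and no database hit
#' @export
filter_germline <- function(variants) {
  req <- c("gnomad_present", "clinvar_present", "cosmic_count")
  missing <- setdiff(req, names(variants))
  if (length(missing)) {
    stop_her2("variant table is missing required column(s): %s",
              paste(missing, collapse = ", "), class = "her2_schema_error")
  }
  keep <- (!variants$gnomad_present & !variants$clinvar_present) |
    variants$cosmic_count >= 2L
  keep[is.na(keep)] <- FALSE
  variants[keep, , drop = FALSE]
}

#' Classify filtered mutations as oncogenic
#'
#' A mutation is oncogenic when its curated label is `oncogenic`,
#' `likely_oncogenic` or `predicted_oncogenic`, or when it is a
#' loss-of-function event (nonsense, frameshift or splice) in a tumor
#' suppressor gene. Synonymous variants are never oncogenic (they still
#' count toward TMB upstream). The provenance column records which branch
#' fired (`"oncokb_label"`, `"lof_tsg"` or `"none"`); label-based calls take
#' precedence in the tag when both branches apply.
#'
#' @param variants Data frame with columns `gene`, `variant_class`,
#'   `oncokb_label`.
#' @param annotation Gene annotation data frame with `gene` and `role`;
#'   genes absent from it are classified through the label branch only,
#'   with a warning.
#' @return `variants` with added logical `oncogenic` and character
#'   `oncogenic_via` columns.
#' @export
classify_mutation_oncogenic <- function(variants, annotation) {
  role <- annotation$role[match(variants$gene, annotation$gene)]
  unknown <- unique(variants$gene[is.na(role)])
  if (length(unknown)) {
    warning(sprintf(
      "gene(s) absent from annotation, classified by label only: %s",
      paste(unknown, collapse = ", ")), call. = FALSE)
  }
  not_syn <- variants$variant_class != "synonymous"
  by_label <- variants$oncokb_label %in% ONCOGENIC_LABELS & not_syn
  by_lof <- !is.na(role) & role == "TSG" &
    variants$variant_class %in% LOF_CLASSES & not_syn
  variants$oncogenic <- by_label | by_lof
  variants$oncogenic_via <- ifelse(by_label, "oncokb_label",
                                   ifelse(by_lof, "lof_tsg", "none"))
  variants
}

#' Classify copy-number events as oncogenic
#'
#' High amplifications (more than 6 called copies on this assay) are
#' oncogenic in oncogenes; two-copy deletions are oncogenic in tumor
#' suppressor genes. Every other copy-number event — including single-copy
#' deletions of TSGs and low-level amplifications of oncogenes — is a
#' variant of unknown significance. Genes with unknown role are never
#' oncogenic.
#'
#' @param cnv Data frame with columns `gene` and `call`.
#' @param annotation Gene annotation data frame with `gene` and `role`.
#' @return `cnv` with an added logical `oncogenic` column.
#' @export
classify_cnv_oncogenic <- function(cnv, annotation) {
  role <- annotation$role[match(cnv$gene, annotation$gene)]
  cnv$oncogenic <- (!is.na(role) & role == "oncogene" &
                      cnv$call == "high_amplification") |
    (!is.na(role) & role == "TSG" & cnv$call == "two_copy_deletion")
  cnv
}

#' Restrict events to genes assayed on every panel version
#'
#' Panel versions differ in gene content; cross-version comparisons are only
#' valid on the common denominator. Keeps events whose gene is present on
#' all of the requested panel versions.
#'
#' @param events Data frame with a `gene` column (mutations or CNVs).
#' @param annotation Gene annotation with `gene` and `panel_versions`
#'   (comma-separated, e.g. `"v1,v2,v3"`).
#' @param versions Character vector of versions that must all carry the gene.
#' @return The retained rows of `events`.
#' @export
restrict_to_common_genes <- function(events, annotation,
                                     versions = c("v1", "v2", "v3")) {
  vlist <- strsplit(annotation$panel_versions, ",", fixed = TRUE)
  common <- annotation$gene[vapply(vlist, function(v) all(versions %in% trimws(v)),
                                   logical(1))]
  events[events$gene %in% common, , drop = FALSE]
}
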