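#' @keywords internal
#' @noRd
stop_her2 <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "her2landscape_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Read a tab-delimited table and check its schema
#'
#' Reads a TSV with a header row, tolerates extra columns, and fails with an
#' informative error naming the first missing required column. Used by all
#' format-specific readers.
#'
#' @param path Path to a tab-delimited text file.
#' @param required Character vector of column names that must be present.
#' @param what Human-readable name of the table (used in error messages).
#' @return A `data.frame` with `stringsAsFactors = FALSE`.
#' @keywords internal
read_tsv_checked <- function(path, required = character(), what = "table") {
  if (!file.exists(path)) {
    stop_her2("%s file not found: %s", what, path, class = "her2_io_error")
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop_her2("%s '%s' is missing required column(s): %s",
              what, basename(path), paste(missing, collapse = ", "),
              class = "her2_schema_error")
  }
  x
}

#' @keywords internal
#' @noRd
coerce_logical_column <- function(x, column, what) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop_her2("%s: column '%s' is not interpretable as logical at row(s) %s",
              what, column, paste(utils::head(bad, 5), collapse = ", "),
              class = "her2_parse_error")
  }
  out
}

# MAF Variant_Classification -> internal variant_class enum
.maf_class_map <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frameshift",
  Frame_Shift_Ins   = "frameshift",
  Splice_Site       = "splice",
  Splice_Region     = "splice",
  In_Frame_Del      = "inframe_indel",
  In_Frame_Ins      = "inframe_indel",
  Silent            = "synonymous"
)

.internal_class_map <- c(
  missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
  frameshift = "Frame_Shift_Del", splice = "Splice_Site",
  inframe_indel = "In_Frame_Del", synonymous = "Silent", other = "Other"
)

#' Read mutation calls in MAF-dialect TSV
#'
#' Parses a tab-delimited mutation table in the MAF dialect used throughout
#' the package: the standard `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification` columns, augmented with the pre-computed database
#' flags `gnomad_present`, `clinvar_present` and `cosmic_count` (and
#' optionally `oncokb_label`). Extra columns are ignored. Variant
#' classifications are mapped to the internal enum (`missense`, `nonsense`,
#' `frameshift`, `splice`, `inframe_indel`, `synonymous`, `other`).
#'
#' @param path Path to the MAF-dialect TSV.
#' @return A `data.frame` with columns `sample_id`, `gene`, `variant_class`,
#'   `gnomad_present`, `clinvar_present`, `cosmic_count`, `oncokb_label`.
#' @seealso [write_maf()], [filter_germline()]
#' @export
read_maf <- function(path) {
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
           "gnomad_present", "clinvar_present", "cosmic_count")
  x <- read_tsv_checked(path, req, what = "MAF")
  cls <- .maf_class_map[x$Variant_Classification]
  cls[is.na(cls)] <- "other"
  cosmic <- suppressWarnings(as.integer(x$cosmic_count))
  bad <- which(is.na(cosmic) & !is.na(x$cosmic_count))
  if (length(bad)) {
    stop_her2("MAF '%s': cosmic_count not integer at row(s) %s", basename(path),
              paste(utils::head(bad, 5), collapse = ", "),
              class = "her2_parse_error")
  }
  data.frame(
    sample_id = as.character(x$Tumor_Sample_Barcode),
    gene = as.character(x$Hugo_Symbol),
    variant_class = unname(cls),
    gnomad_present = coerce_logical_column(x$gnomad_present, "gnomad_present", "MAF"),
    clinvar_present = coerce_logical_column(x$clinvar_present, "clinvar_present", "MAF"),
    cosmic_count = cosmic,
    oncokb_label = if ("oncokb_label" %in% names(x)) as.character(x$oncokb_label) else "none",
    stringsAsFactors = FALSE
  )
}

#' Write mutation calls as MAF-dialect TSV
#'
#' @param variants Variant table in internal form (see [read_maf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  out <- data.frame(
    Hugo_Symbol = variants$gene,
    Tumor_Sample_Barcode = variants$sample_id,
    Variant_Classification = unname(.internal_class_map[variants$variant_class]),
    gnomad_present = variants$gnomad_present,
    clinvar_present = variants$clinvar_present,
    cosmic_count = variants$cosmic_count,
    oncokb_label = variants$oncokb_label,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}

#' Read a clinical cohort table
#'
#' @param path TSV with columns `sample_id`, `her2_class`, `ihc_score`,
#'   `er_status`, `er_percent`, `purity`, `specimen_type`, `panel_version`.
#' @return A `data.frame`.
#' @export
read_clinical <- function(path) {
  req <- c("sample_id", "her2_class", "ihc_score", "er_status", "er_percent",
           "purity", "specimen_type", "panel_version")
  x <- read_tsv_checked(path, req, what = "clinical table")
  x$sample_id <- as.character(x$sample_id)
  x$ihc_score <- as.character(x$ihc_score)
  x$purity <- as.numeric(x$purity)
  x
}

#' Read segmented copy-number data (SEG dialect)
#'
#' Coordinates are 1-based and end-inclusive.
#'
#' @param path TSV with columns `sample_id`, `chrom`, `start`, `end`,
#'   `log2_ratio`.
#' @return A `data.frame`.
#' @export
read_seg <- function(path) {
  x <- read_tsv_checked(path, c("sample_id", "chrom", "start", "end", "log2_ratio"),
                        what = "SEG")
  x$sample_id <- as.character(x$sample_id)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  x$log2_ratio <- as.numeric(x$log2_ratio)
  x
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene`, `role` (one of `oncogene`, `TSG`,
#'   `other`) and `panel_versions` (comma-separated subset of `v1,v2,v3`).
#' @return A `data.frame`.
#' @export
read_gene_annotation <- function(path) {
  x <- read_tsv_checked(path, c("gene", "role", "panel_versions"),
                        what = "gene annotation")
  if (anyDuplicated(x$gene)) {
    stop_her2("gene annotation has duplicated gene symbols: %s",
              paste(unique(x$gene[duplicated(x$gene)]), collapse = ", "),
              class = "her2_schema_error")
  }
  x
}

#' Read per-gene copy-number calls
#'
#' @param path TSV with columns `sample_id`, `gene`, `call` (one of
#'   `high_amplification`, `amplification`, `single_copy_deletion`,
#'   `two_copy_deletion`, `neutral`) and optionally `copies_called`.
#' @return A `data.frame`.
#' @export
read_cnv_calls <- function(path) {
  x <- read_tsv_checked(path, c("sample_id", "gene", "call"), what = "CNV calls")
  valid <- c("high_amplification", "amplification", "single_copy_deletion",
             "two_copy_deletion", "neutral")
  bad <- which(!x$call %in% valid)
  if (length(bad)) {
    stop_her2("CNV calls '%s': invalid call at row(s) %s", basename(path),
              paste(utils::head(bad, 5), collapse = ", "),
              class = "her2_parse_error")
  }
  x$sample_id <- as.character(x$sample_id)
  x
}

#' Write a data frame as TSV with stable formatting
#'
#' Writes tab-separated text with a header, no quoting and no row names, so
#' that identical inputs produce byte-identical files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
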