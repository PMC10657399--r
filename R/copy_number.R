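#' Purity-corrected relative copy count from a segment log2 ratio
#'
#' A sequenced specimen is a mixture of tumor (fraction `purity`, carrying
#' `CN` copies) and normal cells (diploid), so the observed depth ratio is
#' `ratio = (purity * CN + 2 * (1 - purity)) / 2`. Inverting with
#' `ratio = 2^log2_ratio` gives
#' `copies = (2 * 2^log2_ratio - 2 * (1 - purity)) / purity`,
#' the default `"doubling"` model. At `log2_ratio = 0` it returns exactly 2
#' for every purity. An alternative `"plus_one"` reading,
#' `copies = (2^log2_ratio + 1 - 2 * (1 - purity)) / purity`, is provided
#' for comparison; the two agree at `log2_ratio = 0` but only the default is
#' the algebraic inverse of the contamination model. Computed copies below
#' zero are floored at 0. Without a matched normal there is no ploidy
#' correction, so outputs are relative copy counts.
#'
#' @param log2_ratio Segment log2 depth ratio (finite numeric).
#' @param purity Tumor fraction in (0, 1]; `NA` propagates to `NA` copies
#'   (missing purity is an eligibility matter, not an error).
#' @param model `"doubling"` (default) or `"plus_one"`.
#' @return Relative copy count(s), floored at 0.
#' @examples
#' estimate_copy_count(0, 0.5)            # 2
#' estimate_copy_count(1, 1)              # 4
#' estimate_copy_count(log2(1.5), 0.5)    # 4
#' @export
estimate_copy_count <- function(log2_ratio, purity,
                                model = c("doubling", "plus_one")) {
  model <- match.arg(model)
  bad <- !is.na(purity) & (purity <= 0 | purity > 1)
  if (any(bad)) {
    stop_her2("purity must be in (0, 1]; got %s",
              paste(format(purity[bad][1]), collapse = ""),
              class = "her2_argument_error")
  }
  if (any(!is.na(log2_ratio) & !is.finite(log2_ratio))) {
    stop_her2("log2_ratio must be finite", class = "her2_argument_error")
  }
  tumor_signal <- if (model == "doubling") 2 * 2^log2_ratio else 2^log2_ratio + 1
  pmax(0, (tumor_signal - 2 * (1 - purity)) / purity)
}

#' Forward contamination model: log2 ratio from a true copy number
#'
#' The exact inverse of [estimate_copy_count()] (default model); used by the
#' synthetic generator and by round-trip tests.
#'
#' @param copies True copy number (non-negative).
#' @param purity Tumor fraction in (0, 1].
#' @return Expected segment log2 ratio.
#' @export
log2_ratio_from_copy_count <- function(copies, purity) {
  log2((purity * copies + 2 * (1 - purity)) / 2)
}

#' Categorize a relative copy count
#'
#' Copy counts are read as allelic states with noise: below 1.5 is a
#' single-copy deletion, 1.5 to 2.5 (closed interval) no change, and
#' strictly above 2.5 an allelic gain.
#'
#' @param copies Numeric copy counts (`NA` allowed).
#' @return Character vector with values `single_copy_deletion`, `no_change`,
#'   `allelic_gain` (or `NA`).
#' @export
categorize_copy_count <- function(copies) {
  out <- rep(NA_character_, length(copies))
  out[!is.na(copies) & copies < 1.5] <- "single_copy_deletion"
  out[!is.na(copies) & copies >= 1.5 & copies <= 2.5] <- "no_change"
  out[!is.na(copies) & copies > 2.5] <- "allelic_gain"
  out
}

#' Eligibility of samples for ERBB2 copy-count estimation
#'
#' A sample is ineligible when its tumor purity is unrecorded, when no
#' segment overlaps the ERBB2 locus, or when its IHC value was recorded as
#' "Not Otherwise Specified" under 2+ (such samples cannot be placed on the
#' IHC axis and are excluded from all copy-count comparisons). All
#' applicable reasons are reported, joined by `"+"`.
#'
#' @param clinical Clinical table with `sample_id`, `purity`, `ihc_score`.
#' @param segments SEG-dialect data frame (`sample_id`, `chrom`, `start`,
#'   `end`, `log2_ratio`).
#' @param region Locus to require coverage for; defaults to [erbb2_region()].
#' @return Data frame with `sample_id`, `eligible`, `reason` (`"none"` when
#'   eligible).
#' @export
assess_eligibility <- function(clinical, segments, region = erbb2_region()) {
  ov <- segments$chrom == region$chrom & segments$start <= region$end &
    segments$end >= region$start
  covered <- unique(segments$sample_id[ov])
  no_purity <- is.na(clinical$purity)
  no_segment <- !clinical$sample_id %in% covered
  ihc_nos <- !is.na(clinical$ihc_score) & clinical$ihc_score == "NOS"
  reason <- mapply(function(p, s, i) {
    r <- c(if (p) "no_purity", if (s) "no_segment", if (i) "ihc_nos")
    if (length(r)) paste(r, collapse = "+") else "none"
  }, no_purity, no_segment, ihc_nos)
  data.frame(sample_id = clinical$sample_id,
             eligible = !(no_purity | no_segment | ihc_nos),
             reason = unname(reason), stringsAsFactors = FALSE)
}

#' ERBB2 copy-count table for a cohort
#'
#' For each eligible sample, the log2 ratios of all segments overlapping the
#' ERBB2 locus are combined by a length-weighted mean (weights are the
#' overlap widths, so a gene split across segments is handled
#' deterministically), converted to a purity-corrected relative copy count
#' and categorized. Ineligible samples are kept in the output with `NA`
#' estimates and their exclusion reason.
#'
#' @inheritParams assess_eligibility
#' @param model Copy-count model passed to [estimate_copy_count()].
#' @return Data frame with `sample_id`, `log2_ratio`, `purity`, `copies`,
#'   `category`, `eligible`, `reason`.
#' @export
erbb2_copy_counts <- function(clinical, segments, region = erbb2_region(),
                              model = c("doubling", "plus_one")) {
  model <- match.arg(model)
  elig <- assess_eligibility(clinical, segments, region)
  ov <- segments[segments$chrom == region$chrom &
                   segments$start <= region$end &
                   segments$end >= region$start, , drop = FALSE]
  if (nrow(ov)) {
    width <- pmin(ov$end, region$end) - pmax(ov$start, region$start) + 1
    l2r <- vapply(split(seq_len(nrow(ov)), ov$sample_id), function(ix) {
      stats::weighted.mean(ov$log2_ratio[ix], width[ix])
    }, numeric(1))
  } else {
    l2r <- numeric(0)
  }
  log2_ratio <- unname(l2r[clinical$sample_id])
  out <- data.frame(sample_id = clinical$sample_id,
                    log2_ratio = log2_ratio,
                    purity = clinical$purity,
                    copies = NA_real_, category = NA_character_,
                    eligible = elig$eligible, reason = elig$reason,
                    stringsAsFactors = FALSE)
  ok <- out$eligible
  out$copies[ok] <- estimate_copy_count(out$log2_ratio[ok], out$purity[ok],
                                        model = model)
  out$category[ok] <- categorize_copy_count(out$copies[ok])
  out
}
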