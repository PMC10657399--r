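#' Tumor mutational burden of one sample
#'
#' TMB is the count of germline-filtered mutations (all classes, including
#' synonymous — oncogenicity plays no role here) divided by the sequenced
#' panel footprint in megabases.
#'
#' @param variants Germline-filtered variant rows of one sample (a data
#'   frame; only its row count is used), or a single non-negative count.
#' @param panel_size_mb Panel footprint in megabases; must be positive.
#' @return TMB in mutations per megabase.
#' @examples
#' compute_tmb(30, 1.5) # 20 mut/Mb
#' @export
compute_tmb <- function(variants, panel_size_mb) {
  if (!is.numeric(panel_size_mb) || length(panel_size_mb) != 1 ||
      is.na(panel_size_mb) || panel_size_mb <= 0) {
    stop_her2("panel_size_mb must be a single positive number (got %s)",
              format(panel_size_mb), class = "her2_argument_error")
  }
  n <- if (is.data.frame(variants)) nrow(variants) else as.numeric(variants)
  n / panel_size_mb
}

#' Per-sample TMB table for a cohort
#'
#' Counts filtered variants per sample (zero for samples with none) and
#' divides by the panel footprint of each sample's panel version.
#'
#' @param variants Germline-filtered variant table (`sample_id` column).
#' @param clinical Clinical table with `sample_id` and `panel_version`.
#' @param panel_sizes_mb Named vector of megabase footprints per panel
#'   version.
#' @return Data frame with `sample_id`, `n_mutations`, `panel_size_mb`,
#'   `tmb`.
#' @export
tmb_by_sample <- function(variants, clinical,
                          panel_sizes_mb = c(v1 = 0.8, v2 = 0.9, v3 = 1.2)) {
  counts <- table(factor(variants$sample_id, levels = clinical$sample_id))
  size <- unname(panel_sizes_mb[clinical$panel_version])
  if (anyNA(size)) {
    stop_her2("panel version(s) without a configured size: %s",
              paste(unique(clinical$panel_version[is.na(size)]), collapse = ", "),
              class = "her2_argument_error")
  }
  data.frame(sample_id = clinical$sample_id,
             n_mutations = as.integer(counts),
             panel_size_mb = size,
             tmb = as.integer(counts) / size,
             stringsAsFactors = FALSE)
}

#' Cohort hypermutation threshold by two-segment changepoint fit
#'
#' Hypermutated tumors form a sparse high tail on the cohort TMB
#' distribution; the threshold is placed at the inflection where sorted TMB
#' starts rising rapidly. The detector fits an exact two-segment
#' least-squares model (two regression lines) to the sorted `log1p(TMB)`
#' curve, scanning every admissible breakpoint and minimizing the pooled
#' within-segment residual sum of squares; the threshold is the midpoint (on
#' the original scale) between the last value of the lower segment and the
#' first value of the upper segment. A linear trend per segment, rather
#' than a constant, is what makes the fit track the curve's inflection
#' instead of splitting the bulk of the distribution at its center.
#'
#' Cohorts smaller than `min_n`, or with all-identical TMB, fall back to the
#' configured threshold (default 15 mut/Mb) with `degenerate = TRUE`.
#'
#' @param tmb_values Numeric vector of per-sample TMB.
#' @param fallback Threshold returned when no changepoint can be fit.
#' @param min_n Minimum cohort size for fitting.
#' @param min_segment_frac Minimum fraction of the cohort in each segment
#'   (also bounded below by 3 points per segment).
#' @return A list with `threshold`, `degenerate`, `method`, `n`,
#'   `split_index` (last index of the lower segment, NA when degenerate).
#' @export
find_hypermutation_threshold <- function(tmb_values, fallback = 15,
                                         min_n = 20, min_segment_frac = 0.02) {
  x <- tmb_values[!is.na(tmb_values)]
  n <- length(x)
  degenerate <- list(threshold = fallback, degenerate = TRUE,
                     method = "fallback", n = n, split_index = NA_integer_)
  if (n < min_n || length(unique(x)) < 2) return(degenerate)
  y <- sort(log1p(x))
  i <- as.numeric(seq_len(n)) # numeric: integer prefix sums overflow at large n
  minseg <- max(3L, ceiling(min_segment_frac * n))
  if (2 * minseg > n) return(degenerate)
  # prefix sums give each segment's OLS residual SS in O(1)
  Sx <- cumsum(i); Sy <- cumsum(y)
  Sxx <- cumsum(i * i); Sxy <- cumsum(i * y); Syy <- cumsum(y * y)
  seg_sse <- function(a, b) {
    m <- b - a + 1
    p <- function(S) S[b] - if (a > 1) S[a - 1] else 0
    sx <- p(Sx); sy <- p(Sy)
    vx <- p(Sxx) - sx^2 / m
    vxy <- p(Sxy) - sx * sy / m
    vy <- p(Syy) - sy^2 / m
    if (vx > 1e-12) vy - vxy^2 / vx else vy
  }
  ks <- minseg:(n - minseg)
  sse <- vapply(ks, function(k) seg_sse(1L, k) + seg_sse(k + 1L, n), numeric(1))
  k <- ks[which.min(sse)]
  list(threshold = expm1((y[k] + y[k + 1]) / 2), degenerate = FALSE,
       method = "two_segment_linear", n = n, split_index = k)
}

#' Hypermutation call for given TMB values
#'
#' Strictly-greater comparison against the threshold: a tumor exactly at the
#' threshold is not hypermutated.
#'
#' @param tmb Numeric TMB value(s).
#' @param threshold Threshold in mut/Mb.
#' @return Logical vector.
#' @export
classify_hypermutated <- function(tmb, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, !is.na(threshold))
  tmb > threshold
}

#' Full TMB and hypermutation table for a cohort
#'
#' Convenience wrapper: per-sample TMB, cohort threshold detection, and the
#' hypermutation call.
#'
#' @inheritParams tmb_by_sample
#' @param fallback Fallback threshold for [find_hypermutation_threshold()].
#' @return Data frame with `sample_id`, `tmb`, `hypermutated`,
#'   `threshold_used`; the threshold fit is attached as attribute
#'   `"threshold_fit"`.
#' @export
hypermutation_table <- function(variants, clinical,
                                panel_sizes_mb = c(v1 = 0.8, v2 = 0.9, v3 = 1.2),
                                fallback = 15) {
  tab <- tmb_by_sample(variants, clinical, panel_sizes_mb)
  fit <- find_hypermutation_threshold(tab$tmb, fallback = fallback)
  out <- data.frame(sample_id = tab$sample_id, tmb = tab$tmb,
                    hypermutated = classify_hypermutated(tab$tmb, fit$threshold),
                    threshold_used = fit$threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold_fit") <- fit
  out
}
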