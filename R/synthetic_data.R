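#' Default gene profiles for the synthetic cohort generator
#'
#' One row per simulated panel gene: its role (oncogene or tumor suppressor),
#' baseline oncogenic-mutation frequencies by ER group in the HER2-0 arm,
#' oncogenic CNV frequency (high amplification for oncogenes, two-copy
#' deletion for TSGs), the planted log-odds for the HER2-low term on the
#' mutation indicator, and panel-version membership. Baseline frequencies
#' mirror the alteration tiers typical of ER-stratified metastatic breast
#' cancer panels (TP53 dominating ER-negative disease; PIK3CA, CDH1, GATA3,
#' ESR1 enriched in ER-positive disease; CCND1/FGFR1/MYC as the common
#' amplifications). The default HER2-low log-odds are 0 for every gene: the
#' generator's null landscape in which HER2-low and HER2-0 share one genomic
#' background, with ER status as the confounder.
#'
#' @return A `data.frame` with columns `gene`, `role`, `mut_freq_er_neg`,
#'   `mut_freq_er_pos`, `cnv_freq`, `her2_log_or`, `panel_versions`.
#' @export
default_gene_profiles <- function() {
  p <- function(gene, role, fn, fp, cnv, lor = 0, panels = "v1,v2,v3") {
    data.frame(gene = gene, role = role, mut_freq_er_neg = fn,
               mut_freq_er_pos = fp, cnv_freq = cnv, her2_log_or = lor,
               panel_versions = panels, stringsAsFactors = FALSE)
  }
  rbind(
    p("TP53",   "TSG",      0.870, 0.250, 0.005),
    p("PIK3CA", "oncogene", 0.130, 0.410, 0.010),
    p("CDH1",   "TSG",      0.030, 0.170, 0.002),
    p("GATA3",  "TSG",      0.015, 0.140, 0.002),
    p("ESR1",   "oncogene", 0.002, 0.120, 0.010),
    p("MTOR",   "oncogene", 0.025, 0.045, 0.002),
    p("MAP3K1", "TSG",      0.020, 0.090, 0.002),
    p("NF1",    "TSG",      0.040, 0.035, 0.004),
    p("PTEN",   "TSG",      0.080, 0.050, 0.030),
    p("RB1",    "TSG",      0.070, 0.020, 0.010),
    p("CCND1",  "oncogene", 0.005, 0.008, 0.132),
    p("FGFR1",  "oncogene", 0.004, 0.006, 0.105),
    p("MYC",    "oncogene", 0.004, 0.004, 0.061),
    p("IGF1R",  "oncogene", 0.003, 0.005, 0.015),
    p("ERBB2",  "oncogene", 0.010, 0.010, 0.000),
    p("KMT2D",  "TSG",      0.040, 0.040, 0.002, panels = "v2,v3"),
    p("NTRK3",  "oncogene", 0.005, 0.005, 0.002, panels = "v3")
  )
}

#' Build and validate a synthetic-cohort configuration
#'
#' Collects every knob of the generator, validates it, and returns a
#' `her2_sim_config` object consumed by [generate_cohort()]. Defaults emulate
#' a metastatic HER2-negative breast cancer cohort profiled on a tumor-only
#' targeted panel: a 46.9% HER2-low prevalence, the ER-by-HER2 imbalance
#' (HER2-low enriched for ER-positive disease), Beta-distributed tumor purity
#' rescaled onto the [0.2, 1] support that histologic review enforces, a
#' lognormal TMB body (median about 7.4 mut/Mb) with a 7% hypermutated tail
#' drawn uniformly on 20-60 mut/Mb, and true ERBB2 copy numbers centered at
#' 2.05 (HER2-low) versus 1.79 (HER2-0) with SD 0.5, observed through the
#' purity contamination model plus measurement noise on the log2 ratio.
#'
#' @param n_samples Number of samples (positive integer).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param her2_low_prevalence Probability a sample is HER2-low.
#' @param er_given_her2 Named list with elements `her2_low` and `her2_0`,
#'   each a probability triple `c(positive, low, negative)` summing to 1.
#' @param er_missing_rate Probability ER status is unrecorded.
#' @param gene_profiles Data frame as returned by [default_gene_profiles()].
#' @param erbb2_model List: `cn_mean_her2_low`, `cn_mean_her2_0`, `cn_sd`
#'   (true copy-number distribution, truncated at `cn_min`), `cn_min`, and
#'   `noise_sd` (Gaussian noise on the observed log2 ratio).
#' @param purity_model List: Beta `shape1`, `shape2` and `floor`; purity is
#'   `floor + (1 - floor) * Beta(shape1, shape2)`.
#' @param tmb_model List: `meanlog`, `sdlog` (lognormal body),
#'   `tail_fraction`, `tail_min`, `tail_max` (uniform hypermutated tail).
#' @param germline_contamination_rate Probability that a generated variant
#'   carries gnomAD/ClinVar flags (germline leakage of the tumor-only assay).
#' @param cosmic_rescue_rate Probability a flagged variant has a COSMIC
#'   recurrence count of at least 2 (and so survives the filter).
#' @param ihc_nos_rate Probability the recorded IHC value is "Not Otherwise
#'   Specified" under 2+ (excluded from copy-count comparisons).
#' @param purity_missing_rate,seg_missing_rate Probabilities that purity or
#'   the ERBB2 segmentation is unrecorded.
#' @param ihc2_fraction Fraction of HER2-low samples scored IHC 2+ (rest 1+).
#' @param specimen_probs Named probabilities for `primary_breast`,
#'   `local_recurrence`, `metastasis`.
#' @param panel_probs Named probabilities for panel versions `v1`, `v2`, `v3`.
#' @param panel_sizes_mb Named megabase footprints of the panel versions,
#'   used to convert latent TMB into integer mutation counts.
#' @param passenger_vus_rate Probability a passenger mutation carries a VUS
#'   label rather than no label.
#' @return An object of class `her2_sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 1039,
                       seed = 20230101,
                       her2_low_prevalence = 0.469,
                       er_given_her2 = list(
                         her2_low = c(positive = 0.768, low = 0.037, negative = 0.195),
                         her2_0   = c(positive = 0.610, low = 0.038, negative = 0.352)
                       ),
                       er_missing_rate = 0.006,
                       gene_profiles = default_gene_profiles(),
                       erbb2_model = list(cn_mean_her2_low = 2.05,
                                          cn_mean_her2_0 = 1.79,
                                          cn_sd = 0.5, cn_min = 0.5,
                                          noise_sd = 0.1),
                       purity_model = list(shape1 = 2, shape2 = 2, floor = 0.2),
                       tmb_model = list(meanlog = log(7.4), sdlog = 0.55,
                                        tail_fraction = 0.07,
                                        tail_min = 20, tail_max = 60),
                       germline_contamination_rate = 0.3,
                       cosmic_rescue_rate = 0.2,
                       ihc_nos_rate = 0.13,
                       purity_missing_rate = 0.08,
                       seg_missing_rate = 0.05,
                       ihc2_fraction = 0.43,
                       specimen_probs = c(primary_breast = 0.229,
                                          local_recurrence = 0.023,
                                          metastasis = 0.748),
                       panel_probs = c(v1 = 0.060, v2 = 0.258, v3 = 0.682),
                       panel_sizes_mb = c(v1 = 0.8, v2 = 0.9, v3 = 1.2),
                       passenger_vus_rate = 0.15) {
  cfg <- structure(
    list(n_samples = n_samples, seed = seed,
         her2_low_prevalence = her2_low_prevalence,
         er_given_her2 = er_given_her2, er_missing_rate = er_missing_rate,
         gene_profiles = gene_profiles, erbb2_model = erbb2_model,
         purity_model = purity_model, tmb_model = tmb_model,
         germline_contamination_rate = germline_contamination_rate,
         cosmic_rescue_rate = cosmic_rescue_rate,
         ihc_nos_rate = ihc_nos_rate,
         purity_missing_rate = purity_missing_rate,
         seg_missing_rate = seg_missing_rate,
         ihc2_fraction = ihc2_fraction,
         specimen_probs = specimen_probs, panel_probs = panel_probs,
         panel_sizes_mb = panel_sizes_mb,
         passenger_vus_rate = passenger_vus_rate),
    class = "her2_sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' Validate a synthetic-cohort configuration
#'
#' Checks every probability lies in [0, 1], the ER triples sum to 1, the
#' purity floor is honored, and `n_samples >= 1`. Errors name the offending
#' field.
#'
#' @param config A `her2_sim_config` object.
#' @return `config`, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  fail <- function(field, fmt, ...) {
    stop_her2(paste0("invalid configuration field '", field, "': ", fmt), ...,
              class = "her2_config_error")
  }
  chk_prob <- function(value, field) {
    if (!is.numeric(value) || anyNA(value) || any(value < 0) || any(value > 1)) {
      fail(field, "must be a probability in [0, 1] (got %s)",
           paste(format(value), collapse = ", "))
    }
  }
  n <- config$n_samples
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n)) {
    fail("n_samples", "must be a positive integer (got %s)", format(n))
  }
  chk_prob(config$her2_low_prevalence, "her2_low_prevalence")
  for (cls in c("her2_low", "her2_0")) {
    tri <- config$er_given_her2[[cls]]
    if (is.null(tri) || length(tri) != 3) {
      fail(paste0("er_given_her2$", cls), "must be a probability triple")
    }
    chk_prob(tri, paste0("er_given_her2$", cls))
    if (abs(sum(tri) - 1) > 1e-8) {
      fail(paste0("er_given_her2$", cls), "must sum to 1 (sums to %g)", sum(tri))
    }
  }
  chk_prob(config$er_missing_rate, "er_missing_rate")
  chk_prob(config$germline_contamination_rate, "germline_contamination_rate")
  chk_prob(config$cosmic_rescue_rate, "cosmic_rescue_rate")
  chk_prob(config$ihc_nos_rate, "ihc_nos_rate")
  chk_prob(config$purity_missing_rate, "purity_missing_rate")
  chk_prob(config$seg_missing_rate, "seg_missing_rate")
  chk_prob(config$ihc2_fraction, "ihc2_fraction")
  chk_prob(config$tmb_model$tail_fraction, "tmb_model$tail_fraction")
  chk_prob(config$passenger_vus_rate, "passenger_vus_rate")
  gp <- config$gene_profiles
  chk_prob(gp$mut_freq_er_neg, "gene_profiles$mut_freq_er_neg")
  chk_prob(gp$mut_freq_er_pos, "gene_profiles$mut_freq_er_pos")
  chk_prob(gp$cnv_freq, "gene_profiles$cnv_freq")
  if (!all(gp$role %in% c("oncogene", "TSG", "other"))) {
    fail("gene_profiles$role", "must be oncogene/TSG/other")
  }
  if (config$purity_model$floor < 0.2 - 1e-12) {
    fail("purity_model$floor", "must be at least 0.2 (got %g)",
         config$purity_model$floor)
  }
  invisible(config)
}

# ERBB2 locus (GRCh37, 1-based inclusive); only overlap with simulated or
# supplied segments matters, not the assembly per se.
.erbb2_region <- list(chrom = "17", start = 37844393, end = 37886915)

#' ERBB2 locus used for segment overlap
#'
#' @return A list with `chrom`, `start`, `end` (1-based, end-inclusive).
#' @export
erbb2_region <- function() .erbb2_region

#' Generate a synthetic HER2-low / HER2-0 cohort
#'
#' Draws a full cohort under the configured joint model: HER2 class and IHC
#' score, ER status with its HER2 imbalance, tumor purity, specimen type and
#' panel version; per-gene true oncogenic mutations (Bernoulli per ER-by-HER2
#' cell via the planted log-odds), passenger and germline-contaminant
#' variants with gnomAD/ClinVar/COSMIC flags; oncogenic and VUS copy-number
#' calls; and an observed ERBB2 segment log2 ratio produced by the forward
#' contamination model `log2((purity * CN + 2 * (1 - purity)) / 2)` plus
#' noise — the exact inverse of [estimate_copy_count()], so parameter
#' recovery is well-posed. All latent quantities are emitted in a truth
#' table for recovery tests.
#'
#' @param config A `her2_sim_config` from [sim_config()].
#' @return An object of class `her2_cohort`: a list with data frames
#'   `clinical`, `variants`, `cnv_calls`, `segments`, `gene_annotation`,
#'   `truth`, plus the `config`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_samples = 50, seed = 1))
#' nrow(cohort$clinical)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "her2_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  sample_id <- sprintf("S%05d", seq_len(n))

  ## clinical backbone -------------------------------------------------------
  her2_class <- ifelse(stats::runif(n) < config$her2_low_prevalence,
                       "her2_low", "her2_0")
  ihc_score <- ifelse(her2_class == "her2_0", "0",
                      ifelse(stats::runif(n) < config$ihc2_fraction, "2+", "1+"))
  ihc_score[stats::runif(n) < config$ihc_nos_rate] <- "NOS"

  er_status <- character(n)
  for (cls in c("her2_low", "her2_0")) {
    idx <- which(her2_class == cls)
    tri <- config$er_given_her2[[cls]]
    er_status[idx] <- sample(c("positive", "low", "negative"), length(idx),
                             replace = TRUE, prob = tri)
  }
  er_status[stats::runif(n) < config$er_missing_rate] <- "unknown"
  er_percent <- rep(NA_integer_, n)
  er_percent[er_status == "negative"] <- 0L
  n_low <- sum(er_status == "low")
  er_percent[er_status == "low"] <- sample(1:9, n_low, replace = TRUE)
  n_pos <- sum(er_status == "positive")
  er_percent[er_status == "positive"] <- sample(10:100, n_pos, replace = TRUE)

  pm <- config$purity_model
  purity <- pm$floor + (1 - pm$floor) * stats::rbeta(n, pm$shape1, pm$shape2)
  purity[stats::runif(n) < config$purity_missing_rate] <- NA_real_

  specimen_type <- sample(names(config$specimen_probs), n, replace = TRUE,
                          prob = config$specimen_probs)
  panel_version <- sample(names(config$panel_probs), n, replace = TRUE,
                          prob = config$panel_probs)
  panel_mb <- unname(config$panel_sizes_mb[panel_version])

  clinical <- data.frame(sample_id, her2_class, ihc_score, er_status,
                         er_percent, purity, specimen_type, panel_version,
                         stringsAsFactors = FALSE)

  ## latent TMB and ERBB2 copy number ---------------------------------------
  tm <- config$tmb_model
  hypermutated_true <- stats::runif(n) < tm$tail_fraction
  tmb_latent <- ifelse(hypermutated_true,
                       stats::runif(n, tm$tail_min, tm$tail_max),
                       stats::rlnorm(n, tm$meanlog, tm$sdlog))

  em <- config$erbb2_model
  cn_mean <- ifelse(her2_class == "her2_low", em$cn_mean_her2_low,
                    em$cn_mean_her2_0)
  erbb2_cn_true <- stats::rnorm(n, cn_mean, em$cn_sd)
  while (any(bad <- erbb2_cn_true < em$cn_min)) { # truncation by resampling
    erbb2_cn_true[bad] <- stats::rnorm(sum(bad), cn_mean[bad], em$cn_sd)
  }

  ## segments: observed ERBB2 log2 ratio through the contamination model ----
  purity_for_seg <- ifelse(is.na(purity),
                           pm$floor + (1 - pm$floor) * stats::rbeta(n, pm$shape1, pm$shape2),
                           purity)
  log2r_clean <- log2_ratio_from_copy_count(erbb2_cn_true, purity_for_seg)
  has_seg <- stats::runif(n) >= config$seg_missing_rate
  split_seg <- stats::runif(n) < 0.1 # a fraction of samples get a split locus
  reg <- .erbb2_region
  mid <- floor((reg$start + reg$end) / 2)
  seg_rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (!has_seg[i]) next
    if (split_seg[i]) {
      seg_rows[[i]] <- data.frame(
        sample_id = sample_id[i], chrom = reg$chrom,
        start = c(reg$start, mid + 1), end = c(mid, reg$end),
        log2_ratio = log2r_clean[i] + stats::rnorm(2, 0, em$noise_sd),
        stringsAsFactors = FALSE)
    } else {
      seg_rows[[i]] <- data.frame(
        sample_id = sample_id[i], chrom = reg$chrom,
        start = reg$start, end = reg$end,
        log2_ratio = log2r_clean[i] + stats::rnorm(1, 0, em$noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, seg_rows[!vapply(seg_rows, is.null, logical(1))])
  if (is.null(segments)) {
    segments <- data.frame(sample_id = character(), chrom = character(),
                           start = numeric(), end = numeric(),
                           log2_ratio = numeric(), stringsAsFactors = FALSE)
  }

  ## per-gene true driver mutations -----------------------------------------
  gp <- config$gene_profiles
  G <- nrow(gp)
  er_for_freq <- ifelse(er_status == "negative", "negative", "positive")
  mut_true <- matrix(FALSE, n, G, dimnames = list(sample_id, gp$gene))
  for (j in seq_len(G)) {
    base <- ifelse(er_for_freq == "negative", gp$mut_freq_er_neg[j],
                   gp$mut_freq_er_pos[j])
    eta <- stats::qlogis(pmin(pmax(base, 1e-9), 1 - 1e-9)) +
      gp$her2_log_or[j] * (her2_class == "her2_low")
    mut_true[, j] <- stats::runif(n) < stats::plogis(eta)
  }

  ## variant rows ------------------------------------------------------------
  lof_classes <- c("nonsense", "frameshift", "splice")
  onc_labels <- c("oncogenic", "likely_oncogenic", "predicted_oncogenic")
  variant_rows <- vector("list", n)
  g_rate <- config$germline_contamination_rate
  for (i in seq_len(n)) {
    drivers <- which(mut_true[i, ])
    n_drv <- length(drivers)
    drv <- NULL
    if (n_drv) {
      is_tsg <- gp$role[drivers] == "TSG"
      vclass <- ifelse(is_tsg,
                       sample(lof_classes, n_drv, replace = TRUE),
                       sample(c("missense", "inframe_indel"), n_drv,
                              replace = TRUE, prob = c(0.85, 0.15)))
      # TSG drivers are LOF events: half also carry a curated oncogenic label;
      # oncogene drivers are oncogenic by label.
      label <- ifelse(is_tsg & stats::runif(n_drv) < 0.5, "none",
                      sample(onc_labels, n_drv, replace = TRUE,
                             prob = c(0.5, 0.35, 0.15)))
      drv <- data.frame(sample_id = sample_id[i], gene = gp$gene[drivers],
                        variant_class = vclass, oncokb_label = label,
                        stringsAsFactors = FALSE)
    }
    n_clean_target <- max(n_drv, round(tmb_latent[i] * panel_mb[i]))
    n_pass <- n_clean_target - n_drv
    pas <- NULL
    if (n_pass > 0) {
      pas <- data.frame(
        sample_id = sample_id[i],
        gene = sample(gp$gene, n_pass, replace = TRUE),
        variant_class = sample(c("missense", "synonymous", "other"), n_pass,
                               replace = TRUE, prob = c(0.55, 0.30, 0.15)),
        oncokb_label = ifelse(stats::runif(n_pass) < config$passenger_vus_rate,
                              "vus", "none"),
        stringsAsFactors = FALSE)
    }
    germ <- NULL
    if (g_rate > 0) {
      n_germ <- stats::rpois(1, n_clean_target * g_rate / (1 - g_rate))
      if (n_germ > 0) {
        germ <- data.frame(
          sample_id = sample_id[i],
          gene = sample(gp$gene, n_germ, replace = TRUE),
          variant_class = sample(c("missense", "synonymous"), n_germ,
                                 replace = TRUE, prob = c(0.7, 0.3)),
          oncokb_label = "none",
          stringsAsFactors = FALSE)
      }
    }
    som <- rbind(drv, pas)
    if (!is.null(som) && nrow(som)) {
      som$gnomad_present <- FALSE
      som$clinvar_present <- FALSE
      som$cosmic_count <- stats::rpois(nrow(som), 0.3)
    }
    if (!is.null(germ) && nrow(germ)) {
      flag_kind <- sample(c("both", "gnomad", "clinvar"), nrow(germ),
                          replace = TRUE, prob = c(0.6, 0.3, 0.1))
      germ$gnomad_present <- flag_kind %in% c("both", "gnomad")
      germ$clinvar_present <- flag_kind %in% c("both", "clinvar")
      rescued <- stats::runif(nrow(germ)) < config$cosmic_rescue_rate
      germ$cosmic_count <- ifelse(rescued, 2L + stats::rpois(nrow(germ), 1),
                                  sample(0:1, nrow(germ), replace = TRUE))
    }
    variant_rows[[i]] <- rbind(som, germ)
  }
  variants <- do.call(rbind, variant_rows[!vapply(variant_rows, is.null, logical(1))])
  if (is.null(variants)) {
    variants <- data.frame(sample_id = character(), gene = character(),
                           variant_class = character(), oncokb_label = character(),
                           gnomad_present = logical(), clinvar_present = logical(),
                           cosmic_count = integer(), stringsAsFactors = FALSE)
  }
  rownames(variants) <- NULL

  ## CNV calls ---------------------------------------------------------------
  cnv_true <- matrix(FALSE, n, G, dimnames = list(sample_id, gp$gene))
  for (j in seq_len(G)) {
    cnv_true[, j] <- stats::runif(n) < gp$cnv_freq[j]
  }
  cnv_rows <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- which(cnv_true[i, ])
    onc <- NULL
    if (length(hits)) {
      call <- ifelse(gp$role[hits] == "oncogene", "high_amplification",
                     "two_copy_deletion")
      onc <- data.frame(sample_id = sample_id[i], gene = gp$gene[hits],
                        call = call,
                        copies_called = ifelse(call == "high_amplification",
                                               sample(7:20, length(hits), replace = TRUE),
                                               0L),
                        stringsAsFactors = FALSE)
    }
    n_vus <- stats::rpois(1, 0.5) # sub-threshold CNV noise -> VUS category
    vus <- NULL
    if (n_vus > 0) {
      vg <- sample(gp$gene, n_vus, replace = TRUE)
      vus <- data.frame(sample_id = sample_id[i], gene = vg,
                        call = sample(c("amplification", "single_copy_deletion"),
                                      n_vus, replace = TRUE),
                        copies_called = NA_integer_,
                        stringsAsFactors = FALSE)
    }
    cnv_rows[[i]] <- rbind(onc, vus)
  }
  cnv_calls <- do.call(rbind, cnv_rows[!vapply(cnv_rows, is.null, logical(1))])
  if (is.null(cnv_calls)) {
    cnv_calls <- data.frame(sample_id = character(), gene = character(),
                            call = character(), copies_called = integer(),
                            stringsAsFactors = FALSE)
  }
  rownames(cnv_calls) <- NULL

  gene_annotation <- data.frame(gene = gp$gene, role = gp$role,
                                panel_versions = gp$panel_versions,
                                stringsAsFactors = FALSE)

  truth <- data.frame(sample_id, her2_class, tmb_latent, hypermutated_true,
                      erbb2_cn_true, stringsAsFactors = FALSE)
  mut_cols <- as.data.frame(mut_true)
  names(mut_cols) <- paste0("mut_", gp$gene)
  cnv_cols <- as.data.frame(cnv_true)
  names(cnv_cols) <- paste0("cnv_", gp$gene)
  truth <- cbind(truth, mut_cols, cnv_cols)
  rownames(truth) <- NULL

  structure(list(clinical = clinical, variants = variants,
                 cnv_calls = cnv_calls, segments = segments,
                 gene_annotation = gene_annotation, truth = truth,
                 config = config),
            class = "her2_cohort")
}

#' Extract the latent truth table of a generated cohort
#'
#' Returns the per-sample latent quantities (true ERBB2 copy number,
#' hypermutation indicator, latent TMB, per-gene true mutation and CNV
#' indicators) after checking that truth and clinical tables describe exactly
#' the same samples.
#'
#' @param config The `her2_sim_config` the cohort was generated from.
#' @param cohort A `her2_cohort` from [generate_cohort()].
#' @return The truth `data.frame`, one row per sample.
#' @export
emit_truth <- function(config, cohort) {
  stopifnot(inherits(cohort, "her2_cohort"))
  if (!setequal(cohort$truth$sample_id, cohort$clinical$sample_id) ||
      anyDuplicated(cohort$truth$sample_id) ||
      nrow(cohort$truth) != nrow(cohort$clinical)) {
    stop_her2("truth and clinical tables do not describe the same samples",
              class = "her2_consistency_error")
  }
  cohort$truth
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes `clinical.tsv`, `variants.maf.tsv` (MAF dialect),
#' `cnv_calls.tsv`, `segments.seg.tsv`, `gene_annotation.tsv`, `truth.tsv`
#' and the generator configuration as `config.yaml`.
#'
#' @param cohort A `her2_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "her2_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_maf(cohort$variants, file.path(dir, "variants.maf.tsv"))
  write_tsv(cohort$cnv_calls, file.path(dir, "cnv_calls.tsv"))
  write_tsv(cohort$segments, file.path(dir, "segments.seg.tsv"))
  write_tsv(cohort$gene_annotation, file.path(dir, "gene_annotation.tsv"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  cfg <- cohort$config
  cfg$gene_profiles <- as.list(cfg$gene_profiles)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A `her2_cohort` (without the generator config's class validation;
#'   `truth` is included when present).
#' @export
read_cohort <- function(dir) {
  out <- list(
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    variants = read_maf(file.path(dir, "variants.maf.tsv")),
    cnv_calls = read_cnv_calls(file.path(dir, "cnv_calls.tsv")),
    segments = read_seg(file.path(dir, "segments.seg.tsv")),
    gene_annotation = read_gene_annotation(file.path(dir, "gene_annotation.tsv"))
  )
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    out$truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
  }
  structure(out, class = "her2_cohort")
}
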