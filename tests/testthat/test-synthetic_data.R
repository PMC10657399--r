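test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_samples = 0), "n_samples",
               class = "her2_config_error")
  expect_error(sim_config(her2_low_prevalence = 1.2), "her2_low_prevalence",
               class = "her2_config_error")
  expect_error(
    sim_config(er_given_her2 = list(her2_low = c(0.5, 0.3, 0.3),
                                    her2_0 = c(0.6, 0.04, 0.36))),
    "er_given_her2", class = "her2_config_error")
  expect_error(
    sim_config(purity_model = list(shape1 = 2, shape2 = 2, floor = 0.1)),
    "floor", class = "her2_config_error")
})

test_that("a single-sample cohort is generated with consistent tables", {
  cohort <- generate_cohort(sim_config(n_samples = 1, seed = 7,
                                       seg_missing_rate = 0,
                                       purity_missing_rate = 0))
  expect_equal(nrow(cohort$clinical), 1L)
  expect_equal(nrow(cohort$truth), 1L)
  expect_true(all(cohort$variants$sample_id == cohort$clinical$sample_id))
  expect_true(all(cohort$segments$sample_id == cohort$clinical$sample_id))
})

test_that("identical config and seed give identical cohorts", {
  cfg <- sim_config(n_samples = 120, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$variants, b$variants)
  expect_identical(a$cnv_calls, b$cnv_calls)
  expect_identical(a$segments, b$segments)
  expect_identical(a$truth, b$truth)
  d <- generate_cohort(sim_config(n_samples = 120, seed = 32))
  expect_false(identical(a$variants, d$variants))
})

test_that("marginal prevalences are recovered within 3 binomial SEs at n = 5000", {
  n <- 5000
  cfg <- sim_config(n_samples = n, seed = 99)
  cohort <- generate_cohort(cfg)
  clin <- cohort$clinical
  band <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(clin$her2_class == "her2_low") - cfg$her2_low_prevalence),
            band(cfg$her2_low_prevalence))
  # ER-negative fraction within the HER2-0 arm (missingness inflates the
  # tolerance only marginally at the configured 0.6% rate)
  zero <- clin[clin$her2_class == "her2_0" & clin$er_status != "unknown", ]
  p_neg <- cfg$er_given_her2$her2_0[["negative"]]
  expect_lt(abs(mean(zero$er_status == "negative") - p_neg),
            3 * sqrt(p_neg * (1 - p_neg) / nrow(zero)))
  # hypermutated tail fraction against the truth indicator
  p_t <- cfg$tmb_model$tail_fraction
  expect_lt(abs(mean(cohort$truth$hypermutated_true) - p_t), band(p_t))
  # a planted per-gene mutation frequency: TP53 in the ER-negative, HER2-0 cell
  cell <- clin$er_status == "negative" & clin$her2_class == "her2_0"
  f <- cfg$gene_profiles$mut_freq_er_neg[cfg$gene_profiles$gene == "TP53"]
  expect_lt(abs(mean(cohort$truth$mut_TP53[cell]) - f),
            3 * sqrt(f * (1 - f) / sum(cell)))
})

test_that("purity support is the configured [0.2, 1] interval", {
  cohort <- generate_cohort(sim_config(n_samples = 2000, seed = 5))
  p <- cohort$clinical$purity
  expect_true(all(p[!is.na(p)] >= 0.2))
  expect_true(all(p[!is.na(p)] <= 1))
})

test_that("zero germline contamination makes the filter cascade a no-op", {
  cohort <- generate_cohort(sim_config(n_samples = 150, seed = 12,
                                       germline_contamination_rate = 0))
  expect_false(any(cohort$variants$gnomad_present))
  expect_false(any(cohort$variants$clinvar_present))
  expect_identical(filter_germline(cohort$variants), cohort$variants)
})

test_that("truth table is a bijection on cohort samples and recovers plants", {
  # equal ER triples across HER2 classes: without the ER confounder the
  # zero planted log-odds must give a crude mutation OR near 1
  tri <- c(positive = 0.68, low = 0.04, negative = 0.28)
  cfg <- sim_config(n_samples = 4000, seed = 77, purity_missing_rate = 0,
                    er_given_her2 = list(her2_low = tri, her2_0 = tri),
                    erbb2_model = list(cn_mean_her2_low = 2.05,
                                       cn_mean_her2_0 = 1.79,
                                       cn_sd = 0.5, cn_min = 0.5,
                                       noise_sd = 0))
  cohort <- generate_cohort(cfg)
  truth <- emit_truth(cfg, cohort)
  expect_setequal(truth$sample_id, cohort$clinical$sample_id)
  expect_equal(anyDuplicated(truth$sample_id), 0L)
  # with all HER2 log-odds at 0 the empirical mutation OR vs HER2 class is ~1
  tab <- table(truth$mut_PIK3CA, truth$her2_class)
  or <- (tab[2, "her2_low"] * tab[1, "her2_0"]) /
    (tab[1, "her2_low"] * tab[2, "her2_0"])
  expect_gt(or, 0.75)
  expect_lt(or, 1.35)
  # truncated-normal medians sit close to the planted means at sd 0.5
  med <- tapply(truth$erbb2_cn_true, truth$her2_class, median)
  expect_lt(abs(med[["her2_low"]] - 2.05), 0.05)
  expect_lt(abs(med[["her2_0"]] - 1.79), 0.05)
})

test_that("emit_truth rejects mismatched samples", {
  cfg <- sim_config(n_samples = 10, seed = 3)
  cohort <- generate_cohort(cfg)
  cohort$truth <- cohort$truth[-1, ]
  expect_error(emit_truth(cfg, cohort), class = "her2_consistency_error")
})

test_that("cohorts round-trip through the plain-text writers", {
  cohort <- generate_cohort(sim_config(n_samples = 40, seed = 21))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$clinical$sample_id, cohort$clinical$sample_id)
  expect_equal(nrow(back$variants), nrow(cohort$variants))
  expect_equal(back$variants$cosmic_count, cohort$variants$cosmic_count)
  expect_equal(back$segments$log2_ratio, cohort$segments$log2_ratio,
               tolerance = 1e-12)
  # writing twice is byte-identical
  dir2 <- withr::local_tempdir()
  write_cohort(cohort, dir2)
  for (f in c("clinical.tsv", "variants.maf.tsv", "segments.seg.tsv")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})
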