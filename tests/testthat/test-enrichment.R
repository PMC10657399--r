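test_that("frequency selection is strict in either arm", {
  # 100 samples per arm: gene A at 4.5% in HER2-0 only; gene B at exactly 4%
  # in both arms; gene C above threshold in HER2-low only
  her2 <- rep(c("her2_low", "her2_0"), each = 100)
  m <- cbind(
    A = c(rep(FALSE, 100), rep(TRUE, 5), rep(FALSE, 95)),
    B = rep(c(rep(TRUE, 4), rep(FALSE, 96)), 2),
    C = c(rep(TRUE, 6), rep(FALSE, 194))
  )
  rownames(m) <- paste0("S", 1:200)
  expect_setequal(select_common_events(m, her2, 0.04), c("A", "C"))
})

test_that("a planted odds ratio is recovered with covariate adjustment", {
  set.seed(321)
  n <- 2000
  her2 <- sample(c("her2_low", "her2_0"), n, TRUE)
  er <- sample(c("er_positive", "er_negative"), n, TRUE)
  burden <- factor(sample(c("low", "high"), n, TRUE, prob = c(0.9, 0.1)))
  eta <- qlogis(0.10) + log(3) * (her2 == "her2_low")
  y <- runif(n) < plogis(eta)
  res <- fit_gene_model(y, her2, er, burden)
  expect_true(res$converged)
  expect_gt(res$odds_ratio, 2)
  expect_lt(res$odds_ratio, 4.5)
  expect_lt(res$p_coef, 0.05)
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
})

test_that("a null gene with balanced covariates gives OR near 1", {
  set.seed(99)
  n <- 5000
  her2 <- rep(c("her2_low", "her2_0"), n / 2)
  er <- rep(c("er_positive", "er_negative"), each = n / 2)
  burden <- factor(rep(c("low", "high"), length.out = n))
  y <- runif(n) < 0.15
  res <- fit_gene_model(y, her2, er, burden)
  expect_true(res$converged)
  expect_true(res$ci_low < 1 && 1 < res$ci_high)
})

test_that("separation and constant outcomes are reported, not estimated", {
  her2 <- rep(c("her2_low", "her2_0"), each = 20)
  er <- rep(c("er_positive", "er_negative"), 20)
  burden <- factor(rep("low", 40))
  y_sep <- her2 == "her2_low" # all events in one arm
  res <- fit_gene_model(y_sep, her2, er, burden)
  expect_false(res$converged)
  expect_equal(res$reason, "separation")
  expect_true(is.na(res$odds_ratio))
  res0 <- fit_gene_model(rep(FALSE, 40), her2, er, burden)
  expect_false(res0$converged)
  expect_equal(res0$reason, "degenerate outcome")
})

test_that("adjustment moves the estimate toward the planted direct effect", {
  # ER is associated with both HER2 class and the outcome, inflating the
  # crude OR; averaged over seeds the adjusted OR is closer to the plant.
  planted <- log(1.5)
  crude_err <- adj_err <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    n <- 3000
    her2 <- sample(c("her2_low", "her2_0"), n, TRUE)
    p_pos <- ifelse(her2 == "her2_low", 0.77, 0.61)
    er <- ifelse(runif(n) < p_pos, "er_positive", "er_negative")
    eta <- qlogis(0.08) + planted * (her2 == "her2_low") +
      log(3) * (er == "er_positive")
    y <- runif(n) < plogis(eta)
    burden <- factor(rep("low", n))
    adj <- fit_gene_model(y, her2, er, burden)
    tab <- table(y, her2)
    crude <- log((tab[2, "her2_low"] * tab[1, "her2_0"]) /
                   (tab[1, "her2_low"] * tab[2, "her2_0"]))
    crude_err[s] <- abs(crude - planted)
    adj_err[s] <- abs(log(adj$odds_ratio) - planted)
  }
  expect_lt(mean(adj_err), mean(crude_err))
})

test_that("bh_fdr matches hand-derived examples and handles NA", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  q <- bh_fdr(c(0.04, NA, 0.01))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], c(0.04, 0.02))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "her2_argument_error")
})

test_that("bh_fdr equals the brute-force step-up definition on random vectors", {
  set.seed(8)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), brute_force_bh(p), tolerance = 1e-12)
  }
  # q >= p elementwise and q monotone in p
  p <- runif(200)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # cross-check against the standard implementation
  expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("run_enrichment gates, corrects within family and logs exclusions", {
  set.seed(2718)
  n <- 800
  ids <- sprintf("S%04d", 1:n)
  clinical <- data.frame(
    sample_id = ids,
    her2_class = sample(c("her2_low", "her2_0"), n, TRUE),
    er_status = sample(c("positive", "negative", "unknown"), n, TRUE,
                       prob = c(0.65, 0.34, 0.01)))
  burden <- factor(sample(c("low", "high"), n, TRUE, prob = c(0.93, 0.07)))
  mk <- function(p_her2_low, p_her2_0) {
    ifelse(clinical$her2_class == "her2_low", runif(n) < p_her2_low,
           runif(n) < p_her2_0)
  }
  m <- cbind(ENRICHED = mk(0.25, 0.10), NULL1 = mk(0.15, 0.15),
             RARE = mk(0.01, 0.01), SEP = clinical$her2_class == "her2_low")
  rownames(m) <- ids
  res <- run_enrichment(list(
    mutation = list(events = m, burden = burden, family = "mutation")),
    clinical)
  # the rare gene falls below the 4% inclusion rule
  expect_false("RARE" %in% res$gene)
  # the separated gene is excluded and logged, never silently dropped
  excl <- attr(res, "excluded")
  expect_true("SEP" %in% excl$gene)
  expect_false("SEP" %in% res$gene)
  # the planted gene leads the family and passes the LL gate
  expect_equal(res$gene[1], "ENRICHED")
  expect_true(res$ll_pass[res$gene == "ENRICHED"])
  expect_lt(res$q_coef[res$gene == "ENRICHED"], 0.05)
  # q >= p within the family
  expect_true(all(res$q_coef >= res$p_coef - 1e-12))
  # samples without recorded ER are excluded from modeling
  expect_true(all(res$n_used <= sum(clinical$er_status != "unknown")))
})

test_that("a single tested gene has q equal to p", {
  set.seed(5)
  n <- 400
  ids <- paste0("S", 1:n)
  clinical <- data.frame(sample_id = ids,
                         her2_class = sample(c("her2_low", "her2_0"), n, TRUE),
                         er_status = sample(c("positive", "negative"), n, TRUE))
  m <- cbind(ONLY = runif(n) < 0.2)
  rownames(m) <- ids
  res <- run_enrichment(list(
    mutation = list(events = m, burden = factor(rep("low", n)),
                    family = "mutation")), clinical)
  expect_equal(res$q_coef, res$p_coef)
  expect_equal(res$q_ll, res$p_ll)
})

test_that("an empty gene list yields an empty table with a warning", {
  clinical <- data.frame(sample_id = c("A", "B"),
                         her2_class = c("her2_low", "her2_0"),
                         er_status = c("positive", "negative"))
  m <- matrix(FALSE, 2, 0, dimnames = list(c("A", "B"), NULL))
  expect_warning(
    res <- run_enrichment(list(mutation = list(events = m,
                                               burden = factor(c("low", "low")),
                                               family = "mutation")), clinical),
    "no genes")
  expect_equal(nrow(res), 0L)
})

test_that("leave-one-out burden counts avoid outcome leakage", {
  set.seed(33)
  n <- 600
  ids <- paste0("S", 1:n)
  clinical <- data.frame(sample_id = ids,
                         her2_class = sample(c("her2_low", "her2_0"), n, TRUE),
                         er_status = sample(c("positive", "negative"), n, TRUE))
  m <- matrix(runif(n * 3) < 0.1, n, 3, dimnames = list(ids, c("A", "B", "C")))
  counts <- rowSums(m)
  # with a cutoff below 1, a gene's own event forces burden "high": the as-is
  # covariate separates, the leave-one-out counts do not
  leaky <- suppressWarnings(run_enrichment(list(cnv = list(
    events = m, family = "cnv",
    burden = factor(ifelse(counts > 0.5, "high", "low")))), clinical))
  loo <- run_enrichment(list(cnv = list(
    events = m, family = "cnv",
    burden_counts = counts, burden_cutoff = 0.5)), clinical)
  expect_equal(nrow(leaky), 0L)
  expect_equal(sort(loo$gene), c("A", "B", "C"))
  expect_true(all(loo$converged))
})

test_that("cnv burden dichotomization uses a detectable cutoff", {
  set.seed(10)
  counts <- c(rpois(500, 0.5), rpois(40, 12))
  cat <- cnv_burden_category(counts)
  expect_s3_class(cat, "factor")
  cutoff <- attr(cat, "cutoff")
  expect_gt(cutoff, 1)
  expect_lt(cutoff, 12)
  expect_equal(as.vector(table(cat)["high"]), sum(counts > cutoff))
})
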