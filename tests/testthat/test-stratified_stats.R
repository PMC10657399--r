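test_that("single-stratum 2x2 equals the hand-computed MH chi-square", {
  # table [[10,20],[20,10]]: (n-1)(ad-bc)^2 / (r1 r2 c1 c2)
  #   = 59 * (10*10 - 20*20)^2 / 30^4 = 59 * 90000 / 810000 = 6.555556
  res <- cmh_general_association(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(res$statistic, 59 * 90000 / 810000, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(59 * 90000 / 810000, 1, lower.tail = FALSE))
})

test_that("identical group distributions give statistic 0 and p 1", {
  tab <- array(rep(c(5, 5, 7, 7, 3, 3), 2), dim = c(2, 3, 2))
  res <- cmh_general_association(tab)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
})

test_that("CMH matches mantelhaen.test on stratified 2xKxS tables", {
  set.seed(17)
  for (rep in 1:10) {
    K <- sample(2:4, 1); S <- sample(2:3, 1)
    tab <- array(rpois(2 * K * S, 8) + 1, dim = c(2, K, S))
    res <- cmh_general_association(tab)
    mh <- mantelhaen.test(aperm(tab, c(2, 1, 3)), correct = FALSE)
    expect_equal(res$statistic, unname(mh$statistic), tolerance = 1e-9)
    expect_equal(res$df, unname(mh$parameter))
    expect_equal(res$p_value, mh$p.value, tolerance = 1e-9)
  }
})

test_that("CMH is invariant to stratum order and category relabeling", {
  set.seed(23)
  tab <- array(rpois(12, 6) + 1, dim = c(2, 3, 2))
  a <- cmh_general_association(tab)
  b <- cmh_general_association(tab[, , 2:1])
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  perm <- c(3, 1, 2)
  c_ <- cmh_general_association(tab[, perm, ])
  expect_equal(a$statistic, c_$statistic, tolerance = 1e-9)
})

test_that("duplicating every stratum doubles information consistently", {
  set.seed(29)
  tab <- array(rpois(12, 6) + 1, dim = c(2, 3, 2))
  dup <- array(c(tab, tab), dim = c(2, 3, 4))
  a <- cmh_general_association(tab)
  d <- cmh_general_association(dup)
  # centered sums and covariance both double, so the statistic doubles
  expect_equal(d$statistic, 2 * a$statistic, tolerance = 1e-9)
  expect_equal(d$strata_used, 4L)
})

test_that("asymptotic CMH p agrees with the permutation oracle", {
  set.seed(41)
  found <- 0
  while (found < 2) {
    tab <- array(rpois(12, 10) + 2, dim = c(2, 3, 2))
    res <- cmh_general_association(tab)
    if (res$p_value < 0.05 || res$p_value > 0.95) next
    found <- found + 1
    p_perm <- cmh_permutation_p(tab, n_perm = 5000)
    expect_lt(abs(res$p_value - p_perm), 0.03)
  }
})

test_that("zero-margin strata are dropped with a warning, all-zero errors", {
  tab <- array(c(4, 6, 6, 4, 3, 0, 5, 0), dim = c(2, 2, 2)) # stratum 2: empty group
  expect_warning(res <- cmh_general_association(tab), "dropped")
  expect_equal(res$strata_used, 1L)
  expect_error(suppressWarnings(
    cmh_general_association(array(0, dim = c(2, 2, 1)))),
    class = "her2_degenerate_error")
})

test_that("ordinal CMH has 1 df and detects a monotone shift", {
  # monotone shift across 3 ordered categories, two strata
  tab <- array(c(20, 5, 15, 15, 5, 20,
                 18, 6, 14, 14, 6, 18), dim = c(2, 3, 2))
  g <- cmh_general_association(tab)
  o <- cmh_general_association(tab, type = "ordinal")
  expect_equal(o$df, 1)
  expect_lt(o$p_value, 0.05)
  expect_lte(o$p_value, g$p_value) # ordinal test concentrates the power
})

test_that("single-stratum stratified KW equals the rank-sum and KW oracles", {
  set.seed(31)
  x <- c(rnorm(18), rnorm(14, 0.8))
  g <- rep(c("A", "B"), c(18, 14))
  res <- stratified_kruskal_wallis(x, g)
  # two-sided normal-approximation Wilcoxon (tie-corrected, no correction)
  w <- wilcox.test(x ~ g, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, w$p.value, tolerance = 1e-9)
  # equals the tie-corrected Kruskal-Wallis statistic, with ties too
  xt <- round(c(rnorm(25), rnorm(25, 0.5)), 1)
  gt <- rep(c("A", "B"), each = 25)
  res_t <- stratified_kruskal_wallis(xt, gt)
  kw <- kruskal.test(xt, factor(gt))
  expect_equal(res_t$statistic, unname(kw$statistic), tolerance = 1e-9)
  # three groups, single stratum
  x3 <- c(rnorm(15), rnorm(15, 0.3), rnorm(15, 0.6))
  g3 <- rep(c("A", "B", "C"), each = 15)
  res3 <- stratified_kruskal_wallis(x3, g3)
  kw3 <- kruskal.test(x3, factor(g3))
  expect_equal(res3$statistic, unname(kw3$statistic), tolerance = 1e-9)
  expect_equal(res3$df, 2)
})

test_that("constant values give statistic 0; tiny strata are dropped", {
  res <- stratified_kruskal_wallis(rep(3.5, 30), rep(c("A", "B"), 15))
  expect_equal(res$statistic, 0)
  expect_warning(
    res2 <- stratified_kruskal_wallis(c(rnorm(20), 1), rep(c("A", "B"), length.out = 21),
                                      c(rep("s1", 20), "s2")),
    "dropped")
  expect_equal(res2$strata_used, 1L)
})

test_that("stratification removes a planted stratum confounder", {
  set.seed(61)
  n <- 400
  stratum <- rep(c("er_pos", "er_neg"), each = n / 2)
  # group imbalanced across strata; outcome depends on stratum only
  group <- ifelse(runif(n) < ifelse(stratum == "er_pos", 0.7, 0.3),
                  "her2_low", "her2_0")
  values <- rnorm(n, mean = ifelse(stratum == "er_pos", 2, 0))
  plain <- stratified_kruskal_wallis(values, group)
  strat <- stratified_kruskal_wallis(values, group, stratum)
  expect_lt(plain$p_value, 0.05)  # confounded comparison finds a fake shift
  expect_gt(strat$p_value, 0.05)  # stratified comparison does not
})

test_that("baseline tests dispatch by column type and skip degenerate columns", {
  set.seed(71)
  n <- 1039
  her2 <- sample(c("her2_low", "her2_0"), n, TRUE, prob = c(0.469, 0.531))
  p_pos <- ifelse(her2 == "her2_low", 0.77, 0.61)
  clin <- data.frame(
    her2_class = her2,
    er_status = ifelse(runif(n) < p_pos, "positive", "negative"),
    purity = runif(n, 0.2, 1),
    dur = rexp(n, 0.1),
    constant_col = "x")
  res <- baseline_tests(clin, categorical = c("er_status", "constant_col"),
                        continuous = "purity", durations = "dur")
  expect_lt(res$p_value[res$variable == "er_status"], 0.001)
  expect_true(grepl("skipped", res$note[res$variable == "constant_col"]))
  expect_equal(res$method[res$variable == "purity"], "welch_t")
  expect_equal(res$method[res$variable == "dur"], "wilcoxon")
})
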