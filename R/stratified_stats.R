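#' @keywords internal
#' @noRd
her2_test_result <- function(statistic, df, p_value, method, strata_used,
                             note = "") {
  data.frame(statistic = statistic, df = df, p_value = p_value,
             method = method, strata_used = strata_used, note = note,
             stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
as_cmh_array <- function(x, group, category, stratum) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1)))
  table(factor(group), factor(category), factor(stratum))
}

#' Generalized Cochran-Mantel-Haenszel test of general association
#'
#' Tests whether the category distribution differs between two groups after
#' pooling over strata. Within each stratum the first group's category-count
#' vector is centered at its conditional expectation and the multivariate
#' hypergeometric covariance (with the `n_s - 1` finite-population
#' denominator) is accumulated; the statistic is the quadratic form of the
#' pooled centered vector, referred to chi-square with `K - 1` degrees of
#' freedom. With one stratum and two categories this reduces to the
#' Mantel-Haenszel chi-square without continuity correction. Strata with a
#' zero group or category margin contribute nothing and are dropped with a
#' warning. An ordinal (correlation-type) variant using integer category
#' scores is available for ordered categories such as IHC 0 / 1+ / 2+; it
#' has 1 degree of freedom and power against monotone shifts.
#'
#' @param x Either a 3-d array of counts with dimensions (2 groups, K
#'   categories, S strata), a 2 x K matrix (single stratum), or `NULL` when
#'   `group`/`category`/`stratum` vectors are supplied.
#' @param group,category,stratum Optional per-observation vectors used when
#'   `x` is `NULL`.
#' @param type `"general"` (nominal categories, default) or `"ordinal"`
#'   (integer scores on the category dimension).
#' @return A one-row data frame: `statistic`, `df`, `p_value`, `method`,
#'   `strata_used`, `note`.
#' @examples
#' cmh_general_association(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
#' @export
cmh_general_association <- function(x = NULL, group = NULL, category = NULL,
                                    stratum = NULL,
                                    type = c("general", "ordinal")) {
  type <- match.arg(type)
  tab <- as_cmh_array(x, group, category, stratum)
  if (dim(tab)[1] != 2) {
    stop_her2("CMH test requires exactly 2 groups (got %d)", dim(tab)[1],
              class = "her2_argument_error")
  }
  K <- dim(tab)[2]; S <- dim(tab)[3]
  if (sum(tab) == 0) {
    stop_her2("all counts are zero", class = "her2_degenerate_error")
  }
  used <- 0L; dropped <- 0L
  if (type == "general") {
    U <- numeric(K - 1); V <- matrix(0, K - 1, K - 1)
  } else {
    score <- seq_len(K)
    U <- 0; V <- 0
  }
  for (s in seq_len(S)) {
    t_s <- tab[, , s, drop = TRUE]
    if (is.null(dim(t_s))) t_s <- matrix(t_s, nrow = 2)
    n_s <- sum(t_s)
    n1 <- sum(t_s[1, ]); n2 <- sum(t_s[2, ])
    m <- colSums(t_s)
    if (n_s < 2 || n1 == 0 || n2 == 0 || sum(m > 0) < 2) {
      if (n_s > 0) dropped <- dropped + 1L
      next
    }
    used <- used + 1L
    if (type == "general") {
      U <- U + (t_s[1, -K] - n1 * m[-K] / n_s)
      V <- V + n1 * n2 / (n_s^2 * (n_s - 1)) *
        (n_s * diag(m[-K], K - 1) - outer(m[-K], m[-K]))
    } else {
      U <- U + sum(score * t_s[1, ]) - n1 * sum(score * m) / n_s
      V <- V + n1 * n2 / (n_s^2 * (n_s - 1)) *
        (n_s * sum(score^2 * m) - sum(score * m)^2)
    }
  }
  if (dropped) {
    warning(sprintf("%d stratum(a) with a zero margin dropped", dropped),
            call. = FALSE)
  }
  if (used == 0) {
    stop_her2("no usable stratum", class = "her2_degenerate_error")
  }
  if (type == "general") {
    Vinv <- MASS::ginv(V)
    stat <- drop(t(U) %*% Vinv %*% U)
    df <- qr(V)$rank
    method <- "cmh_general_association"
  } else {
    stat <- if (V > 0) U^2 / V else 0
    df <- 1L
    method <- "cmh_ordinal"
  }
  if (df == 0) { # degenerate covariance: no variation to test
    return(her2_test_result(0, 1L, 1, method, used, note = "degenerate"))
  }
  her2_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                   method, used)
}

#' Stratified Kruskal-Wallis (van Elteren-type) rank test
#'
#' Asymptotic rank test of a location difference between groups, stratified
#' on a blocking factor. Observations are midranked within each stratum
#' (ties get midranks), the ranks are centered at the stratum mean, and the
#' group sums of centered ranks are pooled across strata. The statistic is
#' the quadratic form of the pooled sums against their within-stratum
#' permutation covariance, referred to chi-square with `groups - 1` degrees
#' of freedom. With a single stratum this is exactly the tie-corrected
#' Kruskal-Wallis statistic; with two groups and one stratum its p-value
#' equals the two-sided normal-approximation Wilcoxon rank-sum p-value.
#' Strata with fewer than two observations, or where a group is absent,
#' carry no information and are dropped with a warning.
#'
#' @param values Numeric outcome (e.g. TMB).
#' @param groups Group labels (2 or more levels).
#' @param strata Stratum labels; defaults to a single stratum.
#' @return A one-row data frame: `statistic`, `df`, `p_value`, `method`,
#'   `strata_used`, `note`.
#' @export
stratified_kruskal_wallis <- function(values, groups, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, length(values))
  ok <- !is.na(values) & !is.na(groups) & !is.na(strata)
  values <- values[ok]; groups <- factor(groups[ok]); strata <- factor(strata[ok])
  G <- nlevels(groups)
  if (G < 2) {
    stop_her2("need at least 2 groups", class = "her2_argument_error")
  }
  U <- numeric(G); V <- matrix(0, G, G)
  used <- 0L; dropped <- 0L
  for (s in levels(strata)) {
    ix <- which(strata == s)
    n_s <- length(ix)
    if (n_s < 2) { if (n_s > 0) dropped <- dropped + 1L; next }
    a <- rank(values[ix]) - (n_s + 1) / 2
    g <- groups[ix]
    n_g <- tabulate(g, nbins = G)
    s2 <- sum(a^2) / (n_s - 1)
    U <- U + vapply(seq_len(G), function(k) sum(a[as.integer(g) == k]), numeric(1))
    V <- V + s2 * (diag(n_g, G) - outer(n_g, n_g) / n_s)
    used <- used + 1L
  }
  if (dropped) {
    warning(sprintf("%d stratum(a) with fewer than 2 observations dropped",
                    dropped), call. = FALSE)
  }
  if (used == 0) {
    stop_her2("no usable stratum", class = "her2_degenerate_error")
  }
  Uc <- U[-G]; Vc <- V[-G, -G, drop = FALSE]
  rk <- qr(Vc)$rank
  if (rk == 0) {
    return(her2_test_result(0, G - 1L, 1, "stratified_kruskal_wallis", used,
                            note = "degenerate"))
  }
  stat <- drop(t(Uc) %*% MASS::ginv(Vc) %*% Uc)
  df <- G - 1L
  her2_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                   "stratified_kruskal_wallis", used)
}

#' Baseline between-group comparisons of a clinical table
#'
#' The conventional cohort-description tests: chi-square (no continuity
#' correction) for categorical columns, Welch t-test for continuous
#' columns, and the Wilcoxon rank-sum test (normal approximation) for
#' duration-type columns. Columns with a single observed level, or
#' continuous columns without enough observations per group, are skipped
#' with a note.
#'
#' @param clinical Data frame.
#' @param group_col Name of the two-level grouping column (default
#'   `her2_class`).
#' @param categorical,continuous,durations Character vectors of column
#'   names to test.
#' @return Data frame with one row per tested column: `variable`, `method`,
#'   `statistic`, `df`, `p_value`, `note`.
#' @export
baseline_tests <- function(clinical, group_col = "her2_class",
                           categorical = character(),
                           continuous = character(),
                           durations = character()) {
  g <- factor(clinical[[group_col]])
  rows <- list()
  add <- function(variable, method, statistic, df, p_value, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, method = method, statistic = statistic, df = df,
      p_value = p_value, note = note, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- factor(clinical[[v]])
    keep <- !is.na(x) & !is.na(g)
    if (nlevels(droplevels(x[keep])) < 2 || nlevels(droplevels(g[keep])) < 2) {
      add(v, "chi_square", NA, NA, NA, "skipped: single level")
      next
    }
    ct <- suppressWarnings(stats::chisq.test(table(g[keep], x[keep]),
                                             correct = FALSE))
    add(v, "chi_square", unname(ct$statistic), unname(ct$parameter), ct$p.value)
  }
  for (v in continuous) {
    x <- as.numeric(clinical[[v]])
    keep <- !is.na(x) & !is.na(g)
    if (min(table(droplevels(g[keep]))) < 2 ||
        nlevels(droplevels(g[keep])) < 2) {
      add(v, "welch_t", NA, NA, NA, "skipped: insufficient data")
      next
    }
    tt <- stats::t.test(x[keep] ~ droplevels(g[keep]))
    add(v, "welch_t", unname(tt$statistic), unname(tt$parameter), tt$p.value)
  }
  for (v in durations) {
    x <- as.numeric(clinical[[v]])
    keep <- !is.na(x) & !is.na(g)
    if (nlevels(droplevels(g[keep])) < 2) {
      add(v, "wilcoxon", NA, NA, NA, "skipped: single level")
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(x[keep] ~ droplevels(g[keep]),
                                              exact = FALSE, correct = FALSE))
    add(v, "wilcoxon", unname(wt$statistic), NA, wt$p.value)
  }
  if (!length(rows)) {
    return(data.frame(variable = character(), method = character(),
                      statistic = numeric(), df = numeric(),
                      p_value = numeric(), note = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
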