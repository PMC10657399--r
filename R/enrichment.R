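#' Build a samples-by-genes alteration matrix
#'
#' @param events Data frame with `sample_id` and `gene` (one row per event).
#' @param sample_ids Character vector defining the row set and order.
#' @param genes Optional character vector defining the column set; defaults
#'   to the genes present in `events`.
#' @return Logical matrix, samples in rows, genes in columns.
#' @export
build_alteration_matrix <- function(events, sample_ids, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(events$gene))
  m <- matrix(FALSE, length(sample_ids), length(genes),
              dimnames = list(sample_ids, genes))
  keep <- events$sample_id %in% sample_ids & events$gene %in% genes
  if (any(keep)) m[cbind(events$sample_id[keep], events$gene[keep])] <- TRUE
  m
}

#' Select genes altered in more than a threshold fraction of either arm
#'
#' Mirrors the inclusion rule for the mutation enrichment analysis: a gene
#' enters modeling when its alteration frequency is strictly above the
#' threshold in the HER2-low arm or in the HER2-0 arm. The comparison is
#' strict, so a gene at exactly the threshold in both arms is dropped.
#'
#' @param matrix Logical samples-by-genes matrix.
#' @param her2_class Character vector (`her2_low` / `her2_0`) aligned with
#'   the matrix rows.
#' @param threshold Frequency threshold; default 0.04.
#' @return Character vector of selected gene names.
#' @export
select_common_events <- function(matrix, her2_class, threshold = 0.04) {
  f_low <- colMeans(matrix[her2_class == "her2_low", , drop = FALSE])
  f_zero <- colMeans(matrix[her2_class == "her2_0", , drop = FALSE])
  colnames(matrix)[f_low > threshold | f_zero > threshold]
}

#' Fit the per-gene logistic enrichment model
#'
#' Maximum-likelihood logistic regression of a gene's per-sample event
#' indicator on HER2 class, ER group (positive including ER-low, versus
#' negative) and a categorical background-burden covariate. The reported
#' odds ratio is `exp` of the HER2-low coefficient with a Wald 95% CI and
#' two-tailed Wald p-value; the model-level p-value is a likelihood-ratio
#' test against the intercept-only model. Fits that fail to converge within
#' `max_iter` iterations, sit on the boundary, or show the degenerate
#' standard errors of complete separation are reported as non-converged and
#' carry no estimates. A constant outcome is reported as non-converged with
#' reason `"degenerate outcome"`.
#'
#' @param y Logical (or 0/1) event indicator per sample.
#' @param her2_class Character vector, `her2_low` / `her2_0`.
#' @param er_group Factor or character, `er_positive` / `er_negative`;
#'   samples with `NA` are excluded from the fit.
#' @param burden Categorical background-burden covariate (e.g.
#'   hypermutation status for mutations, high CNV burden for CNVs).
#' @param max_iter IRLS iteration cap; default 500.
#' @return One-row data frame: `odds_ratio`, `ci_low`, `ci_high`, `p_coef`,
#'   `p_ll`, `converged`, `n_iterations`, `n_used`, `reason`.
#' @export
fit_gene_model <- function(y, her2_class, er_group, burden, max_iter = 500) {
  keep <- !is.na(er_group) & !is.na(y) & !is.na(her2_class) & !is.na(burden)
  y <- as.integer(y[keep])
  dat <- data.frame(
    y = y,
    her2 = factor(her2_class[keep], levels = c("her2_0", "her2_low")),
    er = factor(er_group[keep]),
    burden = factor(burden[keep])
  )
  blank <- data.frame(odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_coef = NA_real_, p_ll = NA_real_,
                      converged = FALSE, n_iterations = 0L,
                      n_used = nrow(dat), reason = "", stringsAsFactors = FALSE)
  if (length(unique(dat$y)) < 2) {
    blank$reason <- "degenerate outcome"
    return(blank)
  }
  # drop single-level covariates (e.g. no hypermutated sample in a subset)
  form <- y ~ her2
  if (nlevels(droplevels(dat$er)) > 1) form <- stats::update(form, . ~ . + er)
  if (nlevels(droplevels(dat$burden)) > 1) form <- stats::update(form, . ~ . + burden)
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(maxit = max_iter))
  )
  blank$n_iterations <- fit$iter
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  if (!"her2her2_low" %in% rownames(co)) {
    blank$reason <- "degenerate outcome"
    return(blank)
  }
  separated <- any(abs(co[, "Estimate"]) > 15) ||
    any(co[, "Std. Error"] > 10)
  if (!fit$converged || fit$boundary || separated) {
    blank$reason <- if (separated) "separation" else "no convergence"
    return(blank)
  }
  est <- co["her2her2_low", "Estimate"]
  se <- co["her2her2_low", "Std. Error"]
  null_fit <- stats::glm(y ~ 1, family = stats::binomial(), data = dat)
  lrt <- null_fit$deviance - fit$deviance
  df <- null_fit$df.residual - fit$df.residual
  data.frame(odds_ratio = exp(est),
             ci_low = exp(est - 1.959964 * se),
             ci_high = exp(est + 1.959964 * se),
             p_coef = 2 * stats::pnorm(-abs(est / se)),
             p_ll = stats::pchisq(lrt, df, lower.tail = FALSE),
             converged = TRUE, n_iterations = fit$iter, n_used = nrow(dat),
             reason = "none", stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j)`, clipped to
#' 1. Missing values are excluded from the ranking and reinserted as
#' missing; `m` is the number of non-missing p-values.
#'
#' @param p_values Numeric vector of p-values in [0, 1] (`NA` allowed).
#' @return Vector of q-values, same length and order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) {
    stop_her2("p-values must lie in [0, 1]", class = "her2_argument_error")
  }
  q <- rep(NA_real_, length(p_values))
  m <- length(p)
  if (m) {
    o <- order(p, decreasing = TRUE)
    qs <- pmin(1, cummin(p[o] * m / seq(m, 1)))
    q[ok][o] <- qs
  }
  q
}

#' Dichotomize per-sample CNV burden at a changepoint-chosen cutoff
#'
#' The count of high amplifications plus deep deletions per sample serves as
#' the background covariate for CNV enrichment models. The cutoff between
#' "low" and "high" burden is placed by the same two-segment changepoint
#' scan used for the TMB tail ([find_hypermutation_threshold()]), applied to
#' the per-sample counts; it can also be fixed explicitly.
#'
#' @param counts Non-negative integer vector of oncogenic-CNV counts.
#' @param cutoff Optional fixed cutoff; when `NULL` it is detected.
#' @param fallback Cutoff used when no changepoint can be fit.
#' @return Factor with levels `low`/`high`; the cutoff is attached as
#'   attribute `"cutoff"`.
#' @export
cnv_burden_category <- function(counts, cutoff = NULL, fallback = 3) {
  if (is.null(cutoff)) {
    fit <- find_hypermutation_threshold(counts, fallback = fallback)
    cutoff <- fit$threshold
  }
  out <- factor(ifelse(counts > cutoff, "high", "low"), levels = c("low", "high"))
  attr(out, "cutoff") <- cutoff
  out
}

#' Run the per-gene enrichment analysis over event families
#'
#' Fits [fit_gene_model()] for every selected gene in every event class,
#' then applies the two-level multiple-testing scheme within each family
#' (mutations and CNVs are corrected separately): the likelihood-ratio
#' p-values are BH-adjusted and models pass the gate at LL q < `ll_alpha`;
#' coefficient p-values are BH-adjusted across the same family. Mutation
#' families apply the frequency filter ([select_common_events()]); CNV
#' families are exempt. Non-converged models are excluded from the result
#' table and listed, with reasons, in the `"excluded"` attribute.
#'
#' @param matrices Named list of event classes. Each element is a list with
#'   `events` (logical samples-by-genes matrix), `family` (`"mutation"` or
#'   `"cnv"`), and either `burden` (a per-sample categorical covariate used
#'   as-is) or `burden_counts` (per-sample event counts dichotomized at
#'   `burden_cutoff`, detected by changepoint when absent, with the focal
#'   gene's own event subtracted before dichotomizing — leave-one-out, so a
#'   gene's outcome never leaks into its background covariate); optionally
#'   `frequency_filter` (logical; default TRUE for mutation families, FALSE
#'   for CNV families).
#' @param clinical Clinical table providing `her2_class` and `er_status`
#'   aligned with the matrix rows (matched on `sample_id`).
#' @param freq_threshold Frequency threshold for mutation families.
#' @param max_iter Iteration cap per fit.
#' @param ll_alpha Significance level of the log-likelihood gate.
#' @return Data frame of class `her2_enrichment` with one row per converged
#'   gene-by-class model: `gene`, `event_class`, `family`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_coef`, `q_coef`, `p_ll`, `q_ll`, `ll_pass`,
#'   `converged`, `n_iterations`, sorted by `q_coef` then `p_coef` within
#'   family. Attribute `"excluded"` holds non-converged gene records.
#' @export
run_enrichment <- function(matrices, clinical, freq_threshold = 0.04,
                           max_iter = 500, ll_alpha = 0.05) {
  er_group <- er_group_from_status(clinical$er_status)
  rows <- list(); excluded <- list()
  for (class_name in names(matrices)) {
    spec <- matrices[[class_name]]
    mat <- spec$events
    ids <- rownames(mat)
    her2 <- clinical$her2_class[match(ids, clinical$sample_id)]
    erg <- er_group[match(ids, clinical$sample_id)]
    use_filter <- if (!is.null(spec$frequency_filter)) spec$frequency_filter
                  else identical(spec$family, "mutation")
    genes <- if (use_filter) {
      select_common_events(mat, her2, freq_threshold)
    } else {
      colnames(mat)[colSums(mat) > 0]
    }
    if (!length(genes)) next
    loo_counts <- NULL
    if (!is.null(spec$burden_counts)) {
      cutoff <- spec$burden_cutoff
      if (is.null(cutoff)) {
        cutoff <- attr(cnv_burden_category(spec$burden_counts), "cutoff")
      }
      loo_counts <- spec$burden_counts
    }
    for (g in genes) {
      burden_g <- if (is.null(loo_counts)) spec$burden else
        factor(ifelse(loo_counts - mat[, g] > cutoff, "high", "low"),
               levels = c("low", "high"))
      res <- fit_gene_model(mat[, g], her2, erg, burden_g, max_iter)
      res$gene <- g; res$event_class <- class_name; res$family <- spec$family
      if (res$converged) {
        rows[[length(rows) + 1L]] <- res
      } else {
        excluded[[length(excluded) + 1L]] <- data.frame(
          gene = g, event_class = class_name, family = spec$family,
          reason = res$reason, stringsAsFactors = FALSE)
      }
    }
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(gene = character(), event_class = character(),
               family = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (!length(rows)) {
    warning("no genes selected for enrichment modeling", call. = FALSE)
    out <- data.frame(gene = character(), event_class = character(),
                      family = character(), odds_ratio = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_coef = numeric(), q_coef = numeric(),
                      p_ll = numeric(), q_ll = numeric(), ll_pass = logical(),
                      converged = logical(), n_iterations = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    class(out) <- c("her2_enrichment", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_coef <- NA_real_; out$q_ll <- NA_real_
  for (fam in unique(out$family)) {
    ix <- out$family == fam
    out$q_ll[ix] <- bh_fdr(out$p_ll[ix])
    out$q_coef[ix] <- bh_fdr(out$p_coef[ix])
  }
  out$ll_pass <- out$q_ll < ll_alpha
  out <- out[order(out$family, out$q_coef, out$p_coef), ]
  out <- out[, c("gene", "event_class", "family", "odds_ratio", "ci_low",
                 "ci_high", "p_coef", "q_coef", "p_ll", "q_ll", "ll_pass",
                 "converged", "n_iterations", "n_used")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("her2_enrichment", class(out))
  out
}

#' Map recorded ER status to the two-level modeling group
#'
#' ER-low (1-9% staining) is grouped with ER-positive; unknown status maps
#' to `NA` (such samples are excluded wherever ER is a covariate or
#' stratum).
#'
#' @param er_status Character vector with values `positive`, `low`,
#'   `negative`, `unknown`.
#' @return Character vector with values `er_positive`, `er_negative`, `NA`.
#' @export
er_group_from_status <- function(er_status) {
  ifelse(er_status %in% c("positive", "low"), "er_positive",
         ifelse(er_status == "negative", "er_negative", NA_character_))
}
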