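# Hand-built fixtures shared across test files.

# Ten variants with known database flags; the retained set and oncogenicity
# labels below are worked out by hand from the filtering and classification
# rules.  Genes: TP53 (TSG), PIK3CA (oncogene), BRCA2 (TSG), KRAS (oncogene).
fixture_variants <- function() {
  data.frame(
    sample_id = paste0("S", 1:10),
    gene = c("TP53", "TP53", "PIK3CA", "PIK3CA", "BRCA2",
             "BRCA2", "KRAS", "KRAS", "TP53", "PIK3CA"),
    variant_class = c("frameshift", "missense", "missense", "synonymous",
                      "nonsense", "splice", "missense", "missense",
                      "missense", "missense"),
    gnomad_present = c(FALSE, TRUE,  FALSE, FALSE, TRUE,
                       FALSE, TRUE,  FALSE, FALSE, TRUE),
    clinvar_present = c(FALSE, FALSE, TRUE,  FALSE, TRUE,
                        FALSE, FALSE, FALSE, TRUE,  TRUE),
    cosmic_count = c(0L, 2L, 1L, 0L, 5L, 0L, 0L, 3L, 2L, 1L),
    oncokb_label = c("none", "likely_oncogenic", "oncogenic", "none", "none",
                     "none", "predicted_oncogenic", "vus", "none", "vus"),
    stringsAsFactors = FALSE
  )
  # retained by the germline filter (rule applied by hand):
  #  1 TP53  no flags                      -> keep
  #  2 TP53  gnomAD, cosmic 2 (rescue)     -> keep
  #  3 PIK3CA ClinVar, cosmic 1            -> drop
  #  4 PIK3CA no flags                     -> keep
  #  5 BRCA2 both flags, cosmic 5 (rescue) -> keep
  #  6 BRCA2 no flags                      -> keep
  #  7 KRAS  gnomAD, cosmic 0              -> drop
  #  8 KRAS  no flags                      -> keep
  #  9 TP53  ClinVar, cosmic 2 (rescue)    -> keep
  # 10 PIK3CA both flags, cosmic 1         -> drop
}

fixture_retained_ids <- function() c("S1", "S2", "S4", "S5", "S6", "S8", "S9")

# oncogenic among the retained rows, by hand:
#  S1 TP53 frameshift, label none        -> oncogenic via LOF-in-TSG
#  S2 TP53 missense, likely_oncogenic    -> oncogenic via label
#  S4 PIK3CA synonymous                  -> never oncogenic
#  S5 BRCA2 nonsense, label none         -> oncogenic via LOF-in-TSG
#  S6 BRCA2 splice, label none           -> oncogenic via LOF-in-TSG
#  S8 KRAS missense, label vus           -> not oncogenic
#  S9 TP53 missense, label none          -> not oncogenic (missense, no label)
fixture_oncogenic_ids <- function() c("S1", "S2", "S5", "S6")

fixture_annotation <- function() {
  data.frame(
    gene = c("TP53", "PIK3CA", "BRCA2", "KRAS", "NTRK1"),
    role = c("TSG", "oncogene", "TSG", "oncogene", "oncogene"),
    panel_versions = c("v1,v2,v3", "v1,v2,v3", "v2,v3", "v1,v2,v3", "v3"),
    stringsAsFactors = FALSE
  )
}

# Small clinical table exercising the sensitivity subsets: 3 metastatic with
# ER, 2 primaries, 1 metastatic without ER.
fixture_clinical <- function() {
  data.frame(
    sample_id = paste0("C", 1:6),
    her2_class = c("her2_low", "her2_0", "her2_low", "her2_0", "her2_low", "her2_0"),
    ihc_score = c("1+", "0", "2+", "0", "2+", "0"),
    er_status = c("positive", "negative", "low", "positive", "unknown", "positive"),
    er_percent = c(80L, 0L, 5L, 50L, NA, 90L),
    purity = c(0.6, 0.5, 0.7, 0.4, 0.3, 0.55),
    specimen_type = c("metastasis", "metastasis", "metastasis",
                      "primary_breast", "metastasis", "primary_breast"),
    panel_version = c("v3", "v3", "v2", "v1", "v3", "v3"),
    stringsAsFactors = FALSE
  )
}

# Independent brute-force BH oracle, straight from the step-up definition:
# q_i = min over j with p_j >= p_i of p_j * m / rank_j, clipped to 1.
brute_force_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  adj <- p * n / r
  vapply(seq_len(n), function(i) min(1, adj[p >= p[i]]), numeric(1))
}

# Independent CMH general-association statistic for a 2 x K x S count array,
# written directly from the pooled-score definition (first-row counts centered
# at their hypergeometric expectation, pooled covariance, quadratic form).
oracle_cmh_stat <- function(tab) {
  K <- dim(tab)[2]; S <- dim(tab)[3]
  U <- numeric(K - 1); V <- matrix(0, K - 1, K - 1)
  for (s in seq_len(S)) {
    t_s <- tab[, , s]
    n_s <- sum(t_s); n1 <- sum(t_s[1, ]); n2 <- sum(t_s[2, ])
    m <- colSums(t_s)
    U <- U + t_s[1, -K] - n1 * m[-K] / n_s
    V <- V + n1 * n2 / (n_s^2 * (n_s - 1)) *
      (n_s * diag(m[-K], K - 1) - outer(m[-K], m[-K]))
  }
  drop(t(U) %*% solve(V) %*% U)
}

# Permutation oracle for the CMH p-value on a 2 x K x S table: permute group
# membership within each stratum (margins fixed), recompute the statistic,
# and report the mid-p (half weight on ties at the observed value), the
# convention for comparing a discrete permutation null with a continuous
# reference distribution.
cmh_permutation_p <- function(tab, n_perm = 1e4) {
  K <- dim(tab)[2]; S <- dim(tab)[3]
  obs <- oracle_cmh_stat(tab)
  strata <- lapply(seq_len(S), function(s) {
    t_s <- tab[, , s]
    list(cat = c(rep(seq_len(K), t_s[1, ]), rep(seq_len(K), t_s[2, ])),
         n = sum(t_s), n1 = sum(t_s[1, ]))
  })
  gt <- 0L; eq <- 0L
  newtab <- array(0, dim = dim(tab))
  for (b in seq_len(n_perm)) {
    for (s in seq_len(S)) {
      st <- strata[[s]]
      pick <- sample.int(st$n, st$n1)
      x1 <- tabulate(st$cat[pick], K)
      newtab[1, , s] <- x1
      newtab[2, , s] <- tabulate(st$cat, K) - x1
    }
    stat <- oracle_cmh_stat(newtab)
    if (stat > obs + 1e-9) gt <- gt + 1L
    else if (abs(stat - obs) <= 1e-9) eq <- eq + 1L
  }
  (gt + 0.5 * eq) / n_perm
}
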