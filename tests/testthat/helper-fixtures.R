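# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# Default-scale cohort with designed QC violations and MA contamination.
designed_cohort <- function() {
  if (is.null(.fixture_env$designed)) {
    cfg <- sim_config(qc_violations = c(ntc = 2, nuclei = 3, alignment = 1),
                      contam_n_ma = 4, contam_lambda = 0.6, seed = 7)
    .fixture_env$designed <- simulate_cohort(cfg)
  }
  .fixture_env$designed
}

# QC + normalization result for the designed cohort.
designed_qc <- function() {
  if (is.null(.fixture_env$designed_qc)) {
    coh <- designed_cohort()
    .fixture_env$designed_qc <- qc_normalize(
      coh$counts, coh$annotations, coh$negprobes, coh$truth$marker_sets$EP)
  }
  .fixture_env$designed_qc
}

# Balanced cohort for recovery tests: 10 ROIs per grade, effect 1.0.
balanced_cohort <- function() {
  if (is.null(.fixture_env$balanced)) {
    cfg <- sim_config(n_patients = 10, rois_per_patient = 3,
                      rois_per_grade = c(10, 10, 10), seed = 11)
    .fixture_env$balanced <- simulate_cohort(cfg)
  }
  .fixture_env$balanced
}

# Small synthetic 4-type reference with block-marker structure.
toy_reference <- function(n_markers = 15, seed = 5) {
  set.seed(seed)
  types <- paste0("type", 1:4)
  genes <- sprintf("SG%03d", seq_len(n_markers * 4))
  ref <- matrix(stats::rlnorm(length(genes) * 4, log(5), 0.2),
                nrow = length(genes), dimnames = list(genes, types))
  for (j in 1:4) {
    idx <- ((j - 1) * n_markers + 1):(j * n_markers)
    ref[idx, j] <- ref[idx, j] * 50
  }
  ref
}

# Two-sided Wilcoxon rank-sum p by full enumeration of all rank splits.
wilcoxon_enum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(length(pooled), m)
  ws <- apply(splits, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * length(y) / 2
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-12)
}

# Naive O(N * |S|) ssGSEA oracle following the running-sum definition.
ssgsea_oracle <- function(expr, set, alpha) {
  n <- length(expr)
  ord <- order(-expr, names(expr), method = "radix")
  genes <- names(expr)[ord]
  in_set <- genes %in% set
  r <- (n - seq_len(n) + 1)^alpha
  denom_in <- sum(r[in_set])
  n_out <- n - sum(in_set)
  es <- 0
  for (i in seq_len(n)) {
    p_in <- sum(r[seq_len(i)][in_set[seq_len(i)]]) / denom_in
    p_out <- sum(!in_set[seq_len(i)]) / n_out
    es <- es + (p_in - p_out)
  }
  es
}

# Upper-tail hypergeometric p by direct summation of the pmf.
ora_enum_p <- function(k, m, N, n) {
  kk <- k:min(m, n)
  sum(choose(m, kk) * choose(N - m, n - kk)) / choose(N, n)
}

# AUC by brute-force pair counting with 0.5 tie credit.
auc_enum <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
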