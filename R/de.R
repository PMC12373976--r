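# Rank-based differential expression between grade groups within a
# compartment, BH adjustment, and the four-pattern monotone trend
# classifier across well -> moderate -> poor.

PATTERN_LABELS <- c("P1", "P2", "P3", "P4")

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when the pooled size is <= 20 and there are
#' no ties; otherwise the normal approximation with midrank tie
#' correction and continuity correction.
#'
#' @param x,y numeric vectors, each of length >= 2
#' @return list(statistic = W, p_value)
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs >= 2 observations")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  p <- wt$p.value
  # degenerate case: every pooled value tied -> zero-variance normal
  # approximation; the null is symmetric, so p = 1
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = min(1, p))
}

#' Mean log2 fold change of group B over group A
#'
#' mean(log2(B + 1)) - mean(log2(A + 1)) on normalized counts; the +1
#' pseudocount keeps zeros defined.
#'
#' @param a,b numeric vectors of normalized counts
#' @return log2 fold change (positive when B is higher)
#' @export
log_fold_change <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  mean(log2(b + 1)) - mean(log2(a + 1))
}

#' Benjamini-Hochberg adjustment
#'
#' @param p numeric vector of p-values in [0,1]
#' @return adjusted p-values, order preserved
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression between two grade groups
#'
#' Wilcoxon rank-sum p and mean-log2 fold change per gene within one
#' compartment; BH adjustment across genes; a gene is significant when
#' |logFC| > lfc_thr and p < p_thr.
#'
#' @param normalized genes x AOIs normalized matrix
#' @param annotations annotations for (at least) the matrix AOIs
#' @param compartment one of EP/MA/ST
#' @param grade_a,grade_b the two grades compared; logFC is reported in
#'   the direction of `grade_b`
#' @param cfg pipeline config
#' @return data.frame (gene, logFC, p_value, adjusted_p, significant),
#'   genes in matrix order
#' @export
differential_expression <- function(normalized, annotations, compartment,
                                    grade_a, grade_b,
                                    cfg = default_config()) {
  ann <- annotations[match(colnames(normalized), annotations$aoi_id), ]
  sel <- ann$compartment == compartment
  ga <- which(sel & ann$grade == grade_a)
  gb <- which(sel & ann$grade == grade_b)
  if (length(ga) < 2 || length(gb) < 2) {
    stop(sprintf("need >= 2 AOIs per group in %s (%s: %d, %s: %d)",
                 compartment, grade_a, length(ga), grade_b, length(gb)))
  }
  res <- t(apply(normalized, 1, function(v) {
    w <- wilcoxon_rank_sum(v[ga], v[gb])
    c(logFC = log_fold_change(v[ga], v[gb]), p_value = w$p_value)
  }))
  out <- data.frame(gene = rownames(normalized), res,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- abs(out$logFC) > cfg$lfc_thr & out$p_value < cfg$p_thr
  out
}

#' Classify one gene's grade trend from its three pairwise comparisons
#'
#' A gene is eligible when p < pattern_p_thr (default .1) in at least
#' two of the three comparisons (well-moderate, moderate-poor,
#' well-poor). Among eligible genes the signs of the two adjacent-grade
#' logFCs assign the label: (+,+) P1 progressive up, (-,-) P2
#' progressive down, (+,-) P3 moderately peaked, (-,+) P4 moderately
#' troughed. For P1/P2 the long-span well-poor comparison acts as a
#' consistency veto: when its own p < threshold its sign must match the
#' shared adjacent sign. A zero adjacent logFC leaves the gene
#' UNCLASSIFIED.
#'
#' @param lfc_wm,lfc_mp,lfc_wp log2 fold changes well->moderate,
#'   moderate->poor, well->poor
#' @param p_wm,p_mp,p_wp the matching p-values
#' @param cfg pipeline config (`pattern_p_thr`)
#' @return one of "P1","P2","P3","P4","UNCLASSIFIED"
#' @export
classify_pattern <- function(lfc_wm, lfc_mp, lfc_wp, p_wm, p_mp, p_wp,
                             cfg = default_config()) {
  stopifnot(!anyNA(c(lfc_wm, lfc_mp, lfc_wp, p_wm, p_mp, p_wp)))
  thr <- cfg$pattern_p_thr
  if (sum(c(p_wm, p_mp, p_wp) < thr) < 2) return("UNCLASSIFIED")
  if (lfc_wm == 0 || lfc_mp == 0) return("UNCLASSIFIED")
  s_wm <- sign(lfc_wm); s_mp <- sign(lfc_mp)
  label <- if (s_wm > 0 && s_mp > 0) "P1"
    else if (s_wm < 0 && s_mp < 0) "P2"
    else if (s_wm > 0 && s_mp < 0) "P3"
    else "P4"
  if (label %in% c("P1", "P2") && p_wp < thr && sign(lfc_wp) != s_wm) {
    return("UNCLASSIFIED")
  }
  label
}

#' Grade-trend pattern analysis for every gene in a compartment
#'
#' Runs the three pairwise Wilcoxon/logFC comparisons (well-moderate,
#' moderate-poor, well-poor) within one compartment and applies
#' [classify_pattern()] per gene. With `cfg$pattern_adjust` the
#' eligibility rule uses BH-adjusted p-values instead of raw ones.
#'
#' @param normalized genes x AOIs normalized matrix
#' @param annotations matching annotations
#' @param compartment one of EP/MA/ST
#' @param cfg pipeline config
#' @return data.frame per gene: the three logFCs and p-values, n_valid
#'   (pairwise p < threshold count) and pattern label
#' @export
pattern_analysis <- function(normalized, annotations, compartment,
                             cfg = default_config()) {
  pairs <- list(wm = c("well", "moderate"),
                mp = c("moderate", "poor"),
                wp = c("well", "poor"))
  de <- lapply(pairs, function(p) {
    differential_expression(normalized, annotations, compartment,
                            p[1], p[2], cfg)
  })
  pm <- if (isTRUE(cfg$pattern_adjust)) {
    cbind(de$wm$adjusted_p, de$mp$adjusted_p, de$wp$adjusted_p)
  } else {
    cbind(de$wm$p_value, de$mp$p_value, de$wp$p_value)
  }
  out <- data.frame(
    gene = de$wm$gene,
    logFC_wm = de$wm$logFC, logFC_mp = de$mp$logFC, logFC_wp = de$wp$logFC,
    p_wm = pm[, 1], p_mp = pm[, 2], p_wp = pm[, 3],
    stringsAsFactors = FALSE)
  out$n_valid <- rowSums(pm < cfg$pattern_p_thr)
  out$pattern <- vapply(seq_len(nrow(out)), function(i) {
    classify_pattern(out$logFC_wm[i], out$logFC_mp[i], out$logFC_wp[i],
                     out$p_wm[i], out$p_mp[i], out$p_wp[i], cfg)
  }, "")
  out
}
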