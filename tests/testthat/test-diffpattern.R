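# Wilcoxon rank-sum engine, log fold changes, BH adjustment, and the
# four-pattern grade-trend classifier.

test_that("exact Wilcoxon p-values match enumeration on canonical cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(5, 1, 9), c(5, 1, 9))$p_value, 1)
  expect_error(wilcoxon_rank_sum(1, 2:4), ">= 2")
})

test_that("exact Wilcoxon p equals full-enumeration oracle for small groups", {
  set.seed(8)
  for (m in 2:6) for (n in 2:6) {
    x <- sample(100, m)
    y <- sample(100, n) + 0.5   # tie-free against x
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_enum_p(x, y),
                 tolerance = 1e-12,
                 label = sprintf("m=%d n=%d", m, n))
  }
})

test_that("log fold change is the mean log2 difference with +1 offset", {
  a <- c(1000, 2000, 4000)
  expect_equal(log_fold_change(a, 2 * a), 1, tolerance = 1e-2)
  expect_equal(log_fold_change(a, a), 0)
  expect_equal(log_fold_change(c(0, 0), c(1, 1)), 1)
  expect_error(log_fold_change(numeric(0), 1:3), "empty")
})

test_that("group-role antisymmetry: swapping groups negates logFC, keeps p", {
  set.seed(3)
  for (i in 1:10) {
    x <- rlnorm(6, 3, 1)
    y <- rlnorm(5, 3.5, 1)
    ab <- list(lfc = log_fold_change(x, y), p = wilcoxon_rank_sum(x, y)$p_value)
    ba <- list(lfc = log_fold_change(y, x), p = wilcoxon_rank_sum(y, x)$p_value)
    expect_equal(ab$lfc, -ba$lfc)
    expect_equal(ab$p, ba$p)
  }
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("pattern labels follow the printed sign rules", {
  cfg <- default_config()
  expect_equal(classify_pattern(1.2, 0.8, 2.0, .01, .03, .001, cfg), "P1")
  expect_equal(classify_pattern(1.0, -0.9, 0.1, .02, .04, .5, cfg), "P3")
  expect_equal(classify_pattern(-0.5, 0.7, 0.1, .05, .08, .5, cfg), "P4")
  expect_equal(classify_pattern(-1.0, -0.5, -1.5, .01, .05, .01, cfg), "P2")
  # fewer than two pairwise p < .1: not eligible
  expect_equal(classify_pattern(1.2, 0.8, 2.0, .2, .15, .11, cfg),
               "UNCLASSIFIED")
  # long-span veto: adjacent signs say up, significant well-poor says down
  expect_equal(classify_pattern(1.0, 0.5, -2.0, .01, .02, .01, cfg),
               "UNCLASSIFIED")
  # zero adjacent logFC
  expect_equal(classify_pattern(0, 0.5, 0.5, .01, .02, .03, cfg),
               "UNCLASSIFIED")
})

test_that("eligible genes with nonzero adjacent logFCs get exactly one of 4 labels", {
  cfg <- default_config()
  set.seed(14)
  for (i in 1:200) {
    lfc <- stats::runif(3, -2, 2)
    p <- stats::runif(3, 0, 0.09)   # all comparisons eligible
    # suppress the veto by making the long-span sign consistent
    lfc[3] <- sign(lfc[1]) * abs(lfc[3])
    lab <- classify_pattern(lfc[1], lfc[2], lfc[3], p[1], p[2], p[3], cfg)
    expect_true(lab %in% c("P1", "P2", "P3", "P4"))
    expected <- if (lfc[1] > 0 && lfc[2] > 0) "P1"
      else if (lfc[1] < 0 && lfc[2] < 0) "P2"
      else if (lfc[1] > 0) "P3" else "P4"
    expect_equal(lab, expected)
  }
})

test_that("differential expression recovers planted up-regulated genes", {
  coh <- balanced_cohort()
  qc <- qc_normalize(coh$counts, coh$annotations, coh$negprobes,
                     coh$truth$marker_sets$EP)
  de <- differential_expression(qc$normalized, qc$annotations, "EP",
                                "well", "poor")
  classes <- coh$truth$gene_class
  p1 <- classes$gene[classes$class == "pattern1_up"]
  recall <- mean(de$significant[de$gene %in% p1] & de$logFC[de$gene %in% p1] > 0)
  expect_gte(recall, 0.8)

  expect_error(differential_expression(qc$normalized, qc$annotations, "EP",
                                       "well", "unknown"),
               "EP")
})

test_that("permuting grade labels removes the planted signal", {
  coh <- balanced_cohort()
  qc <- qc_normalize(coh$counts, coh$annotations, coh$negprobes,
                     coh$truth$marker_sets$EP)
  ann <- qc$annotations
  set.seed(77)
  perm <- ann
  ep <- perm$compartment == "EP"
  perm$grade[ep] <- sample(perm$grade[ep])
  de_perm <- differential_expression(qc$normalized, perm, "EP",
                                     "well", "poor")
  de_true <- differential_expression(qc$normalized, ann, "EP",
                                     "well", "poor")
  expect_lt(sum(de_perm$significant), sum(de_true$significant) / 2)
  expect_lt(mean(de_perm$p_value < 0.05), 0.15)
})

test_that("pattern analysis recovers the planted trend classes", {
  coh <- balanced_cohort()
  qc <- qc_normalize(coh$counts, coh$annotations, coh$negprobes,
                     coh$truth$marker_sets$EP)
  pat <- pattern_analysis(qc$normalized, qc$annotations, "EP")
  tab <- merge(pat, coh$truth$gene_class, by = "gene")
  acc <- function(cls, lab) {
    mean(tab$pattern[tab$class == cls] == lab)
  }
  expect_gte(acc("pattern1_up", "P1"), 0.9)
  expect_gte(acc("pattern2_down", "P2"), 0.9)
  expect_gte(acc("pattern3_peak", "P3"), 0.8)
  expect_gte(acc("pattern4_trough", "P4"), 0.8)
  # false-pattern rate among nulls at the p < .1 eligibility rule
  expect_lte(mean(tab$pattern[tab$class == "null"] != "UNCLASSIFIED"), 0.1)
  # classifier never labels without two valid comparisons
  expect_true(all(tab$n_valid[tab$pattern != "UNCLASSIFIED"] >= 2))
})
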