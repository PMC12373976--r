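# ROI-level EP/MA pairing and cross-compartment correlation.

pair_ann <- function() {
  data.frame(
    aoi_id = c("R1-EP", "R1-MA", "R2-EP", "R3-EP", "R3-MA1", "R3-MA2"),
    roi_id = c("R1", "R1", "R2", "R3", "R3", "R3"),
    patient_id = "P1",
    compartment = c("EP", "MA", "EP", "EP", "MA", "MA"),
    grade = c("well", "well", "poor", "moderate", "moderate", "moderate"),
    stringsAsFactors = FALSE)
}

test_that("pairing keeps ROIs with both compartments and pools duplicates", {
  pairs <- pair_compartments(pair_ann())
  expect_equal(nrow(pairs), 2)            # R2 lacks MA
  expect_setequal(pairs$roi_id, c("R1", "R3"))
  expect_equal(pairs$ma_aois[pairs$roi_id == "R3"], "R3-MA1;R3-MA2")
})

test_that("set mean expression averages on the log2 scale", {
  m <- matrix(c(4, 16, 4, 16, 10, 20), nrow = 2,
              dimnames = list(c("g1", "g2"), c("A1", "A2", "A3")))
  # singleton set: the gene's own log expression
  expect_equal(set_mean_expression(m, "g1", "A1"), log2(5))
  # {4,16}: mean of log2(5) and log2(17)
  expect_equal(set_mean_expression(m, c("g1", "g2"), "A1"),
               mean(c(log2(5), log2(17))))
  # two AOIs averaged per gene before set averaging
  expect_equal(set_mean_expression(m, "g1", c("A1", "A2")), log2(5))
  expect_error(set_mean_expression(m, "zz", "A1"), "no members")
})

test_that("Spearman correlation handles canonical and enumerated cases", {
  x <- c(3, 1, 4, 1.5, 5)
  expect_equal(correlate(x, x)$rho, 1)
  expect_equal(correlate(x, -x)$rho, -1)

  r <- correlate(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 0.8)
  # independent oracle: cor.test's exact Spearman null (tie-free)
  ct <- stats::cor.test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4),
                        method = "spearman")
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-12)

  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("exact permutation p matches cor.test for tie-free n <= 9", {
  set.seed(4)
  for (n in c(4, 5, 6, 7)) {
    for (i in 1:5) {
      x <- sample(100, n)
      y <- sample(100, n)
      ours <- correlate(x, y)
      ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
      expect_equal(ours$rho, unname(ct$estimate))
      expect_equal(ours$p_value, ct$p.value, tolerance = 1e-12,
                   label = sprintf("n=%d i=%d", n, i))
    }
  }
})

test_that("Spearman rho equals Pearson on midranks under ties", {
  set.seed(19)
  for (i in 1:20) {
    x <- sample(5, 12, replace = TRUE)
    y <- sample(5, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(correlate(x, y)$rho, stats::cor(rank(x), rank(y)))
  }
})

test_that("paired correlation finds a planted shared latent factor", {
  set.seed(30)
  hits <- vapply(1:20, function(i) {
    n_roi <- 20
    latent <- stats::rnorm(n_roi)
    genes <- c("c1", "c2", "e1", "e2", sprintf("f%02d", 1:30))
    mk <- function(comp) {
      m <- matrix(stats::rlnorm(length(genes) * n_roi, 3, 0.3),
                  nrow = length(genes),
                  dimnames = list(genes, sprintf("R%02d-%s", 1:n_roi, comp)))
      loaded <- if (comp == "EP") c("c1", "c2") else c("e1", "e2")
      m[loaded, ] <- m[loaded, ] * 2^rep(latent, each = 2)
      m
    }
    norm <- cbind(mk("EP"), mk("MA"))
    ann <- data.frame(aoi_id = colnames(norm),
                      roi_id = rep(sprintf("R%02d", 1:n_roi), 2),
                      patient_id = "P1",
                      compartment = rep(c("EP", "MA"), each = n_roi),
                      grade = "well", stringsAsFactors = FALSE)
    pairs <- pair_compartments(ann)
    res <- paired_correlation(pairs, norm, c("c1", "c2"), c("e1", "e2"))
    res$rho > 0 && res$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("paired correlation is invariant to annotation row order", {
  coh <- designed_cohort()
  qc <- designed_qc()
  sets <- coh$truth$signature_sets
  p1 <- pair_compartments(qc$annotations)
  set.seed(51)
  shuffled <- qc$annotations[sample(nrow(qc$annotations)), ]
  p2 <- pair_compartments(shuffled)
  r1 <- paired_correlation(p1, qc$normalized, sets$complement_activation,
                           sets$ecm_remodelling)
  r2 <- paired_correlation(p2, qc$normalized, sets$complement_activation,
                           sets$ecm_remodelling)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("duplicating every pair leaves rho unchanged", {
  set.seed(2)
  n <- 10
  x <- stats::rnorm(n); y <- x + stats::rnorm(n)
  rho1 <- correlate(x, y)$rho
  rho2 <- correlate(c(x, x), c(y, y))$rho
  expect_equal(rho1, rho2, tolerance = 1e-12)
})
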