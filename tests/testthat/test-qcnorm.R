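# Technical QC cascade, detection floors, Q3 normalization and
# contamination filtering.

toy_ann <- function(alignment, ntc, nuclei) {
  data.frame(aoi_id = sprintf("A%d", seq_along(alignment)),
             roi_id = "R1", patient_id = "P1", compartment = "EP",
             grade = "well", nuclei = nuclei, alignment_rate = alignment,
             ntc_count = ntc, stringsAsFactors = FALSE)
}

test_that("technical QC applies strict inequalities on the failing side", {
  rep1 <- technical_qc(toy_ann(0.85, 1001, 150))
  expect_false(rep1$pass)
  expect_equal(rep1$reasons, "HIGH_NTC")

  # boundary values pass: 0.80 alignment, NTC 0, exactly 100 nuclei
  rep2 <- technical_qc(toy_ann(0.80, 0, 100))
  expect_true(rep2$pass)

  rep3 <- technical_qc(toy_ann(0.5, 2000, 10))
  expect_equal(rep3$reasons, "LOW_ALIGNMENT;HIGH_NTC;LOW_NUCLEI")

  bad <- toy_ann(0.9, 10, 200)
  bad$nuclei <- NA
  expect_error(technical_qc(bad), "A1")
})

test_that("detection floor is the max of 4 and the negative-probe geometric mean", {
  zeros <- matrix(0, nrow = 10, ncol = 2,
                  dimnames = list(NULL, c("A1", "A2")))
  expect_equal(unname(detection_background(zeros)), c(4, 4))

  eights <- matrix(8, nrow = 10, ncol = 1, dimnames = list(NULL, "A1"))
  expect_equal(unname(detection_background(eights)), 8)

  counts <- matrix(c(3, 10), nrow = 2, dimnames = list(c("G1", "G2"), "A1"))
  det <- detected_matrix(counts, c(A1 = 4))
  expect_false(det["G1", "A1"])
  expect_true(det["G2", "A1"])

  expect_error(detection_background(zeros, c("A1", "A9")), "A9")
})

test_that("gene retention fraction is inclusive at the boundary", {
  counts <- matrix(0, nrow = 3, ncol = 10,
                   dimnames = list(c("never", "once", "always"),
                                   sprintf("A%d", 1:10)))
  counts["once", 1] <- 10
  counts["always", ] <- 10
  floors <- stats::setNames(rep(4, 10), colnames(counts))
  kept <- filter_undetected_genes(counts, floors)
  expect_setequal(rownames(kept), c("once", "always"))
})

test_that("Q3 normalization equalizes the 75th percentile", {
  a <- 1:100
  m <- cbind(A = a, B = 2 * a)
  rownames(m) <- sprintf("G%03d", 1:100)
  expect_equal(unname(stats::quantile(m[, "A"], 0.75)), 75.25)
  expect_equal(unname(stats::quantile(m[, "B"], 0.75)), 150.5)
  norm <- q3_normalize(m)
  q3 <- apply(norm$normalized, 2, stats::quantile, 0.75)
  expect_equal(unname(diff(q3)), 0, tolerance = 1e-9)

  # identical AOIs: both scale factors are 1
  norm2 <- q3_normalize(cbind(A = a, B = a))
  expect_equal(norm2$factors$scale, c(1, 1))

  # single AOI: geometric mean of one Q3 over itself
  norm1 <- q3_normalize(cbind(A = a))
  expect_equal(norm1$factors$scale, 1)

  expect_error(q3_normalize(cbind(A = a, B = rep(0, 100))), "QC")
})

test_that("normalization is invariant to rescaling one AOI", {
  coh <- designed_cohort()
  counts <- coh$counts[1:300, 1:8]
  r1 <- q3_normalize(counts)
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 7
  r2 <- q3_normalize(scaled)
  # rescaling one AOI only shifts the geometric-mean reference; after
  # removing that shift the normalized matrices coincide
  expect_equal(r2$normalized * (r1$reference / r2$reference),
               r1$normalized, tolerance = 1e-9)
})

test_that("technical QC is idempotent on a filtered cohort", {
  coh <- designed_cohort()
  rep1 <- technical_qc(coh$annotations)
  kept <- coh$annotations[rep1$pass, ]
  rep2 <- technical_qc(kept)
  expect_true(all(rep2$pass))
})

test_that("epithelial scores separate compartments and flag mixtures", {
  coh <- designed_cohort()
  qc <- designed_qc()
  scores <- qc$scores
  lam <- coh$truth$contamination$lambda[
    match(scores$aoi_id, coh$truth$contamination$aoi_id)]
  ep <- scores$score[scores$compartment == "EP"]
  st <- scores$score[scores$compartment == "ST" & lam == 0]
  expect_gt(min(ep), max(st))

  contam <- scores$score[lam > 0]
  expect_true(all(contam > 0.05))

  # degenerate constant matrix: scores defined as 0
  const <- matrix(5, nrow = 10, ncol = 3,
                  dimnames = list(sprintf("G%d", 1:10), c("A", "B", "C")))
  sc <- epithelial_score(const, c("G1", "G2", "G3"))
  expect_true(all(sc$score == 0))

  expect_error(epithelial_score(const, c("G1", "G2")), ">= 3")
})

test_that("contamination filter is strict and exempts EP AOIs", {
  ann <- data.frame(aoi_id = c("A1", "A2", "A3"),
                    compartment = c("MA", "MA", "EP"),
                    stringsAsFactors = FALSE)
  scores <- data.frame(aoi_id = c("A1", "A2", "A3"),
                       raw_es = 0, score = c(0.06, 0.05, 0.9))
  out <- filter_contaminated(scores, ann)
  expect_equal(out$contaminated, c(TRUE, FALSE, FALSE))
})

test_that("the designed fixture loses exactly the planted AOIs", {
  coh <- designed_cohort()
  qc <- designed_qc()
  report <- qc$qc
  smry <- attr(technical_qc(coh$annotations), "summary")
  expect_equal(unname(smry),
               c(1, 2, 3))  # LOW_ALIGNMENT, HIGH_NTC, LOW_NUCLEI
  planted_bad <- c(unlist(coh$truth$qc_violation_aois, use.names = FALSE),
                   coh$truth$contamination$aoi_id[
                     coh$truth$contamination$lambda > 0])
  expect_setequal(report$aoi_id[!report$pass], planted_bad)
})
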