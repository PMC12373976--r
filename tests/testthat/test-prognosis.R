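# Signature assembly, Cox solver, risk stratification, survival
# estimators and AUC.

test_that("the bundled pathway GMT assembles to 17 unique genes", {
  sets <- read_gmt(signature17_path())
  genes <- assemble_signature(sets)
  expect_length(genes, 17)
  expect_false(anyDuplicated(genes) > 0)

  toy <- list(complement_activation = c("A", "B"),
              ecm_remodelling = c("B", "C"),
              humoural_immune_response = c("D"))
  expect_equal(assemble_signature(toy), c("A", "B", "C", "D"))
  expect_error(assemble_signature(toy[1:2]), "missing pathway")
})

test_that("the Newton Cox solver maximizes the Breslow partial likelihood", {
  # single binary covariate toy (alternating groups, so the partial
  # likelihood has an interior maximum): oracle by 1-d maximization
  expr <- matrix(c(1, 0, 1, 0), nrow = 1,
                 dimnames = list("g", paste0("P", 1:4)))
  surv <- data.frame(patient_id = paste0("P", 1:4),
                     time = c(1, 2, 3, 4), event = 1)
  lpl <- function(b) {
    2 * b - log(2 * exp(b) + 2) - log(exp(b) + 2) - log(exp(b) + 1)
  }
  oracle <- stats::optimize(lpl, c(-5, 5), maximum = TRUE)$maximum
  fit <- cox_fit(expr, surv)
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-4)
  # monotone likelihood ascent and a stationary endpoint
  expect_true(all(diff(fit$lpl_trace) >= -1e-12))
  expect_lt(fit$grad_norm, 1e-6)
})

test_that("the Cox solver agrees with an independent implementation", {
  set.seed(41)
  n <- 60
  x <- matrix(stats::rnorm(3 * n), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), sprintf("P%02d", 1:n)))
  lp <- 0.8 * x[1, ] - 0.5 * x[2, ]
  t_event <- stats::rexp(n, rate = 0.05 * exp(lp))
  t_cens <- stats::runif(n, 0, 30)
  surv <- data.frame(patient_id = colnames(x),
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens))
  fit <- cox_fit(x, surv)
  df <- data.frame(time = surv$time, event = surv$event, t(x))
  ref <- survival::coxph(survival::Surv(time, event) ~ g1 + g2 + g3,
                         data = df, ties = "breslow")
  expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-6)

  expect_error(cox_fit(x, transform(surv, event = 0)), "no events")
})

test_that("a planted log-hazard of 0.7 is recovered at n = 200", {
  set.seed(52)
  n <- 200
  x <- matrix(stats::rnorm(n), nrow = 1,
              dimnames = list("score", sprintf("P%03d", 1:n)))
  t_event <- stats::rexp(n, rate = 0.05 * exp(0.7 * x[1, ]))
  t_cens <- stats::runif(n, 0, 40)
  surv <- data.frame(patient_id = colnames(x),
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens))
  fit <- cox_fit(x, surv)
  expect_lt(abs(unname(fit$beta) - 0.7), 0.15)
})

test_that("risk scores are the linear predictor", {
  expr <- matrix(c(1, 2, 3, 4), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("Pa", "Pb")))
  model <- list(genes = c("g1", "g2"), beta = c(g1 = 0.5, g2 = -1))
  expect_equal(unname(risk_scores(model, expr)),
               c(0.5 * 1 - 1 * 2, 0.5 * 3 - 1 * 4))
  expect_equal(unname(risk_scores(list(genes = "g1", beta = c(g1 = 0)),
                                  expr)), c(0, 0))
  expect_error(risk_scores(list(genes = "gX", beta = 1), expr), "gX")
})

test_that("median stratification sends ties and the median itself to low", {
  expect_equal(unname(stratify_median(c(1, 2, 3, 4)) == "high"),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(stratify_median(c(1, 2, 3)) == "high"),
               c(FALSE, FALSE, TRUE))
  expect_warning(g <- stratify_median(c(2, 2, 2)), "all scores equal")
  expect_true(all(g == "low"))
})

test_that("Kaplan-Meier product-limit values match hand computation", {
  s <- km_estimator(data.frame(time = c(1, 2, 3), event = 1))
  expect_equal(s$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(s$median, 2)

  s2 <- km_estimator(data.frame(time = c(5, 8), event = c(1, 0)))
  expect_equal(s2$surv[s2$time == 5], 0.5)
  expect_equal(s2$median, 5)

  cens <- km_estimator(data.frame(time = c(3, 6, 9), event = 0))
  expect_true(all(cens$surv == 1))
  expect_true(is.na(cens$median))
  expect_error(km_estimator(data.frame(time = numeric(0),
                                       event = numeric(0))), "empty")
})

test_that("log-rank statistic matches the hand-worked 4-subject table", {
  surv <- data.frame(time = c(1, 3, 2, 4), event = 1)
  groups <- c("A", "A", "B", "B")
  res <- logrank_test(groups, surv)
  expect_equal(res$statistic, 8 / 13, tolerance = 1e-9)
  expect_equal(res$p_value,
               stats::pchisq(8 / 13, 1, lower.tail = FALSE))

  # identical groups: no separation
  surv2 <- data.frame(time = c(1, 2, 1, 2), event = 1)
  res2 <- logrank_test(c("A", "A", "B", "B"), surv2)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1)

  expect_error(logrank_test(c("A", "A", "A", "A"), surv), "2 non-empty")
})

test_that("reverse KM median follow-up treats censoring as the event", {
  all_cens <- data.frame(time = rep(10, 4), event = 0)
  expect_equal(reverse_km_median_followup(all_cens)$median_followup, 10)

  all_events <- data.frame(time = 1:4, event = 1)
  rf <- reverse_km_median_followup(all_events)
  expect_false(rf$defined)
  expect_true(is.na(rf$median_followup))

  mixed <- data.frame(time = c(2, 4, 6, 8), event = c(1, 0, 1, 0))
  expect_equal(reverse_km_median_followup(mixed)$median_followup, 8)

  # with no censoring the forward curve is the empirical survival
  fwd <- km_estimator(all_events)
  expect_equal(fwd$surv, c(3, 2, 1, 0) / 4)
})

test_that("Mann-Whitney AUC equals brute-force pair counting", {
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_mann_whitney(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)

  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    scores <- sample(10, n, replace = TRUE)   # plenty of ties
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_mann_whitney(scores, labels),
                 auc_enum(scores, labels))
  }
  expect_error(auc_mann_whitney(1:4, rep(1, 4)), "both classes")
})

test_that("the composite risk model separates planted risk groups", {
  coh <- designed_cohort()
  qc <- designed_qc()
  res <- risk_model_pipeline(qc$normalized, qc$annotations, coh$survival)
  expect_length(res$model$genes, 17)
  expect_true(all(diff(res$model$lpl_trace) >= -1e-12))
  expect_gte(res$auc, 0.8)
  # fitted risk scores track the planted patient risk in direction;
  # at 11 patients the ridge-penalized betas are noisy, so only a
  # moderate positive correlation is guaranteed
  planted <- coh$truth$patient_risk[names(res$scores)]
  expect_gt(cor(res$scores, planted), 0.3)
})
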