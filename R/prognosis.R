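# Composite pathway signature assembly, Cox-derived risk scores, median
# stratification, Kaplan-Meier / log-rank / reverse-KM follow-up, and
# Mann-Whitney AUC.

#' Assemble the composite pathway signature
#'
#' Union of the members of the three pathway sets (complement
#' activation, ECM remodelling, humoural immune response),
#' deduplicated and sorted. The shipped fixture
#' `inst/extdata/signature17.gmt` carries the printed 17-gene
#' membership.
#'
#' @param collection named list of gene sets containing the three
#'   pathway sets
#' @param set_names the three set names to combine
#' @return sorted character vector of unique signature genes
#' @export
assemble_signature <- function(collection,
                               set_names = c("complement_activation",
                                             "ecm_remodelling",
                                             "humoural_immune_response")) {
  missing <- setdiff(set_names, names(collection))
  if (length(missing) > 0) {
    stop("missing pathway set(s): ", paste(missing, collapse = ", "))
  }
  sort(unique(unlist(collection[set_names], use.names = FALSE)))
}

#' Path to the bundled 17-gene signature GMT
#' @return file path
#' @export
signature17_path <- function() {
  system.file("extdata", "signature17.gmt", package = "dspgrade",
              mustWork = TRUE)
}

#' Patient-level expression of selected genes
#'
#' Mean of log2(normalized + 1) over each patient's retained AOIs of
#' the requested compartments (default EP + MA).
#'
#' @param normalized genes x AOIs matrix
#' @param annotations matching annotations
#' @param genes genes to aggregate (must all be present)
#' @param compartments compartments whose AOIs enter the mean
#' @return genes x patients matrix
#' @export
patient_expression <- function(normalized, annotations, genes,
                               compartments = c("EP", "MA")) {
  missing <- setdiff(genes, rownames(normalized))
  if (length(missing) > 0) {
    stop("genes missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  ann <- annotations[match(colnames(normalized), annotations$aoi_id), ]
  keep <- ann$compartment %in% compartments
  patients <- unique(ann$patient_id[keep])
  lg <- log2(normalized[genes, , drop = FALSE] + 1)
  out <- vapply(patients, function(p) {
    rowMeans(lg[, keep & ann$patient_id == p, drop = FALSE])
  }, numeric(length(genes)))
  matrix(out, nrow = length(genes), dimnames = list(genes, patients))
}

# Breslow-ties log partial likelihood, gradient and Hessian.
cox_lpl <- function(beta, x, time, event, ridge = 0) {
  eta <- as.vector(x %*% beta)
  ord <- order(-time)                       # decreasing time
  xo <- x[ord, , drop = FALSE]
  eo <- exp(eta[ord])
  to <- time[ord]
  do_ <- event[ord]
  p <- ncol(x)
  lpl <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  s0 <- 0; s1 <- numeric(p); s2 <- matrix(0, p, p)
  i <- 1
  n <- length(to)
  while (i <= n) {
    # add all subjects with this time to the risk set
    j <- i
    while (j <= n && to[j] == to[i]) j <- j + 1
    idx <- i:(j - 1)
    for (k in idx) {
      s0 <- s0 + eo[k]
      s1 <- s1 + eo[k] * xo[k, ]
      s2 <- s2 + eo[k] * tcrossprod(xo[k, ])
    }
    ev <- idx[do_[idx] == 1]
    d <- length(ev)
    if (d > 0) {
      sx <- colSums(xo[ev, , drop = FALSE])
      lpl <- lpl + sum(eta[ord][ev]) - d * log(s0)
      mu <- s1 / s0
      grad <- grad + sx - d * mu
      hess <- hess + d * (s2 / s0 - tcrossprod(mu))
    }
    i <- j
  }
  if (ridge > 0) {
    lpl <- lpl - 0.5 * ridge * sum(beta^2)
    grad <- grad - ridge * beta
    hess <- hess + diag(ridge, p)
  }
  list(lpl = lpl, grad = grad, hess = hess)
}

#' Fit a Cox proportional hazards model by Newton-Raphson
#'
#' Maximizes the Breslow-ties log partial likelihood with step-halving;
#' converges when the largest Newton step falls below `tol` or after
#' `max_iter` iterations. An optional L2 (ridge) penalty stabilizes
#' separated or collinear designs. The log partial likelihood is
#' non-decreasing across iterations by construction.
#'
#' @param expr genes x patients expression matrix (covariates)
#' @param survival data.frame (patient_id, time, event)
#' @param ridge L2 penalty (default 0)
#' @param max_iter,tol Newton controls
#' @return `risk_model` list: genes, beta, risk scores, median cutoff,
#'   iterations, log partial likelihood trace, final gradient norm,
#'   hazard ratios exp(beta)
#' @export
cox_fit <- function(expr, survival, ridge = 0, max_iter = 50, tol = 1e-8) {
  patients <- intersect(colnames(expr), survival$patient_id)
  if (length(patients) < 2) stop("need >= 2 patients with expression and outcome")
  surv <- survival[match(patients, survival$patient_id), ]
  if (sum(surv$event) == 0) stop("no events in survival table")
  x <- t(expr[, patients, drop = FALSE])
  x <- scale(x, center = TRUE, scale = FALSE)   # centring leaves betas unchanged
  p <- ncol(x)
  beta <- numeric(p)
  cur <- cox_lpl(beta, x, surv$time, surv$event, ridge)
  trace <- cur$lpl
  iter <- 0
  repeat {
    iter <- iter + 1
    step <- tryCatch(solve(cur$hess, cur$grad), error = function(e) {
      solve(cur$hess + diag(1e-8, p), cur$grad)
    })
    halve <- 0
    repeat {
      cand <- beta + step
      nxt <- cox_lpl(cand, x, surv$time, surv$event, ridge)
      if (is.finite(nxt$lpl) && nxt$lpl >= cur$lpl - 1e-12) break
      step <- step / 2
      halve <- halve + 1
      if (halve > 30) stop("cox_fit did not converge: step-halving failed at iteration ",
                           iter, " (lpl = ", cur$lpl, ")")
    }
    beta <- cand
    cur <- nxt
    trace <- c(trace, cur$lpl)
    if (max(abs(step)) < tol || iter >= max_iter) break
  }
  if (iter >= max_iter && max(abs(step)) >= tol) {
    stop("cox_fit did not converge in ", max_iter,
         " iterations (last step ", max(abs(step)), ")")
  }
  beta <- stats::setNames(as.vector(beta), rownames(expr))
  scores <- risk_scores(list(genes = names(beta), beta = beta), expr)
  model <- list(genes = names(beta), beta = beta,
                hazard_ratio = exp(beta),
                scores = scores, cutoff = stats::median(scores),
                iterations = iter, lpl_trace = trace,
                grad_norm = max(abs(cur$grad)))
  class(model) <- "risk_model"
  model
}

#' Linear-predictor risk scores
#'
#' score(patient) = sum_g beta_g * expr_g, no baseline term.
#'
#' @param model list with `genes` and `beta`
#' @param expr genes x patients matrix
#' @return named numeric vector of per-patient scores
#' @export
risk_scores <- function(model, expr) {
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing) > 0) {
    stop("genes missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  as.vector(t(expr[model$genes, , drop = FALSE]) %*% model$beta) |>
    stats::setNames(colnames(expr))
}

#' Median-split risk stratification
#'
#' Scores strictly above the median are "high", the rest "low" (ties,
#' including the odd-n median sample itself, go to low).
#'
#' @param scores named numeric vector, length >= 2
#' @return factor of "high"/"low" labels
#' @export
stratify_median <- function(scores) {
  stopifnot(length(scores) >= 2)
  med <- stats::median(scores)
  labels <- ifelse(scores > med, "high", "low")
  if (all(labels == "low")) warning("all scores equal: every patient low-risk")
  factor(labels, levels = c("low", "high")) |> stats::setNames(names(scores))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param survival data.frame (time, event)
#' @return `km_curve` list: time, n_risk, n_event, n_censor, surv,
#'   median (first time S(t) <= 0.5, NA when never reached)
#' @export
km_estimator <- function(survival) {
  if (nrow(survival) == 0) stop("empty survival table")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1]] else NA_real_
  out <- list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
              n_censor = fit$n.censor, surv = fit$surv, median = med)
  class(out) <- "km_curve"
  out
}

#' Log-rank test between two groups
#'
#' @param groups two-level factor/character vector, aligned with
#'   `survival` rows
#' @param survival data.frame (time, event)
#' @return list(statistic, df, p_value)
#' @export
logrank_test <- function(groups, survival) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2 || any(table(groups) == 0)) {
    stop("need exactly 2 non-empty groups")
  }
  if (sum(survival$event) == 0) stop("no events")
  df <- data.frame(time = survival$time, event = survival$event,
                   group = groups)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(statistic = unname(sd_$chisq), df = 1,
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' K-M with the censoring indicator treated as the event; returns the
#' median of that curve, NA (flagged) when every subject had the event
#' (no censoring information).
#'
#' @param survival data.frame (time, event)
#' @return list(median_followup, defined)
#' @export
reverse_km_median_followup <- function(survival) {
  rev <- data.frame(time = survival$time, event = 1 - survival$event)
  if (sum(rev$event) == 0) {
    return(list(median_followup = NA_real_, defined = FALSE))
  }
  km <- km_estimator(rev)
  list(median_followup = km$median, defined = !is.na(km$median))
}

#' Mann-Whitney AUC of scores against binary labels
#'
#' AUC = (rank-sum U with 0.5 tie credit) / (n1 * n0): the probability
#' that a random positive outscores a random negative.
#'
#' @param scores numeric vector
#' @param labels binary vector (1 = positive class)
#' @return AUC in [0,1]
#' @export
auc_mann_whitney <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Fit the composite-signature risk model end to end
#'
#' Assembles the signature from a pathway collection, aggregates
#' patient-level expression, fits the Cox model, median-stratifies the
#' risk scores, and evaluates K-M separation (log-rank), recurrence AUC
#' and reverse-KM median follow-up.
#'
#' @param normalized genes x AOIs matrix
#' @param annotations matching annotations
#' @param survival patient survival data.frame
#' @param collection pathway gene-set collection (default: the bundled
#'   17-gene signature GMT)
#' @param compartments compartments aggregated per patient
#' @param cfg pipeline config (`cox_ridge`, `cox_max_iter`, `cox_tol`)
#' @return list: model, expr, scores, groups, logrank, auc,
#'   median_followup, km (per-group curves)
#' @export
risk_model_pipeline <- function(normalized, annotations, survival,
                                collection = read_gmt(signature17_path()),
                                compartments = c("EP", "MA"),
                                cfg = default_config()) {
  genes <- assemble_signature(collection)
  genes <- intersect(genes, rownames(normalized))
  if (length(genes) < 2) stop("signature genes absent from the panel")
  expr <- patient_expression(normalized, annotations, genes, compartments)
  patients <- intersect(colnames(expr), survival$patient_id)
  surv <- survival[match(patients, survival$patient_id), ]
  model <- cox_fit(expr[, patients, drop = FALSE], surv,
                   ridge = cfg$cox_ridge, max_iter = cfg$cox_max_iter,
                   tol = cfg$cox_tol)
  scores <- model$scores
  groups <- stratify_median(scores)
  lr <- logrank_test(groups, surv)
  auc <- auc_mann_whitney(scores, surv$event)
  mf <- reverse_km_median_followup(surv)
  km <- lapply(split(surv, groups), km_estimator)
  list(model = model, expr = expr, scores = scores, groups = groups,
       logrank = lr, auc = auc, median_followup = mf, km = km)
}
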