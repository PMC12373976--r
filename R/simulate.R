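# Synthetic cohort generator. Emulates the ROI/AOI/compartment structure
# of segmented DSP data: negative-binomial counts with log-normal AOI
# size factors, compartment marker structure, genes with planted
# grade-monotone/peaked/troughed effects, epithelial contamination of a
# subset of MA/ST AOIs, negative-probe and NTC technical background, and
# recurrence outcomes tied to a planted patient-level risk score.

SIGNATURE_SETS <- list(
  complement_activation   = c("CFB", "IGHA1", "IGHG", "IGHG2", "IGHG4", "IGHM"),
  ecm_remodelling         = c("COL6A2", "MMP1", "SPP1", "TNC", "P3H3"),
  humoural_immune_response = c("BPIFA1", "CXCL1", "CXCL3", "CXCL5", "CXCL8",
                               "DMBT1")
)

#' Simulation configuration
#'
#' Defaults mirror the cohort scale the pipeline is designed for: 11
#' patients with ~5 ROIs each, every ROI segmented into one EP, one MA
#' and one ST AOI, 2000 genes. Grade is assigned per ROI (all of a ROI's
#' AOIs share it) with probabilities matching the observed grade mix
#' (roughly 25/35/40 well/moderate/poor). Counts are negative binomial
#' with a single dispersion (0.1) around a mean built from a log-normal
#' gene baseline, a log-normal AOI library size (sdlog 0.3), a 16-fold
#' (4 log2 units) compartment-marker effect, planted grade effects of 1
#' log2 unit per grade step, and a planted per-patient risk factor
#' loading 0.5 log2 units per unit risk on the 17 composite-signature
#' genes. Survival is exponential with log-hazard 1 per unit risk and
#' uniform administrative censoring.
#'
#' @param n_patients number of patients
#' @param rois_per_patient ROIs sampled per patient
#' @param rois_per_grade optional integer vector (well, moderate, poor);
#'   when given, total ROIs are allocated deterministically by grade and
#'   `grade_probs` is ignored
#' @param grade_probs ROI grade probabilities (well, moderate, poor)
#' @param n_genes total panel size
#' @param class_sizes named integer vector of planted class sizes; the
#'   three signature classes are fixed by their printed member lists
#' @param pattern_effect log2 effect per grade step for pattern genes
#' @param marker_effect log2 enrichment of a marker gene in its own
#'   compartment
#' @param marker_depletion log2 depletion of a marker gene outside its
#'   own compartment (segmentation purifies compartments, so foreign
#'   markers sit well below baseline)
#' @param risk_loading log2 shift per unit patient risk on signature genes
#' @param baseline_meanlog,baseline_sdlog log-normal gene baseline mean
#' @param libsize_sdlog log-normal AOI size factor (meanlog 0)
#' @param dispersion NB dispersion (1/size); 0 gives Poisson counts
#' @param contam_fraction fraction of MA/ST AOIs mixed with the
#'   epithelial profile
#' @param contam_n_ma,contam_n_st exact contaminated AOI counts per
#'   compartment (override the fraction when non-NULL)
#' @param contam_lambda epithelial mixing weight in [0,1]
#' @param qc_violations integer vector (ntc, nuclei, alignment): how many
#'   AOIs are planted to fail each technical QC rule
#' @param n_negative_probes,negprobe_mean negative-probe panel size and
#'   Poisson background mean
#' @param ntc_mean,nuclei_mean NTC and nuclei means for clean AOIs
#' @param baseline_hazard exponential event hazard per month at risk 0
#' @param risk_loghr log hazard ratio per unit planted risk
#' @param max_followup administrative censoring horizon (months)
#' @param seed RNG seed
#' @return config list for [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 11,
                       rois_per_patient = 5,
                       rois_per_grade = NULL,
                       grade_probs = c(well = 0.25, moderate = 0.35,
                                       poor = 0.40),
                       n_genes = 2000,
                       class_sizes = c(pattern1_up = 50, pattern2_down = 50,
                                       pattern3_peak = 40,
                                       pattern4_trough = 40,
                                       epithelial_markers = 20,
                                       macrophage_markers = 20,
                                       stromal_markers = 20),
                       pattern_effect = 1.0,
                       marker_effect = 4.0,
                       marker_depletion = 8.0,
                       risk_loading = 0.5,
                       baseline_meanlog = log(20),
                       baseline_sdlog = 1.0,
                       libsize_sdlog = 0.3,
                       dispersion = 0.1,
                       contam_fraction = 0,
                       contam_n_ma = NULL,
                       contam_n_st = NULL,
                       contam_lambda = 0.6,
                       qc_violations = c(ntc = 0, nuclei = 0, alignment = 0),
                       n_negative_probes = 100,
                       negprobe_mean = 2,
                       ntc_mean = 50,
                       nuclei_mean = 300,
                       baseline_hazard = 0.02,
                       risk_loghr = 1.0,
                       max_followup = 60,
                       seed = 1L) {
  cfg <- as.list(environment())
  n_sig <- sum(lengths(SIGNATURE_SETS))
  if (sum(class_sizes) + n_sig > n_genes) {
    stop("planted class sizes exceed n_genes")
  }
  stopifnot(all(c("ntc", "nuclei", "alignment") %in% names(qc_violations)),
            contam_lambda >= 0, contam_lambda <= 1,
            contam_fraction >= 0, contam_fraction <= 1,
            all(grade_probs >= 0), abs(sum(grade_probs) - 1) < 1e-8,
            dispersion >= 0)
  cfg
}

# Per-gene log2 grade multiplier, steps well=0, moderate=1, poor=2.
grade_log2_effect <- function(class, grade_step, effect) {
  switch(class,
    pattern1_up     = effect * grade_step,
    pattern2_down   = -effect * grade_step,
    pattern3_peak   = if (grade_step == 1) effect else 0,
    pattern4_trough = if (grade_step == 1) -effect else 0,
    0)
}

assign_gene_classes <- function(cfg) {
  n_sig <- sum(lengths(SIGNATURE_SETS))
  ids <- sprintf("G%04d", seq_len(cfg$n_genes - n_sig))
  class <- rep("null", cfg$n_genes - n_sig)
  idx <- 1L
  for (cl in names(cfg$class_sizes)) {
    k <- cfg$class_sizes[[cl]]
    if (k == 0) next
    take <- idx:(idx + k - 1L)
    class[take] <- cl
    prefix <- switch(cl,
      epithelial_markers = "EPM", macrophage_markers = "MAM",
      stromal_markers = "STM", NULL)
    if (!is.null(prefix)) ids[take] <- sprintf("%s%02d", prefix, seq_len(k))
    idx <- idx + k
  }
  sig_ids <- unlist(SIGNATURE_SETS, use.names = FALSE)
  sig_class <- rep(names(SIGNATURE_SETS), lengths(SIGNATURE_SETS))
  data.frame(gene = c(sig_ids, ids), class = c(sig_class, class),
             stringsAsFactors = FALSE)
}

#' Simulate negative-probe counts and NTC values
#'
#' Negative probes are Poisson around a constant background mean;
#' designated QC-violation AOIs receive NTC counts above the removal
#' threshold, everyone else a low Poisson NTC.
#'
#' @param cfg config from [sim_config()]
#' @param aoi_ids AOI identifiers
#' @param ntc_violation_idx indices of AOIs planted to exceed the NTC
#'   threshold
#' @param ntc_max NTC threshold the violations must exceed
#' @return list with `negprobes` (probes x AOIs matrix) and `ntc`
#'   (per-AOI counts)
#' @export
simulate_negative_controls <- function(cfg, aoi_ids,
                                       ntc_violation_idx = integer(0),
                                       ntc_max = 1000) {
  n_aoi <- length(aoi_ids)
  m <- matrix(stats::rpois(cfg$n_negative_probes * n_aoi, cfg$negprobe_mean),
              nrow = cfg$n_negative_probes, ncol = n_aoi,
              dimnames = list(sprintf("NegPrb%03d", seq_len(cfg$n_negative_probes)),
                              aoi_ids))
  ntc <- stats::rpois(n_aoi, cfg$ntc_mean)
  ntc <- pmin(ntc, ntc_max)          # clean AOIs never trip the rule
  if (length(ntc_violation_idx) > 0) {
    ntc[ntc_violation_idx] <- ntc_max + 1 + stats::rpois(length(ntc_violation_idx), 200)
  }
  list(negprobes = m, ntc = ntc)
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Generates the five pipeline inputs (counts, annotations, negative
#' probes, survival, truth). Counts follow NB(mean, dispersion) with
#' mean = library size x gene baseline x compartment-marker effect x
#' grade effect x signature-risk effect; contaminated MA/ST AOIs draw
#' from a (1-lambda) own + lambda epithelial mixture of mean profiles.
#' Event times are exponential with log-hazard proportional to the
#' planted patient risk; censoring is uniform administrative. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg config from [sim_config()]
#' @return list: `counts` (genes x AOIs integer matrix), `annotations`,
#'   `negprobes`, `survival`, `truth` (gene classes, per-AOI
#'   contamination lambda, patient risk, true betas, marker/signature
#'   sets)
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  genes <- assign_gene_classes(cfg)
  n_genes <- nrow(genes)

  # cohort layout: ROIs per patient, one EP + one MA + one ST AOI per ROI
  n_rois <- cfg$n_patients * cfg$rois_per_patient
  roi <- data.frame(
    roi_id = sprintf("ROI%03d", seq_len(n_rois)),
    patient_id = rep(sprintf("P%02d", seq_len(cfg$n_patients)),
                     each = cfg$rois_per_patient),
    stringsAsFactors = FALSE)
  if (!is.null(cfg$rois_per_grade)) {
    stopifnot(sum(cfg$rois_per_grade) == n_rois)
    roi$grade <- sample(rep(GRADES, cfg$rois_per_grade))
  } else {
    roi$grade <- sample(GRADES, n_rois, replace = TRUE,
                        prob = cfg$grade_probs)
  }

  ann <- do.call(rbind, lapply(COMPARTMENTS, function(comp) {
    data.frame(aoi_id = paste0(roi$roi_id, "-", comp),
               roi_id = roi$roi_id, patient_id = roi$patient_id,
               compartment = comp, grade = roi$grade,
               stringsAsFactors = FALSE)
  }))
  ann <- ann[order(ann$roi_id, match(ann$compartment, COMPARTMENTS)), ]
  rownames(ann) <- NULL
  n_aoi <- nrow(ann)

  # technical metrics, clean by default
  ann$nuclei <- pmax(101L, stats::rpois(n_aoi, cfg$nuclei_mean))
  ann$alignment_rate <- stats::runif(n_aoi, 0.85, 0.98)

  # planted QC violations on disjoint AOIs, disjoint from contamination
  qv <- cfg$qc_violations
  need <- sum(qv)
  if (need > n_aoi) stop("more QC violations than AOIs")
  viol_idx <- sample.int(n_aoi, need)
  ntc_idx <- utils::head(viol_idx, qv[["ntc"]])
  nuc_idx <- viol_idx[seq_len(qv[["nuclei"]]) + qv[["ntc"]]]
  aln_idx <- utils::tail(viol_idx, qv[["alignment"]])
  if (qv[["nuclei"]] > 0) ann$nuclei[nuc_idx] <- sample(10:99, qv[["nuclei"]], replace = TRUE)
  if (qv[["alignment"]] > 0) ann$alignment_rate[aln_idx] <- stats::runif(qv[["alignment"]], 0.5, 0.79)

  nc <- simulate_negative_controls(cfg, ann$aoi_id, ntc_idx)
  ann$ntc_count <- nc$ntc

  # contaminated MA/ST AOIs (never the QC-violating ones)
  pick_contam <- function(comp, n_explicit) {
    pool <- setdiff(which(ann$compartment == comp), viol_idx)
    k <- if (!is.null(n_explicit)) n_explicit
         else round(cfg$contam_fraction * length(pool))
    if (k > length(pool)) stop("not enough clean ", comp, " AOIs to contaminate")
    pool[sample.int(length(pool), k)]
  }
  contam_idx <- c(pick_contam("MA", cfg$contam_n_ma),
                  pick_contam("ST", cfg$contam_n_st))
  lambda <- rep(0, n_aoi)
  lambda[contam_idx] <- cfg$contam_lambda

  # patient risk and survival
  risk <- stats::setNames(stats::rnorm(cfg$n_patients),
                          sprintf("P%02d", seq_len(cfg$n_patients)))
  hazard <- cfg$baseline_hazard * exp(cfg$risk_loghr * risk)
  t_event <- stats::rexp(cfg$n_patients, rate = hazard)
  t_cens <- stats::runif(cfg$n_patients, 0, cfg$max_followup)
  surv <- data.frame(patient_id = names(risk),
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)

  # mean model
  base <- stats::rlnorm(n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  libsize <- stats::rlnorm(n_aoi, 0, cfg$libsize_sdlog)
  grade_step <- match(ann$grade, GRADES) - 1L
  marker_class <- c(EP = "epithelial_markers", MA = "macrophage_markers",
                    ST = "stromal_markers")
  sig_classes <- names(SIGNATURE_SETS)

  # per-gene grade effect lookup, columns = grade steps 0..2
  grade_eff <- vapply(0:2, function(step) {
    vapply(genes$class, grade_log2_effect, 0,
           grade_step = step, effect = cfg$pattern_effect)
  }, numeric(n_genes))
  in_sig <- genes$class %in% sig_classes

  log2_mean_profile <- function(a, comp) {
    # per-gene log2 mean for AOI a as if it belonged to compartment comp
    l2 <- log2(base) + grade_eff[, grade_step[a] + 1L]
    is_marker <- genes$class %in% marker_class
    l2 <- l2 + ifelse(genes$class == marker_class[[comp]], cfg$marker_effect,
                      ifelse(is_marker, -cfg$marker_depletion, 0))
    l2[in_sig] <- l2[in_sig] + cfg$risk_loading * risk[[ann$patient_id[a]]]
    l2
  }

  mu <- matrix(0, nrow = n_genes, ncol = n_aoi,
               dimnames = list(genes$gene, ann$aoi_id))
  for (a in seq_len(n_aoi)) {
    own <- 2^log2_mean_profile(a, ann$compartment[a])
    if (lambda[a] > 0) {
      ep <- 2^log2_mean_profile(a, "EP")
      own <- (1 - lambda[a]) * own + lambda[a] * ep
    }
    mu[, a] <- libsize[a] * own
  }

  counts <- if (cfg$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
           nrow = n_genes, dimnames = dimnames(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu),
           nrow = n_genes, dimnames = dimnames(mu))
  }

  n_sig_genes <- sum(genes$class %in% sig_classes)
  truth <- list(
    gene_class = genes,
    contamination = data.frame(aoi_id = ann$aoi_id, lambda = lambda,
                               stringsAsFactors = FALSE),
    patient_risk = risk,
    true_beta = stats::setNames(
      rep(cfg$risk_loghr / (n_sig_genes * cfg$risk_loading), n_sig_genes),
      genes$gene[genes$class %in% sig_classes]),
    marker_sets = list(
      EP = genes$gene[genes$class == "epithelial_markers"],
      MA = genes$gene[genes$class == "macrophage_markers"],
      ST = genes$gene[genes$class == "stromal_markers"]),
    signature_sets = SIGNATURE_SETS,
    qc_violation_aois = list(ntc = ann$aoi_id[ntc_idx],
                             nuclei = ann$aoi_id[nuc_idx],
                             alignment = ann$aoi_id[aln_idx]),
    config = cfg)

  list(counts = counts, annotations = validate_annotations(ann),
       negprobes = nc$negprobes, survival = surv, truth = truth)
}

#' Serialize planted truth tables for test harnesses
#'
#' Writes gene classes, per-AOI contamination weights and per-patient
#' risk (with recomputed risk scores from true betas) as TSVs under a
#' directory.
#'
#' @param truth `truth` element of [simulate_cohort()] output
#' @param dir output directory (created if needed)
#' @return invisible vector of written paths
#' @export
planted_truth_report <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_table(truth$gene_class, file.path(dir, "gene_classes.tsv")),
    write_table(truth$contamination, file.path(dir, "contamination.tsv")),
    write_table(data.frame(patient_id = names(truth$patient_risk),
                           risk = unname(truth$patient_risk)),
                file.path(dir, "patient_risk.tsv")),
    write_table(data.frame(gene = names(truth$true_beta),
                           beta = unname(truth$true_beta)),
                file.path(dir, "true_betas.tsv")))
  invisible(paths)
}
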