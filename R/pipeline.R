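# End-to-end driver chaining every stage on a cohort (real files or a
# simulated one): QC + normalization, grade-trend patterns, signature
# scoring + ORA, paired correlation, deconvolution, prognosis.

#' Run the full analysis pipeline
#'
#' Stages: `qc` (technical QC, detection floors, gene filter, Q3
#' normalization, contamination filter), `patterns` (per-compartment
#' four-pattern grade-trend classification), `score` (ssGSEA over the
#' planted/provided gene sets plus ORA of pattern genes), `pair`
#' (within-ROI EP-MA paired correlation), `deconv` (NNLS fractions of
#' ST AOIs against a compartment-mean marker reference, permutation
#' filter), `prognosis` (composite-signature Cox risk model, median
#' split, log-rank, AUC, reverse-KM follow-up).
#'
#' @param cohort list with counts, annotations, negprobes, survival and
#'   (for simulated cohorts) truth — the shape returned by
#'   [simulate_cohort()]
#' @param cfg pipeline config
#' @param marker_set epithelial marker genes for contamination scoring;
#'   defaults to the simulated truth's EP marker set
#' @param collection gene-set collection for scoring; defaults to the
#'   planted signature + marker sets for simulated cohorts
#' @param stages subset of stages to run (qc always runs)
#' @return named list of per-stage results
#' @export
run_pipeline <- function(cohort, cfg = default_config(),
                         marker_set = cohort$truth$marker_sets$EP,
                         collection = NULL,
                         stages = c("patterns", "score", "pair", "deconv",
                                    "prognosis")) {
  if (is.null(marker_set)) stop("marker_set required for contamination scoring")
  if (is.null(collection)) {
    collection <- c(cohort$truth$signature_sets,
                    list(epithelial_markers = cohort$truth$marker_sets$EP,
                         macrophage_markers = cohort$truth$marker_sets$MA,
                         stromal_markers = cohort$truth$marker_sets$ST))
  }
  res <- list()
  res$qc <- qc_normalize(cohort$counts, cohort$annotations,
                         cohort$negprobes, marker_set, cfg)
  norm <- res$qc$normalized
  ann <- res$qc$annotations

  if ("patterns" %in% stages) {
    res$patterns <- lapply(stats::setNames(COMPARTMENTS, COMPARTMENTS),
      function(comp) {
        tryCatch(pattern_analysis(norm, ann, comp, cfg),
                 error = function(e) {
                   pipeline_log("patterns: %s skipped (%s)", comp,
                                conditionMessage(e))
                   NULL
                 })
      })
  }

  if ("score" %in% stages) {
    res$scores <- score_matrix(norm, collection,
                               alpha = cfg$ssgsea_alpha,
                               normalize = cfg$ssgsea_normalize)
    ep_pat <- res$patterns$EP
    if (!is.null(ep_pat)) {
      query <- ep_pat$gene[ep_pat$pattern == "P1"]
      if (length(query) > 0) {
        res$ora <- hypergeometric_ora(query, collection, ep_pat$gene, cfg)
      }
    }
  }

  if ("pair" %in% stages) {
    pairs <- pair_compartments(ann)
    res$pairs <- pairs
    if (nrow(pairs) >= 3) {
      ep_set <- collection[["complement_activation"]]
      ma_set <- collection[["ecm_remodelling"]]
      if (!is.null(ep_set) && !is.null(ma_set)) {
        res$paired_correlation <- paired_correlation(
          pairs, norm, ep_set, ma_set, method = "spearman",
          by_grade = TRUE)
      }
    }
  }

  if ("deconv" %in% stages) {
    markers <- unique(unlist(cohort$truth$marker_sets, use.names = FALSE))
    if (is.null(markers)) markers <- marker_set
    reference <- build_reference(norm, ann, markers)
    st_aois <- ann$aoi_id[ann$compartment == "ST"]
    if (length(st_aois) > 0 && ncol(reference) >= 2) {
      res$deconv <- deconvolve(norm, reference, st_aois, cfg)
    }
  }

  if ("prognosis" %in% stages) {
    sig_sets <- collection[intersect(names(collection),
                                     c("complement_activation",
                                       "ecm_remodelling",
                                       "humoural_immune_response"))]
    if (length(sig_sets) == 3) {
      res$prognosis <- risk_model_pipeline(norm, ann, cohort$survival,
                                           collection = sig_sets,
                                           cfg = cfg)
    }
  }
  res
}

#' Load a cohort from pipeline input files
#'
#' @param counts_path,annotations_path,negprobes_path,survival_path TSV
#'   paths in the formats of the matching readers
#' @return cohort list as consumed by [run_pipeline()] (no truth)
#' @export
read_cohort <- function(counts_path, annotations_path, negprobes_path,
                        survival_path) {
  list(counts = read_count_matrix(counts_path),
       annotations = read_annotations(annotations_path),
       negprobes = read_negprobe_matrix(negprobes_path),
       survival = read_survival(survival_path))
}

#' Write a cohort to pipeline input files
#'
#' @param cohort cohort list (counts, annotations, negprobes, survival,
#'   optional truth)
#' @param dir output directory
#' @return invisible vector of written paths
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_matrix(cohort$counts, file.path(dir, "counts.tsv"), "gene"),
    write_matrix(cohort$negprobes, file.path(dir, "negprobes.tsv"), "probe"))
  utils::write.table(cohort$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, file.path(dir, c("annotations.tsv", "survival.tsv")))
  if (!is.null(cohort$truth)) {
    planted_truth_report(cohort$truth, file.path(dir, "truth"))
    paths <- c(paths, file.path(dir, "truth"))
  }
  invisible(paths)
}
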