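# Technical QC cascade, negative-probe detection floors, Q3 (75th
# percentile) normalization, and epithelial-contamination filtering of
# non-epithelial AOIs.

QC_REASONS <- c("LOW_ALIGNMENT", "HIGH_NTC", "LOW_NUCLEI", "CONTAMINATED")

#' Technical QC of AOIs
#'
#' An AOI fails iff alignment_rate < min_alignment OR ntc_count >
#' ntc_max OR nuclei < min_nuclei; boundary values pass (the rules are
#' strict inequalities on the failing side). All violated reasons are
#' reported, in the fixed cascade order alignment, NTC, nuclei.
#'
#' @param annotations validated annotation data.frame
#' @param cfg pipeline config (see [default_config()])
#' @return `qc_report`: data.frame (aoi_id, pass, reasons
#'   semicolon-joined) plus a `summary` attribute of counts per reason
#' @export
technical_qc <- function(annotations, cfg = default_config()) {
  ann <- validate_annotations(annotations)
  need <- c("alignment_rate", "ntc_count", "nuclei")
  for (m in need) {
    if (anyNA(ann[[m]])) {
      stop("missing ", m, " for AOI ",
           ann$aoi_id[which(is.na(ann[[m]]))[1]])
    }
  }
  reasons <- mapply(function(aln, ntc, nuc) {
    r <- character(0)
    if (aln < cfg$min_alignment) r <- c(r, "LOW_ALIGNMENT")
    if (ntc > cfg$ntc_max) r <- c(r, "HIGH_NTC")
    if (nuc < cfg$min_nuclei) r <- c(r, "LOW_NUCLEI")
    paste(r, collapse = ";")
  }, ann$alignment_rate, ann$ntc_count, ann$nuclei)
  rep_df <- data.frame(aoi_id = ann$aoi_id, pass = !nzchar(reasons),
                       reasons = reasons, stringsAsFactors = FALSE)
  counts <- vapply(QC_REASONS[1:3], function(rc) {
    sum(grepl(rc, rep_df$reasons, fixed = TRUE))
  }, 0L)
  pipeline_log("technical_qc: %d/%d AOIs pass (LOW_ALIGNMENT=%d, HIGH_NTC=%d, LOW_NUCLEI=%d)",
               sum(rep_df$pass), nrow(rep_df),
               counts[["LOW_ALIGNMENT"]], counts[["HIGH_NTC"]],
               counts[["LOW_NUCLEI"]])
  attr(rep_df, "summary") <- counts
  class(rep_df) <- c("qc_report", class(rep_df))
  rep_df
}

#' Per-AOI detection floor from negative probes
#'
#' The floor for AOI a is the larger of the configured minimum
#' (`negprobe_floor`, default 4 counts) and the geometric mean of that
#' AOI's negative-probe counts (computed with a +1 offset so zeros are
#' defined, offset removed afterwards). A gene is "detected" in an AOI
#' when its count is >= the floor.
#'
#' @param negprobes probes x AOIs matrix
#' @param aoi_ids AOIs the floor is needed for (must all be columns)
#' @param cfg pipeline config
#' @return named numeric vector of per-AOI floors
#' @export
detection_background <- function(negprobes, aoi_ids = colnames(negprobes),
                                 cfg = default_config()) {
  missing <- setdiff(aoi_ids, colnames(negprobes))
  if (length(missing) > 0) {
    stop("AOI(s) absent from negative-probe matrix: ",
         paste(missing, collapse = ", "))
  }
  floors <- vapply(aoi_ids, function(a) {
    max(cfg$negprobe_floor, geomean(negprobes[, a], offset = 1))
  }, 0)
  stats::setNames(floors, aoi_ids)
}

#' Detection indicator matrix
#'
#' @param counts genes x AOIs matrix
#' @param floors per-AOI floors from [detection_background()]
#' @return logical matrix, TRUE where count >= floor
#' @export
detected_matrix <- function(counts, floors) {
  stopifnot(all(colnames(counts) %in% names(floors)))
  sweep(counts, 2, floors[colnames(counts)], `>=`)
}

#' Drop genes detected in too few AOIs
#'
#' Retains genes detected (count >= per-AOI floor) in at least
#' `min_detect_fraction` of the AOIs, inclusive at the boundary.
#'
#' @param counts genes x AOIs matrix (QC-passed AOIs)
#' @param floors per-AOI detection floors
#' @param cfg pipeline config
#' @return filtered count matrix
#' @export
filter_undetected_genes <- function(counts, floors, cfg = default_config()) {
  det <- detected_matrix(counts, floors)
  frac <- rowMeans(det)
  keep <- frac >= cfg$min_detect_fraction
  pipeline_log("filter_undetected_genes: kept %d/%d genes at detection fraction >= %g",
               sum(keep), nrow(counts), cfg$min_detect_fraction)
  counts[keep, , drop = FALSE]
}

#' Q3 (75th percentile) normalization
#'
#' Each AOI's Q3 is the 75th percentile (linear-interpolation
#' definition) of its detected-gene counts; the scale factor is the
#' geometric mean of all Q3s divided by the AOI's own Q3, so that after
#' scaling every AOI shares the same Q3.
#'
#' @param counts genes x AOIs matrix, gene-filtered
#' @param floors per-AOI detection floors; when NULL, Q3 is computed
#'   over all genes
#' @return list: `normalized` matrix, `factors` data.frame (aoi_id, q3,
#'   scale), `reference` (geometric mean of Q3s)
#' @export
q3_normalize <- function(counts, floors = NULL) {
  q3 <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    if (!is.null(floors)) x <- x[x >= floors[[colnames(counts)[j]]]]
    if (length(x) == 0 || all(x == 0)) return(0)
    stats::quantile(x, 0.75, names = FALSE, type = 7)
  }, 0)
  if (any(q3 <= 0)) {
    stop("Q3 is zero for AOI(s) ",
         paste(colnames(counts)[q3 <= 0], collapse = ", "),
         "; these should have been removed by QC")
  }
  ref <- geomean(q3)
  scale <- ref / q3
  normalized <- sweep(counts, 2, scale, `*`)
  list(normalized = normalized,
       factors = data.frame(aoi_id = colnames(counts), q3 = q3,
                            scale = scale, stringsAsFactors = FALSE),
       reference = ref)
}

#' Per-AOI epithelial contamination score
#'
#' ssGSEA enrichment of an epithelial marker set in each AOI, min-max
#' rescaled to [0,1] across the AOIs of the run (a degenerate
#' zero-range run scores 0 everywhere). Scores above the configured
#' threshold in MA/ST AOIs flag epithelial contamination.
#'
#' @param normalized genes x AOIs normalized matrix
#' @param marker_set character vector of epithelial marker genes (>= 3
#'   present in the panel)
#' @param cfg pipeline config
#' @return data.frame (aoi_id, raw_es, score) with the threshold in
#'   `attr(, "threshold")`
#' @export
epithelial_score <- function(normalized, marker_set, cfg = default_config()) {
  members <- intersect(marker_set, rownames(normalized))
  if (length(members) < 3) {
    stop("need >= 3 epithelial markers in the panel, found ", length(members))
  }
  es <- vapply(seq_len(ncol(normalized)), function(j) {
    ssgsea_score(normalized[, j], members, alpha = cfg$ssgsea_alpha)
  }, 0)
  rng <- max(es) - min(es)
  score <- if (rng > 0) (es - min(es)) / rng else rep(0, length(es))
  out <- data.frame(aoi_id = colnames(normalized), raw_es = es,
                    score = score, stringsAsFactors = FALSE)
  attr(out, "threshold") <- cfg$contamination_thr
  out
}

#' Flag contaminated non-epithelial AOIs
#'
#' MA/ST AOIs whose epithelial score exceeds the threshold (strict
#' inequality) are flagged CONTAMINATED; EP AOIs are never removed by
#' this rule. In `data_driven` mode the threshold is set just below the
#' minimum EP score instead of the fixed config value.
#'
#' @param scores output of [epithelial_score()]
#' @param annotations annotation data.frame covering the scored AOIs
#' @param cfg pipeline config
#' @return data.frame (aoi_id, compartment, score, contaminated) with
#'   the threshold used in `attr(, "threshold")`
#' @export
filter_contaminated <- function(scores, annotations, cfg = default_config()) {
  ann <- annotations[match(scores$aoi_id, annotations$aoi_id), ]
  stopifnot(!anyNA(ann$aoi_id))
  thr <- cfg$contamination_thr
  if (cfg$contamination_mode == "data_driven") {
    ep_scores <- scores$score[ann$compartment == "EP"]
    if (length(ep_scores) == 0) stop("data_driven mode needs EP AOIs")
    thr <- min(ep_scores) - 1e-9
  }
  contaminated <- ann$compartment %in% c("MA", "ST") & scores$score > thr
  pipeline_log("filter_contaminated: %d MA/ST AOIs flagged at score > %g",
               sum(contaminated), thr)
  out <- data.frame(aoi_id = scores$aoi_id, compartment = ann$compartment,
                    score = scores$score, contaminated = contaminated,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}

#' Run the full QC + normalization cascade
#'
#' technical QC -> detection floors -> gene filter -> Q3 normalization
#' -> epithelial-contamination filter, returning everything downstream
#' stages need.
#'
#' @param counts raw genes x AOIs matrix
#' @param annotations annotation data.frame
#' @param negprobes probes x AOIs matrix
#' @param marker_set epithelial marker genes
#' @param cfg pipeline config
#' @return list: `qc` (per-AOI report incl. CONTAMINATED), `retained`
#'   (AOI ids kept for downstream DE), `normalized`, `factors`,
#'   `floors`, `scores`, `annotations` (retained rows)
#' @export
qc_normalize <- function(counts, annotations, negprobes, marker_set,
                         cfg = default_config()) {
  qc <- technical_qc(annotations, cfg)
  keep1 <- qc$aoi_id[qc$pass]
  counts1 <- counts[, keep1, drop = FALSE]
  floors <- detection_background(negprobes, keep1, cfg)
  counts2 <- filter_undetected_genes(counts1, floors, cfg)
  norm <- q3_normalize(counts2, floors)
  scores <- epithelial_score(norm$normalized, marker_set, cfg)
  contam <- filter_contaminated(scores, annotations, cfg)
  bad <- contam$aoi_id[contam$contaminated]
  report <- qc
  report$reasons[report$aoi_id %in% bad] <- vapply(
    report$reasons[report$aoi_id %in% bad],
    function(r) paste(c(r[nzchar(r)], "CONTAMINATED"), collapse = ";"), "")
  report$pass <- report$pass & !(report$aoi_id %in% bad)
  retained <- report$aoi_id[report$pass]
  pipeline_log("qc_normalize: %d/%d AOIs retained overall",
               length(retained), nrow(annotations))
  list(qc = report, retained = retained,
       normalized = norm$normalized[, retained, drop = FALSE],
       factors = norm$factors, floors = floors, scores = contam,
       annotations = annotations[annotations$aoi_id %in% retained, ])
}
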