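# Within-ROI pairing of epithelial and macrophage AOIs and
# cross-compartment correlation of gene-set expression.

#' Pair EP and MA AOIs within each ROI
#'
#' One pair per ROI that contains at least one QC-passed EP and one MA
#' AOI; ROIs lacking either compartment are skipped with a log line.
#' Multiple AOIs of a compartment within a ROI are kept as a list and
#' averaged on the log scale at expression time.
#'
#' @param annotations QC-passed annotation data.frame
#' @return data.frame (roi_id, grade, ep_aois, ma_aois) with AOI ids
#'   semicolon-joined
#' @export
pair_compartments <- function(annotations) {
  rois <- unique(annotations$roi_id)
  rows <- lapply(rois, function(r) {
    sub <- annotations[annotations$roi_id == r, ]
    ep <- sub$aoi_id[sub$compartment == "EP"]
    ma <- sub$aoi_id[sub$compartment == "MA"]
    if (length(ep) == 0 || length(ma) == 0) {
      pipeline_log("pair_compartments: ROI %s skipped (EP=%d, MA=%d)",
                   r, length(ep), length(ma))
      return(NULL)
    }
    data.frame(roi_id = r, grade = sub$grade[1],
               ep_aois = paste(ep, collapse = ";"),
               ma_aois = paste(ma, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(roi_id = character(0), grade = character(0),
                      ep_aois = character(0), ma_aois = character(0))
  }
  pipeline_log("pair_compartments: %d/%d ROIs paired", nrow(out), length(rois))
  out
}

#' Mean log expression of a gene set in an AOI profile
#'
#' Profiles with several AOIs are first averaged on the log2 scale
#' (mean over AOIs of log2(normalized + 1)), then averaged over the
#' set members. Singleton sets are allowed.
#'
#' @param normalized genes x AOIs normalized matrix
#' @param set character vector of gene ids (>= 1 present in panel)
#' @param aoi_ids one or more AOI ids forming the profile
#' @return scalar mean log2 expression
#' @export
set_mean_expression <- function(normalized, set, aoi_ids) {
  members <- intersect(set, rownames(normalized))
  if (length(members) == 0) stop("gene set has no members in the panel")
  sub <- log2(normalized[members, aoi_ids, drop = FALSE] + 1)
  mean(rowMeans(sub))
}

#' Spearman (or Pearson) correlation with exact small-n permutation p
#'
#' Spearman rho is Pearson correlation on midranks. The two-sided p is
#' exact (enumeration of all n! orderings) for n <= 9 and the
#' t-approximation t = rho * sqrt((n-2)/(1-rho^2)) otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @param method "spearman" (default) or "pearson"
#' @return list(rho, p_value, n, method)
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  if (method == "pearson") {
    ct <- stats::cor.test(x, y, method = "pearson")
    return(list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                method = method))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    # rho is affine in sum(rx[perm] * ry); enumerate that inner product
    null_ip <- as.vector(matrix(rx[perms], nrow = nrow(perms)) %*% ry)
    centre <- n * mean(rx) * mean(ry)
    scale_ <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    null_rho <- (null_ip - centre) / scale_
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- min(1, p)
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Correlate an EP-compartment set with an MA-compartment set across
#' paired ROIs
#'
#' For each ROI pair, the EP value is the mean log expression of
#' `ep_set` over the ROI's EP profile and the MA value that of `ma_set`
#' over the MA profile; the two vectors are then correlated across
#' ROIs, optionally per grade.
#'
#' @param pairs output of [pair_compartments()]
#' @param normalized genes x AOIs normalized matrix
#' @param ep_set,ma_set gene sets evaluated on the EP / MA profiles
#' @param method "spearman" or "pearson"
#' @param by_grade additionally stratify by grade
#' @return data.frame (label, n, rho, p_value, method)
#' @export
paired_correlation <- function(pairs, normalized, ep_set, ma_set,
                               method = "spearman", by_grade = FALSE) {
  if (nrow(pairs) < 3) stop("need >= 3 ROI pairs")
  ep_val <- vapply(seq_len(nrow(pairs)), function(i) {
    set_mean_expression(normalized, ep_set,
                        strsplit(pairs$ep_aois[i], ";")[[1]])
  }, 0)
  ma_val <- vapply(seq_len(nrow(pairs)), function(i) {
    set_mean_expression(normalized, ma_set,
                        strsplit(pairs$ma_aois[i], ";")[[1]])
  }, 0)
  one <- function(idx, label) {
    r <- correlate(ep_val[idx], ma_val[idx], method)
    data.frame(label = label, n = r$n, rho = r$rho, p_value = r$p_value,
               method = r$method, stringsAsFactors = FALSE)
  }
  out <- one(seq_len(nrow(pairs)), "pooled")
  if (by_grade) {
    for (g in intersect(GRADES, unique(pairs$grade))) {
      idx <- which(pairs$grade == g)
      if (length(idx) >= 3) out <- rbind(out, one(idx, g))
    }
  }
  out
}
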