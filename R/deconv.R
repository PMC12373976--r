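# Reference-based cell-fraction estimation from mixture profiles:
# quantile normalization to a reference distribution, non-negative
# least squares over signature genes, Monte Carlo permutation
# significance, and the retention filter (p < .05 and R > .7).

#' Quantile-normalize mixture columns to a reference distribution
#'
#' Each column's values are replaced by the reference distribution's
#' values at matching ranks (midrank ties give interpolated reference
#' positions). The reference must be at least as long as the gene
#' count; a longer reference is linearly interpolated.
#'
#' @param mixture genes x AOIs non-negative matrix
#' @param reference numeric vector defining the target distribution
#' @return matrix of the same shape
#' @export
quantile_normalize <- function(mixture, reference) {
  n <- nrow(mixture)
  if (length(reference) < n) stop("reference shorter than gene count")
  qs <- sort(reference)
  m <- length(qs)
  out <- apply(mixture, 2, function(col) {
    r <- rank(col, ties.method = "average")
    pos <- if (m == n) r else 1 + (r - 1) * (m - 1) / (n - 1)
    stats::approx(seq_len(m), qs, xout = pos)$y
  })
  dimnames(out) <- dimnames(mixture)
  out
}

#' Estimate cell-type fractions for one mixture by NNLS
#'
#' Non-negative least squares of the mixture on the reference columns
#' over the shared signature genes; coefficients renormalized to the
#' simplex. An all-zero solution falls back to uniform fractions with a
#' warning.
#'
#' @param reference signature genes x cell types matrix (rownames =
#'   genes)
#' @param mixture named numeric vector for one AOI
#' @return list: `fractions` (sums to 1), `coef` (raw NNLS
#'   coefficients), `genes` used
#' @export
estimate_fractions <- function(reference, mixture) {
  stopifnot(!is.null(rownames(reference)), ncol(reference) >= 2)
  genes <- intersect(rownames(reference), names(mixture))
  if (length(genes) == 0) stop("no overlap between reference and mixture genes")
  if (length(genes) < ncol(reference)) {
    stop("fewer shared signature genes than cell types")
  }
  A <- reference[genes, , drop = FALSE]
  b <- mixture[genes]
  coef <- pracma::lsqnonneg(A, b)$x
  names(coef) <- colnames(reference)
  if (sum(coef) == 0) {
    warning("all-zero NNLS solution; falling back to uniform fractions")
    fractions <- rep(1 / ncol(A), ncol(A))
    names(fractions) <- colnames(reference)
  } else {
    fractions <- coef / sum(coef)
  }
  list(fractions = fractions, coef = coef, genes = genes)
}

#' Monte Carlo permutation significance of a deconvolution fit
#'
#' Observed goodness R is the Pearson correlation between the NNLS
#' reconstruction and the mixture over signature genes. The null
#' permutes the mixture's gene labels and refits; p = (1 + #\{R_b >=
#' R\}) / (1 + n_perm).
#'
#' @param reference signature genes x cell types matrix
#' @param mixture named numeric vector
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed for the permutation stream
#' @return list(p_value, R, fractions)
#' @export
permutation_significance <- function(reference, mixture, n_perm = 1000,
                                     seed = 1L) {
  stopifnot(n_perm >= 100)
  fit <- estimate_fractions(reference, mixture)
  A <- reference[fit$genes, , drop = FALSE]
  b <- mixture[fit$genes]
  if (stats::sd(b) == 0) stop("zero-variance mixture")
  recon <- as.vector(A %*% fit$coef)
  R <- if (stats::sd(recon) == 0) 0 else stats::cor(recon, b)
  set.seed(seed)
  null_R <- vapply(seq_len(n_perm), function(i) {
    bp <- b[sample.int(length(b))]
    cf <- pracma::lsqnonneg(A, bp)$x
    rc <- as.vector(A %*% cf)
    if (stats::sd(rc) == 0) -Inf else stats::cor(rc, bp)
  }, 0)
  p <- (1 + sum(null_R >= R)) / (1 + n_perm)
  list(p_value = p, R = R, fractions = fit$fractions)
}

#' Apply the deconvolution retention filter
#'
#' Results are retained iff permutation p < p_max and goodness R >
#' r_min, both strict.
#'
#' @param results data.frame with columns p_value and R
#' @param cfg pipeline config (`deconv_p_max`, `deconv_r_min`)
#' @return the data.frame with a logical `retained` column
#' @export
filter_results <- function(results, cfg = default_config()) {
  results$retained <- results$p_value < cfg$deconv_p_max &
    results$R > cfg$deconv_r_min
  pipeline_log("deconv filter: %d/%d AOIs retained at p < %g and R > %g",
               sum(results$retained), nrow(results),
               cfg$deconv_p_max, cfg$deconv_r_min)
  results
}

#' Deconvolve a set of AOIs against a reference
#'
#' Optional quantile normalization of the mixtures to the pooled
#' reference distribution, NNLS fractions, permutation significance and
#' the retention filter, per AOI.
#'
#' @param normalized genes x AOIs matrix
#' @param reference signature genes x cell types matrix
#' @param aoi_ids AOIs to deconvolve (default all columns)
#' @param cfg pipeline config
#' @return data.frame: aoi_id, one fraction column per cell type, R,
#'   p_value, retained
#' @export
deconvolve <- function(normalized, reference, aoi_ids = colnames(normalized),
                       cfg = default_config()) {
  genes <- intersect(rownames(reference), rownames(normalized))
  mix <- normalized[genes, aoi_ids, drop = FALSE]
  if (isTRUE(cfg$deconv_qn)) {
    mix <- quantile_normalize(mix, as.vector(reference[genes, ]))
  }
  rows <- lapply(seq_along(aoi_ids), function(j) {
    ps <- permutation_significance(reference, mix[, j],
                                   n_perm = cfg$deconv_n_perm,
                                   seed = cfg$seed + j)
    cbind(data.frame(aoi_id = aoi_ids[j], stringsAsFactors = FALSE),
          as.data.frame(as.list(ps$fractions)),
          data.frame(R = ps$R, p_value = ps$p_value))
  })
  filter_results(do.call(rbind, rows), cfg)
}

#' Compartment-mean reference from marker genes
#'
#' Builds a genes x compartments reference by averaging normalized
#' expression of the pooled marker genes within each compartment's
#' AOIs; a stand-in with the schema of published leukocyte signature
#' matrices, derived from the run's own marker structure.
#'
#' @param normalized genes x AOIs matrix
#' @param annotations matching annotations
#' @param marker_genes character vector of signature (marker) genes
#' @return marker genes x compartments matrix
#' @export
build_reference <- function(normalized, annotations, marker_genes) {
  genes <- intersect(marker_genes, rownames(normalized))
  stopifnot(length(genes) >= 2)
  ann <- annotations[match(colnames(normalized), annotations$aoi_id), ]
  comps <- intersect(COMPARTMENTS, unique(ann$compartment))
  ref <- vapply(comps, function(cc) {
    rowMeans(normalized[genes, ann$compartment == cc, drop = FALSE])
  }, numeric(length(genes)))
  matrix(ref, nrow = length(genes), dimnames = list(genes, comps))
}
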