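# Single-sample gene-set enrichment (ssGSEA) scoring, score-level grade
# trend classification, and hypergeometric over-representation analysis.

#' ssGSEA enrichment score for one sample
#'
#' Genes are ranked by descending expression (ties broken by stable
#' gene-id order); gene at position pos gets rank weight
#' r = N - pos + 1. The score is the sum over all positions of the
#' difference between the weighted in-set ECDF
#' P_in(i) = sum_{g in S, pos(g) <= i} r_g^alpha / sum_{g in S} r_g^alpha
#' and the out-of-set ECDF P_out(i) = #\{g not in S, pos(g) <= i\}/(N-|S|).
#'
#' @param expr named numeric expression vector for one AOI
#' @param set character vector of member gene ids; must intersect the
#'   panel and must not cover it entirely
#' @param alpha rank weight exponent (>= 0, default 0.25)
#' @return enrichment score (unnormalized)
#' @export
ssgsea_score <- function(expr, set, alpha = 0.25) {
  stopifnot(!is.null(names(expr)), alpha >= 0)
  n <- length(expr)
  members <- names(expr) %in% set
  k <- sum(members)
  if (k == 0) stop("gene set has no members in the panel")
  if (k == n) stop("gene set covers the whole panel; P_out undefined")
  ord <- order(-expr, names(expr), method = "radix")
  in_set <- members[ord]
  r <- (n - seq_len(n) + 1)^alpha
  w_in <- ifelse(in_set, r, 0)
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!in_set) / (n - k)
  sum(p_in - p_out)
}

#' ssGSEA score matrix over a gene-set collection
#'
#' One score per set per AOI; with `normalize` every score is divided
#' by the global range (max - min) over the whole matrix, the
#' convention of the method.
#'
#' @param normalized genes x AOIs normalized expression matrix
#' @param collection named list of gene sets (e.g. from [read_gmt()])
#' @param alpha rank weight exponent
#' @param normalize divide by the global score range
#' @return sets x AOIs numeric matrix
#' @export
score_matrix <- function(normalized, collection, alpha = 0.25,
                         normalize = TRUE) {
  usable <- vapply(collection, function(s) {
    length(intersect(s, rownames(normalized))) >= 1
  }, TRUE)
  if (!any(usable)) stop("no gene set has members in the panel")
  collection <- collection[usable]
  scores <- vapply(seq_len(ncol(normalized)), function(j) {
    v <- normalized[, j]
    vapply(collection, function(s) ssgsea_score(v, s, alpha), 0)
  }, numeric(length(collection)))
  scores <- matrix(scores, nrow = length(collection),
                   dimnames = list(names(collection), colnames(normalized)))
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Grade trend of one signature score
#'
#' Applies the four-pattern grade-trend classifier to a per-AOI score
#' vector: P1 is gradual upregulation across well -> moderate -> poor,
#' P2 gradual downregulation, P3/P4 moderately peaked/troughed.
#'
#' @param scores named per-AOI score vector for one set
#' @param grades grade label per AOI (well/moderate/poor)
#' @param cfg pipeline config
#' @return one-row data.frame as in [pattern_analysis()]
#' @export
grade_trend <- function(scores, grades, cfg = default_config()) {
  stopifnot(length(scores) == length(grades))
  m <- matrix(scores, nrow = 1,
              dimnames = list("score", names(scores)))
  ann <- data.frame(aoi_id = names(scores), grade = grades,
                    compartment = "EP", stringsAsFactors = FALSE)
  pattern_analysis(m, ann, "EP", cfg)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p = P(X >= k) for the overlap k between a
#' query gene list (size n) and each set (size m after intersection
#' with the universe, size N); BH adjustment across sets.
#'
#' @param query character vector of query genes, a subset of `universe`
#' @param collection named list of gene sets
#' @param universe character vector of all testable genes
#' @param cfg pipeline config
#' @return data.frame (set, k, m, n, N, p_value, adjusted_p) sorted by
#'   p
#' @export
hypergeometric_ora <- function(query, collection, universe,
                               cfg = default_config()) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop("query genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    m <- length(members)
    k <- length(intersect(query, members))
    p <- if (k == 0) 1 else stats::phyper(k - 1, m, N - m, n,
                                          lower.tail = FALSE)
    data.frame(set = nm, k = k, m = m, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- bh_adjust(out$p_value)
  out[order(out$p_value, out$set), ]
}
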