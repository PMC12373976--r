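#' Geometric mean
#'
#' @param x numeric vector, all positive
#' @param offset added before and subtracted after the log transform; an
#'   offset of 1 makes the mean defined for zero counts
#' @return geometric mean of `x + offset`, minus `offset`
#' @keywords internal
geomean <- function(x, offset = 0) {
  stopifnot(all(x + offset > 0))
  exp(mean(log(x + offset))) - offset
}

# Stage logging: one line per filter/aggregation event, silenced via option.
pipeline_log <- function(...) {
  if (isTRUE(getOption("dspgrade.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(...))
  invisible(NULL)
}

#' Enumerate all permutations of 1..n
#'
#' Iterative heap-style construction; intended for exact permutation tests
#' at small n (n <= 9).
#'
#' @param n integer, 0 < n <= 9
#' @return matrix with n! rows, each row a permutation of 1..n
#' @keywords internal
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  p <- matrix(1L, nrow = 1L)
  if (n == 1L) return(p)
  for (k in 2L:n) {
    nr <- nrow(p)
    out <- matrix(0L, nrow = nr * k, ncol = k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * nr + seq_len(nr)
      if (pos == 1L) {
        out[rows, ] <- cbind(k, p)
      } else if (pos == k) {
        out[rows, ] <- cbind(p, k)
      } else {
        out[rows, ] <- cbind(p[, seq_len(pos - 1L), drop = FALSE], k,
                             p[, pos:(k - 1L), drop = FALSE])
      }
    }
    p <- out
  }
  p
}
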