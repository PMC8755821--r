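#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic \eqn{\sum (O - E)^2 / E} with expected counts
#' from the row/column margins, `(rows - 1)(cols - 1)` degrees of freedom and
#' an upper-tail chi-square p-value. No continuity correction is applied,
#' including for 2x2 tables: region-proportion comparisons in this field are
#' conventionally reported uncorrected.
#'
#' @param counts A numeric matrix of non-negative integer counts with at
#'   least 2 rows and 2 columns and no all-zero row or column; or anything
#'   coercible with `as.matrix()`.
#'
#' @return A one-row tibble: `statistic`, `dof`, `p_value`, `n`.
#' @examples
#' # visually-responsive vs not across three regions
#' pearson_chi_square(rbind(c(51, 45), c(88, 52), c(77, 43)))
#' @export
pearson_chi_square <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L || ncol(m) < 2L) abort("`counts` must be at least 2x2.")
  if (any(m < 0) || any(m != round(m))) abort("`counts` must be non-negative integers.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Every row and column must have a positive margin.")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(
    statistic = unname(res$statistic),
    dof = unname(res$parameter),
    p_value = res$p.value,
    n = sum(m)
  )
}

#' Count/percentage report of neuron-class proportions
#'
#' Formats "k of n (p%)" proportion statements with integer-rounded
#' percentages.
#'
#' @param numerators,denominators Integer vectors (recycled to the longer).
#' @param labels Optional row labels.
#' @return A tibble: `label`, `count`, `total`, `percent` (integer),
#'   `formatted`.
#' @examples
#' proportion_report(c(51, 88, 77), c(96, 140, 120), c("Wulst", "ENTO", "MVL"))
#' @export
proportion_report <- function(numerators, denominators, labels = NULL) {
  n <- max(length(numerators), length(denominators))
  num <- rep_len(numerators, n)
  den <- rep_len(denominators, n)
  if (any(den <= 0)) abort("`denominators` must be positive.")
  if (any(num < 0) || any(num > den)) abort("`numerators` must lie in [0, denominator].")
  pct <- as.integer(round(100 * num / den))
  tibble::tibble(
    label = labels %||% as.character(seq_len(n)),
    count = as.integer(num),
    total = as.integer(den),
    percent = pct,
    formatted = sprintf("%d (%d%%)", as.integer(num), pct)
  )
}
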