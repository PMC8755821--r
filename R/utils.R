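# internal helpers shared across modules

# run expr under a temporary RNG state when seed is given, otherwise use the
# session RNG (keeps user pipelines reproducible without clobbering .Random.seed)
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok) {
    abort(sprintf(
      "`%s` must be %s %s and %s %s (got %g).", name,
      if (strict) ">" else ">=", format(lower),
      if (strict) "<" else "<=", format(upper), x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

check_range <- function(x, name, lower = 0) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
      x[1] > x[2] || x[1] <= lower) {
    abort(sprintf("`%s` must be an increasing pair of values > %g.", name, lower))
  }
  as.numeric(x)
}

# Mann-Whitney rank statistic AUC: P(score_pos > score_neg) + 0.5 P(tie).
# Used inside the resampling loops where a full ROC object per call would
# dominate the runtime; agreement with pROC::auc is asserted in the tests.
auc_rank <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

grouping_labels <- function(n) sprintf("G%02d", seq_len(n))
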