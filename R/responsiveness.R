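#' Classify neurons as visually responsive and pause-period active
#'
#' For each neuron, the stimulus-window firing rate is compared with the
#' paired baseline ITI-window rate across trials using a two-tailed paired
#' t-test; a neuron is visually responsive when `p < alpha`, excitatory when
#' its mean stimulus rate exceeds its mean baseline rate and inhibitory
#' otherwise. The same contract applied to the pause-period rate yields the
#' pause-activity classification.
#'
#' Trials where every paired difference is exactly zero carry no evidence of a
#' response: the test is reported with `t = 0`, `p = 1`, class `"none"`.
#'
#' @param trials A session tibble ([simulate_session()] schema); may contain
#'   many neurons.
#' @param alpha Significance level. Default 0.05.
#'
#' @return A tibble with one row per neuron, class `responsiveness_result`:
#'   `neuron_id`, `visually_responsive`, `response_sign`
#'   (`"excitatory"|"inhibitory"|"none"`), `t_statistic`, `p_value`,
#'   `pause_active`, `pause_sign`, `pause_t`, `pause_p`, `n_trials`.
#' @examples
#' trials <- simulate_session(neuron_profile("excitatory", stim_gain = 4), seed = 1)
#' classify_responsiveness(trials)
#' @export
classify_responsiveness <- function(trials, alpha = 0.05) {
  check_number(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  res <- trials |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L) abort("At least 2 trials are required per neuron.")
      vis <- paired_response_test(d$rate_stim_hz, d$rate_baseline_hz, alpha)
      pau <- paired_response_test(d$rate_pause_hz, d$rate_baseline_hz, alpha)
      tibble::tibble(
        visually_responsive = vis$significant, response_sign = vis$sign,
        t_statistic = vis$t, p_value = vis$p,
        pause_active = pau$significant, pause_sign = pau$sign,
        pause_t = pau$t, pause_p = pau$p,
        n_trials = nrow(d)
      )
    }) |>
    dplyr::ungroup()
  class(res) <- c("responsiveness_result", class(res))
  attr(res, "alpha") <- alpha
  res
}

paired_response_test <- function(rate, baseline, alpha) {
  diffs <- rate - baseline
  if (all(diffs == 0) || sd(diffs) == 0 && mean(diffs) == 0) {
    return(list(significant = FALSE, sign = "none", t = 0, p = 1))
  }
  if (sd(diffs) == 0) {
    # constant non-zero difference: infinitely strong paired evidence
    return(list(significant = TRUE,
                sign = if (mean(diffs) > 0) "excitatory" else "inhibitory",
                t = sign(mean(diffs)) * Inf, p = 0))
  }
  tt <- t.test(rate, baseline, paired = TRUE)
  sig <- tt$p.value < alpha
  list(
    significant = sig,
    sign = if (!sig) "none" else if (mean(diffs) > 0) "excitatory" else "inhibitory",
    t = unname(tt$statistic), p = tt$p.value
  )
}

#' Class-averaged normalised period time courses
#'
#' Each neuron's per-period firing rates (baseline ITI, pause, stimulus) are
#' z-scored against that neuron's baseline-window mean and standard deviation,
#' then averaged within response class (excitatory / inhibitory /
#' nonresponsive as assigned by [classify_responsiveness()]). Neurons with
#' zero baseline variance cannot be normalised and are dropped with a warning.
#'
#' @param trials A session tibble.
#' @param classes A `responsiveness_result` for the same neurons.
#'
#' @return A tibble `response_class` x `period` (`baseline`, `pause`,
#'   `stimulus`) with columns `mean_norm_rate`, `sem`, `n_neurons`.
#' @export
normalized_timecourse <- function(trials, classes = classify_responsiveness(trials)) {
  cls <- classes |>
    dplyr::transmute(.data$neuron_id,
                     response_class = ifelse(.data$visually_responsive,
                                             .data$response_sign, "nonresponsive"))
  per_neuron <- trials |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(
      base_mu = mean(.data$rate_baseline_hz),
      base_sd = sd(.data$rate_baseline_hz),
      baseline = mean(.data$rate_baseline_hz),
      pause = mean(.data$rate_pause_hz),
      stimulus = mean(.data$rate_stim_hz),
      .groups = "drop"
    )
  degenerate <- per_neuron$base_sd == 0
  if (any(degenerate)) {
    warn(sprintf("Dropping %d neuron(s) with zero baseline variance from the time course.",
                 sum(degenerate)))
    per_neuron <- per_neuron[!degenerate, ]
  }
  per_neuron |>
    tidyr::pivot_longer(c("baseline", "pause", "stimulus"),
                        names_to = "period", values_to = "rate") |>
    dplyr::mutate(norm_rate = (.data$rate - .data$base_mu) / .data$base_sd) |>
    dplyr::inner_join(cls, by = "neuron_id") |>
    dplyr::group_by(.data$response_class, .data$period) |>
    dplyr::summarise(
      mean_norm_rate = mean(.data$norm_rate),
      sem = sd(.data$norm_rate) / sqrt(dplyr::n()),
      n_neurons = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(period = factor(.data$period, levels = c("baseline", "pause", "stimulus")))
}

#' @exportS3Method generics::tidy
tidy.responsiveness_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.responsiveness_result <- function(x, ...) {
  tibble::tibble(
    n_neurons = nrow(x),
    n_responsive = sum(x$visually_responsive),
    n_excitatory = sum(x$response_sign == "excitatory"),
    n_inhibitory = sum(x$response_sign == "inhibitory"),
    n_pause_active = sum(x$pause_active),
    alpha = attr(x, "alpha")
  )
}
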