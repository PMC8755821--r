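#' Behavioural task configuration
#'
#' Describes the trial structure of the go/no-go response-inhibition task:
#' a session presents `n_groupings * n_exemplars` distinct images,
#' `n_reps` times each, in a random order. Every trial has a pause period of
#' random duration (response inhibition, black screen), a stimulus period of
#' random duration, and a fixed inter-trial interval (ITI) whose final part
#' supplies the baseline firing-rate window.
#'
#' @param n_groupings Number of stimulus groupings (categories). Default 5.
#' @param n_exemplars Exemplar images per grouping. Default 4.
#' @param n_reps Presentations of each image per session. Default 8, giving
#'   the default `5 * 4 * 8 = 160` trials.
#' @param iti_s Inter-trial interval duration, seconds.
#' @param ready_pecks Number of orienting-stimulus pecks required to start a
#'   trial (task bookkeeping only; no rates are attached to the ready period).
#' @param pause_range_s Length-2 numeric, uniform range of the pause-period
#'   duration in seconds. Default `c(2, 4)`.
#' @param stim_range_s Length-2 numeric, uniform range of the stimulus-period
#'   duration in seconds. Default `c(1.5, 3)`.
#' @param analysis_window_s Window, in seconds, over which baseline and
#'   post-stimulus-onset firing rates are measured. Default 0.5.
#' @param rng_seed Optional integer seed attached to the config; used by
#'   [simulate_session()] when no explicit seed is passed.
#'
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' n_trials(cfg) # 160
#' @export
task_config <- function(n_groupings = 5, n_exemplars = 4, n_reps = 8,
                        iti_s = 6, ready_pecks = 2,
                        pause_range_s = c(2, 4), stim_range_s = c(1.5, 3),
                        analysis_window_s = 0.5, rng_seed = NULL) {
  cfg <- list(
    n_groupings = check_count(n_groupings, "n_groupings", min = 2L),
    n_exemplars = check_count(n_exemplars, "n_exemplars"),
    n_reps = check_count(n_reps, "n_reps"),
    iti_s = check_number(iti_s, "iti_s", lower = 0, strict = TRUE),
    ready_pecks = check_count(ready_pecks, "ready_pecks", min = 0L),
    pause_range_s = check_range(pause_range_s, "pause_range_s"),
    stim_range_s = check_range(stim_range_s, "stim_range_s"),
    analysis_window_s = check_number(analysis_window_s, "analysis_window_s",
                                     lower = 0, strict = TRUE),
    rng_seed = if (is.null(rng_seed)) NULL else check_count(rng_seed, "rng_seed", min = 0L)
  )
  if (cfg$analysis_window_s > cfg$iti_s) {
    abort("`analysis_window_s` cannot exceed `iti_s` (baseline window lives in the ITI).")
  }
  structure(cfg, class = "task_config")
}

#' @rdname task_config
#' @param x A `task_config`.
#' @export
n_trials <- function(x) {
  stopifnot(inherits(x, "task_config"))
  x$n_groupings * x$n_exemplars * x$n_reps
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  %d groupings x %d exemplars x %d reps = %d trials\n",
              x$n_groupings, x$n_exemplars, x$n_reps, n_trials(x)))
  cat(sprintf("  pause %g-%g s, stimulus %g-%g s, ITI %g s, analysis window %g s\n",
              x$pause_range_s[1], x$pause_range_s[2],
              x$stim_range_s[1], x$stim_range_s[2],
              x$iti_s, x$analysis_window_s))
  invisible(x)
}

#' Generative description of a simulated neuron
#'
#' A neuron is characterised by its baseline firing rate, its response class
#' (excitatory, inhibitory or nonresponsive, expressed as a multiplicative
#' stimulus gain), an optional preferred stimulus grouping with a target
#' selectivity index, and a multiplicative pause-period gain modelling
#' activity during the pre-stimulus response-inhibition epoch.
#'
#' @param response_class One of `"excitatory"`, `"inhibitory"`,
#'   `"nonresponsive"`. Must be consistent with `stim_gain` (> 1, < 1 and
#'   = 1 respectively).
#' @param baseline_rate_hz Baseline firing rate, spikes/s; must be positive.
#' @param stim_gain Multiplicative rate change during the stimulus window for
#'   non-preferred groupings.
#' @param preferred_grouping Integer index of the preferred grouping, or `NA`
#'   for an untuned neuron.
#' @param target_si Planted selectivity index in `[0, 1)`; only meaningful
#'   when `preferred_grouping` is set. The preferred-grouping stimulus rate is
#'   solved from the SI definition, see [plant_selectivity()].
#' @param pause_gain Multiplicative rate change during the pause period.
#'
#' @return An object of class `neuron_profile`.
#' @examples
#' neuron_profile("excitatory", baseline_rate_hz = 5, stim_gain = 2,
#'                preferred_grouping = 3, target_si = 0.5)
#' @export
neuron_profile <- function(response_class = c("excitatory", "inhibitory", "nonresponsive"),
                           baseline_rate_hz = 10, stim_gain = NULL,
                           preferred_grouping = NA_integer_, target_si = 0,
                           pause_gain = 1) {
  response_class <- match.arg(response_class)
  if (is.null(stim_gain)) {
    stim_gain <- switch(response_class, excitatory = 2, inhibitory = 0.5, nonresponsive = 1)
  }
  check_number(baseline_rate_hz, "baseline_rate_hz", lower = 0, strict = TRUE)
  check_number(stim_gain, "stim_gain", lower = 0, strict = TRUE)
  check_number(pause_gain, "pause_gain", lower = 0, strict = TRUE)
  ok <- switch(response_class,
    excitatory = stim_gain > 1,
    inhibitory = stim_gain < 1,
    nonresponsive = stim_gain == 1
  )
  if (!ok) {
    abort(sprintf("`stim_gain` = %g is inconsistent with response class '%s'.",
                  stim_gain, response_class))
  }
  if (!is.na(preferred_grouping)) {
    preferred_grouping <- check_count(preferred_grouping, "preferred_grouping")
    check_number(target_si, "target_si", lower = 0, upper = 1)
    if (target_si >= 1) {
      abort("`target_si` must be < 1: an SI of 1 needs a zero rate, unreachable with positive rates.")
    }
  } else if (!identical(target_si, 0) && !isTRUE(all.equal(target_si, 0))) {
    abort("`target_si` requires `preferred_grouping` to be set.")
  }
  structure(
    list(response_class = response_class, baseline_rate_hz = baseline_rate_hz,
         stim_gain = stim_gain, preferred_grouping = preferred_grouping,
         target_si = target_si, pause_gain = pause_gain),
    class = "neuron_profile"
  )
}

#' @export
print.neuron_profile <- function(x, ...) {
  pref <- if (is.na(x$preferred_grouping)) "untuned" else
    sprintf("prefers grouping %d at SI %.2f", x$preferred_grouping, x$target_si)
  cat(sprintf("<neuron_profile> %s, baseline %g Hz, stim gain %g, pause gain %g, %s\n",
              x$response_class, x$baseline_rate_hz, x$stim_gain, x$pause_gain, pref))
  invisible(x)
}

#' Per-grouping stimulus rates implied by a planted selectivity index
#'
#' Inverts the selectivity-index definition
#' \eqn{SI = (P - O)/(P + O)} (signs swapped for inhibitory neurons, where the
#' preferred grouping is the most suppressed one) to obtain the stimulus-window
#' Poisson rate of the preferred grouping, given that every other grouping
#' fires at `baseline_rate_hz * stim_gain`.
#'
#' For an excitatory neuron \eqn{P = O (1 + s) / (1 - s)}; for an inhibitory
#' neuron \eqn{P = O (1 - s) / (1 + s)}. An SI of 1/3 therefore corresponds to
#' a 2:1 rate ratio between the preferred and non-preferred groupings.
#'
#' @param profile A [neuron_profile()] with `preferred_grouping` set.
#' @param n_groupings Number of stimulus groupings. Default 5.
#'
#' @return A tibble with one row per grouping: `grouping` (integer),
#'   `stim_rate_hz`, `preferred` (logical).
#' @examples
#' p <- neuron_profile("excitatory", baseline_rate_hz = 5, stim_gain = 2,
#'                     preferred_grouping = 1, target_si = 1 / 3)
#' plant_selectivity(p) # preferred rate 20 Hz, others 10 Hz
#' @export
plant_selectivity <- function(profile, n_groupings = 5) {
  stopifnot(inherits(profile, "neuron_profile"))
  n_groupings <- check_count(n_groupings, "n_groupings", min = 2L)
  r_other <- profile$baseline_rate_hz * profile$stim_gain
  rates <- rep(r_other, n_groupings)
  pref <- profile$preferred_grouping
  if (!is.na(pref)) {
    if (pref > n_groupings) abort("`preferred_grouping` exceeds `n_groupings`.")
    s <- profile$target_si
    if (s >= 1) abort("`target_si` must be < 1.")
    rates[pref] <- if (profile$response_class == "inhibitory") {
      r_other * (1 - s) / (1 + s)
    } else {
      r_other * (1 + s) / (1 - s)
    }
  }
  tibble::tibble(
    grouping = seq_len(n_groupings),
    stim_rate_hz = rates,
    preferred = seq_len(n_groupings) == (pref %||% 0L) & !is.na(pref)
  )
}

#' Build a tibble of neuron profiles for a simulated region
#'
#' Convenience constructor for populations: draws response classes with given
#' proportions and optionally tunes a fraction of the responsive neurons to a
#' preferred grouping (assigned round-robin across groupings).
#'
#' @param n Number of neurons.
#' @param p_excitatory,p_inhibitory Proportions of excitatory / inhibitory
#'   neurons (the remainder is nonresponsive).
#' @param p_tuned Fraction of responsive neurons given a preferred grouping.
#' @param target_si Planted selectivity index for the tuned neurons.
#' @param baseline_range_hz Uniform range for per-neuron baseline rates.
#' @param excitatory_gain,inhibitory_gain Stimulus gains per class.
#' @param p_pause_active Fraction of neurons given pause-period modulation.
#' @param pause_gain Pause gain applied to pause-active neurons.
#' @param n_groupings Number of stimulus groupings.
#' @param seed Optional integer seed.
#'
#' @return A list of [neuron_profile()] objects of length `n`.
#' @export
sample_profiles <- function(n, p_excitatory = 0.4, p_inhibitory = 0.2,
                            p_tuned = 0, target_si = 0.5,
                            baseline_range_hz = c(4, 12),
                            excitatory_gain = 2, inhibitory_gain = 0.5,
                            p_pause_active = 0, pause_gain = 2,
                            n_groupings = 5, seed = NULL) {
  n <- check_count(n, "n")
  stopifnot(p_excitatory + p_inhibitory <= 1)
  with_seed_if(seed, {
    classes <- sample(c("excitatory", "inhibitory", "nonresponsive"), n, replace = TRUE,
                      prob = c(p_excitatory, p_inhibitory, 1 - p_excitatory - p_inhibitory))
    base <- runif(n, baseline_range_hz[1], baseline_range_hz[2])
    responsive <- which(classes != "nonresponsive")
    tuned <- responsive[runif(length(responsive)) < p_tuned]
    prefs <- rep(NA_integer_, n)
    if (length(tuned)) prefs[tuned] <- rep_len(seq_len(n_groupings), length(tuned))
    pause_on <- runif(n) < p_pause_active
    purrr::map(seq_len(n), function(i) {
      neuron_profile(
        response_class = classes[i],
        baseline_rate_hz = base[i],
        stim_gain = switch(classes[i], excitatory = excitatory_gain,
                           inhibitory = inhibitory_gain, nonresponsive = 1),
        preferred_grouping = prefs[i],
        target_si = if (is.na(prefs[i])) 0 else target_si,
        pause_gain = if (pause_on[i]) pause_gain else 1
      )
    })
  })
}
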