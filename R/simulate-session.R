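#' Simulate a recording session
#'
#' Generates per-trial firing rates for a set of simulated neurons under the
#' response-inhibition task. The trial schedule (stimulus order, pause and
#' stimulus durations) is drawn once per session and shared across neurons;
#' spike counts are independent homogeneous-Poisson draws per neuron and
#' period, at rate `baseline_rate_hz` in the ITI baseline window, scaled by
#' `pause_gain` in the pause window, and by the grouping-dependent stimulus
#' rate (see [plant_selectivity()]) in the post-onset analysis window.
#' Rates are reported in spikes/s (count divided by the window length).
#'
#' @param neurons A single [neuron_profile()] or a list of them.
#' @param task A [task_config()].
#' @param seed Integer seed; defaults to `task$rng_seed`. The same
#'   (config, neurons, seed) triple always yields a bit-identical table.
#'
#' @return A tibble with one row per neuron and trial:
#'   `neuron_id`, `trial_index`, `image_id`, `grouping`, `pause_dur_s`,
#'   `stim_dur_s`, `rate_baseline_hz`, `rate_pause_hz`, `rate_stim_hz`.
#'   Each `image_id` appears exactly `n_reps` times per neuron.
#' @examples
#' trials <- simulate_session(neuron_profile("excitatory"), task_config(), seed = 1)
#' nrow(trials) # 160
#' @export
simulate_session <- function(neurons, task = task_config(), seed = task$rng_seed) {
  stopifnot(inherits(task, "task_config"))
  if (inherits(neurons, "neuron_profile")) neurons <- list(neurons)
  if (!length(neurons) || !all(purrr::map_lgl(neurons, inherits, "neuron_profile"))) {
    abort("`neurons` must be one or more `neuron_profile` objects.")
  }
  ids <- names(neurons) %||% sprintf("n%03d", seq_along(neurons))
  if (is.null(names(neurons))) names(neurons) <- ids

  with_seed_if(seed, {
    schedule <- trial_schedule(task)
    purrr::imap_dfr(neurons, function(prof, id) {
      rates <- plant_selectivity(prof, task$n_groupings)
      stim_rate <- rates$stim_rate_hz[schedule$grouping_idx]
      w <- task$analysis_window_s
      dplyr::mutate(
        schedule,
        neuron_id = id,
        rate_baseline_hz = rpois(dplyr::n(), prof$baseline_rate_hz * w) / w,
        rate_pause_hz = rpois(dplyr::n(), prof$baseline_rate_hz * prof$pause_gain *
                                .data$pause_dur_s) / .data$pause_dur_s,
        rate_stim_hz = rpois(dplyr::n(), stim_rate * w) / w
      )
    }) |>
      dplyr::select("neuron_id", "trial_index", "image_id", "grouping",
                    "pause_dur_s", "stim_dur_s",
                    "rate_baseline_hz", "rate_pause_hz", "rate_stim_hz")
  })
}

# randomised presentation order + per-trial period durations, shared by all
# neurons in the session
trial_schedule <- function(task) {
  n <- n_trials(task)
  images <- tidyr::expand_grid(
    grouping_idx = seq_len(task$n_groupings),
    exemplar = seq_len(task$n_exemplars)
  ) |>
    dplyr::mutate(image_id = sprintf("g%d_e%d", .data$grouping_idx, .data$exemplar))
  order <- sample(rep(seq_len(nrow(images)), task$n_reps))
  tibble::tibble(
    trial_index = seq_len(n),
    image_id = images$image_id[order],
    grouping_idx = images$grouping_idx[order],
    grouping = grouping_labels(task$n_groupings)[images$grouping_idx[order]],
    pause_dur_s = runif(n, task$pause_range_s[1], task$pause_range_s[2]),
    stim_dur_s = runif(n, task$stim_range_s[1], task$stim_range_s[2])
  )
}

#' Read or write a session trial table
#'
#' Sessions are stored as plain CSV in the schema produced by
#' [simulate_session()], with an optional JSON sidecar echoing the task
#' configuration and seed.
#'
#' @param trials A session tibble.
#' @param path CSV file path.
#' @param task Optional [task_config()] echoed into `<path>.json`.
#' @param seed Optional seed echoed into the sidecar.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the session tibble.
#' @export
write_session <- function(trials, path, task = NULL, seed = NULL) {
  readr::write_csv(trials, path)
  if (!is.null(task)) {
    meta <- unclass(task)
    meta$rng_seed <- seed %||% meta$rng_seed
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    neuron_id = readr::col_character(),
                    image_id = readr::col_character(),
                    grouping = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
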