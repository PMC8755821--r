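#' Pipeline configuration
#'
#' Bundles everything needed for an end-to-end run: the task structure, a
#' population specification per simulated region-like group, analysis alphas,
#' decoding resamples, stimulus-image options and the global seed.
#'
#' @param task A [task_config()].
#' @param regions Named list; each element is a list of arguments for
#'   [sample_profiles()] (at minimum `n`). Region names label the outputs.
#' @param alpha Significance level shared by the responsiveness and
#'   selectivity screens.
#' @param n_resamples Decoding resamples per condition.
#' @param chance_neurons Neurons in the chance-level simulation (one per
#'   visually-responsive neuron of the largest region by convention).
#' @param image_size,grating_freqs,scramble_grid Stimulus-set options, see
#'   [make_stimulus_set()].
#' @param seed Global integer seed (mandatory: every stage derives its
#'   randomness from it).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(task = task_config(),
                            regions = list(
                              Wulst = list(n = 96, p_excitatory = 0.27, p_inhibitory = 0.26,
                                           p_tuned = 0.08, p_pause_active = 0.27),
                              ENTO = list(n = 140, p_excitatory = 0.25, p_inhibitory = 0.38,
                                          p_tuned = 0.11, p_pause_active = 0.41),
                              MVL = list(n = 120, p_excitatory = 0.48, p_inhibitory = 0.16,
                                         p_tuned = 0.29, p_pause_active = 0.28)
                            ),
                            alpha = 0.05, n_resamples = 1200, chance_neurons = 77,
                            image_size = 480, grating_freqs = c(2, 4, 8, 16),
                            scramble_grid = c(15, 32), seed = 1) {
  stopifnot(inherits(task, "task_config"))
  if (!length(regions) || is.null(names(regions)) || any(names(regions) == "")) {
    abort("`regions` must be a non-empty named list.")
  }
  for (r in regions) {
    if (is.null(r$n) || r$n < 1) abort("Every region needs a positive neuron count `n`.")
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(task = task, regions = regions, alpha = alpha,
         n_resamples = check_count(n_resamples, "n_resamples"),
         chance_neurons = check_count(chance_neurons, "chance_neurons"),
         image_size = image_size, grating_freqs = grating_freqs,
         scramble_grid = scramble_grid, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on synthetic data: session simulation per region,
#' responsiveness typing and time courses, selectivity (ANOVA + Tukey + SI)
#' with the chance-level simulation, between-region chi-square comparisons,
#' pseudo-population decoding of the visually-responsive neurons, and
#' spectral characterisation of the stimulus set. Fully deterministic given
#' the config seed. When `out_dir` is given, per-stage CSV/JSON artifacts are
#' written there.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param decode If `FALSE`, the (comparatively slow) decoding stage is
#'   skipped.
#' @return A named list report: `sessions`, `responsiveness`, `timecourses`,
#'   `selectivity`, `chance`, `proportions`, `chi_square`, `decoding`,
#'   `spectra`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL, decode = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  region_names <- names(cfg$regions)
  base <- cfg$seed

  sessions <- purrr::imap(cfg$regions, function(spec, rn) {
    i <- match(rn, region_names)
    profiles <- rlang::exec(sample_profiles, !!!spec,
                            n_groupings = cfg$task$n_groupings, seed = base + 1000L * i)
    simulate_session(profiles, cfg$task, seed = base + 1000L * i + 1L)
  })

  responsiveness <- purrr::map(sessions, classify_responsiveness, alpha = cfg$alpha)
  timecourses <- purrr::map2(sessions, responsiveness, normalized_timecourse)

  vr_sessions <- purrr::map2(sessions, responsiveness, function(s, r) {
    dplyr::filter(s, .data$neuron_id %in% r$neuron_id[r$visually_responsive])
  })
  selectivity <- purrr::map(vr_sessions, function(s) {
    if (!nrow(s)) return(NULL)
    analyze_selectivity(s, alpha = cfg$alpha)
  })

  chance <- chance_simulation(n_neurons = cfg$chance_neurons,
                              trials_per_grouping = cfg$task$n_exemplars * cfg$task$n_reps,
                              n_groupings = cfg$task$n_groupings,
                              alpha = cfg$alpha, seed = base + 77L)

  counts <- tibble::tibble(
    region = region_names,
    n_neurons = unname(purrr::map_int(responsiveness, nrow)),
    n_responsive = unname(purrr::map_int(responsiveness, ~ sum(.x$visually_responsive))),
    n_excitatory = unname(purrr::map_int(responsiveness, ~ sum(.x$response_sign == "excitatory"))),
    n_inhibitory = unname(purrr::map_int(responsiveness, ~ sum(.x$response_sign == "inhibitory"))),
    n_pause_active = unname(purrr::map_int(responsiveness, ~ sum(.x$pause_active & .x$visually_responsive))),
    n_selective = unname(purrr::map_int(selectivity, ~ if (is.null(.x)) 0L else sum(.x$selective)))
  )
  proportions <- proportion_report(counts$n_responsive, counts$n_neurons, counts$region)

  chi <- list(
    responsive_by_region = pearson_chi_square(
      cbind(counts$n_responsive, counts$n_neurons - counts$n_responsive))
  )
  if (length(region_names) >= 2) {
    pairs <- utils::combn(seq_along(region_names), 2, simplify = FALSE)
    for (p in pairs) {
      nm <- paste(region_names[p], collapse = "_vs_")
      ei <- rbind(c(counts$n_excitatory[p[1]], counts$n_inhibitory[p[1]]),
                  c(counts$n_excitatory[p[2]], counts$n_inhibitory[p[2]]))
      if (all(rowSums(ei) > 0) && all(colSums(ei) > 0)) {
        chi[[paste0("excit_inhib_", nm)]] <- pearson_chi_square(ei)
      }
      pa <- rbind(c(counts$n_pause_active[p[1]], counts$n_responsive[p[1]] - counts$n_pause_active[p[1]]),
                  c(counts$n_pause_active[p[2]], counts$n_responsive[p[2]] - counts$n_pause_active[p[2]]))
      if (all(rowSums(pa) > 0) && all(colSums(pa) > 0)) {
        chi[[paste0("pause_", nm)]] <- pearson_chi_square(pa)
      }
    }
  }
  # observed selective fraction of the largest region vs the chance simulation
  big <- which.max(counts$n_responsive)
  sel_tab <- rbind(c(counts$n_selective[big], counts$n_responsive[big] - counts$n_selective[big]),
                   c(chance$n_significant, chance$n_neurons - chance$n_significant))
  if (all(rowSums(sel_tab) > 0) && all(colSums(sel_tab) > 0)) {
    chi$selective_vs_chance <- pearson_chi_square(sel_tab)
  }

  decoding <- NULL
  if (decode) {
    decoding <- purrr::imap(vr_sessions, function(s, rn) {
      if (dplyr::n_distinct(s$neuron_id) < 2) return(NULL)
      permutation_analysis(s, n_resamples = cfg$n_resamples,
                           seed = base + 500L + match(rn, region_names))
    })
  }

  images <- make_stimulus_set(size = cfg$image_size, grating_freqs = cfg$grating_freqs,
                              grid = cfg$scramble_grid, seed = base + 9L)
  spectra <- spectral_summary(images)

  report <- list(sessions = sessions, responsiveness = responsiveness,
                 timecourses = timecourses, selectivity = selectivity,
                 chance = chance[c("n_significant", "fraction_significant", "n_neurons", "alpha")],
                 counts = counts, proportions = proportions, chi_square = chi,
                 decoding = decoding, spectra = spectra, config = cfg)

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (rn in names(report$sessions)) {
    readr::write_csv(report$sessions[[rn]], file.path(out_dir, paste0("session_", rn, ".csv")))
    readr::write_csv(tibble::as_tibble(report$responsiveness[[rn]]),
                     file.path(out_dir, paste0("responsiveness_", rn, ".csv")))
    if (!is.null(report$selectivity[[rn]])) {
      readr::write_csv(dplyr::select(report$selectivity[[rn]], -"significant_pairs"),
                       file.path(out_dir, paste0("selectivity_", rn, ".csv")))
    }
    if (!is.null(report$decoding[[rn]])) {
      readr::write_csv(report$decoding[[rn]]$summary,
                       file.path(out_dir, paste0("decoding_", rn, ".csv")))
    }
  }
  readr::write_csv(report$counts, file.path(out_dir, "counts.csv"))
  readr::write_csv(report$spectra, file.path(out_dir, "spectra.csv"))
  summary <- list(
    seed = report$config$seed,
    chance = report$chance,
    chi_square = purrr::map(report$chi_square, as.list),
    decoding_p = purrr::map(purrr::compact(report$decoding %||% list()),
                            ~ setNames(as.list(.x$summary$p_value), .x$summary$grouping))
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
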