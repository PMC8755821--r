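#' One-way ANOVA screen for stimulus-grouping selectivity
#'
#' Per neuron, stimulus-window firing rates are compared across the stimulus
#' groupings with a classic fixed-effects one-way ANOVA; a neuron is
#' stimulus-selective when `p < alpha`. Degenerate neurons whose rates are
#' identical on every trial are reported with `F = 0`, `p = 1`.
#'
#' @param trials A session tibble (one or many neurons).
#' @param alpha Significance level. Default 0.05.
#'
#' @return A tibble, one row per neuron: `neuron_id`, `anova_F`, `anova_p`,
#'   `selective`, `n_groupings`, `n_trials`.
#' @export
anova_selectivity <- function(trials, alpha = 0.05) {
  check_number(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  trials |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$grouping) < 2L) {
        abort("At least 2 stimulus groupings are required.")
      }
      if (any(table(d$grouping) < 2L)) {
        abort("At least 2 trials per grouping are required.")
      }
      if (var(d$rate_stim_hz) == 0) {
        f <- 0; p <- 1
      } else {
        ow <- oneway.test(rate_stim_hz ~ grouping, data = d, var.equal = TRUE)
        f <- unname(ow$statistic); p <- ow$p.value
      }
      tibble::tibble(anova_F = f, anova_p = p, selective = p < alpha,
                     n_groupings = dplyr::n_distinct(d$grouping), n_trials = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Preferred stimulus grouping by Tukey HSD post hoc
#'
#' For a stimulus-selective neuron, all pairwise grouping contrasts are tested
#' with Tukey's Honest Significant Difference. The preferred grouping is the
#' one whose mean stimulus rate deviates most from the neuron's baseline mean
#' (maximum rate for excitatory deviations, minimum for inhibitory ones, i.e.
#' largest absolute deviation), and it must take part in at least one
#' significant pairwise contrast; otherwise the preference is ambiguous and
#' `NA` is returned.
#'
#' @param trials Session tibble for a single neuron.
#' @param alpha Significance level for the Tukey family-wise test.
#'
#' @return A one-row tibble: `preferred_grouping`, `preferred_sign`
#'   (`"excitatory"` if the preferred mean lies above baseline), `pref_mean`,
#'   `other_mean`, `n_significant_pairs`, and a list-column
#'   `significant_pairs` of the significant grouping pairs.
#' @export
preferred_grouping <- function(trials, alpha = 0.05) {
  stopifnot(dplyr::n_distinct(trials$neuron_id) == 1L)
  means <- trials |>
    dplyr::group_by(.data$grouping) |>
    dplyr::summarise(mean_rate = mean(.data$rate_stim_hz), .groups = "drop")
  base_mu <- mean(trials$rate_baseline_hz)

  fit <- aov(rate_stim_hz ~ grouping, data = dplyr::mutate(trials, grouping = factor(.data$grouping)))
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$grouping
  sig <- rownames(tk)[tk[, "p adj"] < alpha]
  sig_pairs <- strsplit(sig, "-", fixed = TRUE)

  dev <- abs(means$mean_rate - base_mu)
  top <- which.max(dev)
  in_sig <- function(g) any(purrr::map_lgl(sig_pairs, ~ g %in% .x))
  # a tied extreme deviation has no single winner; an extreme grouping that
  # takes part in no significant contrast is not a defensible preference
  pref <- NA_character_
  if (sum(dev == dev[top]) == 1L && in_sig(means$grouping[top])) {
    pref <- means$grouping[top]
  }
  pref_mean <- if (is.na(pref)) NA_real_ else means$mean_rate[means$grouping == pref]
  other_mean <- if (is.na(pref)) NA_real_ else mean(means$mean_rate[means$grouping != pref])
  tibble::tibble(
    neuron_id = trials$neuron_id[1],
    preferred_grouping = pref,
    preferred_sign = if (is.na(pref)) NA_character_ else
      if (pref_mean >= base_mu) "excitatory" else "inhibitory",
    pref_mean = pref_mean,
    other_mean = other_mean,
    n_significant_pairs = length(sig_pairs),
    significant_pairs = list(sig_pairs)
  )
}

#' Selectivity index
#'
#' Contrast ratio of the mean response to the preferred stimulus grouping
#' (`P`) against the mean of the other groupings' means (`O`):
#' excitatory \eqn{SI = (P - O)/(P + O)}, inhibitory \eqn{SI = (O - P)/(O + P)}.
#' An SI of 0.33 corresponds to a 2:1 preferred-to-other rate ratio. Computed
#' on raw window rates; negative values (preferred direction violated) are
#' clipped to 0.
#'
#' @param pref_mean Mean rate for the preferred grouping, spikes/s.
#' @param other_means Mean rates of the remaining groupings (their mean is
#'   used), spikes/s.
#' @param sign `"excitatory"` or `"inhibitory"`.
#'
#' @return SI in `[0, 1]`.
#' @examples
#' selectivity_index(20, rep(10, 4)) # 1/3
#' @export
selectivity_index <- function(pref_mean, other_means, sign = c("excitatory", "inhibitory")) {
  sign <- match.arg(sign)
  check_number(pref_mean, "pref_mean", lower = 0)
  if (!is.numeric(other_means) || !length(other_means) || any(other_means < 0)) {
    abort("`other_means` must be non-negative rates.")
  }
  o <- mean(other_means)
  if (pref_mean + o == 0) abort("Undefined SI: preferred and other rates are both zero.")
  si <- (pref_mean - o) / (pref_mean + o)
  if (sign == "inhibitory") si <- -si
  max(si, 0)
}

#' Full per-neuron selectivity analysis
#'
#' Chains [anova_selectivity()], [preferred_grouping()] and
#' [selectivity_index()]: selective neurons get a Tukey-backed preferred
#' grouping and an SI; non-selective neurons carry `NA`s.
#'
#' @inheritParams anova_selectivity
#' @return A tibble of class `selectivity_result`, one row per neuron, with
#'   ANOVA, preference and `si` columns.
#' @export
analyze_selectivity <- function(trials, alpha = 0.05) {
  an <- anova_selectivity(trials, alpha = alpha)
  prefs <- trials |>
    dplyr::filter(.data$neuron_id %in% an$neuron_id[an$selective]) |>
    dplyr::group_split(.data$neuron_id) |>
    purrr::map_dfr(preferred_grouping, alpha = alpha)
  if (!nrow(prefs)) {
    prefs <- tibble::tibble(
      neuron_id = character(), preferred_grouping = character(),
      preferred_sign = character(), pref_mean = double(), other_mean = double(),
      n_significant_pairs = integer(), significant_pairs = list()
    )
  }
  res <- an |>
    dplyr::left_join(prefs, by = "neuron_id") |>
    dplyr::mutate(
      si = purrr::pmap_dbl(
        list(.data$pref_mean, .data$other_mean, .data$preferred_sign),
        function(p, o, s) if (is.na(p)) NA_real_ else selectivity_index(p, o, s)
      )
    )
  class(res) <- c("selectivity_result", class(res))
  attr(res, "alpha") <- alpha
  res
}

#' @exportS3Method generics::glance
glance.selectivity_result <- function(x, ...) {
  tibble::tibble(
    n_neurons = nrow(x),
    n_selective = sum(x$selective),
    prop_selective = mean(x$selective),
    mean_si = mean(x$si, na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}

#' Chance-level simulation for the selectivity screen
#'
#' Estimates how many neurons the ANOVA screen flags by chance alone: for each
#' simulated neuron, per-trial firing rates are drawn i.i.d. uniformly between
#' that neuron's minimum and maximum rate for every stimulus grouping (so no
#' grouping carries information), and the same one-way ANOVA is applied.
#'
#' @param n_neurons Number of simulated neurons. Default 77.
#' @param rate_min,rate_max Per-neuron rate bounds in spikes/s; scalars are
#'   recycled, or supply length-`n_neurons` vectors for neuron-specific ranges.
#' @param trials_per_grouping Trials per grouping per neuron. Default 32
#'   (8 presentations of each of 4 exemplars).
#' @param n_groupings Number of groupings. Default 5.
#' @param alpha Significance level. Default 0.05.
#' @param seed Optional integer seed.
#'
#' @return A list with `per_neuron` (tibble of F and p), `n_significant`,
#'   `fraction_significant`, and the config echo.
#' @export
chance_simulation <- function(n_neurons = 77, rate_min = 0, rate_max = 20,
                              trials_per_grouping = 32, n_groupings = 5,
                              alpha = 0.05, seed = NULL) {
  n_neurons <- check_count(n_neurons, "n_neurons")
  trials_per_grouping <- check_count(trials_per_grouping, "trials_per_grouping", min = 2L)
  n_groupings <- check_count(n_groupings, "n_groupings", min = 2L)
  rate_min <- rep_len(rate_min, n_neurons)
  rate_max <- rep_len(rate_max, n_neurons)
  if (any(rate_min > rate_max) || any(rate_min < 0)) {
    abort("`rate_min` must be >= 0 and <= `rate_max` for every neuron.")
  }
  if (all(rate_min == rate_max)) {
    warn("All rate ranges are degenerate: every F is undefined, fraction 0.")
    return(list(per_neuron = tibble::tibble(neuron = seq_len(n_neurons),
                                            anova_F = NA_real_, anova_p = NA_real_,
                                            selective = FALSE),
                n_significant = 0L, fraction_significant = 0,
                alpha = alpha, n_neurons = n_neurons))
  }
  grp <- factor(rep(seq_len(n_groupings), each = trials_per_grouping))
  per_neuron <- with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_neurons), function(i) {
      rates <- runif(length(grp), rate_min[i], rate_max[i])
      if (var(rates) == 0) return(tibble::tibble(neuron = i, anova_F = 0,
                                                 anova_p = 1, selective = FALSE))
      ow <- oneway.test(rates ~ grp, var.equal = TRUE)
      tibble::tibble(neuron = i, anova_F = unname(ow$statistic),
                     anova_p = ow$p.value, selective = ow$p.value < alpha)
    })
  })
  list(per_neuron = per_neuron,
       n_significant = sum(per_neuron$selective),
       fraction_significant = mean(per_neuron$selective),
       alpha = alpha, n_neurons = n_neurons)
}

#' Population comparison of responses to scrambled versus original images
#'
#' Two-tailed paired t-test, across visually-responsive neurons, of each
#' neuron's mean stimulus-window rate for the scrambled groupings against its
#' mean rate for the original (unscrambled) image groupings.
#'
#' @param neuron_means A tibble with one row per neuron and columns
#'   `scrambled_mean` and `original_mean` (spikes/s).
#'
#' @return A one-row tibble: condition means, `t_statistic`, `df`, `p_value`,
#'   `mean_difference` (scrambled minus original), `n_neurons`.
#' @export
scrambled_vs_original <- function(neuron_means) {
  if (!all(c("scrambled_mean", "original_mean") %in% names(neuron_means))) {
    abort("`neuron_means` needs `scrambled_mean` and `original_mean` columns.")
  }
  if (nrow(neuron_means) < 2L) abort("At least 2 neurons are required.")
  d <- neuron_means$scrambled_mean - neuron_means$original_mean
  if (sd(d) <= 1e-10 * max(abs(mean(d)), 1)) {
    # every neuron shifted by the same amount: no within-pair variance
    return(tibble::tibble(
      scrambled_mean = mean(neuron_means$scrambled_mean),
      original_mean = mean(neuron_means$original_mean),
      mean_difference = mean(d),
      t_statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
      df = nrow(neuron_means) - 1L,
      p_value = if (mean(d) == 0) 1 else 0,
      n_neurons = nrow(neuron_means)
    ))
  }
  tt <- t.test(neuron_means$scrambled_mean, neuron_means$original_mean, paired = TRUE)
  tibble::tibble(
    scrambled_mean = mean(neuron_means$scrambled_mean),
    original_mean = mean(neuron_means$original_mean),
    mean_difference = mean(d),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n_neurons = nrow(neuron_means)
  )
}
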