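# shared fixture builders; everything is generated in code under fixed seeds

# population of category-tuned excitatory neurons, preferred groupings
# assigned round-robin
tuned_population <- function(n, si, baseline = 10, gain = 2, n_groupings = 5) {
  lapply(seq_len(n), function(i) {
    neuron_profile("excitatory", baseline_rate_hz = baseline, stim_gain = gain,
                   preferred_grouping = ((i - 1) %% n_groupings) + 1,
                   target_si = si)
  })
}

untuned_population <- function(n, baseline = 8) {
  lapply(seq_len(n), function(i) neuron_profile("nonresponsive", baseline))
}

# trial table for neurons tuned to exactly one exemplar image (not to its
# grouping): grouping information does not transfer across exemplars
exemplar_tuned_trials <- function(n_groupings = 5, n_exemplars = 4, reps = 8,
                                  seed = 1) {
  withr::with_seed(seed, {
    images <- expand.grid(g = seq_len(n_groupings), e = seq_len(n_exemplars))
    images$image_id <- sprintf("g%d_e%d", images$g, images$e)
    neurons <- sprintf("n%02d", seq_len(nrow(images)))
    do.call(rbind, lapply(seq_along(neurons), function(i) {
      do.call(rbind, lapply(seq_len(nrow(images)), function(j) {
        rate <- if (i == j) 40 else 10
        data.frame(
          neuron_id = neurons[i],
          image_id = images$image_id[j],
          grouping = sprintf("G%02d", images$g[j]),
          rate_stim_hz = rpois(reps, rate * 0.5) / 0.5,
          rate_baseline_hz = rpois(reps, 10 * 0.5) / 0.5
        )
      }))
    })) |> tibble::as_tibble()
  })
}
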