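test_that("default task emits the full balanced trial structure", {
  task <- task_config()
  expect_equal(n_trials(task), 160)
  trials <- simulate_session(neuron_profile("nonresponsive"), task, seed = 11)
  expect_equal(nrow(trials), 160)
  expect_true(all(table(trials$image_id) == 8))
  expect_equal(dplyr::n_distinct(trials$image_id), 20)
  expect_true(all(trials$pause_dur_s >= 2 & trials$pause_dur_s <= 4))
  expect_true(all(trials$stim_dur_s >= 1.5 & trials$stim_dur_s <= 3))
  expect_true(all(trials$rate_baseline_hz >= 0))
  # image ids encode their grouping consistently
  expect_true(all(sub("^g(\\d+)_.*$", "G0\\1", trials$image_id) == trials$grouping))
})

test_that("trial-count conservation holds for non-default shapes", {
  for (dims in list(c(2, 3, 5), c(4, 2, 2), c(5, 4, 8))) {
    task <- task_config(n_groupings = dims[1], n_exemplars = dims[2], n_reps = dims[3])
    trials <- simulate_session(neuron_profile("excitatory"), task, seed = 3)
    expect_equal(nrow(trials), prod(dims))
    expect_true(all(table(trials$image_id) == dims[3]))
  }
})

test_that("identical config, profiles and seed reproduce bit-identical tables", {
  profs <- tuned_population(4, si = 0.4)
  a <- simulate_session(profs, task_config(), seed = 21)
  b <- simulate_session(profs, task_config(), seed = 21)
  expect_identical(a, b)
  c <- simulate_session(profs, task_config(), seed = 22)
  expect_false(identical(a, c))
})

test_that("planted selectivity inverts the SI definition", {
  # SI 1/3 corresponds to a 2:1 preferred:other rate ratio
  p <- neuron_profile("excitatory", baseline_rate_hz = 5, stim_gain = 2,
                      preferred_grouping = 1, target_si = 1 / 3)
  r <- plant_selectivity(p)
  expect_equal(r$stim_rate_hz[1], 20, tolerance = 1e-12)
  expect_equal(r$stim_rate_hz[-1], rep(10, 4))
  # (P - 10)/(P + 10) = 0.5 gives P = 30
  p2 <- neuron_profile("excitatory", baseline_rate_hz = 5, stim_gain = 2,
                       preferred_grouping = 2, target_si = 0.5)
  expect_equal(plant_selectivity(p2)$stim_rate_hz[2], 30)
  # zero selectivity keeps rates flat
  p3 <- neuron_profile("excitatory", baseline_rate_hz = 5, stim_gain = 2,
                       preferred_grouping = 1, target_si = 0)
  expect_true(all(plant_selectivity(p3)$stim_rate_hz == 10))
  # inhibitory neurons are suppressed most by their preferred grouping
  p4 <- neuron_profile("inhibitory", baseline_rate_hz = 20, stim_gain = 0.5,
                       preferred_grouping = 3, target_si = 1 / 3)
  r4 <- plant_selectivity(p4)
  expect_equal(r4$stim_rate_hz[3], 5)
  expect_equal(r4$stim_rate_hz[-3], rep(10, 4))
})

test_that("invalid profiles and configs are rejected", {
  expect_error(neuron_profile("excitatory", baseline_rate_hz = 0), "baseline")
  expect_error(neuron_profile("excitatory", stim_gain = 0.5), "inconsistent")
  expect_error(neuron_profile("inhibitory", stim_gain = 2), "inconsistent")
  expect_error(neuron_profile("excitatory", preferred_grouping = 1, target_si = 1))
  expect_error(task_config(n_reps = 0), "n_reps")
  expect_error(task_config(pause_range_s = c(4, 2)), "pause_range_s")
  expect_error(simulate_session(list(), task_config()), "neuron_profile")
})

test_that("a nonresponsive neuron fires at baseline during the stimulus", {
  task <- task_config(n_groupings = 5, n_exemplars = 4, n_reps = 125) # 10000 trials
  trials <- simulate_session(neuron_profile("nonresponsive", baseline_rate_hz = 10),
                             task, seed = 31)
  diff <- mean(trials$rate_stim_hz) - mean(trials$rate_baseline_hz)
  se <- sqrt(var(trials$rate_stim_hz) / nrow(trials) +
               var(trials$rate_baseline_hz) / nrow(trials))
  expect_lt(abs(diff), 2 * se)
})

test_that("planted SI is recovered empirically (spot check)", {
  # the unbiasedness sweep (200 replicates x 3 SI levels, 3-SE bound) runs in
  # the acceptance suite; here a batch of 50 sessions just has to land close
  si <- sapply(seq_len(50), function(i) {
    tr <- simulate_session(
      neuron_profile("excitatory", 10, 2, preferred_grouping = 1, target_si = 0.33),
      task_config(), seed = 700 + i
    )
    mu <- tapply(tr$rate_stim_hz, tr$grouping, mean)
    selectivity_index(mu[["G01"]], mu[names(mu) != "G01"])
  })
  expect_lt(abs(mean(si) - 0.33), 0.02)
  expect_lt(sd(si), 0.05)
})

test_that("session round-trips through CSV with metadata sidecar", {
  tmp <- withr::local_tempdir()
  trials <- simulate_session(tuned_population(2, 0.3), task_config(), seed = 41)
  path <- file.path(tmp, "session.csv")
  write_session(trials, path, task = task_config(), seed = 41)
  back <- read_session(path)
  expect_equal(as.data.frame(back), as.data.frame(trials))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$rng_seed, 41)
  expect_equal(meta$n_groupings, 5)
})
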