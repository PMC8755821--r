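test_that("pseudo-population assembly counts, balances and reproduces", {
  trials <- simulate_session(
    list(a = neuron_profile("excitatory"), b = neuron_profile("inhibitory")),
    task_config(n_groupings = 2, n_exemplars = 3, n_reps = 1), seed = 71
  )
  pop <- build_pseudopopulation(trials, seed = 1)
  expect_equal(dim(pop$x), c(6, 2))
  expect_equal(as.vector(table(pop$grouping)), c(3, 3))
  # determinism
  pop2 <- build_pseudopopulation(trials, seed = 1)
  expect_identical(pop$x, pop2$x)
  # the shuffle leaves each neuron's per-grouping rate multiset unchanged
  for (g in levels(pop$grouping)) {
    expect_equal(sort(pop$x[pop$grouping == g, "a"]),
                 sort(trials$rate_stim_hz[trials$neuron_id == "a" & trials$grouping == g]))
  }
})

test_that("neurons missing a grouping are excluded with a warning", {
  trials <- simulate_session(
    list(a = neuron_profile("excitatory"), b = neuron_profile("excitatory")),
    task_config(), seed = 72
  )
  trials <- trials[!(trials$neuron_id == "b" & trials$grouping == "G03"), ]
  expect_warning(pop <- build_pseudopopulation(trials, seed = 1), "zero trials")
  expect_equal(pop$neuron_ids, "a")
})

test_that("a perfectly separable neuron decodes at ceiling, an uninformative population at chance", {
  # one neuron, two groupings, non-overlapping rate distributions
  sep <- withr::with_seed(70, tibble::tibble(
    neuron_id = "a",
    grouping = rep(c("G01", "G02"), each = 16),
    rate_stim_hz = c(rnorm(16, 100, 1), rnorm(16, 5, 1))
  ))
  perf <- decode_once(build_pseudopopulation(sep, seed = 2), seed = 3)
  expect_equal(perf$auc, c(1, 1), ignore_attr = TRUE)
  # untuned population: mean AUC near chance over resamples
  profs <- untuned_population(8)
  names(profs) <- sprintf("n%02d", 1:8)
  trials <- simulate_session(profs, task_config(), seed = 73)
  idx <- sapply(1:40, function(i) {
    decode_once(build_pseudopopulation(trials, seed = 100 + i), seed = 200 + i)$auc
  })
  expect_lt(abs(mean(idx) - 0.5), 0.05)
})

test_that("rank-statistic ROC areas agree with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(74, {
    for (i in 1:5) {
      scores <- rnorm(60)
      labels <- sample(c(TRUE, FALSE), 60, replace = TRUE)
      ours <- vispop:::auc_rank(scores, labels)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = labels, predictor = scores,
        levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
      )))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("permutation analysis is deterministic and its p-values use the add-one rule", {
  profs <- tuned_population(10, si = 0.5)
  names(profs) <- sprintf("n%02d", 1:10)
  trials <- simulate_session(profs, task_config(n_reps = 4), seed = 75)
  a <- permutation_analysis(trials, n_resamples = 120, seed = 76)
  b <- permutation_analysis(trials, n_resamples = 120, seed = 76)
  expect_identical(a$summary, b$summary)
  expect_identical(a$performance, b$performance)
  expect_true(all(a$summary$p_value > 0))
  expect_true(all(a$summary$p_value <= 1))
  # strong planted signal: labelled median above every null draw
  expect_equal(a$summary$p_value, rep(1 / 121, 5), tolerance = 1e-12)
  expect_equal(a$summary$p_error, rep(sqrt((1 / 121) * (1 - 1 / 121) / 120), 5),
               tolerance = 1e-12)
  expect_equal(nrow(a$performance), 2 * 120 * 5)
})

test_that("decoding power is monotone in planted selectivity", {
  med <- sapply(c(0, 0.2, 0.5), function(si) {
    profs <- if (si == 0) untuned_population(12, baseline = 10) else
      tuned_population(12, si = si)
    names(profs) <- sprintf("n%02d", 1:12)
    trials <- simulate_session(profs, task_config(n_reps = 4), seed = 77)
    dr <- permutation_analysis(trials, n_resamples = 100, seed = 78)
    median(dr$summary$median_auc)
  })
  expect_true(all(diff(med) > 0))
  expect_lt(abs(med[1] - 0.5), 0.1)
  expect_gt(med[3], 0.9)
})

test_that("grouping-tuned populations generalise to held-out exemplars, exemplar-tuned ones do not", {
  profs <- tuned_population(10, si = 0.5)
  names(profs) <- sprintf("n%02d", 1:10)
  trials <- simulate_session(profs, task_config(n_reps = 4), seed = 79)
  gen <- held_out_generalization(trials, n_resamples = 20, seed = 80)
  expect_true(all(gen$auc > 0.9))
  ex <- exemplar_tuned_trials(seed = 81)
  gen_ex <- held_out_generalization(ex, n_resamples = 20, seed = 82)
  # tuning to single exemplars carries no grouping information that transfers:
  # performance collapses to near chance (individual groupings wobble with the
  # particular draw, so the population mean is the stable quantity)
  expect_lt(abs(mean(gen_ex$auc) - 0.5), 0.1)
  expect_lt(max(gen_ex$auc), min(gen$auc))
  # single-exemplar groupings are skipped with a warning
  solo <- trials[trials$grouping != "G01" | trials$image_id == "g1_e1", ]
  expect_warning(held_out_generalization(solo, n_resamples = 2, seed = 83),
                 "single exemplar")
})

test_that("tidy, glance and autoplot expose the decoding result", {
  profs <- tuned_population(6, si = 0.5)
  names(profs) <- sprintf("n%02d", 1:6)
  trials <- simulate_session(profs, task_config(n_reps = 2), seed = 84)
  dr <- suppressWarnings(permutation_analysis(trials, n_resamples = 60, seed = 85))
  td <- generics::tidy(dr)
  expect_equal(nrow(td), 5)
  expect_true(all(c("grouping", "p_value", "p_error") %in% names(td)))
  gl <- generics::glance(dr)
  expect_equal(gl$n_resamples, 60)
  expect_s3_class(ggplot2::autoplot(dr), "ggplot")
})
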