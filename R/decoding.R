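#' Assemble a pseudo-population from sequentially recorded neurons
#'
#' Neurons recorded in separate sessions have no shared single-trial
#' structure, so their rates cannot be joined into true multivariate
#' observations. A pseudo-population is built instead: within each stimulus
#' grouping, each neuron's trials are independently shuffled and truncated to
#' the minimum per-grouping trial count `k` across neurons; the i-th shuffled
#' trial of every neuron is then concatenated into population vector i, and
#' grouping labels are attached after the shuffle. Any across-neuron
#' single-trial covariance is destroyed by construction.
#'
#' @param trials A session tibble covering >= 2 neurons.
#' @param seed Optional integer seed for the within-grouping shuffles.
#'
#' @return An object of class `pseudopopulation`: list with `x` (matrix,
#'   rows = surrogate trials, columns = neurons, entries = stimulus-window
#'   rates in spikes/s), `grouping` (factor label per row), `neuron_ids`, and
#'   `k` (trials per grouping per neuron).
#' @export
build_pseudopopulation <- function(trials, seed = NULL) {
  idx <- pp_index(trials)
  with_seed_if(seed, pp_draw(idx))
}

# pre-split per-neuron, per-grouping rate vectors so the resampling loop can
# rebuild populations without touching the trial table again
pp_index <- function(trials) {
  neurons <- sort(unique(trials$neuron_id))
  groupings <- sort(unique(trials$grouping))
  rates <- lapply(neurons, function(nid) {
    d <- trials[trials$neuron_id == nid, ]
    lapply(groupings, function(g) d$rate_stim_hz[d$grouping == g])
  })
  n_per <- vapply(rates, function(r) vapply(r, length, integer(1)),
                  integer(length(groupings)))
  bad <- which(apply(as.matrix(n_per), 2, min) == 0L)
  if (length(bad)) {
    warn(sprintf("Excluding %d neuron(s) with zero trials for some grouping: %s",
                 length(bad), paste(neurons[bad], collapse = ", ")))
    neurons <- neurons[-bad]
    rates <- rates[-bad]
    n_per <- as.matrix(n_per)[, -bad, drop = FALSE]
  }
  if (!length(neurons)) abort("No usable neurons left.")
  list(neurons = neurons, groupings = groupings, rates = rates,
       k = min(n_per))
}

pp_draw <- function(idx) {
  k <- idx$k
  n_g <- length(idx$groupings)
  x <- vapply(idx$rates, function(r) {
    unlist(lapply(r, function(v) v[sample.int(length(v))][seq_len(k)]), use.names = FALSE)
  }, numeric(k * n_g))
  if (is.null(dim(x))) x <- matrix(x, nrow = k * n_g)
  colnames(x) <- idx$neurons
  structure(
    list(x = x,
         grouping = factor(rep(idx$groupings, each = k), levels = idx$groupings),
         neuron_ids = idx$neurons, k = k),
    class = "pseudopopulation"
  )
}

#' @export
print.pseudopopulation <- function(x, ...) {
  cat(sprintf("<pseudopopulation> %d vectors (%d/grouping) x %d neurons, %d groupings\n",
              nrow(x$x), x$k, ncol(x$x), nlevels(x$grouping)))
  invisible(x)
}

# linear-discriminant decision scores with a regularised fallback for
# singular within-class scatter (few surrogate trials, many neurons)
lda_scores <- function(x_train, y_train, x_test, shrink = 0.1) {
  fit <- tryCatch(
    suppressWarnings(MASS::lda(x_train, grouping = y_train)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    ps <- tryCatch(predict(fit, x_test)$posterior, error = function(e) NULL)
    if (!is.null(ps)) return(list(scores = ps, regularized = FALSE))
  }
  # shrinkage LDA: pooled covariance blended towards its diagonal average
  classes <- levels(y_train)
  mus <- t(vapply(classes, function(g) colMeans(x_train[y_train == g, , drop = FALSE]),
                  numeric(ncol(x_train))))
  centred <- x_train - mus[as.integer(y_train), , drop = FALSE]
  w <- crossprod(centred) / (nrow(x_train) - length(classes))
  w <- (1 - shrink) * w + shrink * mean(diag(w)) * diag(ncol(x_train))
  wi <- solve(w)
  disc <- vapply(seq_along(classes), function(i) {
    a <- wi %*% mus[i, ]
    drop(x_test %*% a) - 0.5 * drop(mus[i, ] %*% a)
  }, numeric(nrow(x_test)))
  colnames(disc) <- classes
  list(scores = disc, regularized = TRUE)
}

#' Decode stimulus grouping from one pseudo-population draw
#'
#' Fits a linear discriminant classifier on a stratified training split of the
#' pseudo-population and scores the held-out vectors; performance per grouping
#' is the one-vs-rest area under the ROC curve built from the classifier's
#' decision scores for that grouping (0.5 = chance). Singular within-class
#' scatter triggers an automatic shrinkage-regularised fit (reported in the
#' `regularized` column).
#'
#' @param pop A [build_pseudopopulation()] result.
#' @param train_fraction Fraction of vectors per grouping used for training.
#'   Default 0.75.
#' @param seed Optional integer seed for the split.
#' @param shuffle_labels If `TRUE`, grouping labels are randomly permuted
#'   across vectors before the split — the "no information" null.
#'
#' @return A tibble, one row per grouping: `grouping`, `auc`, `regularized`.
#' @export
decode_once <- function(pop, train_fraction = 0.75, seed = NULL,
                        shuffle_labels = FALSE) {
  stopifnot(inherits(pop, "pseudopopulation"))
  check_number(train_fraction, "train_fraction", lower = 0, upper = 1, strict = TRUE)
  with_seed_if(seed, {
    y <- pop$grouping
    if (shuffle_labels) y <- sample(y)
    idx_train <- unlist(purrr::map(levels(y), function(g) {
      rows <- which(y == g)
      n_tr <- max(1L, floor(length(rows) * train_fraction))
      rows[sample.int(length(rows))][seq_len(n_tr)]
    }))
    idx_test <- setdiff(seq_along(y), idx_train)
    if (length(idx_test) < 2L) abort("Test split too small; lower `train_fraction`.")
    sc <- lda_scores(pop$x[idx_train, , drop = FALSE], droplevels(y[idx_train]),
                     pop$x[idx_test, , drop = FALSE])
    y_test <- y[idx_test]
    tibble::tibble(
      grouping = levels(y),
      auc = vapply(levels(y), function(g) {
        if (!g %in% colnames(sc$scores)) return(NA_real_)
        auc_rank(sc$scores[, g], y_test == g)
      }, numeric(1)),
      regularized = sc$regularized
    )
  })
}

#' Pseudo-population decoding with permutation resampling
#'
#' The full population-level analysis: for each of `n_resamples` resamples the
#' pseudo-population is rebuilt with a fresh within-grouping shuffle and
#' decoded with [decode_once()] (the "labelled" distribution); a matched null
#' distribution is built the same way but with grouping labels randomly
#' permuted across vectors before training ("no information"). The
#' permutation p-value per grouping uses the add-one estimator
#' \eqn{p = (1 + \#\{null \ge median(labelled)\}) / (1 + n)} — never exactly
#' zero — with standard error \eqn{\sqrt{p(1-p)/n}}.
#'
#' @param trials A session tibble (typically restricted to the
#'   visually-responsive neurons, see [classify_responsiveness()]).
#' @param n_resamples Number of resamples for each of the labelled and null
#'   distributions. Default 1200. Fewer than 100 triggers a warning.
#' @param seed Integer seed governing the entire resampling schedule.
#' @param train_fraction Passed to [decode_once()].
#'
#' @return An object of class `decoding_result`: list with `performance`
#'   (long tibble: `condition` in labelled/null, `resample`, `grouping`,
#'   `auc`), `summary` (per grouping: `median_auc`, `null_median`, `p_value`,
#'   `p_error`), and metadata (`n_resamples`, `n_neurons`, `k`,
#'   `train_fraction`, `seed`, `regularized_fraction`).
#' @export
permutation_analysis <- function(trials, n_resamples = 1200, seed = NULL,
                                 train_fraction = 0.75) {
  n_resamples <- check_count(n_resamples, "n_resamples")
  if (n_resamples < 100) warn("Fewer than 100 resamples gives unstable permutation p-values.")
  idx <- pp_index(trials)
  with_seed_if(seed, {
    run <- function(shuffle) {
      purrr::map_dfr(seq_len(n_resamples), function(i) {
        pop <- pp_draw(idx)
        decode_once(pop, train_fraction = train_fraction,
                    shuffle_labels = shuffle) |>
          dplyr::mutate(resample = i)
      })
    }
    labelled <- dplyr::mutate(run(FALSE), condition = "labelled")
    null <- dplyr::mutate(run(TRUE), condition = "null")
    perf <- dplyr::bind_rows(labelled, null)

    summary <- perf |>
      tidyr::pivot_wider(id_cols = c("resample", "grouping"),
                         names_from = "condition", values_from = "auc") |>
      dplyr::group_by(.data$grouping) |>
      dplyr::summarise(
        median_auc = median(.data$labelled, na.rm = TRUE),
        null_median = median(.data$null, na.rm = TRUE),
        p_value = (1 + sum(.data$null >= median(.data$labelled, na.rm = TRUE),
                           na.rm = TRUE)) / (1 + n_resamples),
        .groups = "drop"
      ) |>
      dplyr::mutate(p_error = sqrt(.data$p_value * (1 - .data$p_value) / n_resamples))

    structure(
      list(performance = perf, summary = summary,
           n_resamples = n_resamples,
           n_neurons = dplyr::n_distinct(trials$neuron_id),
           k = dplyr::n_distinct(trials$grouping),
           train_fraction = train_fraction, seed = seed,
           regularized_fraction = mean(perf$regularized)),
      class = "decoding_result"
    )
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d neurons, %d resamples per condition\n",
              x$n_neurons, x$n_resamples))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decoding_result <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.decoding_result <- function(x, ...) {
  tibble::tibble(
    n_neurons = x$n_neurons,
    n_resamples = x$n_resamples,
    median_auc = median(x$summary$median_auc),
    min_p = min(x$summary$p_value),
    max_p = max(x$summary$p_value),
    regularized_fraction = x$regularized_fraction
  )
}

#' Generalisation of the population code to held-out exemplars
#'
#' Tests whether the decoder transfers across exemplar images within a
#' grouping: each fold holds out one exemplar of every grouping, builds
#' training pseudo-population vectors from the remaining exemplars' trials and
#' test vectors from the held-out exemplars' trials, fits the discriminant on
#' grouping labels, and measures per-grouping one-vs-rest ROC performance on
#' the held-out vectors. Results are averaged over folds and resamples.
#' Groupings with a single exemplar cannot be assessed and are skipped with a
#' warning.
#'
#' @param trials A session tibble with an `image_id` column distinguishing
#'   exemplars.
#' @param n_resamples Resamples per held-out fold. Default 100.
#' @param seed Optional integer seed.
#'
#' @return A tibble per grouping: `auc` (mean held-out performance), `sd`
#'   (over folds x resamples), `n_folds`.
#' @export
held_out_generalization <- function(trials, n_resamples = 100, seed = NULL) {
  n_resamples <- check_count(n_resamples, "n_resamples")
  exemplars <- trials |>
    dplyr::distinct(.data$grouping, .data$image_id) |>
    dplyr::arrange(.data$grouping, .data$image_id) |>
    dplyr::group_by(.data$grouping) |>
    dplyr::mutate(rank = dplyr::row_number(), n_ex = dplyr::n()) |>
    dplyr::ungroup()
  single <- unique(exemplars$grouping[exemplars$n_ex < 2L])
  if (length(single)) {
    warn(sprintf("Skipping grouping(s) with a single exemplar: %s",
                 paste(single, collapse = ", ")))
    exemplars <- dplyr::filter(exemplars, !.data$grouping %in% single)
    trials <- dplyr::filter(trials, !.data$grouping %in% single)
  }
  if (!nrow(exemplars)) abort("No grouping has >= 2 exemplars.")
  n_folds <- max(exemplars$n_ex)

  with_seed_if(seed, {
    res <- purrr::map_dfr(seq_len(n_folds), function(j) {
      held <- exemplars$image_id[((j - 1L) %% exemplars$n_ex) + 1L == exemplars$rank]
      idx_train <- pp_index(dplyr::filter(trials, !.data$image_id %in% held))
      idx_test <- pp_index(dplyr::filter(trials, .data$image_id %in% held))
      purrr::map_dfr(seq_len(n_resamples), function(r) {
        tr_pop <- pp_draw(idx_train)
        te_pop <- pp_draw(idx_test)
        sc <- lda_scores(tr_pop$x, tr_pop$grouping,
                         te_pop$x[, tr_pop$neuron_ids, drop = FALSE])
        y_test <- te_pop$grouping
        tibble::tibble(
          fold = j,
          grouping = levels(tr_pop$grouping),
          auc = vapply(levels(tr_pop$grouping), function(g) {
            if (!g %in% colnames(sc$scores)) return(NA_real_)
            auc_rank(sc$scores[, g], y_test == g)
          }, numeric(1))
        )
      })
    })
    res |>
      dplyr::group_by(.data$grouping) |>
      dplyr::summarise(
        sd = sd(.data$auc, na.rm = TRUE),
        auc = mean(.data$auc, na.rm = TRUE),
        n_folds = dplyr::n_distinct(.data$fold),
        .groups = "drop"
      ) |>
      dplyr::select("grouping", "auc", "sd", "n_folds")
  })
}
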