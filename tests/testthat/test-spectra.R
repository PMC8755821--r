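test_that("cross-section spectra isolate known frequency content", {
  g <- make_sine_grating(4, 128)
  sp <- cross_section_spectrum(g, "horizontal")
  expect_equal(nrow(sp), 64)
  expect_equal(sp$frequency, 1:64)
  # essentially all energy at 4 cycles/image
  expect_gt(sp$amplitude[4]^2 / sum(sp$amplitude^2), 0.999)
  # the orthogonal direction of a grating is constant: zero spectrum
  spv <- cross_section_spectrum(g, "vertical")
  expect_true(all(abs(spv$amplitude) < 1e-9))
  # constant image: all-zero spectrum and undefined centroid
  flat <- stim_image(matrix(0.5, 32, 32))
  expect_true(all(cross_section_spectrum(flat, "horizontal")$amplitude == 0))
  expect_error(spectral_average(cross_section_spectrum(flat, "horizontal")),
               "Zero total")
})

test_that("the energy-weighted spectral average is an energy centroid", {
  # pure grating: point mass at its frequency
  expect_equal(spectral_average(cross_section_spectrum(make_sine_grating(8, 256))), 8,
               tolerance = 1e-6)
  # equal energy at 2 and 6 averages to 4
  spec <- tibble::tibble(frequency = c(2, 6), amplitude = c(3, 3))
  expect_equal(spectral_average(spec), 4)
  # direct-sum oracle on an arbitrary spectrum
  spec2 <- tibble::tibble(frequency = 1:5, amplitude = c(0.3, 1.2, 0.1, 0.8, 0.5))
  expect_equal(spectral_average(spec2),
               sum((1:5) * spec2$amplitude^2) / sum(spec2$amplitude^2))
  # amplitude weighting is exposed as a variant
  expect_equal(spectral_average(spec2, weights = "amplitude"),
               sum((1:5) * spec2$amplitude) / sum(spec2$amplitude))
})

test_that("the spectral average is invariant to intensity scaling", {
  img <- make_naturalistic(12, 128)
  half <- stim_image(unclass(img) * 0.5)
  for (axis in c("horizontal", "vertical")) {
    expect_equal(spectral_average(cross_section_spectrum(half, axis)),
                 spectral_average(cross_section_spectrum(img, axis)),
                 tolerance = 1e-9)
  }
})

test_that("single-line and mean cross-sections are both available", {
  img <- make_naturalistic(13, 64)
  a <- cross_section_spectrum(img, "horizontal", mode = "mean")
  b <- cross_section_spectrum(img, "horizontal", mode = "center")
  expect_equal(nrow(a), nrow(b))
  expect_false(isTRUE(all.equal(a$amplitude, b$amplitude)))
})

test_that("spectral correlation matrices pack directions into triangles", {
  imgs <- list(a = make_naturalistic(1, 128), b = make_naturalistic(2, 128),
               c = make_naturalistic(3, 128))
  m <- spectral_correlation_matrix(imgs)
  expect_equal(dim(m), c(3, 3))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_true(all(m >= -1 & m <= 1, na.rm = TRUE))
  # upper triangle is the horizontal direction, lower the vertical
  h_ab <- cor(cross_section_spectrum(imgs$a, "horizontal")$amplitude /
                sqrt(sum(cross_section_spectrum(imgs$a, "horizontal")$amplitude^2)),
              cross_section_spectrum(imgs$b, "horizontal")$amplitude /
                sqrt(sum(cross_section_spectrum(imgs$b, "horizontal")$amplitude^2)))
  expect_equal(m["a", "b"], h_ab, tolerance = 1e-12)
  # 1/f surrogates share low-frequency dominance: high positive correlation
  expect_gt(m["a", "b"], 0.7)
  expect_gt(m["b", "a"], 0.7)
  # gratings at well-separated frequencies barely correlate
  g <- spectral_correlation_matrix(list(g4 = make_sine_grating(4, 128),
                                        g32 = make_sine_grating(32, 128)))
  expect_lt(g["g4", "g32"], 0.1)
  expect_error(spectral_correlation_matrix(list(a = make_naturalistic(1, 64),
                                                b = make_naturalistic(2, 128))),
               "same size")
  expect_error(spectral_correlation_matrix(list(a = make_naturalistic(1, 64))),
               "2 images")
})

test_that("scrambling raises the spectral centroid across seeded surrogates", {
  # the 32-row tiling inserts many vertical transitions, so the vertical
  # centroid rises for every surrogate; the 15-column tiling is coarser and
  # the horizontal centroid rises for most but not every draw. A 20-surrogate
  # sign test runs in the acceptance suite.
  d <- sapply(1:5, function(i) {
    img <- make_naturalistic(400 + i, 480)
    scr <- scramble_image(img, seed = 500 + i)
    c(h = spectral_average(cross_section_spectrum(scr, "horizontal")) -
        spectral_average(cross_section_spectrum(img, "horizontal")),
      v = spectral_average(cross_section_spectrum(scr, "vertical")) -
        spectral_average(cross_section_spectrum(img, "vertical")))
  })
  expect_true(all(d["v", ] > 0))
  expect_gte(sum(d["h", ] > 0), 4)
  expect_gt(mean(d["h", ]), 0)
})

test_that("spectral summaries separate scrambled from intact surrogates", {
  set <- make_stimulus_set(size = 96, grid = c(8, 16), seed = 14)
  sm <- spectral_summary(set)
  expect_equal(nrow(sm), 20)
  intact <- sm[sm$label %in% c("face_a", "face_b"), ]
  scr <- sm[grepl("^scrambled", sm$label), ]
  # scrambled surrogates sit at clearly higher spectral centroids on both axes
  expect_gt(mean(scr$ewsa_h), mean(intact$ewsa_h))
  expect_gt(mean(scr$ewsa_v), mean(intact$ewsa_v))
  # gratings have no vertical frequency content: reported as NA
  expect_true(all(is.na(sm$ewsa_v[sm$label == "grating"])))
  expect_false(anyNA(sm$ewsa_h))
})
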