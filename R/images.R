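#' Stimulus images
#'
#' Stimulus images are plain numeric matrices with intensities in `[0, 1]`
#' (rows = image rows, columns = image columns) carrying a `label` and a
#' `provenance` attribute, class `stim_image`. Three generators cover the
#' stimulus set: sine gratings, naturalistic `1/f` surrogates, and
#' grid-scrambled versions of either.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param label Grouping tag.
#' @param provenance Named list describing how the image was made.
#' @return A `stim_image`.
#' @export
stim_image <- function(pixels, label = NA_character_, provenance = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) abort("`pixels` must be a numeric matrix.")
  if (any(pixels < -1e-9) || any(pixels > 1 + 1e-9)) {
    abort("Intensities must lie in [0, 1].")
  }
  structure(pmin(pmax(pixels, 0), 1), label = label, provenance = provenance,
            class = c("stim_image", "matrix", "array"))
}

#' @export
print.stim_image <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("<stim_image> %dx%d (w x h), label '%s', kind '%s'\n",
              ncol(x), nrow(x), attr(x, "label"), pv$kind %||% "unknown"))
  invisible(x)
}

#' Sine grating stimulus
#'
#' Intensity `0.5 + 0.5 * sin(2 * pi * frequency * x / width)` along the
#' chosen orientation axis. Spatial frequency is in cycles per image width
#' (or height for vertically varying gratings) and must lie strictly below
#' the Nyquist limit of `size / 2` cycles.
#'
#' @param frequency Cycles per image, `1 <= frequency < size / 2`.
#' @param size Image side length in pixels (square image). Default 512.
#' @param orientation Axis along which intensity varies: `"horizontal"`
#'   (vertical stripes, default) or `"vertical"`.
#' @return A [stim_image()].
#' @examples
#' g <- make_sine_grating(4, size = 128)
#' @export
make_sine_grating <- function(frequency, size = 512,
                              orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  size <- check_count(size, "size", min = 4L)
  check_number(frequency, "frequency", lower = 1, upper = size / 2)
  if (frequency >= size / 2) {
    abort(sprintf("`frequency` must be below the Nyquist limit %g.", size / 2))
  }
  wave <- 0.5 + 0.5 * sin(2 * pi * frequency * (seq_len(size) - 1) / size)
  px <- if (orientation == "horizontal") {
    matrix(wave, nrow = size, ncol = size, byrow = TRUE)
  } else {
    matrix(wave, nrow = size, ncol = size)
  }
  stim_image(px, label = "grating",
             provenance = list(kind = "grating", frequency = frequency,
                               orientation = orientation))
}

#' Naturalistic surrogate image
#'
#' Random-phase field with amplitude spectrum proportional to
#' `1 / f^(spectral_exponent / 2)` over radial spatial frequency `f`, rescaled
#' to `[0, 1]`. With the default exponent 2 the power spectrum falls as
#' `1/f^2`, the hallmark shared by natural photographs: most spectral energy
#' sits at low spatial frequencies, and any two surrogates share that
#' low-frequency dominance. Exponent 0 gives white noise.
#'
#' @param seed Integer seed; the same seed always gives identical pixels.
#' @param size Side length in pixels (square), >= 32. Default 512.
#' @param spectral_exponent Power-spectrum exponent. Default 2.
#' @return A [stim_image()].
#' @export
make_naturalistic <- function(seed, size = 512, spectral_exponent = 2) {
  size <- check_count(size, "size", min = 32L)
  check_number(spectral_exponent, "spectral_exponent", lower = 0)
  seed <- check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(size * size), size, size)
    f <- fft(noise)
    fx <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
    rad <- sqrt(outer(fx^2, fx^2, `+`))
    amp <- 1 / pmax(rad, 1 / size)^(spectral_exponent / 2)
    amp[1, 1] <- 0 # mean fixed afterwards by rescaling
    img <- Re(fft(f * amp, inverse = TRUE)) / (size * size)
    rng <- range(img)
    px <- if (diff(rng) == 0) matrix(0.5, size, size) else (img - rng[1]) / diff(rng)
    stim_image(px, label = "naturalistic",
               provenance = list(kind = "naturalistic", seed = seed,
                                 spectral_exponent = spectral_exponent))
  })
}

#' Grid-scramble an image
#'
#' Divides the image into a `grid[1]`-column by `grid[2]`-row lattice of
#' tiles, randomly permutes tile positions, and gives each tile a random
#' orientation. Square tiles draw orientations from rotations
#' \{0, 90, 180, 270\} degrees; non-square tiles are restricted to \{0, 180\}
#' plus horizontal/vertical flips (when `flips = TRUE`) so every allowed
#' operation maps a tile onto its own footprint. The pixel multiset — and
#' therefore the mean luminance — is conserved exactly.
#'
#' @param img A [stim_image()] (or plain matrix) whose width is divisible by
#'   `grid[1]` and height by `grid[2]`.
#' @param grid `c(cols, rows)`. Default `c(15, 32)` (480 tiles).
#' @param seed Integer seed for the permutation and orientations.
#' @param rotations,flips Include rotations / flips in the orientation
#'   shuffle. With both `FALSE` only tile positions are permuted.
#' @return A [stim_image()] with provenance recording the parent and seed.
#' @export
scramble_image <- function(img, grid = c(15, 32), seed = 1,
                           rotations = TRUE, flips = TRUE) {
  px <- unclass(img)
  attributes(px) <- attributes(px)["dim"]
  h <- nrow(px); w <- ncol(px)
  cols <- check_count(grid[1], "grid[1]"); rows <- check_count(grid[2], "grid[2]")
  if (cols > w || rows > h) abort("Scrambling grid is larger than the image.")
  if (w %% cols != 0L || h %% rows != 0L) {
    abort(sprintf("Image %dx%d is not divisible by a %dx%d grid; crop or pad first.",
                  w, h, cols, rows))
  }
  tw <- w %/% cols; th <- h %/% rows
  square <- tw == th
  seed <- check_count(seed, "seed", min = 0L)

  withr::with_seed(seed, {
    n_tiles <- cols * rows
    perm <- sample(n_tiles)
    tiles <- vector("list", n_tiles)
    idx <- 1L
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      tiles[[idx]] <- px[((r - 1L) * th + 1L):(r * th), ((c - 1L) * tw + 1L):(c * tw)]
      idx <- idx + 1L
    }
    orient_tile <- function(t) {
      ops <- c("id")
      if (rotations) ops <- c(ops, "r180", if (square) c("r90", "r270"))
      if (flips) ops <- c(ops, "fh", "fv")
      switch(sample(ops, 1L),
        id = t,
        r90 = t(t[rev(seq_len(nrow(t))), , drop = FALSE]),
        r180 = t[rev(seq_len(nrow(t))), rev(seq_len(ncol(t))), drop = FALSE],
        r270 = t(t)[rev(seq_len(nrow(t))), , drop = FALSE],
        fh = t[, rev(seq_len(ncol(t))), drop = FALSE],
        fv = t[rev(seq_len(nrow(t))), , drop = FALSE]
      )
    }
    out <- matrix(0, h, w)
    idx <- 1L
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      t0 <- orient_tile(tiles[[perm[idx]]])
      out[((r - 1L) * th + 1L):(r * th), ((c - 1L) * tw + 1L):(c * tw)] <- t0
      idx <- idx + 1L
    }
    parent <- attr(img, "provenance") %||% list()
    stim_image(out, label = paste0("scrambled_", attr(img, "label") %||% "image"),
               provenance = list(kind = "scrambled",
                                 parent = parent$kind %||% "matrix",
                                 parent_label = attr(img, "label"),
                                 grid = c(cols, rows), seed = seed,
                                 rotations = rotations, flips = flips))
  })
}

#' Read and write 8-bit grayscale PNG stimulus images
#'
#' @param img A [stim_image()].
#' @param path PNG path.
#' @param label Label attached on read.
#' @return `write_stimulus_png()` returns `path` invisibly; the writer also
#'   drops a `<path>.json` provenance sidecar. `read_stimulus_png()` returns
#'   a [stim_image()] (color PNGs are converted to luminance).
#' @export
write_stimulus_png <- function(img, path) {
  png::writePNG(unclass(img), target = path)
  pv <- attr(img, "provenance") %||% list()
  pv$label <- attr(img, "label")
  jsonlite::write_json(pv, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_stimulus_png
#' @export
read_stimulus_png <- function(path, label = NA_character_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  }
  stim_image(px, label = label, provenance = list(kind = "file", path = path))
}

#' Generate the default 20-image stimulus set
#'
#' Five groupings by four exemplars mirroring the task's stimulus design:
#' two groupings of naturalistic surrogates ("faces" stand-ins for two
#' species), their grid-scrambled counterparts, and sine gratings of four
#' spatial frequencies.
#'
#' @param size Image side length in pixels; must be divisible by both grid
#'   dimensions. Default 480.
#' @param grating_freqs Four spatial frequencies, cycles/image.
#' @param grid Scrambling grid `c(cols, rows)`.
#' @param seed Integer seed.
#' @return A named list of 20 [stim_image()]s; names `"<grouping>_<k>"` with
#'   groupings `face_a`, `face_a_scr`, `face_b`, `face_b_scr`, `grating`.
#' @export
make_stimulus_set <- function(size = 480, grating_freqs = c(2, 4, 8, 16),
                              grid = c(15, 32), seed = 1) {
  stopifnot(length(grating_freqs) == 4L)
  seed <- check_count(seed, "seed", min = 0L)
  set <- list()
  for (k in 1:4) {
    a <- `attr<-`(make_naturalistic(seed + k, size = size), "label", "face_a")
    b <- `attr<-`(make_naturalistic(seed + 100 + k, size = size), "label", "face_b")
    set[[paste0("face_a_", k)]] <- a
    set[[paste0("face_b_", k)]] <- b
    set[[paste0("face_a_scr_", k)]] <- scramble_image(a, grid = grid, seed = seed + 200 + k)
    set[[paste0("face_b_scr_", k)]] <- scramble_image(b, grid = grid, seed = seed + 300 + k)
    set[[paste0("grating_", k)]] <- make_sine_grating(grating_freqs[k], size = size)
  }
  set[order(names(set))]
}
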