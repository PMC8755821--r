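#' Cross-sectional Fourier amplitude spectrum of an image
#'
#' One-dimensional discrete Fourier amplitude spectrum along the chosen axis,
#' averaged across all lines of the orthogonal axis (the default; a single
#' central line is available via `mode = "center"`). Frequencies run from 1
#' to the Nyquist limit in cycles/image; the zero-frequency (DC) component is
#' omitted. A constant image yields an all-zero spectrum.
#'
#' @param img A [stim_image()] or numeric matrix.
#' @param axis `"horizontal"` (spectrum along rows, left-right) or
#'   `"vertical"` (along columns).
#' @param mode `"mean"` (average spectrum over all lines) or `"center"`
#'   (single central line).
#' @return A tibble `frequency` (cycles/image), `amplitude`.
#' @examples
#' sp <- cross_section_spectrum(make_sine_grating(4, 128), "horizontal")
#' sp$frequency[which.max(sp$amplitude)] # 4
#' @export
cross_section_spectrum <- function(img, axis = c("horizontal", "vertical"),
                                   mode = c("mean", "center")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  px <- unclass(img)
  attributes(px) <- attributes(px)["dim"]
  if (!is.matrix(px) || min(dim(px)) < 4L) abort("`img` must be a matrix of at least 4x4 pixels.")
  lines <- if (axis == "horizontal") px else t(px) # rows become the transform axis
  if (mode == "center") lines <- lines[ceiling(nrow(lines) / 2), , drop = FALSE]
  n <- ncol(lines)
  nyq <- n %/% 2
  amps <- t(apply(lines, 1, function(v) Mod(fft(v))[2:(nyq + 1)]))
  if (nyq == 1L) amps <- t(amps)
  tibble::tibble(frequency = seq_len(nyq), amplitude = colMeans(amps) / n)
}

#' Energy-weighted spectral average
#'
#' Spectral centroid of a cross-section spectrum with energy (squared
#' amplitude) weights: \eqn{\sum_f f |A(f)|^2 / \sum_f |A(f)|^2} over the
#' non-DC frequencies. Invariant to multiplicative intensity scaling.
#' Amplitude weighting (`weights = "amplitude"`) is available as a variant.
#'
#' @param spectrum A tibble from [cross_section_spectrum()] (columns
#'   `frequency`, `amplitude`).
#' @param weights `"energy"` (default, `|A|^2`) or `"amplitude"` (`|A|`).
#' @return Centroid frequency in cycles/image.
#' @examples
#' spectral_average(cross_section_spectrum(make_sine_grating(8, 256))) # 8
#' @export
spectral_average <- function(spectrum, weights = c("energy", "amplitude")) {
  weights <- match.arg(weights)
  if (!all(c("frequency", "amplitude") %in% names(spectrum))) {
    abort("`spectrum` needs `frequency` and `amplitude` columns.")
  }
  w <- if (weights == "energy") spectrum$amplitude^2 else abs(spectrum$amplitude)
  tot <- sum(w)
  if (tot == 0) abort("Zero total spectral energy: spectral average undefined (constant image?).")
  sum(spectrum$frequency * w) / tot
}

#' Spectral summary of an image set
#'
#' Convenience wrapper computing both cross-section spectra and their
#' energy-weighted spectral averages for a list of images.
#'
#' @param images Named list of [stim_image()]s.
#' @param ... Passed to [cross_section_spectrum()].
#' @return A tibble per image: `image_id`, `label`, `ewsa_h`, `ewsa_v`. An
#'   axis with no spectral energy (e.g. the direction orthogonal to a pure
#'   grating's stripes) is reported as `NA`.
#' @export
spectral_summary <- function(images, ...) {
  safe_ewsa <- function(img, axis, ...) {
    tryCatch(spectral_average(cross_section_spectrum(img, axis, ...)),
             error = function(e) NA_real_)
  }
  purrr::imap_dfr(images, function(img, id) {
    tibble::tibble(
      image_id = id,
      label = attr(img, "label") %||% NA_character_,
      ewsa_h = safe_ewsa(img, "horizontal", ...),
      ewsa_v = safe_ewsa(img, "vertical", ...)
    )
  })
}

#' Energy-normalised spectral correlation matrix
#'
#' Each image's cross-section amplitude spectrum is normalised to unit energy
#' and pairwise Pearson correlations of the normalised spectra are computed.
#' Horizontal-direction correlations are packed into the upper triangle and
#' vertical-direction correlations into the lower triangle of a single
#' matrix with unit diagonal.
#'
#' @param images Named list of images of a common size (>= 2).
#' @param ... Passed to [cross_section_spectrum()].
#' @return A symmetric-per-direction square matrix with image names on both
#'   dimensions.
#' @export
spectral_correlation_matrix <- function(images, ...) {
  if (length(images) < 2L) abort("At least 2 images are required.")
  dims <- purrr::map(images, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1L) {
    abort("All images must share the same size.")
  }
  norm_spec <- function(img, axis) {
    a <- cross_section_spectrum(img, axis, ...)$amplitude
    a / sqrt(sum(a^2))
  }
  sp_h <- purrr::map(images, norm_spec, axis = "horizontal")
  sp_v <- purrr::map(images, norm_spec, axis = "vertical")
  n <- length(images)
  m <- diag(1, n)
  dimnames(m) <- list(names(images), names(images))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- cor(sp_h[[i]], sp_h[[j]]) # horizontal: upper triangle
    m[j, i] <- cor(sp_v[[i]], sp_v[[j]]) # vertical: lower triangle
  }
  m
}
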