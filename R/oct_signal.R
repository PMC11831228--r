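#' Swept-source spectrum configuration
#'
#' Describes the light source sampled across one wavelength sweep: the
#' central wavelength, the full-width-half-maximum bandwidth of the
#' (Gaussian) spectral envelope, the number of spectral samples recorded
#' per A-line, and the refractive index of the medium used when converting
#' optical path lengths to geometric depth.
#'
#' @param center_wavelength_nm Central wavelength \eqn{\lambda_0} in nm.
#' @param bandwidth_fwhm_nm Spectral FWHM \eqn{\Delta\lambda} in nm.
#' @param n_samples Number of spectral samples per A-line (even, >= 16).
#' @param refractive_index Refractive index of the sample medium.
#' @return An object of class `spectrum_config`.
#' @examples
#' cfg <- spectrum_config(1300, 90, 256)
#' axial_resolution(cfg)
#' @export
spectrum_config <- function(center_wavelength_nm = 1300,
                            bandwidth_fwhm_nm = 90,
                            n_samples = 256,
                            refractive_index = 1.0) {
  stop_if_not(center_wavelength_nm > 0, "center_wavelength_nm must be > 0")
  stop_if_not(bandwidth_fwhm_nm > 0 && bandwidth_fwhm_nm < center_wavelength_nm,
              "bandwidth_fwhm_nm must be in (0, center_wavelength_nm)")
  stop_if_not(is_count(n_samples) && n_samples >= 16 && n_samples %% 2 == 0,
              "n_samples must be an even count >= 16")
  stop_if_not(refractive_index > 0, "refractive_index must be > 0")
  structure(list(center_wavelength_nm = center_wavelength_nm,
                 bandwidth_fwhm_nm = bandwidth_fwhm_nm,
                 n_samples = as.integer(n_samples),
                 refractive_index = refractive_index),
            class = "spectrum_config")
}

#' Theoretical axial resolution of a Gaussian-spectrum OCT source
#'
#' Round-trip coherence length (FWHM) for a Gaussian spectrum:
#' \deqn{\delta z = \frac{2\ln 2}{\pi}\,\frac{\lambda_0^2}{n\,\Delta\lambda}}
#' For a 1300 nm source with 90 nm bandwidth this is 8.3 um in air,
#' commonly quoted as "around 8 um".
#'
#' @param cfg A [spectrum_config()], or the central wavelength in nm.
#' @param bandwidth_fwhm_nm Bandwidth in nm (when `cfg` is numeric).
#' @param refractive_index Medium index (when `cfg` is numeric).
#' @return Axial resolution in micrometres.
#' @export
axial_resolution <- function(cfg, bandwidth_fwhm_nm = NULL,
                             refractive_index = 1.0) {
  if (inherits(cfg, "spectrum_config")) {
    l0 <- cfg$center_wavelength_nm
    dl <- cfg$bandwidth_fwhm_nm
    n <- cfg$refractive_index
  } else {
    l0 <- cfg; dl <- bandwidth_fwhm_nm; n <- refractive_index
    stop_if_not(!is.null(dl), "bandwidth_fwhm_nm required")
  }
  (2 * log(2) / pi) * l0^2 / (n * dl) / 1000  # nm -> um
}

#' 8-bit grayscale image container
#'
#' @param pixels Integer matrix with values in \[0, 255\] (rows = depth).
#' @param channel_kind `"intensity"` or `"phase"`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, channel_kind = c("intensity", "phase")) {
  channel_kind <- match.arg(channel_kind)
  stop_if_not(is.matrix(pixels), "pixels must be a matrix")
  stop_if_not(all(is.finite(pixels)) && all(pixels >= 0) && all(pixels <= 255),
              "pixel values must be finite and within [0, 255]")
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  structure(px, class = c("gray_image", "matrix"), channel_kind = channel_kind)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %s, %d x %d, range [%d, %d]>\n",
              attr(x, "channel_kind"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

channel_kind <- function(img) attr(img, "channel_kind")

#' Normalization window for log-scale intensity images
#'
#' The dB values mapped to pixel 0 (`log_floor`) and pixel 255
#' (`log_ceil`).  Keeping these alongside an image makes the 0-255
#' normalization invertible (see [denormalize()]).
#'
#' @param log_floor dB value mapped to pixel 0.
#' @param log_ceil dB value mapped to pixel 255; must exceed `log_floor`.
#' @export
norm_params <- function(log_floor, log_ceil) {
  stop_if_not(is.finite(log_floor) && is.finite(log_ceil),
              "norm bounds must be finite")
  stop_if_not(log_ceil > log_floor, "log_ceil must exceed log_floor")
  structure(list(log_floor = log_floor, log_ceil = log_ceil),
            class = "norm_params")
}

#' Reconstruct a complex tomogram from spectral fringes
#'
#' Columnwise discrete Fourier transform of real-valued interference
#' fringes.  Because the detected fringe is real, the transform is
#' Hermitian-symmetric: `X[N-k] = Conj(X[k])` — the origin of the complex
#' conjugate (mirror) artifact.  With `half_range = TRUE` only the
#' positive-depth bins `0..N/2-1` are retained (row 1 = zero delay).
#'
#' @param fringes Numeric matrix, one A-line per column (rows = spectral
#'   samples, even count) or a single numeric vector.
#' @param half_range Keep only the positive-depth half (default `TRUE`).
#' @param window `"none"` (default) or `"hann"` spectral apodization.
#' @return Complex matrix of class `complex_tomogram`, depth x width.
#' @export
reconstruct <- function(fringes, half_range = TRUE,
                        window = c("none", "hann")) {
  window <- match.arg(window)
  if (is.vector(fringes)) fringes <- matrix(fringes, ncol = 1)
  stop_if_not(is.matrix(fringes), "fringes must be a matrix or vector")
  stop_if_not(all(is.finite(fringes)), "fringes contain non-finite samples")
  n <- nrow(fringes)
  stop_if_not(n %% 2 == 0, "number of spectral samples must be even")
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
    fringes <- fringes * w
  }
  tom <- stats::mvfft(fringes)
  if (half_range) tom <- tom[seq_len(n %/% 2), , drop = FALSE]
  structure(tom, class = c("complex_tomogram", class(tom)),
            half_range = half_range, n_samples = n)
}

#' Log-scale intensity image from a complex tomogram
#'
#' Magnitudes are converted to dB (`20*log10(|z| + eps)`) and mapped
#' linearly onto 0-255.  Two normalization modes are available: a fixed dB
#' window given by [norm_params()] (invertible; the simulator default) and
#' per-image min-max scaling.  The degenerate min-max case (constant
#' magnitude) maps every pixel to 0.
#'
#' @param tom `complex_tomogram` (or complex/numeric matrix of values).
#' @param norm [norm_params()] window; required for `mode = "window"`.
#' @param mode `"window"` or `"minmax"`.
#' @param eps Magnitude offset guarding `log10(0)`.
#' @return A `gray_image` with `channel_kind = "intensity"` and the
#'   applied window attached as attribute `norm`.
#' @export
to_intensity <- function(tom, norm = NULL, mode = c("window", "minmax"),
                         eps = 1e-12) {
  mode <- match.arg(mode)
  db <- 20 * log10(Mod(unclass(tom)) + eps)
  if (mode == "window") {
    stop_if_not(inherits(norm, "norm_params"),
                "mode = \"window\" requires a norm_params object")
    lo <- norm$log_floor; hi <- norm$log_ceil
  } else {
    lo <- min(db); hi <- max(db)
    if (hi <= lo) {
      img <- gray_image(matrix(0L, nrow(db), ncol(db)), "intensity")
      attr(img, "norm") <- NULL
      return(img)
    }
    norm <- norm_params(lo, hi)
  }
  px <- round(255 * clip01((db - lo) / (hi - lo)))
  img <- gray_image(px, "intensity")
  attr(img, "norm") <- norm
  img
}

#' Phase image from a complex tomogram
#'
#' The argument of each complex pixel is wrapped into \[0, 2\pi) and
#' quantized as `floor(256 * phi / (2*pi))`, clipped to 255.  Zero-magnitude
#' pixels take phase 0 by convention.  Under this rule conjugating the
#' tomogram maps pixel `p` to `(256 - p) mod 256`, the signature that makes
#' the phase channel informative about mirror-artifact content.
#'
#' @param tom `complex_tomogram` (or complex matrix).
#' @return A `gray_image` with `channel_kind = "phase"`.
#' @export
to_phase <- function(tom) {
  z <- unclass(tom)
  phi <- Arg(z) %% (2 * pi)
  phi[Mod(z) == 0] <- 0
  px <- pmin(floor(256 * phi / (2 * pi)), 255)
  gray_image(px, "phase")
}

#' Invert the 0-255 intensity normalization back to dB
#'
#' Maps pixel values linearly back onto the dB window recorded in `norm`,
#' recovering the clipped log-magnitude to within half a quantization step
#' (`(log_ceil - log_floor) / 510`).
#'
#' @param img Intensity `gray_image`.
#' @param norm [norm_params()] used to produce the image.
#' @return Numeric matrix of dB values.
#' @export
denormalize <- function(img, norm) {
  stop_if_not(inherits(img, "gray_image"), "img must be a gray_image")
  if (!identical(channel_kind(img), "intensity"))
    stop("denormalize() applies to intensity images only", call. = FALSE)
  stop_if_not(inherits(norm, "norm_params"), "norm must be a norm_params")
  norm$log_floor + unclass(img) / 255 * (norm$log_ceil - norm$log_floor)
}

#' Read / write 8-bit grayscale PNG images
#'
#' @param img A `gray_image`.
#' @param path File path.
#' @param channel_kind Channel tag to attach on read.
#' @return `write_gray_png` returns `path` invisibly; `read_gray_png`
#'   returns a `gray_image`.
#' @export
write_gray_png <- function(img, path) {
  stop_if_not(inherits(img, "gray_image"), "img must be a gray_image")
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path, channel_kind = "intensity") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  gray_image(round(m * 255), channel_kind)
}
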