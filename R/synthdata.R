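#' Acquisition configuration for the fringe simulator
#'
#' Fixes the sweep sampling and display geometry shared by the two passes
#' of a paired acquisition.  The wavenumber axis is linear in k with
#' spacing `pi / (2 * depth_range_um)` so that the positive-depth half of
#' the FFT spans exactly `depth_range_um`; the spectral envelope is
#' Gaussian with FWHM set by the source bandwidth.
#'
#' @param spectrum A [spectrum_config()].
#' @param z_offset_um Reference-arm delay applied to every scatterer in the
#'   ground-truth pass; defaults to `depth_range_um / 2`, centring the
#'   sample in the displayed half-range.  The artifact-corrupted input pass
#'   always uses offset 0 (sample at the zero-delay position).
#' @param noise_floor_db Mean magnitude of the additive detection noise in
#'   the half-range image, in dB relative to a unit reflector.
#' @param ascans_per_bscan A-lines per B-scan.
#' @param depth_range_um Displayed (half-range) imaging depth in um.
#' @param seed Integer seed for the noise realizations.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(spectrum = spectrum_config(),
                               z_offset_um = NULL,
                               noise_floor_db = -50,
                               ascans_per_bscan = 64,
                               depth_range_um = 600,
                               seed = 1) {
  stop_if_not(inherits(spectrum, "spectrum_config"),
              "spectrum must be a spectrum_config")
  stop_if_not(is_count(ascans_per_bscan), "ascans_per_bscan must be >= 1")
  stop_if_not(depth_range_um > 0, "depth_range_um must be > 0")
  if (is.null(z_offset_um)) z_offset_um <- depth_range_um / 2
  structure(list(spectrum = spectrum, z_offset_um = z_offset_um,
                 noise_floor_db = noise_floor_db,
                 ascans_per_bscan = as.integer(ascans_per_bscan),
                 depth_range_um = depth_range_um, seed = as.integer(seed)),
            class = "acquisition_config")
}

# Wavenumber axis (rad/um), Gaussian envelope, and derived scales.
sweep_axis <- function(acq) {
  sp <- acq$spectrum
  n <- sp$n_samples
  dk <- pi / (2 * acq$depth_range_um)
  k0 <- 2 * pi / (sp$center_wavelength_nm / 1000)
  k <- k0 + (seq_len(n) - 1 - n / 2) * dk
  dk_fwhm <- 2 * pi * (sp$bandwidth_fwhm_nm / 1000) /
    (sp$center_wavelength_nm / 1000)^2
  env <- exp(-4 * log(2) * ((k - k0) / dk_fwhm)^2)
  # half-range peak magnitude of a unit reflector (cos -> two exponentials)
  m_ref <- sum(env) / 2
  list(k = k, envelope = env, dk = dk, m_ref = m_ref,
       bin_size_um = acq$depth_range_um / (n / 2))
}

#' Synthesize the spectral fringe of one A-line
#'
#' Standard FD-OCT forward model: each scatterer at optical depth `z`
#' (plus the pass's reference offset) with reflectivity `r` and phase
#' offset `phi` contributes `r * S(k) * cos(2 k (z + z_offset) + phi)` to
#' the detected fringe, where `S(k)` is the Gaussian source envelope.
#' Additive white Gaussian detection noise is scaled so that the mean
#' noise-bin magnitude of the reconstructed image sits at
#' `noise_floor_db`.
#'
#' @param phantom A [phantom()].
#' @param acq An [acquisition_config()].
#' @param ascan A-line index (1-based, <= phantom width).
#' @param z_offset_um Reference offset for this pass (default from `acq`).
#' @param noise_seed Integer seed for the noise draw; `NULL` for noiseless.
#' @return Numeric fringe vector of length `n_samples` (real-valued).
#' @export
synth_fringe <- function(phantom, acq, ascan, z_offset_um = acq$z_offset_um,
                         noise_seed = NULL) {
  stop_if_not(inherits(phantom, "phantom"), "phantom must be a phantom")
  stop_if_not(is_count(ascan) && ascan <= phantom$width,
              "ascan must be within the phantom width")
  ax <- sweep_axis(acq)
  sc <- phantom$scatterers[phantom$scatterers$lateral == ascan, , drop = FALSE]
  n <- acq$spectrum$n_samples
  f <- numeric(n)
  if (nrow(sc) > 0) {
    z <- sc$depth_um + z_offset_um
    if (any(abs(z) > acq$depth_range_um))
      warning("scatterer beyond the unambiguous range; it will alias",
              call. = FALSE)
    # n_samples x n_scatterers phase matrix, weighted coherent sum
    ph <- outer(2 * ax$k, z) + matrix(sc$phase, n, nrow(sc), byrow = TRUE)
    f <- as.vector((ax$envelope * cos(ph)) %*% sc$reflectivity)
  }
  if (!is.null(noise_seed)) {
    sigma <- ax$m_ref * 10^(acq$noise_floor_db / 20) * 2 / sqrt(n * pi)
    f <- f + with_seed(noise_seed, stats::rnorm(n, 0, sigma))
  }
  f
}

# All A-lines of one pass as an n_samples x width fringe matrix.
synth_bscan_fringes <- function(phantom, acq, z_offset_um, noise_seed) {
  cols <- lapply(seq_len(phantom$width), function(a) {
    ns <- if (is.null(noise_seed)) NULL else derive_seed(noise_seed, a)
    synth_fringe(phantom, acq, a, z_offset_um, ns)
  })
  do.call(cbind, cols)
}

# Default invertible dB window used for simulator images: from just below
# the noise floor up to a strong specular reflection.
default_norm <- function(acq) norm_params(acq$noise_floor_db - 5, 5)

#' Render one artifact/ground-truth image pair
#'
#' Emulates the paired zero-delay-shift acquisition: the ground-truth pass
#' renders the phantom at the reference offset `acq$z_offset_um` so the
#' mirror artifact falls outside the displayed half-range; the input pass
#' renders the *same* phantom (same scatterers, same speckle phases) at
#' offset 0, so the structure straddles the zero delay and its complex
#' conjugate folds onto it.  The input pass supplies both the intensity
#' and the phase image; the target is intensity only.  Depth positions of
#' the two passes are not pixel-aligned by construction.
#'
#' @param phantom A [phantom()].
#' @param acq An [acquisition_config()]; its `z_offset_um` must be at least
#'   `phantom$extent_depth_um / 2`, otherwise the ground truth itself would
#'   contain the artifact.
#' @param volume_id,frame_index Metadata recorded on the sample.
#' @param noise Logical; add detection noise (default `TRUE`).
#' @param norm [norm_params()] window for the intensity images.
#' @param window Spectral apodization passed to [reconstruct()]
#'   (`"none"` or `"hann"`); apodization suppresses the truncation
#'   sidelobes of a sweep that does not cover the full source envelope.
#' @return An object of class `paired_sample`: list with `input_intensity`,
#'   `input_phase`, `target_intensity` ([gray_image()]s of identical size),
#'   `volume_id`, `frame_index`.
#' @export
make_pair <- function(phantom, acq, volume_id = "vol01", frame_index = 1L,
                      noise = TRUE, norm = default_norm(acq),
                      window = c("none", "hann")) {
  window <- match.arg(window)
  stop_if_not(inherits(acq, "acquisition_config"),
              "acq must be an acquisition_config")
  if (acq$z_offset_um < phantom$extent_depth_um / 2)
    stop("z_offset_um must be >= extent_depth_um / 2: the ground-truth ",
         "pass would otherwise fold onto itself", call. = FALSE)
  base <- derive_seed(acq$seed, phantom$seed, frame_index)
  fr_in <- synth_bscan_fringes(phantom, acq, 0,
                               if (noise) derive_seed(base, 1) else NULL)
  fr_gt <- synth_bscan_fringes(phantom, acq, acq$z_offset_um,
                               if (noise) derive_seed(base, 2) else NULL)
  ax <- sweep_axis(acq)
  tom_in <- reconstruct(fr_in / ax$m_ref, window = window)
  tom_gt <- reconstruct(fr_gt / ax$m_ref, window = window)
  structure(list(input_intensity = to_intensity(tom_in, norm),
                 input_phase = to_phase(tom_in),
                 target_intensity = to_intensity(tom_gt, norm),
                 volume_id = volume_id, frame_index = as.integer(frame_index)),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample %s/%03d, %d x %d>\n", x$volume_id,
              x$frame_index, nrow(x$input_intensity),
              ncol(x$input_intensity)))
  invisible(x)
}

#' Generate a paired training dataset
#'
#' Draws `n_volumes` phantoms (geometry resampled per volume) and renders
#' `frames_per_volume` paired B-scans from each.  Frames within a volume
#' emulate adjacent scan positions: the volume geometry is kept while
#' speckle phases are resampled and depths receive a small jitter.
#'
#' @param n_volumes,frames_per_volume Dataset dimensions.
#' @param kinds Character vector of structure kinds sampled per volume
#'   (recycled deterministically when shorter than `n_volumes`).
#' @param acq An [acquisition_config()].
#' @param seed Integer master seed; the full dataset is a pure function of
#'   its arguments.
#' @param extent_depth_um Phantom axial extent.
#' @param noise Add detection noise.
#' @param norm [norm_params()] display window for all intensity images;
#'   defaults to `default_norm(acq)` (5 dB below the noise floor up to a
#'   strong specular reflection).  A floor above the noise floor clips
#'   the background to black, as displays commonly do.
#' @return An object of class `paired_dataset`: list with `pairs` (list of
#'   [make_pair()] results) and `manifest` (data frame with `volume_id`,
#'   `frame_index`, `kind`, `seed`).
#' @export
generate_dataset <- function(n_volumes, frames_per_volume,
                             kinds = "layered",
                             acq = acquisition_config(),
                             seed = 1,
                             extent_depth_um = 0.5 * acq$depth_range_um,
                             noise = TRUE, norm = default_norm(acq),
                             window = c("none", "hann")) {
  window <- match.arg(window)
  stop_if_not(is_count(n_volumes) && is_count(frames_per_volume),
              "counts must be >= 1")
  kinds <- rep_len(kinds, n_volumes)
  pairs <- list()
  manifest <- NULL
  for (v in seq_len(n_volumes)) {
    vseed <- derive_seed(seed, v)
    vid <- sprintf("vol%02d", v)
    # alternate the fold side across volumes so both classes are equally
    # represented however few volumes are drawn
    ph <- phantom(kinds[v], width = acq$ascans_per_bscan,
                  extent_depth_um = extent_depth_um, seed = vseed,
                  side = if (v %% 2 == 1) 1 else -1)
    for (f in seq_len(frames_per_volume)) {
      phf <- perturb_phantom(ph, derive_seed(vseed, f))
      pairs[[length(pairs) + 1]] <-
        make_pair(phf, acq, volume_id = vid, frame_index = f,
                  noise = noise, norm = norm, window = window)
      manifest <- rbind(manifest,
                        data.frame(volume_id = vid, frame_index = f,
                                   kind = kinds[v], seed = vseed))
    }
  }
  structure(list(pairs = pairs, manifest = manifest, acq = acq),
            class = "paired_dataset")
}

# Frame-to-frame variation at adjacent scan positions: fresh diffuse
# speckle phases and a common-mode axial shift.  The shift is shared by
# all scatterers (sample geometry is rigid), so sub-wavelength phase
# relations *within* the structure — interface phase differences set by
# sheet thickness — are preserved, exactly as for a rigid sample under a
# phase-stable source.
perturb_phantom <- function(phantom, frame_seed) {
  sc <- phantom$scatterers
  e <- phantom$extent_depth_um
  sc2 <- with_seed(frame_seed, {
    diffuse <- !sc$specular
    sc$phase[diffuse] <- stats::runif(sum(diffuse), 0, 2 * pi)
    sc$depth_um <- sc$depth_um + stats::rnorm(1, 0, e / 150)
    sc
  })
  sc2$depth_um <- pmin(pmax(sc2$depth_um, -e / 2), e / 2)
  out <- phantom
  out$scatterers <- sc2
  out
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset: %d pairs, %d volumes>\n", length(x$pairs),
              length(unique(x$manifest$volume_id))))
  invisible(x)
}

#' Write a paired dataset to disk
#'
#' Writes PNG triples under `input_i/`, `input_p/`, `target/` plus a
#' `manifest.csv`.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stop_if_not(inherits(ds, "paired_dataset"), "ds must be a paired_dataset")
  for (sub in c("input_i", "input_p", "target"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (p in ds$pairs) {
    nm <- sprintf("%s_%03d.png", p$volume_id, p$frame_index)
    write_gray_png(p$input_intensity, file.path(dir, "input_i", nm))
    write_gray_png(p$input_phase, file.path(dir, "input_p", nm))
    write_gray_png(p$target_intensity, file.path(dir, "target", nm))
  }
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
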