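#' Write / read raw fringe volumes as float TIFF with a JSON sidecar
#'
#' Stores one page per B-scan (rows = spectral samples, columns =
#' A-lines) as 32-bit float TIFF.  Sample values are scaled into [0, 1]
#' for storage; the affine scale, together with the acquisition
#' parameters, lives in a JSON sidecar (`<path>.json`) so the volume
#' round-trips to within float precision.
#'
#' @param fringes A numeric matrix (one B-scan) or list of matrices.
#' @param acq The [acquisition_config()] the fringes were simulated (or
#'   acquired) with; stored in the sidecar.
#' @param path Output TIFF path.
#' @return `write_fringes` returns `path` invisibly; `read_fringes`
#'   returns a list with `fringes` (list of matrices) and `meta` (the
#'   sidecar contents).
#' @export
write_fringes <- function(fringes, acq, path) {
  stop_if_not(requireNamespace("tiff", quietly = TRUE),
              "the tiff package is required to write fringe volumes")
  if (is.matrix(fringes)) fringes <- list(fringes)
  rng <- range(unlist(lapply(fringes, range)))
  scale <- max(rng[2] - rng[1], .Machine$double.eps)
  pages <- lapply(fringes, function(m) (m - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sp <- acq$spectrum
  meta <- list(offset = rng[1], scale = scale,
               n_samples = sp$n_samples,
               center_wavelength_nm = sp$center_wavelength_nm,
               bandwidth_fwhm_nm = sp$bandwidth_fwhm_nm,
               refractive_index = sp$refractive_index,
               depth_range_um = acq$depth_range_um,
               z_offset_um = acq$z_offset_um,
               noise_floor_db = acq$noise_floor_db,
               n_bscans = length(fringes))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fringes
#' @export
read_fringes <- function(path) {
  stop_if_not(requireNamespace("tiff", quietly = TRUE),
              "the tiff package is required to read fringe volumes")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  fringes <- lapply(pages, function(m) m * meta$scale + meta$offset)
  list(fringes = fringes, meta = meta)
}
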