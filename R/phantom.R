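#' Synthetic scattering phantoms
#'
#' A phantom is a cloud of point scatterers: for each scatterer a lateral
#' A-line index, a signed depth (um of optical path relative to the sample
#' centre), a reflectivity amplitude in \[0, 1\] and a phase offset.
#' Extended structures are realized as many sub-resolution scatterers with
#' uniformly random phases, which produces fully developed speckle in the
#' reconstructed image (random-phasor sum).  Sheet faces additionally carry
#' brighter specular reflections with deterministic phases differing by
#' pi/2 between the two faces of a sheet.  Because a structure kept on one
#' side of the zero delay folds into the exact complex conjugate of its
#' mirrored counterpart, the folded *intensity* image carries no
#' information about the fold side, while the interface-pair phase
#' difference (set by the constant sheet thickness) negates under
#' conjugation: the fold side is readable from the phase image only.
#'
#' `structure_kind` selects the geometry:
#' * `"layered"` — 2-3 flat (slightly tilted) bands, multilayer-sheet
#'   phantom analog;
#' * `"skin_like"` — two bright bands (epidermis/dermis analogs) with an
#'   embedded parabolic duct;
#' * `"eye_like"` — thin curved anterior arc plus a posterior multi-band
#'   arc;
#' * `"random"` — uniformly scattered isolated points.
#' The tissue-like kinds are qualitative fixtures; no anatomical claim is
#' made.
#'
#' @param kind Structure kind (see above).
#' @param width Number of A-lines.
#' @param extent_depth_um Axial extent of the phantom; all scatterer depths
#'   lie within `+/- extent_depth_um / 2`.
#' @param seed Integer seed; the same seed reproduces the same phantom.
#' @param side Fold side of the asymmetric structure: `+1`, `-1`, or `NULL`
#'   to draw it at random.  Flipping `side` mirrors the geometry about the
#'   sample centre, which is invisible in folded intensity but visible in
#'   phase.
#' @return An object of class `phantom`: a list with a `scatterers` data
#'   frame (`lateral`, `depth_um`, `reflectivity`, `phase`), plus the
#'   geometry metadata.
#' @export
phantom <- function(kind = c("layered", "skin_like", "eye_like", "random"),
                    width = 64, extent_depth_um = 300, seed = 1,
                    side = NULL) {
  kind <- match.arg(kind)
  stop_if_not(is_count(width), "width must be a positive count")
  stop_if_not(extent_depth_um > 0, "extent_depth_um must be > 0")
  sc <- with_seed(seed, {
    if (is.null(side)) side <- sample(c(-1, 1), 1)
    gen <- switch(kind,
                  layered = phantom_layered,
                  skin_like = phantom_skin_like,
                  eye_like = phantom_eye_like,
                  random = phantom_random)
    gen(width, extent_depth_um, side)
  })
  sc$depth_um <- pmin(pmax(sc$depth_um, -extent_depth_um / 2),
                      extent_depth_um / 2)
  sc$reflectivity <- pmin(pmax(sc$reflectivity, 0), 1)
  structure(list(scatterers = sc, structure_kind = kind, width = width,
                 extent_depth_um = extent_depth_um, seed = as.integer(seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s: %d scatterers, %d A-lines, extent %.0f um>\n",
              x$structure_kind, nrow(x$scatterers), x$width,
              x$extent_depth_um))
  invisible(x)
}

# One band: specular top interface (phase +pi/2; also a bottom face at
# -pi/2 when both_faces) + diffuse speckle body with random phasors.
band_scatterers <- function(width, top, thickness, tilt, r_spec, r_diff,
                            n_diff = 4, both_faces = FALSE) {
  lat <- seq_len(width)
  tops <- top + tilt * (lat - (width + 1) / 2)
  spec <- data.frame(lateral = lat, depth_um = tops,
                     reflectivity = r_spec * stats::runif(width, 0.9, 1.1),
                     phase = pi / 2, specular = TRUE)
  if (both_faces)
    spec <- rbind(spec, data.frame(
      lateral = lat, depth_um = tops + thickness,
      reflectivity = r_spec * stats::runif(width, 0.9, 1.1),
      phase = 0, specular = TRUE))
  diff <- data.frame(
    lateral = rep(lat, each = n_diff),
    depth_um = rep(tops, each = n_diff) +
      stats::runif(width * n_diff, 0, thickness),
    reflectivity = r_diff * stats::runif(width * n_diff, 0.5, 1.5),
    phase = stats::runif(width * n_diff, 0, 2 * pi),
    specular = FALSE)
  rbind(spec, diff)
}

# Polymer-sheet analog.  The sheet thickness is a manufacturing constant
# of the emulated material, identical across every phantom; only the
# sheet position, tilt and fold side vary.  The sheet carries specular
# reflections at both faces whose reflection phases differ by pi/2, so
# the phase difference between the two displayed interface peaks is a
# dataset-wide constant that negates under complex conjugation: the
# fold side is visible in phase while the folded intensity stays
# ambiguous.  The default thickness is an integer multiple of the depth
# bin at both reference samplings (8 bins at 4.6875 um, 4 bins at
# 9.375 um), so both faces sample the transform's per-bin phase
# alternation at the same fractional offset, its interface phase
# difference sits well away from 0 and pi (mod 2*pi) at 1300 nm, where
# the cue would degenerate, and the faces are far enough apart that
# their point-spread tails do not interfere (overlapping
# deterministic-phase reflections would imprint their relative phase on
# the intensity between them and leak the fold side).
SHEET_THICKNESS_UM <- 37.5

# The sheet is kept strictly on one side of the zero delay with a guard
# band of several depth bins.  A structure that never reaches its own
# conjugate leaves the folded intensity statistically side-symmetric;
# deterministic-phase content at (or within a PSF tail of) the zero
# delay would self-interfere with its own mirror and leak the fold side
# into intensity.
phantom_layered <- function(width, extent, side) {
  e2 <- extent / 2
  tilt <- stats::runif(1, -1, 1) * extent / (30 * width)
  height <- SHEET_THICKNESS_UM
  top_lo <- -0.95 * e2
  top_hi <- min(-height - 0.15 * e2, top_lo + 0.01 * e2)
  top <- stats::runif(1, top_lo, max(top_lo, top_hi))
  sc <- band_scatterers(width, top, thickness = height, tilt = tilt,
                        r_spec = stats::runif(1, 0.45, 0.55),
                        r_diff = stats::runif(1, 0.04, 0.06),
                        both_faces = TRUE)
  sc$depth_um <- side * sc$depth_um
  sc
}

phantom_skin_like <- function(width, extent, side) {
  e2 <- extent / 2
  lat <- seq_len(width)
  surf_top <- stats::runif(1, -0.8, -0.5) * e2
  derm_top <- surf_top + stats::runif(1, 0.25, 0.4) * extent
  sc <- rbind(
    band_scatterers(width, surf_top, 0.1 * extent, 0, 0.5, 0.1),
    band_scatterers(width, derm_top, 0.2 * extent, 0, 0.35, 0.08))
  # sweat-duct analog: bright parabolic thread through the epidermis
  x0 <- sample(seq(width %/% 4, 3 * width %/% 4), 1)
  xs <- lat[abs(lat - x0) <= width / 8]
  duct <- data.frame(
    lateral = xs,
    depth_um = surf_top + 0.05 * extent +
      0.15 * extent * ((xs - x0) / (width / 8))^2,
    reflectivity = 0.45, phase = pi / 2, specular = TRUE)
  sc <- rbind(sc, duct)
  sc$depth_um <- side * sc$depth_um
  sc
}

phantom_eye_like <- function(width, extent, side) {
  e2 <- extent / 2
  lat <- seq_len(width)
  u <- (lat - (width + 1) / 2) / (width / 2)
  cornea <- data.frame(lateral = lat,
                       depth_um = -0.7 * e2 + 0.25 * e2 * u^2,
                       reflectivity = 0.4, phase = pi / 2,
                       specular = TRUE)
  sc <- cornea
  for (off in c(0.35, 0.5, 0.62)) {
    band <- data.frame(
      lateral = rep(lat, each = 3),
      depth_um = rep(off * e2 - 0.2 * e2 * u^2, each = 3) +
        stats::runif(3 * width, 0, 0.04 * extent),
      reflectivity = 0.1 * stats::runif(3 * width, 0.5, 1.5),
      phase = stats::runif(3 * width, 0, 2 * pi),
      specular = FALSE)
    sc <- rbind(sc, band)
  }
  sc$depth_um <- side * sc$depth_um
  sc
}

phantom_random <- function(width, extent, side) {
  n <- 6 * width
  data.frame(lateral = sample.int(width, n, replace = TRUE),
             depth_um = side * stats::runif(n, -extent / 2, extent / 2),
             reflectivity = stats::runif(n, 0.05, 0.5),
             phase = stats::runif(n, 0, 2 * pi),
             specular = FALSE)
}
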