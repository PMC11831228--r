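single_scatterer <- function(depth, refl = 0.5, phase = 0, width = 1) {
  structure(list(
    scatterers = data.frame(lateral = seq_len(width), depth_um = depth,
                            reflectivity = refl, phase = phase,
                            specular = TRUE),
    structure_kind = "random", width = as.integer(width),
    extent_depth_um = 2 * abs(depth) + 1, seed = 1L),
    class = "phantom")
}

test_that("a single reflector peaks at the predicted depth bin", {
  acq <- test_acq()
  bin_um <- 300 / 64
  for (d in c(40, 87, 133)) {
    fr <- synth_fringe(single_scatterer(d), acq, 1, z_offset_um = 150)
    tom <- reconstruct(fr)
    expect_equal(which.max(Mod(tom)), round((d + 150) / bin_um) + 1,
                 tolerance = 1.01)
  }
})

test_that("an empty phantom yields noise at the configured floor", {
  acq <- test_acq(seed = 2)
  empty <- structure(list(
    scatterers = data.frame(lateral = integer(), depth_um = numeric(),
                            reflectivity = numeric(), phase = numeric(),
                            specular = logical()),
    structure_kind = "random", width = 4L, extent_depth_um = 100,
    seed = 1L), class = "phantom")
  ax <- octccr:::sweep_axis(acq)
  mags <- unlist(lapply(1:200, function(i) {
    fr <- synth_fringe(empty, acq, 1, z_offset_um = 0, noise_seed = i)
    Mod(reconstruct(fr / ax$m_ref))
  }))
  floor_db <- 20 * log10(mean(mags))
  expect_lt(abs(floor_db - acq$noise_floor_db), 1)
})

test_that("zero-delay fringes obey the Hermitian fold identity", {
  acq <- test_acq()
  # two reflectors at +/- d fold onto one displayed location
  d <- 60
  ph2 <- structure(list(
    scatterers = data.frame(lateral = c(1, 1), depth_um = c(d, -d),
                            reflectivity = 0.4, phase = c(0.7, 2.1),
                            specular = TRUE),
    structure_kind = "random", width = 1L, extent_depth_um = 130,
    seed = 1L), class = "phantom")
  fr <- synth_fringe(ph2, acq, 1, z_offset_um = 0)
  half <- Mod(reconstruct(fr))
  peak <- which.max(half)
  expect_equal(peak, round(d / (300 / 64)) + 1, tolerance = 1.01)
  # only ONE peak location: conjugate of -d folds onto +d
  rest <- half[-((peak - 3):(peak + 3))]
  expect_lt(max(rest), 0.05 * half[peak])

  # exact identity FFT(fringe)[b] = C[b] + Conj(C[(N-b) mod N]) with C
  # the analytic one-sided spectrum
  C <- analytic_fringe(c(d, -d), c(0.4, 0.4), c(0.7, 2.1), 0, 128, 300)
  Cm <- naive_dft(C)
  full <- reconstruct(fr, half_range = FALSE)[, 1]
  want <- Cm + Conj(Cm[c(1, 128:2)])
  expect_lt(max(Mod(full - want)), 1e-6 * max(Mod(full)))
})

test_that("make_pair enforces the offset precondition and is deterministic", {
  acq <- test_acq()
  ph <- phantom("layered", width = 8, extent_depth_um = 180, seed = 4)
  bad <- acquisition_config(spectrum_config(n_samples = 128),
                            z_offset_um = 50, ascans_per_bscan = 8,
                            depth_range_um = 300)
  expect_error(make_pair(ph, bad), "z_offset")

  acq8 <- acquisition_config(spectrum_config(n_samples = 128),
                             ascans_per_bscan = 8, depth_range_um = 300,
                             seed = 3)
  p1 <- make_pair(ph, acq8)
  p2 <- make_pair(ph, acq8)
  expect_identical(p1, p2)
  expect_identical(dim(p1$input_intensity), dim(p1$target_intensity))
  expect_identical(dim(p1$input_intensity), dim(p1$input_phase))
})

test_that("the input scan contains the folded artifact, the target does not", {
  acq <- test_acq(seed = 6)
  ph <- phantom("layered", width = 64, extent_depth_um = 180, seed = 8)
  pr <- make_pair(ph, acq, noise = FALSE)
  tgt <- unclass(pr$target_intensity) * 1.0
  inp <- unclass(pr$input_intensity) * 1.0
  # fold the ground truth back about the zero delay: rows at |z - z_off|
  z_off_bin <- 33  # 150 um at 4.6875 um/bin, 1-based
  fold_rows <- abs(seq_len(64) - z_off_bin) + 1
  folded <- rowsum(tgt, fold_rows)[seq_len(32), ]
  score <- function(img) {
    a <- img[seq_len(32), ]
    stats::cor(as.numeric(a), as.numeric(folded))
  }
  expect_gt(score(inp), 0.6)          # artifact-corrupted input matches fold
  expect_gt(score(inp) - score(tgt), 0.3)  # ground truth does not
})

test_that("fold side flips the interface phase difference, not intensity", {
  # a bare sheet: two specular faces a constant (integer-bin) thickness
  # apart with reflection phases differing by pi/2.  Folding the sheet to
  # the other side of the zero delay leaves the two displayed peak
  # magnitudes unchanged but shifts the phase difference between the two
  # peaks by pi — the disambiguation signal the phase channel carries.
  acq <- test_acq()
  bin_um <- 300 / 64
  d1 <- 60; thick <- 4 * bin_um
  sheet <- function(side) structure(list(
    scatterers = data.frame(lateral = 1, depth_um = side * c(d1, d1 + thick),
                            reflectivity = 0.5, phase = c(pi / 2, 0),
                            specular = TRUE),
    structure_kind = "random", width = 1L, extent_depth_um = 300,
    seed = 1L), class = "phantom")
  stats_of <- function(side) {
    tom <- reconstruct(synth_fringe(sheet(side), acq, 1, z_offset_um = 0))
    r1 <- round(d1 / bin_um) + 1
    r2 <- r1 + 4
    list(mags = Mod(tom[c(r1, r2), 1]),
         dphi = Arg(tom[r2, 1] / tom[r1, 1]))
  }
  a <- stats_of(1); b <- stats_of(-1)
  expect_equal(a$mags, b$mags, tolerance = 0.02)
  flip <- (a$dphi - b$dphi) %% (2 * pi)
  expect_equal(flip, pi, tolerance = 0.05)
})

test_that("generate_dataset is reproducible and volume-structured", {
  acq <- acquisition_config(spectrum_config(n_samples = 64),
                            ascans_per_bscan = 16, depth_range_um = 150,
                            seed = 2)
  d1 <- generate_dataset(3, 2, kinds = c("layered", "random"), acq = acq,
                         seed = 5, extent_depth_um = 100)
  d2 <- generate_dataset(3, 2, kinds = c("layered", "random"), acq = acq,
                         seed = 5, extent_depth_um = 100)
  expect_identical(d1$pairs, d2$pairs)
  expect_identical(d1$manifest, d2$manifest)
  expect_equal(nrow(d1$manifest), 6)
  expect_equal(unique(d1$manifest$volume_id), c("vol01", "vol02", "vol03"))
  expect_equal(d1$manifest$kind, c("layered", "layered", "random",
                                   "random", "layered", "layered"))
  # distinct volumes get distinct phantoms; frames within a volume differ
  expect_false(identical(d1$pairs[[1]]$input_intensity,
                         d1$pairs[[3]]$input_intensity))
  expect_false(identical(d1$pairs[[1]]$input_intensity,
                         d1$pairs[[2]]$input_intensity))

  d3 <- generate_dataset(1, 1, acq = acq, seed = 5, extent_depth_um = 100)
  expect_equal(nrow(d3$manifest), 1)

  dir <- tempfile()
  write_dataset(d1, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(file.path(dir, "input_i")), 6)
  back <- read_gray_png(file.path(dir, "target", "vol01_001.png"))
  expect_equal(unclass(back), unclass(d1$pairs[[1]]$target_intensity),
               ignore_attr = TRUE)
})

test_that("all phantom kinds render and stay within their extent", {
  for (k in c("layered", "skin_like", "eye_like", "random")) {
    ph <- phantom(k, width = 12, extent_depth_um = 200, seed = 3)
    expect_true(all(abs(ph$scatterers$depth_um) <= 100))
    expect_true(all(ph$scatterers$reflectivity >= 0 &
                      ph$scatterers$reflectivity <= 1))
    expect_gt(nrow(ph$scatterers), 10)
  }
})

test_that("fringe volumes round-trip through float TIFF + sidecar", {
  acq <- test_acq(seed = 12)
  ph <- phantom("layered", width = 6, extent_depth_um = 180, seed = 2)
  acq6 <- acquisition_config(spectrum_config(n_samples = 128),
                             ascans_per_bscan = 6, depth_range_um = 300,
                             seed = 12)
  fr <- octccr:::synth_bscan_fringes(ph, acq6, 0, noise_seed = 3)
  path <- tempfile(fileext = ".tif")
  write_fringes(list(fr, fr * 0.5), acq6, path)
  back <- read_fringes(path)
  expect_length(back$fringes, 2)
  expect_lt(max(abs(back$fringes[[1]] - fr)), 1e-6 * diff(range(fr)))
  expect_equal(back$meta$n_samples, 128)
  expect_equal(back$meta$depth_range_um, 300)
  # reconstruction from the round-tripped fringes matches
  a <- unclass(to_intensity(reconstruct(fr), norm_params(-60, 5)))
  b <- unclass(to_intensity(reconstruct(back$fringes[[1]]),
                            norm_params(-60, 5)))
  expect_lte(max(abs(a - b)), 1)
})

test_that("out-of-range scatterers trigger the aliasing warning", {
  acq <- test_acq()
  expect_warning(synth_fringe(single_scatterer(200), acq, 1,
                              z_offset_um = 200), "alias")
})
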