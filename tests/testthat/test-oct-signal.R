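test_that("reconstruct recovers cosine peaks and respects linearity", {
  n <- 1024
  f <- cos(2 * pi * 32 * (0:(n - 1)) / n)
  full <- reconstruct(f, half_range = FALSE)
  mags <- Mod(full[, 1])
  peaks <- sort(order(mags, decreasing = TRUE)[1:2])
  expect_equal(peaks, c(33, 993))  # bins 32 and N-32 (1-based rows)
  expect_equal(mags[33], mags[993], tolerance = 1e-12)
  half <- reconstruct(f, half_range = TRUE)
  expect_equal(nrow(half), n / 2)
  expect_equal(which.max(Mod(half[, 1])), 33)

  z <- reconstruct(matrix(0, 64, 3))
  expect_true(all(Mod(z) == 0))
})

test_that("FFT agrees with the direct O(N^2) DFT oracle and is Hermitian", {
  set.seed(11)
  for (n in c(64, 256)) {
    x <- rnorm(n)
    got <- reconstruct(x, half_range = FALSE)[, 1]
    want <- naive_dft(x)
    expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-9)
    # Hermitian symmetry X[N-k] = Conj(X[k])
    k <- 2:n
    expect_lt(max(Mod(got[n + 2 - k] - Conj(got[k]))), 1e-9 * max(Mod(got)))
  }
})

test_that("reconstruct validates its input", {
  expect_error(reconstruct(c(1, 2, NA, 4)), "non-finite")
  expect_error(reconstruct(rnorm(33)), "even")
})

test_that("hann window suppresses spectral leakage sidelobes", {
  n <- 256
  f <- cos(2 * pi * 20.5 * (0:(n - 1)) / n)  # off-bin frequency
  plain <- Mod(reconstruct(f))
  hann <- Mod(reconstruct(f, window = "hann"))
  far <- 60:128  # far from the peak
  expect_lt(max(hann[far, 1]) / max(hann), max(plain[far, 1]) / max(plain))
})

test_that("to_intensity maps the dB window linearly onto 0..255", {
  norm <- norm_params(-40, 0)
  vals <- matrix(complex(modulus = 10^(c(-40, -20, 0) / 20), argument = 0),
                 1, 3)
  img <- to_intensity(vals, norm)
  expect_s3_class(img, "gray_image")
  expect_equal(as.integer(img), c(0L, 128L, 255L))
  # clipping outside the window
  out <- to_intensity(matrix(complex(modulus = c(1e-4, 10), argument = 0),
                             1, 2), norm)
  expect_equal(as.integer(out), c(0L, 255L))
  # monotone nondecreasing in |value|
  mags <- sort(runif(50, 1e-3, 1))
  px <- as.integer(to_intensity(matrix(complex(modulus = mags, argument = 0),
                                       1, 50), norm))
  expect_true(all(diff(px) >= 0))
  expect_error(norm_params(0, 0), "exceed")
})

test_that("per-image min-max mode handles the degenerate constant image", {
  flat <- matrix(complex(modulus = 0.5, argument = 0), 4, 4)
  img <- to_intensity(flat, mode = "minmax")
  expect_true(all(img == 0L))
})

test_that("to_phase quantizes [0, 2pi) to 0..255 with the floor rule", {
  z <- matrix(complex(argument = c(0, pi, 2 * pi - 1e-9), modulus = 1), 1, 3)
  img <- to_phase(z)
  expect_equal(as.integer(img), c(0L, 128L, 255L))
  expect_equal(as.integer(to_phase(matrix(0 + 0i, 1, 1))), 0L)

  # conjugation identity p' = (256 - p) mod 256 holds to within one
  # quantization step under the floor rule: conjugate pairs of interior
  # phases land in bins summing to 255; bin-centre phases do so
  # deterministically
  phis <- 2 * pi * (0:255 + 0.5) / 256
  zb <- matrix(complex(argument = phis, modulus = 1), 1, 256)
  expect_equal(as.integer(to_phase(Conj(zb))),
               255L - as.integer(to_phase(zb)))
  set.seed(3)
  z <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  s <- (as.integer(to_phase(z)) + as.integer(to_phase(Conj(z)))) %% 256
  expect_true(all(s %in% c(0L, 255L)))

  # bijection over the 256 quantized bins
  phis <- (0:255 + 0.5) * 2 * pi / 256
  px <- as.integer(to_phase(matrix(complex(argument = phis, modulus = 1),
                                   1, 256)))
  expect_equal(px, 0:255)
})

test_that("denormalize inverts the intensity mapping to half a gray step", {
  norm <- norm_params(0, 51)
  img <- gray_image(matrix(c(0, 128, 255), 1, 3), "intensity")
  expect_equal(denormalize(img, norm)[1, ], c(0, 25.6, 51))
  expect_error(denormalize(to_phase(matrix(1 + 1i, 2, 2)), norm),
               "intensity")

  set.seed(5)
  tom <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  win <- norm_params(-45, 6)
  db <- 20 * log10(Mod(tom) + 1e-12)
  clipped <- pmin(pmax(db, win$log_floor), win$log_ceil)
  back <- denormalize(to_intensity(tom, win), win)
  expect_lt(max(abs(back - clipped)), (win$log_ceil - win$log_floor) / 510)
})

test_that("axial resolution follows the Gaussian coherence-length formula", {
  expect_equal(axial_resolution(1300, 90), 8.286, tolerance = 1e-3)
  expect_equal(round(axial_resolution(1300, 90)), 8)
  expect_equal(axial_resolution(1300, 180), axial_resolution(1300, 90) / 2)
  expect_equal(axial_resolution(1300, 90, 1.38), 6.004, tolerance = 1e-3)
  expect_equal(axial_resolution(spectrum_config(1300, 90, 256, 1.38)),
               axial_resolution(1300, 90, 1.38))
})

test_that("gray PNG round trip preserves pixels", {
  img <- random_gray(20, 30, seed = 9)
  path <- tempfile(fileext = ".png")
  write_gray_png(img, path)
  back <- read_gray_png(path)
  expect_equal(unclass(back), unclass(img))
})

test_that("spectrum_config rejects invalid sources", {
  expect_error(spectrum_config(n_samples = 33), "even")
  expect_error(spectrum_config(bandwidth_fwhm_nm = 2000), "bandwidth")
  expect_error(spectrum_config(center_wavelength_nm = -1))
})
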