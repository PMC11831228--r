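# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the DFT is the O(N^2) definition, SSIM is a
# per-window double loop, and the complex fringe spectrum is built from
# the analytic (one-sided) signal.

# O(N^2) direct DFT of a real or complex vector (definition, no FFT)
naive_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)), complex(1))
}

# Windowed SSIM recomputed per window with explicit loops (0-255 scale,
# 11x11 Gaussian sigma 1.5, valid positions only)
naive_ssim <- function(a, b) {
  a <- unclass(a) * 1.0; b <- unclass(b) * 1.0
  w <- 11
  g1 <- exp(-((1:w - 6)^2) / (2 * 1.5^2)); g1 <- g1 / sum(g1)
  wts <- outer(g1, g1)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  vals <- c()
  for (i in 1:(nrow(a) - w + 1)) {
    for (j in 1:(ncol(a) - w + 1)) {
      pa <- a[i:(i + w - 1), j:(j + w - 1)]
      pb <- b[i:(i + w - 1), j:(j + w - 1)]
      m1 <- sum(wts * pa); m2 <- sum(wts * pb)
      v1 <- sum(wts * pa^2) - m1^2
      v2 <- sum(wts * pb^2) - m2^2
      cv <- sum(wts * pa * pb) - m1 * m2
      vals <- c(vals, ((2 * m1 * m2 + c1) * (2 * cv + c2)) /
                  ((m1^2 + m2^2 + c1) * (v1 + v2 + c2)))
    }
  }
  mean(vals)
}

# Analytic (complex, one-sided) spectrum of a set of scatterers for one
# A-line, sampled like the simulator's sweep: the real fringe is
# c + Conj(c) for this c, so FFT(fringe)[b] = C[b] + Conj(C[(N-b) mod N]).
analytic_fringe <- function(depths, refl, phases, z_offset, n, depth_range,
                            lambda0_nm = 1300, dlambda_nm = 90) {
  dk <- pi / (2 * depth_range)
  k0 <- 2 * pi / (lambda0_nm / 1000)
  k <- k0 + (seq_len(n) - 1 - n / 2) * dk
  dkf <- 2 * pi * (dlambda_nm / 1000) / (lambda0_nm / 1000)^2
  env <- exp(-4 * log(2) * ((k - k0) / dkf)^2)
  z <- depths + z_offset
  rowSums(vapply(seq_along(z), function(s)
    0.5 * refl[s] * env * exp(1i * (2 * k * z[s] + phases[s])),
    complex(n)))
}

# quick small paired samples for training tests (pure synthetic images)
random_gray <- function(h, w, seed, kind = "intensity") {
  set.seed(seed)
  gray_image(matrix(sample(0:255, h * w, replace = TRUE), h, w), kind)
}

toy_pairs <- function(n, h = 32, w = 32, seed = 1, identity_task = FALSE) {
  lapply(seq_len(n), function(i) {
    ii <- random_gray(h, w, seed + 7 * i)
    pp <- random_gray(h, w, seed + 7 * i + 1, "phase")
    tt <- if (identity_task) ii else random_gray(h, w, seed + 7 * i + 2)
    structure(list(input_intensity = ii, input_phase = pp,
                   target_intensity = tt,
                   volume_id = sprintf("vol%02d", (i - 1) %/% 4 + 1),
                   frame_index = i),
              class = "paired_sample")
  })
}

# small canonical acquisition used by synthetic-data tests
test_acq <- function(seed = 1, n_samples = 128, width = 64)
  acquisition_config(spectrum_config(n_samples = n_samples),
                     ascans_per_bscan = width, depth_range_um = 300,
                     seed = seed)
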