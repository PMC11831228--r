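#!/usr/bin/env Rscript

# Extended (not part of the default test suite) intensity-vs-phase
# comparison at a scale closer to a real acquisition: >= 200 paired
# B-scans of 128x128 pixels, layered and skin-like phantoms, trained for
# dozens of epochs per variant.  Expect on the order of 1-2 h per seed
# on a single CPU core.
#   Rscript scripts/phase_advantage.R --seed 1 --out results/phase_advantage.json

suppressPackageStartupMessages(library(octccr))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
seed <- as.integer(arg_val("--seed", "1"))
out_path <- arg_val("--out", "results/phase_advantage.json")
dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)

P <- S <- matrix(NA, 3, 2)
for (k in 1:3) {
  s <- seed + k - 1
  ex <- run_experiment(experiment_config(
    n_volumes = 18, frames_per_volume = 12,       # 216 pairs
    kinds = c("layered", "layered", "skin_like"),
    seed = s, test_volumes = sprintf("vol%02d", 15:18),
    generator_depth = 7, base_features = 8,
    acq = acquisition_config(spectrum_config(n_samples = 256),
                             ascans_per_bscan = 128,
                             depth_range_um = 600,
                             noise_floor_db = -60, seed = s),
    norm = norm_params(-55, 5), window = "hann",
    train = train_config(max_epochs = 40, val_fraction = 0.05, seed = s)),
    verbose = TRUE)
  P[k, ] <- c(ex$report_i$mean_psnr, ex$report_p$mean_psnr)
  S[k, ] <- c(ex$report_i$mean_ssim, ex$report_p$mean_ssim)
  message(sprintf("seed %d: PSNR i=%.2f p=%.2f | SSIM i=%.3f p=%.3f",
                  s, P[k, 1], P[k, 2], S[k, 1], S[k, 2]))
}

res <- list(
  mean_psnr_intensity = list(value = mean(P[, 1]), n = 3),
  mean_psnr_phase = list(value = mean(P[, 2]), n = 3),
  mean_ssim_intensity = list(value = mean(S[, 1]), n = 3),
  mean_ssim_phase = list(value = mean(S[, 2]), n = 3))
jsonlite::write_json(res, out_path, auto_unbox = TRUE, digits = NA)
cat("wrote", out_path, "\n")
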