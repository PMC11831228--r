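#' Volume-level train/validation/test split
#'
#' Test data are held out by whole volumetric scans (no B-scan of a test
#' volume ever enters training); within the training volumes, B-scans are
#' shuffled and split `1 - val_fraction : val_fraction` (default 95:5)
#' into train and validation.
#'
#' @param manifest Data frame with at least `volume_id` and `frame_index`
#'   (as produced by [generate_dataset()]).
#' @param test_volumes Character vector of volume ids to hold out, or a
#'   single number interpreted as the count of test volumes (chosen by
#'   seeded draw).
#' @param val_fraction Fraction of training B-scans used for validation.
#' @param seed Integer seed.
#' @return List of three manifests `train`, `val`, `test`; volumes in
#'   `test` are disjoint from the others and no frame appears twice.
#' @export
split_dataset <- function(manifest, test_volumes, val_fraction = 0.05,
                          seed = 1) {
  stop_if_not(all(c("volume_id", "frame_index") %in% names(manifest)),
              "manifest must have volume_id and frame_index")
  stop_if_not(val_fraction > 0 && val_fraction < 1,
              "val_fraction must be in (0, 1)")
  vols <- unique(manifest$volume_id)
  stop_if_not(length(vols) >= 2, "need at least 2 volumes to split")
  with_seed(seed, {
    if (is.numeric(test_volumes)) {
      stop_if_not(is_count(test_volumes) && test_volumes < length(vols),
                  "test_volumes count must leave at least 1 training volume")
      test_volumes <- sample(vols, test_volumes)
    }
    stop_if_not(all(test_volumes %in% vols), "unknown test volume id")
    test <- manifest[manifest$volume_id %in% test_volumes, , drop = FALSE]
    tr_all <- manifest[!manifest$volume_id %in% test_volumes, , drop = FALSE]
    n <- nrow(tr_all)
    n_val <- round(val_fraction * n)
    if (n_val < 1)
      stop("val_fraction yields an empty validation set", call. = FALSE)
    stop_if_not(n_val < n, "val_fraction leaves no training B-scans")
    idx <- sample.int(n)
    out <- list(train = tr_all[sort(idx[-seq_len(n_val)]), , drop = FALSE],
                val = tr_all[sort(idx[seq_len(n_val)]), , drop = FALSE],
                test = test)
    stopifnot(!any(out$test$volume_id %in% out$train$volume_id),
              !any(out$test$volume_id %in% out$val$volume_id))
    out
  })
}

#' Experiment configuration for the intensity-vs-phase comparison
#'
#' Bundles everything needed by [run_experiment()]: the synthetic dataset
#' parameters, the shared architecture/optimizer settings for the two
#' model variants (intensity-only and intensity+phase), and the
#' evaluation options.  Both variants share the same data, the same
#' training budget and the same seeds, so any performance difference is
#' attributable to the phase channel.
#'
#' @param n_volumes,frames_per_volume,kinds,extent_depth_um Dataset layout
#'   (see [generate_dataset()]).
#' @param acq An [acquisition_config()].
#' @param test_volumes Count (or ids) of held-out test volumes.
#' @param generator_depth,base_features Architecture shared by variants.
#' @param train A [train_config()].
#' @param weights A [loss_weights()].
#' @param norm [norm_params()] display window for the dataset; the
#'   default floor sits above the default noise floor, clipping the
#'   background to black as displays commonly do.
#' @param window Spectral apodization for the dataset renders; the
#'   default experiment apodizes because its sweep covers only part of
#'   the source envelope, whose truncation sidelobes would otherwise
#'   dominate the deep image rows.
#' @param fid_runs FID subsample runs on the test set (0 disables).
#' @param seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_volumes = 14, frames_per_volume = 3,
                              kinds = "layered",
                              acq = acquisition_config(
                                spectrum = spectrum_config(n_samples = 64),
                                ascans_per_bscan = 32,
                                depth_range_um = 300,
                                noise_floor_db = -60),
                              extent_depth_um = 0.6 * acq$depth_range_um,
                              test_volumes = 4,
                              generator_depth = 5, base_features = 8,
                              train = train_config(max_epochs = 96,
                                                   val_fraction = 0.1),
                              weights = loss_weights(),
                              norm = norm_params(-55, 5),
                              window = c("hann", "none"),
                              fid_runs = 0, seed = 1) {
  window <- match.arg(window)
  structure(list(n_volumes = n_volumes,
                 frames_per_volume = frames_per_volume, kinds = kinds,
                 acq = acq, extent_depth_um = extent_depth_um,
                 test_volumes = test_volumes,
                 generator_depth = generator_depth,
                 base_features = base_features, train = train,
                 weights = weights,
                 norm = norm,
                 window = window,
                 fid_runs = fid_runs,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the end-to-end intensity-vs-phase comparison
#'
#' Generates (or reuses) a paired dataset, splits it at volume level,
#' trains the intensity-only and intensity+phase variants at matched
#' budget, evaluates both on the held-out test volumes, and compares
#' their per-image score distributions with two-sided variance-ratio
#' F-tests.  Fully seeded: the same configuration reproduces the same
#' report.
#'
#' @param cfg An [experiment_config()].
#' @param dataset Optional pre-generated [generate_dataset()] result; by
#'   default the dataset is generated from `cfg`.
#' @param outdir Optional directory; when given, manifests, checkpoints,
#'   the per-image report CSV, a JSON summary and a side-by-side gallery
#'   are written there.
#' @param verbose Print progress.
#' @return An object of class `ccr_experiment`: fitted models `model_i`
#'   and `model_p`, their test-set `report_i` / `report_p`, the split
#'   manifests, and `f_tests` (PSNR and SSIM p-values between variants).
#' @export
run_experiment <- function(cfg, dataset = NULL, outdir = NULL,
                           verbose = FALSE) {
  stop_if_not(inherits(cfg, "experiment_config"),
              "cfg must be an experiment_config")
  if (is.null(dataset))
    dataset <- generate_dataset(cfg$n_volumes, cfg$frames_per_volume,
                                kinds = cfg$kinds, acq = cfg$acq,
                                seed = derive_seed(cfg$seed, 1),
                                extent_depth_um = cfg$extent_depth_um,
                                norm = cfg$norm, window = cfg$window)
  split <- split_dataset(dataset$manifest, cfg$test_volumes,
                         val_fraction = cfg$train$val_fraction,
                         seed = derive_seed(cfg$seed, 2))
  key <- function(m) paste(m$volume_id, m$frame_index)
  all_keys <- key(dataset$manifest)
  trainval <- dataset$pairs[all_keys %in% c(key(split$train),
                                            key(split$val))]
  # volume-level leakage assertion at load time
  stopifnot(!any(vapply(trainval, `[[`, "", "volume_id") %in%
                   split$test$volume_id))
  test_pairs <- dataset$pairs[all_keys %in% key(split$test)]

  h <- nrow(dataset$pairs[[1]]$input_intensity)
  wd <- ncol(dataset$pairs[[1]]$input_intensity)
  fit_variant <- function(chan) {
    mc <- model_config(in_channels = chan,
                       generator_depth = cfg$generator_depth,
                       base_features = cfg$base_features,
                       image_height = h, image_width = wd,
                       seed = cfg$train$seed)
    if (verbose)
      message(sprintf("[train] %d-channel variant", chan))
    ccr_gan(trainval, in_channels = chan, model = mc, train = cfg$train,
            weights = cfg$weights, verbose = verbose)
  }
  model_i <- fit_variant(1)
  model_p <- fit_variant(2)
  emb <- embedder(seed = derive_seed(cfg$seed, 3))
  report_i <- evaluate_model(model_i, test_pairs, fid_runs = cfg$fid_runs,
                             emb = emb, seed = derive_seed(cfg$seed, 4))
  report_p <- evaluate_model(model_p, test_pairs, fid_runs = cfg$fid_runs,
                             emb = emb, seed = derive_seed(cfg$seed, 4))
  f_tests <- list(
    psnr = f_test(report_i$per_image$psnr, report_p$per_image$psnr),
    ssim = f_test(report_i$per_image$ssim, report_p$per_image$ssim))
  out <- structure(list(model_i = model_i, model_p = model_p,
                        report_i = report_i, report_p = report_p,
                        split = split, f_tests = f_tests, config = cfg),
                   class = "ccr_experiment")
  if (!is.null(outdir)) write_experiment(out, test_pairs, outdir)
  out
}

write_experiment <- function(exp, test_pairs, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(exp$split))
    utils::write.csv(exp$split[[s]],
                     file.path(outdir, paste0("manifest_", s, ".csv")),
                     row.names = FALSE)
  save_checkpoint(exp$model_i, file.path(outdir, "model_i.rds"))
  save_checkpoint(exp$model_p, file.path(outdir, "model_p.rds"))
  per <- rbind(cbind(variant = "i", exp$report_i$per_image),
               cbind(variant = "p", exp$report_p$per_image))
  utils::write.csv(per, file.path(outdir, "report.csv"), row.names = FALSE)
  summ <- list(
    mean_psnr = list(i = exp$report_i$mean_psnr, p = exp$report_p$mean_psnr),
    mean_ssim = list(i = exp$report_i$mean_ssim, p = exp$report_p$mean_ssim),
    fid = list(i = exp$report_i$fid[c("mean", "sd")],
               p = exp$report_p$fid[c("mean", "sd")]),
    f_test_p = list(psnr = exp$f_tests$psnr$p_value,
                    ssim = exp$f_tests$ssim$p_value),
    best_epoch = list(i = exp$model_i$best_epoch,
                      p = exp$model_p$best_epoch))
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  gal <- file.path(outdir, "gallery")
  dir.create(gal, showWarnings = FALSE)
  for (i in seq_len(min(4, length(test_pairs)))) {
    p <- test_pairs[[i]]
    panel <- cbind(unclass(p$input_intensity),
                   unclass(exp$report_i$predictions[[i]]),
                   unclass(exp$report_p$predictions[[i]]),
                   unclass(p$target_intensity))
    write_gray_png(gray_image(panel, "intensity"),
                   file.path(gal, sprintf("%s_%03d.png", p$volume_id,
                                          p$frame_index)))
  }
  invisible(outdir)
}

#' @export
print.ccr_experiment <- function(x, ...) {
  cat("Intensity-vs-phase conjugate-removal experiment\n")
  cat(sprintf("  test images: %d\n", nrow(x$report_i$per_image)))
  cat(sprintf("  intensity variant : PSNR %6.2f dB, SSIM %.4f\n",
              x$report_i$mean_psnr, x$report_i$mean_ssim))
  cat(sprintf("  phase variant     : PSNR %6.2f dB, SSIM %.4f\n",
              x$report_p$mean_psnr, x$report_p$mean_ssim))
  cat(sprintf("  F-test p (PSNR) = %.3f, (SSIM) = %.3f\n",
              x$f_tests$psnr$p_value, x$f_tests$ssim$p_value))
  invisible(x)
}
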