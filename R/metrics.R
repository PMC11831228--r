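#' Peak signal-to-noise ratio between two 8-bit images
#'
#' `10 * log10(255^2 / MSE)`.  Identical images (MSE 0) return the capped
#' sentinel 100 dB so that aggregation stays finite.
#'
#' @param a,b `gray_image`s (or numeric matrices on the 0-255 scale) of
#'   identical shape.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  stop_if_not(identical(dim(a), dim(b)), "images must have the same shape")
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(100)
  min(10 * log10(255^2 / mse), 100)
}

#' Structural similarity index between two 8-bit images
#'
#' Windowed SSIM with the standard parameters: 11x11 Gaussian window with
#' sigma 1.5, stabilizers `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`,
#' averaged over all (valid) window positions.
#'
#' @param a,b `gray_image`s or numeric matrices (0-255 scale), identical
#'   shape, at least 11 pixels along each side.
#' @return SSIM in \[-1, 1\]; exactly 1 for identical images.
#' @export
ssim <- function(a, b) {
  a <- unclass(a) * 1.0; b <- unclass(b) * 1.0
  stop_if_not(identical(dim(a), dim(b)), "images must have the same shape")
  win <- 11L
  stop_if_not(nrow(a) >= win && ncol(a) >= win,
              "images must be at least 11x11")
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * 1.5^2))
  g <- g / sum(g)
  kern <- matrix(outer(g, g), 1, win * win)  # row-major over (ki, kj)
  f <- function(m) {
    out <- nn_conv_fwd(array(m, c(dim(m), 1)), kern, 0, win, 1L, 0L)
    out[, , 1]
  }
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  mu1 <- f(a); mu2 <- f(b)
  s1 <- f(a * a) - mu1^2
  s2 <- f(b * b) - mu2^2
  s12 <- f(a * b) - mu1 * mu2
  mean(((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
         ((mu1^2 + mu2^2 + c1) * (s1 + s2 + c2)))
}

#' Lightweight deterministic image embedder for Frechet distances
#'
#' The Frechet distance needs a fixed feature space.  The canonical
#' pretrained classifier embedding is available through the
#' `embed_fn` hook; the default is a seeded fixed random convolutional
#' projection (two 3x3 conv + ReLU stages on a 32x32 downsampled image,
#' per-channel mean and sd pooling), which is deterministic, needs no
#' download, and is adequate for comparing image sets *within* one
#' embedder.  Reports should always record the embedder identity.
#'
#' @param feature_dim Even feature count (default 16).
#' @param seed Seed fixing the random projection.
#' @param embed_fn Optional replacement: `function(list_of_matrices)`
#'   returning an `n x feature_dim` matrix (adapter for an external
#'   pretrained embedder).
#' @return An object of class `embedder`.
#' @export
embedder <- function(feature_dim = 16, seed = 1, embed_fn = NULL) {
  stop_if_not(is_count(feature_dim) && feature_dim %% 2 == 0,
              "feature_dim must be an even count")
  nf <- feature_dim %/% 2
  ws <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(nf * 9, 0, 0.5), nf, 9),
    W2 = matrix(stats::rnorm(nf * 9 * nf, 0, 0.5 / sqrt(nf)), nf, 9 * nf)))
  structure(list(kind = if (is.null(embed_fn)) "lightweight_fixed"
                 else "external", feature_dim = as.integer(feature_dim),
                 seed = as.integer(seed), weights = ws,
                 embed_fn = embed_fn),
            class = "embedder")
}

# nearest-pixel resize to 32x32 (enough for a fixed random projection)
resize32 <- function(m) {
  ri <- pmax(1, round(seq(1, nrow(m), length.out = 32)))
  ci <- pmax(1, round(seq(1, ncol(m), length.out = 32)))
  m[ri, ci]
}

embed_images <- function(emb, imgs) {
  stop_if_not(inherits(emb, "embedder"), "emb must be an embedder")
  if (!is.null(emb$embed_fn)) {
    fe <- emb$embed_fn(lapply(imgs, function(i) unclass(i) * 1.0))
    stop_if_not(ncol(fe) == emb$feature_dim,
                "embed_fn returned the wrong feature_dim")
    return(fe)
  }
  t(vapply(imgs, function(img) {
    x <- resize32(unclass(img) * 1.0) / 127.5 - 1
    nf <- nrow(emb$weights$W1)
    a1 <- nn_conv_fwd(array(x, c(32, 32, 1)), emb$weights$W1, numeric(nf),
                      3L, 1L, 1L)
    a1 <- pmax(a1, 0)
    a2 <- nn_conv_fwd(a1[seq(1, 32, 2), seq(1, 32, 2), , drop = FALSE],
                      emb$weights$W2, numeric(nf), 3L, 1L, 1L)
    a2 <- pmax(a2, 0)
    c(apply(a2, 3, mean), apply(a2, 3, stats::sd))
  }, numeric(emb$feature_dim)))
}

# principal (symmetric PSD) matrix square root via eigendecomposition
sqrtm_sym <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two Gaussians
#'
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^{1/2})`, the quantity behind
#' the Frechet inception distance.
#'
#' @param mu1,mu2 Mean vectors.
#' @param S1,S2 Covariance matrices.
#' @return Nonnegative scalar.
#' @export
frechet_distance <- function(mu1, S1, mu2, S2) {
  a <- sqrtm_sym(S1)
  m <- a %*% S2 %*% a
  tr_sqrt <- sum(sqrt(pmax(eigen((m + t(m)) / 2, symmetric = TRUE,
                                 only.values = TRUE)$values, 0)))
  max(0, sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) - 2 * tr_sqrt)
}

FID_MIN_SET <- 8L

#' Frechet distance between two image sets
#'
#' Embeds both sets with the same [embedder()], fits a Gaussian
#' (mean/covariance) to each feature cloud and returns their
#' [frechet_distance()].  Zero for identical sets, symmetric, nonnegative.
#' Values are only comparable within one embedder.
#'
#' @param set_a,set_b Lists of `gray_image`s (>= 8 each), or numeric
#'   feature matrices (rows = images) to bypass embedding.
#' @param emb An [embedder()].
#' @return Nonnegative scalar.
#' @export
fid <- function(set_a, set_b, emb = embedder()) {
  fa <- if (is.matrix(set_a)) set_a else {
    stop_if_not(length(set_a) >= FID_MIN_SET,
                sprintf("fid needs at least %d images per set", FID_MIN_SET))
    embed_images(emb, set_a)
  }
  fb <- if (is.matrix(set_b)) set_b else {
    stop_if_not(length(set_b) >= FID_MIN_SET,
                sprintf("fid needs at least %d images per set", FID_MIN_SET))
    embed_images(emb, set_b)
  }
  frechet_distance(colMeans(fa), stats::cov(fa), colMeans(fb),
                   stats::cov(fb))
}

#' Frechet distance with subsample error bars
#'
#' Repeats the FID computation `n_runs` times on random subsamples (drawn
#' without replacement at `subsample_fraction`) of both sets, reporting
#' the per-run values together with their mean and standard deviation.
#'
#' @param set_a,set_b Lists of `gray_image`s.
#' @param emb An [embedder()].
#' @param n_runs Number of subsample runs (>= 2).
#' @param subsample_fraction Fraction of each set per run.
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `runs`.
#' @export
fid_with_errorbars <- function(set_a, set_b, emb = embedder(), n_runs = 5,
                               subsample_fraction = 0.8, seed = 1) {
  stop_if_not(is_count(n_runs) && n_runs >= 2, "n_runs must be >= 2")
  na <- floor(length(set_a) * subsample_fraction)
  nb <- floor(length(set_b) * subsample_fraction)
  stop_if_not(na >= FID_MIN_SET && nb >= FID_MIN_SET,
              sprintf("subsample below the minimum FID set size (%d)",
                      FID_MIN_SET))
  runs <- with_seed(seed, vapply(seq_len(n_runs), function(r) {
    ia <- sample.int(length(set_a), na)
    ib <- sample.int(length(set_b), nb)
    fid(set_a[ia], set_b[ib], emb)
  }, numeric(1)))
  list(mean = mean(runs), sd = stats::sd(runs), runs = runs)
}

#' Two-sided variance-ratio F-test
#'
#' Compares the variances of two score lists (e.g. per-image PSNR of two
#' model variants): `F = s_a^2 / s_b^2` referred to the F distribution
#' with `(n_a - 1, n_b - 1)` degrees of freedom, two-sided p-value
#' `2 * min(cdf, 1 - cdf)`.
#'
#' @param scores_a,scores_b Numeric vectors (>= 2 values, nonzero
#'   variance each).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
f_test <- function(scores_a, scores_b) {
  stop_if_not(length(scores_a) >= 2 && length(scores_b) >= 2,
              "each sample needs at least 2 values")
  va <- stats::var(scores_a); vb <- stats::var(scores_b)
  if (va == 0 || vb == 0)
    stop("zero variance in at least one sample", call. = FALSE)
  f <- va / vb
  df <- c(length(scores_a) - 1, length(scores_b) - 1)
  cdf <- stats::pf(f, df[1], df[2])
  list(statistic = f, df = df, p_value = min(1, 2 * min(cdf, 1 - cdf)))
}

#' Evaluate a fitted model on held-out pairs
#'
#' Runs inference on every pair, computes per-image PSNR and SSIM against
#' the ground truth, and (optionally) the Frechet distance between the
#' generated and ground-truth image sets with subsample error bars.
#'
#' @param model A fitted [ccr_gan()].
#' @param pairs A `paired_dataset` or list of `paired_sample`s.
#' @param fid_runs Number of FID subsample runs (0 disables FID).
#' @param emb An [embedder()].
#' @param seed Seed for the FID subsampling.
#' @return An object of class `metric_report`: `per_image` data frame
#'   (`volume_id`, `frame_index`, `psnr`, `ssim`), summary means/sds,
#'   `fid` (mean/sd/runs or NULL), and the embedder identity.
#' @export
evaluate_model <- function(model, pairs, fid_runs = 0, emb = embedder(),
                           seed = 1) {
  if (inherits(pairs, "paired_dataset")) pairs <- pairs$pairs
  preds <- lapply(pairs, function(p) predict(model, p))
  per <- data.frame(
    volume_id = vapply(pairs, `[[`, "", "volume_id"),
    frame_index = vapply(pairs, `[[`, 1L, "frame_index"),
    psnr = vapply(seq_along(pairs), function(i)
      psnr(preds[[i]], pairs[[i]]$target_intensity), numeric(1)),
    ssim = vapply(seq_along(pairs), function(i)
      ssim(preds[[i]], pairs[[i]]$target_intensity), numeric(1)))
  fd <- NULL
  if (fid_runs > 0) {
    targets <- lapply(pairs, `[[`, "target_intensity")
    fd <- fid_with_errorbars(preds, targets, emb, n_runs = fid_runs,
                             seed = seed)
  }
  structure(list(per_image = per,
                 mean_psnr = mean(per$psnr), sd_psnr = stats::sd(per$psnr),
                 mean_ssim = mean(per$ssim), sd_ssim = stats::sd(per$ssim),
                 fid = fd, embedder_kind = emb$kind,
                 predictions = preds),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: %d images, PSNR %.2f +/- %.2f dB, SSIM %.4f +/- %.4f%s>\n",
              nrow(x$per_image), x$mean_psnr,
              ifelse(is.na(x$sd_psnr), 0, x$sd_psnr), x$mean_ssim,
              ifelse(is.na(x$sd_ssim), 0, x$sd_ssim),
              if (!is.null(x$fid))
                sprintf(", FID %.3f +/- %.3f", x$fid$mean, x$fid$sd)
              else ""))
  invisible(x)
}
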