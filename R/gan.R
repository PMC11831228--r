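#' Optimizer and schedule configuration
#'
#' Adam with learning rate 1e-4 and betas (0.5, 0.999); networks are
#' trained for up to `max_epochs` epochs and the reported model is the
#' epoch maximizing validation PSNR (GAN losses oscillate, so the last
#' epoch is not necessarily the best one).
#'
#' @param learning_rate Adam learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param max_epochs Maximum number of epochs (>= 1).
#' @param batch_size Gradient-accumulation batch size (default 1).
#' @param val_fraction Fraction of training B-scans held out for
#'   validation-based epoch selection (default 0.05, a 95:5 split).
#' @param checkpoint_every Epoch interval for history snapshots.
#' @param seed Integer seed controlling shuffling and initialization.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.5, beta2 = 0.999,
                         max_epochs = 140, batch_size = 1,
                         val_fraction = 0.05, checkpoint_every = 1,
                         seed = 1) {
  stop_if_not(learning_rate > 0, "learning_rate must be > 0")
  stop_if_not(is_count(max_epochs), "max_epochs must be >= 1")
  stop_if_not(val_fraction > 0 && val_fraction < 1,
              "val_fraction must be in (0, 1)")
  stop_if_not(is_count(batch_size), "batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

# gray images (0..255) -> network tensors in [-1, 1] and back
img_to_unit <- function(img) unclass(img) / 127.5 - 1

pair_to_tensors <- function(pair, in_channels) {
  h <- nrow(pair$input_intensity); w <- ncol(pair$input_intensity)
  x <- array(0, c(h, w, in_channels))
  x[, , 1] <- img_to_unit(pair$input_intensity)
  if (in_channels == 2) x[, , 2] <- img_to_unit(pair$input_phase)
  y <- array(img_to_unit(pair$target_intensity), c(h, w, 1))
  list(x = x, y = y)
}

tensor_to_gray <- function(t) {
  px <- pmin(pmax(round((t[, , 1] + 1) * 127.5), 0), 255)
  gray_image(px, "intensity")
}

# One optimization step on a single (x, y) pair: simultaneous G/D
# gradient computation against the current discriminator, returning the
# logged losses and both gradient trees.
gan_step_grads <- function(gen, disc, x, y, w) {
  gf <- generator_forward(gen, x)
  fake <- gf$out
  df <- discriminator_forward(disc, concat_c(x, fake))
  dr <- discriminator_forward(disc, concat_c(x, y))
  n_sc <- length(df$scores)
  lg <- loss_generator(df$scores, fake, y, df$features, dr$features, w)
  ld <- loss_discriminator(dr$scores, df$scores, df$features, dr$features, w)

  feat_sign <- lapply(1:4, function(l)
    sign(df$features[[l]] - dr$features[[l]]) / length(df$features[[l]]))

  # --- generator gradients ---
  g_pre <- w$theta_g * (df$scores - 1) / n_sc
  feat_g <- if (w$perc_mode == "pan" && w$perc_weight > 0)
    lapply(feat_sign, function(s) w$perc_weight * s) else NULL
  dbg <- discriminator_backward(disc, df$cache, g_pre, feat_g)
  nin <- dim(x)[3]
  g_fake <- dbg$gx[, , nin + 1, drop = FALSE] +
    w$lambda_l1 * sign(fake - y) / length(fake)
  ggrads <- generator_backward(gen, gf$cache, g_fake)

  # --- discriminator gradients ---
  lperc <- perc_distance(df$features, dr$features)
  cperc <- if (w$perc_mode == "pan") {
    if (lperc < w$perc_margin) -1 else 0
  } else 1
  featf <- featr <- NULL
  if (cperc != 0) {
    featf <- lapply(feat_sign, function(s) cperc * s)
    featr <- lapply(feat_sign, function(s) -cperc * s)
  }
  dbr <- discriminator_backward(disc, dr$cache,
                                w$theta_d / 2 * (dr$scores - 1) / n_sc,
                                featr)
  dbf <- discriminator_backward(disc, df$cache,
                                w$theta_d / 2 * df$scores / n_sc, featf)
  dgrads <- list(layers = grad_add(dbr$layers, dbf$layers))
  list(loss_g = lg, loss_d = ld, ggrads = ggrads, dgrads = dgrads)
}

#' Fit a complex-conjugate-removal GAN
#'
#' Trains the phase-aware conditional GAN that translates an
#' artifact-corrupted B-scan (sample at the zero-delay position, mirror
#' image folded onto the structure) into its artifact-free counterpart.
#' With `in_channels = 1` the generator sees the intensity image only
#' (intensity variant); with `in_channels = 2` it also receives the phase
#' image, whose conjugation signature disambiguates the fold (phase
#' variant).  Generator and discriminator are optimized together with
#' Adam; after each epoch the mean PSNR on a held-out validation split is
#' logged and the returned model carries the generator of the best epoch.
#'
#' @param pairs A [generate_dataset()] result or a list of
#'   [make_pair()] samples (>= 2).
#' @param in_channels 1 (intensity) or 2 (intensity + phase).
#' @param model A [model_config()]; defaults to a configuration inferred
#'   from the data (depth `min(7, log2(min(height, width)))`).
#' @param train A [train_config()].
#' @param weights A [loss_weights()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `ccr_gan`: the best-epoch generator, the
#'   final discriminator, the configuration, and the per-epoch history
#'   (`epoch`, `loss_g`, `loss_d`, `val_psnr`, `val_ssim`).
#' @seealso [predict.ccr_gan()], [save_checkpoint()], [run_experiment()]
#' @export
ccr_gan <- function(pairs, in_channels = 1, model = NULL,
                    train = train_config(), weights = loss_weights(),
                    verbose = FALSE) {
  if (inherits(pairs, "paired_dataset")) pairs <- pairs$pairs
  stop_if_not(is.list(pairs) && length(pairs) >= 2,
              "need at least 2 training pairs")
  stop_if_not(in_channels %in% c(1, 2), "in_channels must be 1 or 2")
  h <- nrow(pairs[[1]]$input_intensity)
  wd <- ncol(pairs[[1]]$input_intensity)
  if (is.null(model)) {
    depth <- min(7, floor(log2(min(h, wd))))
    model <- model_config(in_channels = in_channels,
                          generator_depth = depth,
                          base_features = 16,
                          image_height = h, image_width = wd,
                          seed = train$seed)
  }
  stop_if_not(model$in_channels == in_channels,
              "model in_channels disagrees with in_channels")
  stop_if_not(model$image_height == h && model$image_width == wd,
              "model image size disagrees with the data")

  with_seed(train$seed, {
    gen <- build_generator(model)
    disc <- build_discriminator(model)
    n <- length(pairs)
    n_val <- max(1, round(train$val_fraction * n))
    stop_if_not(n_val < n, "validation split leaves no training pairs")
    idx <- sample.int(n)
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    tensors <- lapply(pairs, pair_to_tensors, in_channels = in_channels)

    opt_g <- adam_init(net_params(gen))
    opt_d <- adam_init(net_params(disc))
    hist <- NULL
    best <- list(psnr = -Inf, epoch = NA_integer_, gen = NULL,
                 val_ssim = NA_real_)
    for (epoch in seq_len(train$max_epochs)) {
      ord <- sample(tr_idx)
      lg_sum <- 0; ld_sum <- 0
      batch_g <- NULL; batch_d <- NULL; in_batch <- 0
      for (i in ord) {
        st <- gan_step_grads(gen, disc, tensors[[i]]$x, tensors[[i]]$y,
                             weights)
        lg_sum <- lg_sum + st$loss_g; ld_sum <- ld_sum + st$loss_d
        batch_g <- grad_add(batch_g, st$ggrads)
        batch_d <- grad_add(batch_d, st$dgrads)
        in_batch <- in_batch + 1
        if (in_batch == train$batch_size || i == ord[length(ord)]) {
          up <- adam_step(net_params(gen), grad_scale(batch_g, 1 / in_batch),
                          opt_g, train$learning_rate, train$beta1,
                          train$beta2)
          gen <- net_set_params(gen, up$params); opt_g <- up$state
          up <- adam_step(net_params(disc), grad_scale(batch_d, 1 / in_batch),
                          opt_d, train$learning_rate, train$beta1,
                          train$beta2)
          disc <- net_set_params(disc, up$params); opt_d <- up$state
          batch_g <- NULL; batch_d <- NULL; in_batch <- 0
        }
      }
      vm <- eval_generator(gen, tensors[val_idx], pairs[val_idx])
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     loss_g = lg_sum / length(tr_idx),
                                     loss_d = ld_sum / length(tr_idx),
                                     val_psnr = vm$psnr,
                                     val_ssim = vm$ssim))
      if (verbose)
        message(sprintf("epoch %3d  L_G %.4f  L_D %.4f  val PSNR %.2f dB",
                        epoch, lg_sum / length(tr_idx),
                        ld_sum / length(tr_idx), vm$psnr))
      if (vm$psnr > best$psnr)
        best <- list(psnr = vm$psnr, epoch = epoch, gen = gen,
                     val_ssim = vm$ssim)
    }
    structure(list(generator = best$gen, discriminator = disc,
                   model = model, train = train, weights = weights,
                   history = hist, best_epoch = best$epoch,
                   val_psnr = best$psnr, val_ssim = best$val_ssim,
                   n_train = length(tr_idx), n_val = n_val),
              class = "ccr_gan")
  })
}

eval_generator <- function(gen, tensors, pairs) {
  ps <- ss <- numeric(length(tensors))
  for (i in seq_along(tensors)) {
    out <- generator_forward(gen, tensors[[i]]$x, keep_cache = FALSE)$out
    img <- tensor_to_gray(out)
    ps[i] <- psnr(img, pairs[[i]]$target_intensity)
    ss[i] <- ssim(img, pairs[[i]]$target_intensity)
  }
  list(psnr = mean(ps), ssim = mean(ss))
}

#' Remove the conjugate artifact from a B-scan with a fitted model
#'
#' @param object A fitted [ccr_gan()] model.
#' @param input_i Intensity `gray_image` (or a `paired_sample`, whose
#'   input channels are used).
#' @param input_p Phase `gray_image`; required iff the model was trained
#'   with `in_channels = 2`.
#' @param ... Unused.
#' @return The artifact-free intensity image as a `gray_image`.
#' @export
predict.ccr_gan <- function(object, input_i, input_p = NULL, ...) {
  if (inherits(input_i, "paired_sample")) {
    if (object$model$in_channels == 2) input_p <- input_i$input_phase
    input_i <- input_i$input_intensity
  }
  stop_if_not(inherits(input_i, "gray_image"),
              "input_i must be a gray_image")
  m <- object$model
  if (m$in_channels == 2 && is.null(input_p))
    stop("this model takes 2 channels; supply the phase image input_p",
         call. = FALSE)
  if (m$in_channels == 1 && !is.null(input_p))
    stop("this model takes 1 channel; input_p must be NULL", call. = FALSE)
  if (nrow(input_i) != m$image_height || ncol(input_i) != m$image_width)
    stop(sprintf("image size %dx%d does not match the model (%dx%d)",
                 nrow(input_i), ncol(input_i), m$image_height,
                 m$image_width), call. = FALSE)
  x <- array(0, c(m$image_height, m$image_width, m$in_channels))
  x[, , 1] <- img_to_unit(input_i)
  if (m$in_channels == 2) {
    stop_if_not(nrow(input_p) == m$image_height &&
                  ncol(input_p) == m$image_width,
                "phase image size does not match the model")
    x[, , 2] <- img_to_unit(input_p)
  }
  out <- generator_forward(object$generator, x, keep_cache = FALSE)$out
  tensor_to_gray(out)
}

#' @export
print.ccr_gan <- function(x, ...) {
  cat(sprintf(paste0(
    "Conjugate-artifact-removal GAN (%s variant)\n",
    "  image size: %d x %d, U-Net depth %d, base features %d\n",
    "  trained %d epochs on %d pairs (%d validation)\n",
    "  best epoch %d: validation PSNR %.2f dB, SSIM %.4f\n"),
    if (x$model$in_channels == 2) "intensity+phase" else "intensity",
    x$model$image_height, x$model$image_width, x$model$generator_depth,
    x$model$base_features, nrow(x$history), x$n_train + x$n_val, x$n_val,
    x$best_epoch, x$val_psnr, x$val_ssim))
  invisible(x)
}

#' @export
summary.ccr_gan <- function(object, ...) {
  print(object)
  cat("\nPer-epoch history (last 5):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.ccr_gan <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss_g, type = "l", xlab = "epoch",
                 ylab = "loss", main = "adversarial losses")
  graphics::lines(h$epoch, h$loss_d, lty = 2)
  graphics::legend("topright", c("generator", "discriminator"),
                   lty = c(1, 2), bty = "n")
  graphics::plot(h$epoch, h$val_psnr, type = "l", xlab = "epoch",
                 ylab = "validation PSNR (dB)", main = "epoch selection")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint carries the best-epoch generator, the final
#' discriminator, the full configuration and the training history;
#' reloading reproduces identical inference outputs.
#'
#' @param model A fitted [ccr_gan()] object.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  stop_if_not(inherits(model, "ccr_gan"), "model must be a ccr_gan")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stop_if_not(inherits(m, "ccr_gan"), "file does not contain a ccr_gan")
  m
}
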