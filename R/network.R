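#' Network architecture configuration
#'
#' The generator is a U-Net: `generator_depth` stride-2 encoder blocks
#' (4x4 convolutions, instance norm, leaky-ReLU 0.2) mirrored by a decoder
#' of transposed convolutions with skip connections, ending in a tanh
#' single-channel (intensity) output.  The discriminator is a conditional
#' patch classifier with `discriminator_layers` convolutional layers whose
#' final layer emits per-patch scores in (0, 1); its four internal feature
#' maps feed the perceptual feature loss.  Feature widths double per level
#' from `base_features`, capped at `8 * base_features`.  Images whose
#' sides are not multiples of `2^generator_depth` are reflect-padded up to
#' the next multiple and the output is cropped back.
#'
#' @param in_channels 1 (intensity only) or 2 (intensity + phase).
#' @param generator_depth Encoder/decoder levels (default 7).
#' @param discriminator_layers Discriminator conv layers (default 5).
#' @param base_features Feature maps at the first level (default 64).
#' @param image_height,image_width Training image size in pixels.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(in_channels = 1, generator_depth = 7,
                         discriminator_layers = 5, base_features = 64,
                         image_height = 256, image_width = 256, seed = 1) {
  stop_if_not(in_channels %in% c(1, 2), "in_channels must be 1 or 2")
  stop_if_not(is_count(generator_depth) && generator_depth >= 2,
              "generator_depth must be >= 2")
  stop_if_not(discriminator_layers == 5,
              "discriminator_layers must be 5 in this architecture")
  stop_if_not(is_count(base_features), "base_features must be >= 1")
  m <- 2^generator_depth
  if (image_height < m || image_width < m)
    stop(sprintf("image size %dx%d is below 2^generator_depth = %d",
                 image_height, image_width, m), call. = FALSE)
  # the 5-layer patch discriminator (strides 2,2,2,1,1) needs >= 32 px
  if (image_height < 32 || image_width < 32)
    stop("image size must be at least 32x32 for the patch discriminator",
         call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 generator_depth = as.integer(generator_depth),
                 discriminator_layers = as.integer(discriminator_layers),
                 base_features = as.integer(base_features),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 pad_height = as.integer(ceiling(image_height / m) * m),
                 pad_width = as.integer(ceiling(image_width / m) * m),
                 seed = as.integer(seed)),
            class = "model_config")
}

feature_widths <- function(base, depth) base * 2^pmin(seq_len(depth) - 1, 3)

winit <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)

#' Build an untrained U-Net generator
#'
#' @param cfg A [model_config()].
#' @return Generator parameter/structure list (class `ccr_generator`).
#' @export
build_generator <- function(cfg) {
  stop_if_not(inherits(cfg, "model_config"), "cfg must be a model_config")
  d <- cfg$generator_depth
  cw <- feature_widths(cfg$base_features, d)
  hs <- cfg$pad_height / 2^(seq_len(d))
  with_seed(derive_seed(cfg$seed, 11), {
    enc <- lapply(seq_len(d), function(i) {
      cin <- if (i == 1) cfg$in_channels else cw[i - 1]
      list(W = winit(cw[i], K_SIZE^2 * cin), b = numeric(cw[i]),
           gamma = rep(1, cw[i]), beta = numeric(cw[i]),
           norm = i > 1 && hs[i] > 1)
    })
    dec <- lapply(seq_len(d), function(j) {
      cin <- if (j == 1) cw[d] else 2 * cw[d - j + 1]
      cout <- if (j == d) 1L else cw[d - j]
      # reverse-conv layout: rows = tconv input channels
      list(W = winit(cin, K_SIZE^2 * cout), b = numeric(cout),
           gamma = rep(1, cout), beta = numeric(cout),
           norm = j < d && cfg$pad_height / 2^(d - j) > 1)
    })
    structure(list(cfg = cfg, enc = enc, dec = dec),
              class = "ccr_generator")
  })
}

pad_reflect <- function(x, ph, pw) {
  d <- dim(x)
  if (d[1] == ph && d[2] == pw) return(x)
  ri <- c(seq_len(d[1]), rev(seq_len(d[1]))[seq_len(ph - d[1]) + 1])
  ci <- c(seq_len(d[2]), rev(seq_len(d[2]))[seq_len(pw - d[2]) + 1])
  x[ri, ci, , drop = FALSE]
}

crop_to <- function(x, h, w) x[seq_len(h), seq_len(w), , drop = FALSE]

generator_forward <- function(gen, x, keep_cache = TRUE) {
  cfg <- gen$cfg
  d <- cfg$generator_depth
  x <- pad_reflect(x, cfg$pad_height, cfg$pad_width)
  e <- vector("list", d)
  zs <- vector("list", d)
  ncs <- vector("list", d)
  a <- x
  for (i in seq_len(d)) {
    L <- gen$enc[[i]]
    z <- conv_forward(a, L$W, L$b)
    if (L$norm) {
      nc <- inorm_forward(z, L$gamma, L$beta)
      zn <- nc$y
    } else {
      nc <- NULL; zn <- z
    }
    a <- lrelu(zn)
    e[[i]] <- a; zs[[i]] <- zn; ncs[[i]] <- nc
  }
  h <- e[[d]]
  dz <- vector("list", d); dnc <- vector("list", d); dins <- vector("list", d)
  hs <- vector("list", d)
  out <- NULL
  for (j in seq_len(d)) {
    inp <- if (j == 1) h else concat_c(h, e[[d - j + 1]])
    L <- gen$dec[[j]]
    oh <- cfg$pad_height / 2^(d - j)
    ow <- cfg$pad_width / 2^(d - j)
    z <- tconv_forward(inp, L$W, L$b, oh, ow)
    dins[[j]] <- inp
    if (j < d) {
      if (L$norm) {
        nc <- inorm_forward(z, L$gamma, L$beta)
        zn <- nc$y
      } else {
        nc <- NULL; zn <- z
      }
      h <- ifelse(zn > 0, zn, 0)
      dz[[j]] <- zn; dnc[[j]] <- nc; hs[[j]] <- h
    } else {
      out <- tanh(z)
      dz[[j]] <- z
    }
  }
  y <- crop_to(out, cfg$image_height, cfg$image_width)
  if (!keep_cache) return(list(out = y))
  list(out = y,
       cache = list(x = x, e = e, zs = zs, ncs = ncs,
                    dz = dz, dnc = dnc, dins = dins, out_full = out))
}

# Backward through the generator; g is the gradient w.r.t. the cropped
# output.  Returns the parameter-gradient tree (same shape as gen's
# enc/dec params).
generator_backward <- function(gen, cache, g) {
  cfg <- gen$cfg
  d <- cfg$generator_depth
  gfull <- array(0, dim(cache$out_full))
  gfull[seq_len(cfg$image_height), seq_len(cfg$image_width), ] <- g
  genc <- vector("list", d)  # grads accumulated on e[[i]]
  gdec <- vector("list", d)
  g <- gfull * (1 - cache$out_full^2)  # through tanh
  for (j in rev(seq_len(d))) {
    L <- gen$dec[[j]]
    if (j < d) {
      g <- relu_bwd(cache$dz[[j]], g)
      if (L$norm) {
        nb <- inorm_backward(cache$dnc[[j]], L$gamma, g)
        g <- nb$gx; ggamma <- nb$ggamma; gbeta <- nb$gbeta
      } else {
        ggamma <- L$gamma * 0; gbeta <- L$b * 0
      }
    } else {
      ggamma <- L$gamma * 0; gbeta <- L$b * 0
    }
    tb <- tconv_backward(cache$dins[[j]], g, L$W)
    gdec[[j]] <- list(W = tb$gW, b = tb$gb, gamma = ggamma, beta = gbeta)
    gi <- tb$gx
    if (j == 1) {
      genc[[d]] <- grad_add(genc[[d]], gi)
      g <- NULL
    } else {
      nh <- dim(gi)[3] - dim(cache$e[[d - j + 1]])[3]
      genc[[d - j + 1]] <- grad_add(genc[[d - j + 1]],
                                    gi[, , nh + seq_len(dim(gi)[3] - nh),
                                       drop = FALSE])
      # remaining channels: grad w.r.t. h_{j-1}, consumed next iteration
      g <- gi[, , seq_len(nh), drop = FALSE]
    }
  }
  # encoder backward, deepest first; grads on e[[i]] come from skips and
  # from the decoder path through h (already accumulated in genc)
  gprev <- NULL
  egrads <- vector("list", d)
  for (i in rev(seq_len(d))) {
    gi <- genc[[i]]
    if (!is.null(gprev)) gi <- grad_add(gi, gprev)
    L <- gen$enc[[i]]
    zn <- cache$zs[[i]]
    gz <- lrelu_bwd(zn, gi)
    if (L$norm) {
      nb <- inorm_backward(cache$ncs[[i]], L$gamma, gz)
      gz <- nb$gx; ggamma <- nb$ggamma; gbeta <- nb$gbeta
    } else {
      ggamma <- L$gamma * 0; gbeta <- L$b * 0
    }
    ain <- if (i == 1) cache$x else cache$e[[i - 1]]
    cb <- conv_backward(ain, L$W, gz)
    egrads[[i]] <- list(W = cb$gW, b = cb$gb, gamma = ggamma, beta = gbeta)
    gprev <- cb$gx
  }
  list(enc = egrads, dec = gdec)
}

#' Build an untrained conditional patch discriminator
#'
#' Five 4x4 convolutional layers (strides 2,2,2,1,1); the first four use
#' leaky-ReLU (instance norm on layers 2-4) and are exposed as feature
#' maps, the fifth maps to per-patch sigmoid scores.  The input is the
#' conditioning image concatenated with a candidate target.
#'
#' @param cfg A [model_config()].
#' @return Discriminator parameter list (class `ccr_discriminator`).
#' @export
build_discriminator <- function(cfg) {
  stop_if_not(inherits(cfg, "model_config"), "cfg must be a model_config")
  f <- cfg$base_features
  cw <- c(f, 2 * f, 4 * f, 8 * f, 1)
  strides <- c(2L, 2L, 2L, 1L, 1L)
  norms <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  with_seed(derive_seed(cfg$seed, 13), {
    layers <- lapply(1:5, function(i) {
      cin <- if (i == 1) cfg$in_channels + 1L else cw[i - 1]
      list(W = winit(cw[i], K_SIZE^2 * cin), b = numeric(cw[i]),
           gamma = rep(1, cw[i]), beta = numeric(cw[i]),
           stride = strides[i], norm = norms[i])
    })
    structure(list(cfg = cfg, layers = layers),
              class = "ccr_discriminator")
  })
}

discriminator_forward <- function(disc, x, keep_cache = TRUE) {
  a <- x
  feats <- vector("list", 4)
  zs <- vector("list", 5); ncs <- vector("list", 5); ains <- vector("list", 5)
  for (i in 1:5) {
    L <- disc$layers[[i]]
    ains[[i]] <- a
    z <- conv_forward(a, L$W, L$b, stride = L$stride)
    if (i < 5) {
      if (L$norm) {
        nc <- inorm_forward(z, L$gamma, L$beta)
        zn <- nc$y
      } else {
        nc <- NULL; zn <- z
      }
      a <- lrelu(zn)
      feats[[i]] <- a
      zs[[i]] <- zn; ncs[[i]] <- nc
    } else {
      zs[[i]] <- z
      a <- sigmoid(z)
    }
  }
  out <- list(scores = a, features = feats, pre = zs[[5]])
  if (keep_cache) out$cache <- list(zs = zs, ncs = ncs, ains = ains)
  out
}

# Backward through the discriminator.  `g_pre` is the gradient w.r.t. the
# pre-sigmoid score map; `g_feats` (optional, list of 4 or NULLs) are
# gradients injected at the post-activation feature maps.  Returns param
# grads and the gradient w.r.t. the input.
discriminator_backward <- function(disc, cache, g_pre, g_feats = NULL) {
  grads <- vector("list", 5)
  g <- g_pre
  for (i in 5:1) {
    L <- disc$layers[[i]]
    if (i < 5) {
      gi <- g
      if (!is.null(g_feats) && !is.null(g_feats[[i]]))
        gi <- gi + g_feats[[i]]
      gz <- lrelu_bwd(cache$zs[[i]], gi)
      if (L$norm) {
        nb <- inorm_backward(cache$ncs[[i]], L$gamma, gz)
        gz <- nb$gx; ggamma <- nb$ggamma; gbeta <- nb$gbeta
      } else {
        ggamma <- L$gamma * 0; gbeta <- L$b * 0
      }
    } else {
      gz <- g
      ggamma <- L$gamma * 0; gbeta <- L$b * 0
    }
    cb <- conv_backward(cache$ains[[i]], L$W, gz, stride = L$stride)
    grads[[i]] <- list(W = cb$gW, b = cb$gb, gamma = ggamma, beta = gbeta)
    g <- cb$gx
  }
  list(layers = grads, gx = g)
}

net_params <- function(net) {
  if (inherits(net, "ccr_generator")) {
    list(enc = lapply(net$enc, `[`, c("W", "b", "gamma", "beta")),
         dec = lapply(net$dec, `[`, c("W", "b", "gamma", "beta")))
  } else {
    list(layers = lapply(net$layers, `[`, c("W", "b", "gamma", "beta")))
  }
}

net_set_params <- function(net, params) {
  if (inherits(net, "ccr_generator")) {
    for (i in seq_along(net$enc))
      net$enc[[i]][c("W", "b", "gamma", "beta")] <- params$enc[[i]]
    for (i in seq_along(net$dec))
      net$dec[[i]][c("W", "b", "gamma", "beta")] <- params$dec[[i]]
  } else {
    for (i in seq_along(net$layers))
      net$layers[[i]][c("W", "b", "gamma", "beta")] <- params$layers[[i]]
  }
  net
}
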