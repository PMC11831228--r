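#' Loss weights for the adversarial objective
#'
#' The training objective is the conditional-GAN min-max game with an
#' L1-weighted reconstruction term,
#' \deqn{\min_G \max_D \; L_{GAN}(G, D) + \lambda L_{L1}(G),}
#' with the generator's adversarial part `theta_g * BCE(D(x, G(x)), 1)`
#' and the discriminator loss
#' `theta_d * (BCE(D(x, y), 1) + BCE(D(x, G(x)), 0)) / 2` plus a
#' perceptual feature term: the sum over internal discriminator layers of
#' the mean L1 distance between feature maps of the generated and real
#' images.
#'
#' Two placements of the perceptual term are supported.  In `"pan"` mode
#' (default, after the perceptual-adversarial formulation) the generator
#' minimizes the feature distance (weight `perc_weight`) while the
#' discriminator keeps it above a margin via `max(0, perc_margin - L_perc)`.
#' In `"paper_literal"` mode the term is added verbatim to the
#' discriminator loss, which is retained for fidelity audits only: a
#' discriminator minimizing the real/fake feature distance degenerates its
#' own features.
#'
#' @param lambda_l1 Weight of the L1 reconstruction term (default 100).
#' @param theta_g,theta_d Weights of the BCE terms (default 1).
#' @param perc_margin Margin m of the pan-mode hinge (default 1).
#' @param perc_weight Generator-side weight of the feature term in pan
#'   mode (default 1).
#' @param perc_mode `"pan"` or `"paper_literal"`.
#' @export
loss_weights <- function(lambda_l1 = 100, theta_g = 1, theta_d = 1,
                         perc_margin = 1, perc_weight = 1,
                         perc_mode = c("pan", "paper_literal")) {
  perc_mode <- match.arg(perc_mode)
  w <- list(lambda_l1 = lambda_l1, theta_g = theta_g, theta_d = theta_d,
            perc_margin = perc_margin, perc_weight = perc_weight,
            perc_mode = perc_mode)
  stop_if_not(all(vapply(w[1:5], function(v) is.finite(v) && v >= 0,
                         logical(1))), "all loss weights must be >= 0")
  structure(w, class = "loss_weights")
}

BCE_EPS <- 1e-7

bce <- function(p, target) {
  p <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

perc_distance <- function(features_fake, features_real) {
  if (is.null(features_fake)) return(0)
  sum(vapply(seq_along(features_fake), function(l)
    mean(abs(features_fake[[l]] - features_real[[l]])), numeric(1)))
}

#' Generator loss
#'
#' `theta_g * BCE(d_scores_fake, 1) + lambda_l1 * mean|fake - real|`,
#' plus `perc_weight * L_perc` in pan mode (see [loss_weights()]).
#'
#' @param d_scores_fake Discriminator scores on the generated image,
#'   values in (0, 1).
#' @param fake,real Generated and ground-truth images (same shape, any
#'   consistent scale).
#' @param features_fake,features_real Discriminator feature maps (lists),
#'   used by the pan-mode perceptual term; may be `NULL`.
#' @param w A [loss_weights()].
#' @return Scalar loss.
#' @export
loss_generator <- function(d_scores_fake, fake, real,
                           features_fake = NULL, features_real = NULL,
                           w = loss_weights()) {
  stop_if_not(identical(dim(fake), dim(real)) ||
                length(fake) == length(real),
              "fake and real must have identical shape")
  l <- w$theta_g * bce(d_scores_fake, 1) +
    w$lambda_l1 * mean(abs(fake - real))
  if (w$perc_mode == "pan")
    l <- l + w$perc_weight * perc_distance(features_fake, features_real)
  l
}

#' Discriminator loss
#'
#' `theta_d * (BCE(d_scores_real, 1) + BCE(d_scores_fake, 0)) / 2` plus
#' the perceptual feature term: added directly in `"paper_literal"` mode,
#' or as the hinge `max(0, perc_margin - L_perc)` in `"pan"` mode.
#'
#' @param d_scores_real,d_scores_fake Discriminator scores in (0, 1).
#' @param features_fake,features_real Discriminator feature-map lists.
#' @param w A [loss_weights()].
#' @return Scalar loss.
#' @export
loss_discriminator <- function(d_scores_real, d_scores_fake,
                               features_fake = NULL, features_real = NULL,
                               w = loss_weights()) {
  l <- w$theta_d * (bce(d_scores_real, 1) + bce(d_scores_fake, 0)) / 2
  lp <- perc_distance(features_fake, features_real)
  if (w$perc_mode == "pan") l + max(0, w$perc_margin - lp) else l + lp
}
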