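#' Generator loss weights
#'
#' The generator objective combines the adversarial (discriminator)
#' loss, the L1 distance, and an SSIM term:
#' `total = lambda_adv * L_adv + lambda_l1 * mean|pred - target| +
#' lambda_ssim * (1 - SSIM(pred, target))`.
#' With `lambda_ssim = 0` the objective reduces exactly to the
#' adversarial + L1 form of the unmodified pix2pix formulation.
#'
#' Losses are computed on the 8-bit scale, so `mean|pred - target|` can
#' reach 255 while `1 - SSIM` is at most 2. The default
#' `lambda_ssim = 2550` (i.e. 10 per unit of dynamic range) brings the
#' SSIM term's gradient onto the same scale as the L1 term's; with a
#' weight of order 10 the SSIM term would be numerically inert next to
#' `lambda_l1 = 100`.
#'
#' @param lambda_adv,lambda_l1,lambda_ssim Non-negative weights
#'   (defaults 1, 100, 2550).
#' @export
loss_weights <- function(lambda_adv = 1, lambda_l1 = 100,
                         lambda_ssim = 2550) {
  if (lambda_adv < 0 || lambda_l1 < 0 || lambda_ssim < 0)
    stop("loss_weights: weights must be non-negative")
  structure(list(lambda_adv = lambda_adv, lambda_l1 = lambda_l1,
                 lambda_ssim = lambda_ssim), class = "loss_weights")
}

#' GAN training configuration
#'
#' @param learning_rate Adam learning rate (reference value 2e-5; small
#'   desk-scale runs use a larger rate, see the package vignette).
#' @param batch_size Must be 1: instance normalization is computed per
#'   image.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epochs Number of passes over the training pairs.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param contrast_target Which contrast the model maps intensity to.
#' @export
train_config <- function(learning_rate = 2e-5, batch_size = 1L,
                         beta1 = 0.5, beta2 = 0.999, epochs = 50L,
                         seed = 1L,
                         contrast_target = c("dopu", "retardation")) {
  if (batch_size != 1L)
    stop("train_config: batch size must be 1 under instance normalization")
  structure(list(learning_rate = learning_rate, batch_size = 1L,
                 beta1 = beta1, beta2 = beta2, epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 contrast_target = match.arg(contrast_target)),
            class = "train_config")
}

# numerically stable binary cross-entropy with logits, mean over the map
bce_logits <- function(z, target) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}

bce_logits_grad <- function(z, target) {
  (1 / (1 + exp(-z)) - target) / length(z)
}

#' Discriminator objective
#'
#' Mean binary cross-entropy on the patch logit maps, pushing real pairs
#' towards 1 and synthetic pairs towards 0 (averaged over the two):
#' non-negative, and minimized at perfect discrimination.
#'
#' @param real_scores,fake_scores Logit maps (arrays or matrices).
#' @return Scalar loss.
#' @export
discriminator_loss <- function(real_scores, fake_scores) {
  0.5 * (bce_logits(real_scores, 1) + bce_logits(fake_scores, 0))
}

#' Generator objective with component breakdown
#'
#' @param fake_scores Discriminator logit map on the synthetic pair, or
#'   `NULL` to force the adversarial component to zero.
#' @param pred,target Predicted and reference contrast tiles on the
#'   8-bit scale.
#' @param weights A [loss_weights()] object.
#' @return List with `total` and the unweighted components `adv`, `l1`,
#'   `ssim` (the SSIM value itself; the loss uses `1 - ssim`). The SSIM
#'   window shrinks to the largest odd size that fits when a tile is
#'   smaller than 11 pixels.
#' @export
generator_loss <- function(fake_scores, pred, target, weights) {
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights, weights)
  if (!all(dim(pred) == dim(target)))
    stop("generator_loss: pred/target shape mismatch")
  adv <- if (is.null(fake_scores)) 0 else bce_logits(fake_scores, 1)
  l1 <- mean(abs(pred - target))
  sv <- ssim_term(pred, target, win_size = fit_win(dim(pred)))
  total <- weights$lambda_adv * adv + weights$lambda_l1 * l1 +
    weights$lambda_ssim * (1 - sv)
  if (!is.finite(total)) stop("generator_loss: non-finite loss")
  list(total = total, adv = adv, l1 = l1, ssim = sv)
}

# largest odd window <= min(11, min spatial side)
fit_win <- function(d) {
  m <- min(11L, min(d[1], d[2]))
  if (m %% 2L == 0L) m <- m - 1L
  max(m, 1L)
}

to_unit <- function(img8) array(img8 / 127.5 - 1, c(nrow(img8), ncol(img8), 1L))
to_8bit_scale <- function(t) (t + 1) * 127.5

#' Train the contrast-synthesis GAN
#'
#' Alternating generator/discriminator optimization at batch size 1 over
#' paired 8-bit tiles (intensity input, contrast target). Each epoch
#' records the mean loss components and the masked SSIM on the
#' validation pairs (the input intensity tile provides the mask); the
#' generator weights with the best validation masked SSIM are retained
#' alongside the final weights. Deterministic for a fixed seed.
#'
#' @param train_pairs,val_pairs Lists of `list(input =, target =)` 8-bit
#'   matrices. `val_pairs` may be empty, in which case checkpoint
#'   selection falls back to the final epoch.
#' @param gen_spec,disc_spec Architecture specs
#'   ([generator_spec()], [discriminator_spec()]).
#' @param weights Loss weights ([loss_weights()]).
#' @param config Training configuration ([train_config()]).
#' @param mask_threshold Intensity threshold for the validation masked
#'   SSIM.
#' @return A `gan_bundle` object; see [synthesize()].
#' @export
train_gan <- function(train_pairs, val_pairs = list(),
                      gen_spec = generator_spec(),
                      disc_spec = discriminator_spec(),
                      weights = loss_weights(),
                      config = train_config(),
                      mask_threshold = 10) {
  if (length(train_pairs) == 0) stop("train_gan: empty training set")
  set.seed(config$seed)
  G <- unet_new(gen_spec)
  D <- disc_new(disc_spec, in_channels = gen_spec$in_channels +
                  gen_spec$out_channels)
  n <- length(train_pairs)
  hist <- vector("list", config$epochs)
  best_val <- -Inf
  best_params <- NULL
  best_epoch <- NA_integer_
  lr <- config$learning_rate
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    comp <- c(d = 0, adv = 0, l1 = 0, ssim = 0, total = 0)
    for (i in ord) {
      pr <- train_pairs[[i]]
      xs <- to_unit(pr$input)
      ts <- to_unit(pr$target)
      fake <- unet_forward(G, xs, train = TRUE)
      fake8 <- to_8bit_scale(fake)
      fake8m <- matrix(fake8, dim(fake8)[1], dim(fake8)[2])
      # --- generator update ---
      zero_grads(G); zero_grads(D)
      logits <- disc_forward(D, xs, fake, train = TRUE)
      adv <- bce_logits(logits, 1)
      dfake_adv <- disc_backward(D, weights$lambda_adv *
                                   bce_logits_grad(logits, 1))
      l1 <- mean(abs(fake8m - pr$target))
      dl1 <- sign(fake8m - pr$target) / length(fake8m)
      st <- ssim_map(fake8m, pr$target, win_size = fit_win(dim(fake8m)))
      sv <- mean(st$map)
      d8 <- weights$lambda_l1 * dl1 - weights$lambda_ssim * ssim_grad_x(st)
      dfake <- dfake_adv + array(d8 * 127.5, dim(fake))
      total <- weights$lambda_adv * adv + weights$lambda_l1 * l1 +
        weights$lambda_ssim * (1 - sv)
      if (!is.finite(total))
        stop("train_gan: non-finite generator loss at epoch ", ep)
      unet_backward(G, dfake)
      adam_step(G, lr, config$beta1, config$beta2)
      # --- discriminator update (synthetic tile treated as constant) ---
      zero_grads(D)
      zr <- disc_forward(D, xs, ts, train = TRUE)
      dls_r <- bce_logits(zr, 1)
      disc_backward(D, 0.5 * bce_logits_grad(zr, 1))
      zf <- disc_forward(D, xs, fake, train = TRUE)
      dls_f <- bce_logits(zf, 0)
      disc_backward(D, 0.5 * bce_logits_grad(zf, 0))
      adam_step(D, lr, config$beta1, config$beta2)
      dl <- 0.5 * (dls_r + dls_f)
      if (!is.finite(dl))
        stop("train_gan: non-finite discriminator loss at epoch ", ep)
      comp <- comp + c(dl, adv, l1, sv, total)
    }
    comp <- comp / n
    vss <- NA_real_
    if (length(val_pairs) > 0) {
      vs <- vapply(val_pairs, function(pr) {
        out8 <- gan_infer(G, pr$input)
        masked_ssim(pr$target, out8, pr$input, threshold = mask_threshold,
                    win_size = fit_win(dim(pr$target)))
      }, 0)
      vss <- mean(vs)
      if (vss > best_val) {
        best_val <- vss
        best_params <- get_params(G)
        best_epoch <- ep
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, gen_steps = n, d_loss = comp[["d"]],
                             g_total = comp[["total"]], g_adv = comp[["adv"]],
                             g_l1 = comp[["l1"]], g_ssim = comp[["ssim"]],
                             val_masked_ssim = vss)
  }
  final_params <- get_params(G)
  if (is.null(best_params)) {
    best_params <- final_params
    best_epoch <- config$epochs
    best_val <- NA_real_
  }
  set_params(G, best_params)
  structure(list(generator_net = G,
                 gen_params_final = final_params,
                 gen_params_best = best_params,
                 gen_spec = gen_spec, disc_spec = disc_spec,
                 weights = weights, config = config,
                 mask_threshold = mask_threshold,
                 history = do.call(rbind, hist),
                 best_epoch = best_epoch, best_val_masked_ssim = best_val),
            class = "gan_bundle")
}

# inference helper on a live generator net: 8-bit matrix in / out
gan_infer <- function(G, img8) {
  out <- unet_forward(G, to_unit(img8), train = FALSE)
  pmin(pmax(to_8bit_scale(matrix(out, dim(out)[1], dim(out)[2])), 0), 255)
}

#' Synthesize a polarization contrast from an intensity image
#'
#' Runs the trained generator on an 8-bit intensity tile (or any image
#' whose sides are compatible with the reflect-pad policy) and returns
#' the synthetic contrast on the 8-bit scale. Inference is deterministic.
#'
#' @param model A `gan_bundle` from [train_gan()].
#' @param image 8-bit intensity matrix.
#' @param which Use the best-validation checkpoint (default) or the
#'   final-epoch weights.
#' @return Matrix of the same shape, values in `[0, 255]`.
#' @export
synthesize <- function(model, image, which = c("best", "final")) {
  if (!inherits(model, "gan_bundle")) stop("synthesize: model is not a gan_bundle")
  which <- match.arg(which)
  G <- model$generator_net
  set_params(G, if (which == "best") model$gen_params_best
             else model$gen_params_final)
  gan_infer(G, image)
}

#' @export
print.gan_bundle <- function(x, ...) {
  cat("Contrast-synthesis GAN (", x$config$contrast_target, ")\n", sep = "")
  print(x$gen_spec)
  print(x$disc_spec)
  cat(sprintf("weights: adv=%g l1=%g ssim=%g | lr=%g | %d epochs\n",
              x$weights$lambda_adv, x$weights$lambda_l1,
              x$weights$lambda_ssim, x$config$learning_rate,
              nrow(x$history)))
  if (!is.na(x$best_epoch))
    cat(sprintf("best validation masked SSIM %.4f at epoch %d\n",
                x$best_val_masked_ssim, x$best_epoch))
  invisible(x)
}

#' @export
plot.gan_bundle <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$g_total, type = "l", xlab = "epoch",
                 ylab = "generator loss", main = "training loss")
  graphics::lines(h$epoch, h$d_loss, lty = 2)
  graphics::legend("topright", c("generator", "discriminator"),
                   lty = c(1, 2), bty = "n")
  graphics::plot(h$epoch, h$val_masked_ssim, type = "b", xlab = "epoch",
                 ylab = "validation masked SSIM", main = "checkpoint metric")
  invisible(x)
}
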