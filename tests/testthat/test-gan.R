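test_that("ssim_term matches the brute-force window oracle", {
  set.seed(21)
  x <- matrix(runif(16 * 16, 0, 255), 16)
  y <- matrix(runif(16 * 16, 0, 255), 16)
  expect_lt(abs(ssim_term(x, y) - bf_ssim(x, y)), 1e-8)
  expect_equal(ssim_term(x, x), 1, tolerance = 1e-12)

  # constant images: value driven purely by the luminance term
  a <- matrix(100, 12, 12)
  b <- matrix(180, 12, 12)
  C1 <- (0.01 * 255)^2
  lum <- (2 * 100 * 180 + C1) / (100^2 + 180^2 + C1)
  expect_equal(ssim_term(a, b), lum, tolerance = 1e-12)
  expect_lt(ssim_term(a, b), 1)

  # symmetry and identity over random pairs
  for (i in 1:10) {
    p <- matrix(runif(144, 0, 255), 12)
    q <- matrix(runif(144, 0, 255), 12)
    expect_equal(ssim_term(p, q), ssim_term(q, p), tolerance = 1e-12)
    expect_equal(ssim_term(p, p), 1, tolerance = 1e-12)
  }
  expect_error(ssim_term(x, y[1:8, 1:8]), "shape")
})

test_that("the analytic SSIM gradient agrees with finite differences", {
  set.seed(22)
  x <- matrix(runif(14 * 14, 0, 255), 14)
  y <- matrix(runif(14 * 14, 0, 255), 14)
  st <- polsynth:::ssim_map(x, y)
  g <- polsynth:::ssim_grad_x(st)
  for (j in sample(length(x), 6)) {
    xp <- x; xp[j] <- xp[j] + 1e-3
    xm <- x; xm[j] <- xm[j] - 1e-3
    num <- (ssim_term(xp, y) - ssim_term(xm, y)) / 2e-3
    expect_equal(g[j], num, tolerance = 1e-6)
  }
})

test_that("generator loss composes its three components", {
  w <- loss_weights(lambda_adv = 0, lambda_l1 = 1, lambda_ssim = 1)
  # printed 2x2 case: pred all 0, target all 255
  pred <- matrix(0, 2, 2)
  targ <- matrix(255, 2, 2)
  gl <- generator_loss(NULL, pred, targ, w)
  expect_equal(gl$l1, 255)
  # window shrinks to 1 px: SSIM reduces to the luminance term
  C1 <- (0.01 * 255)^2
  sv <- (2 * 0 * 255 + C1) / (0^2 + 255^2 + C1)
  expect_equal(gl$ssim, sv, tolerance = 1e-12)
  expect_equal(gl$total, 255 + (1 - sv), tolerance = 1e-12)

  # pred = target with the adversarial term forced off: total 0
  x <- matrix(runif(144, 0, 255), 12)
  expect_equal(generator_loss(NULL, x, x, w)$total, 0, tolerance = 1e-12)

  # lambda_ssim = 0 reduces bit-for-bit to the adversarial + L1 form
  set.seed(23)
  scores <- array(rnorm(16), c(4, 4, 1))
  p <- matrix(runif(144, 0, 255), 12)
  t <- matrix(runif(144, 0, 255), 12)
  w0 <- loss_weights(lambda_adv = 1, lambda_l1 = 100, lambda_ssim = 0)
  gl0 <- generator_loss(scores, p, t, w0)
  pix2pix <- polsynth:::bce_logits(scores, 1) + 100 * mean(abs(p - t))
  expect_identical(gl0$total, pix2pix)

  expect_error(loss_weights(lambda_l1 = -1), "non-negative")
})

test_that("discriminator loss is the mean BCE on patch logits", {
  # all-zero logits: ln 2 per patch
  z <- array(0, c(3, 3, 1))
  expect_equal(discriminator_loss(z, z), log(2), tolerance = 1e-12)
  # perfect discrimination limit
  expect_lt(discriminator_loss(z + 50, z - 50), 1e-12)
  # random maps against the elementwise formula
  set.seed(24)
  zr <- array(rnorm(18), c(3, 6, 1))
  zf <- array(rnorm(18), c(3, 6, 1))
  oracle <- 0.5 * (mean(-log(1 / (1 + exp(-zr)))) +
                     mean(-log(1 - 1 / (1 + exp(-zf)))))
  expect_equal(discriminator_loss(zr, zf), oracle, tolerance = 1e-9)
})

test_that("training bookkeeping, determinism and inference contracts hold", {
  set.seed(30)
  pairs <- lapply(1:2, function(i)
    list(input = matrix(runif(1024, 0, 255), 32),
         target = matrix(runif(1024, 0, 255), 32)))
  cfgt <- train_config(learning_rate = 1e-3, epochs = 1L, seed = 5)
  b <- train_gan(pairs, gen_spec = generator_spec(depth = 2, base_channels = 4),
                 disc_spec = discriminator_spec(4), config = cfgt)
  expect_s3_class(b, "gan_bundle")
  expect_identical(nrow(b$history), 1L)
  expect_identical(b$history$gen_steps, 2L)   # one generator step per tile

  # seeded reproducibility of the first epoch
  b2 <- train_gan(pairs, gen_spec = generator_spec(depth = 2, base_channels = 4),
                  disc_spec = discriminator_spec(4), config = cfgt)
  expect_identical(b$history$g_total, b2$history$g_total)
  expect_identical(b$history$d_loss, b2$history$d_loss)

  # synthesize: shape contract across sides and inference determinism
  for (side in c(64L, 32L)) {
    img <- matrix(runif(side^2, 0, 255), side)
    out <- synthesize(b, img)
    expect_identical(dim(out), c(side, side))
    expect_true(min(out) >= 0 && max(out) <= 255)
    expect_identical(out, synthesize(b, img))
  }
  # non-power-of-two side exercises the reflect-pad/crop policy
  img50 <- matrix(runif(2500, 0, 255), 50)
  expect_identical(dim(synthesize(b, img50)), c(50L, 50L))

  expect_error(train_gan(list(), config = cfgt), "empty")
  expect_error(train_config(batch_size = 2), "batch size")
})

test_that("a briefly trained generator beats the global-mean baseline", {
  pairs <- recovery_task_pairs(60, seed = 3)
  b <- train_gan(pairs[1:48], pairs[49:60],
                 gen_spec = generator_spec(depth = 3, base_channels = 12),
                 disc_spec = discriminator_spec(16),
                 config = train_config(learning_rate = 1e-3, epochs = 6L,
                                       seed = 1))
  gmean <- mean(vapply(pairs[1:48], function(p) mean(p$target), 0))
  mae_model <- mean(vapply(pairs[49:60], function(p)
    mean(abs(synthesize(b, p$input) - p$target)), 0))
  mae_base <- mean(vapply(pairs[49:60], function(p)
    mean(abs(gmean - p$target)), 0))
  expect_lt(mae_model, mae_base)
})

test_that("class structure in synthetic DOPU survives a domain shift", {
  # train on the default phantom, then apply to frames simulated with
  # shifted attenuation, speckle and depolarization parameters: the
  # synthetic contrast should still rank cancer tiles below normal ones
  cfg <- phantom_config(image_height = 40L, image_width = 72L,
                        lesion_density_cancer = 5)
  ds <- generate_dataset(cfg, n_frames_per_class = 40L,
                         n_cases_per_class = 2L, seed = 71)
  pp <- preprocess_dataset(ds, tile_side = 32L)
  sp <- assign_splits(pp$manifest, strategy = "image_based", seed = 72)
  mk <- function(part) {
    ids <- sp$tile_id[sp$partition == part]
    lapply(ids, function(id) list(input = pp$tiles$intensity[[id]],
                                  target = pp$tiles$dopu[[id]]))
  }
  gan <- train_gan(mk("train"), mk("validation"),
                   gen_spec = generator_spec(depth = 3, base_channels = 12),
                   disc_spec = discriminator_spec(16),
                   config = train_config(learning_rate = 1e-3, epochs = 5L,
                                         seed = 73))
  shifted <- phantom_config(image_height = 40L, image_width = 72L,
                            lesion_density_cancer = 5,
                            attenuation_coeff_range = c(0.004, 0.02),
                            speckle_looks = 2L,
                            depol_noise_sigma_dopu = 0.12,
                            depol_noise_sigma_ret = 0.3)
  ds2 <- generate_dataset(shifted, n_frames_per_class = 20L,
                          n_cases_per_class = 2L, seed = 74)
  pp2 <- preprocess_dataset(ds2, tile_side = 32L)
  syn_mean <- vapply(pp2$manifest$tile_id, function(id)
    mean(synthesize(gan, pp2$tiles$intensity[[id]])), 0)
  lab <- pp2$manifest$label
  expect_gt(mean(syn_mean[lab == "normal"]), mean(syn_mean[lab == "cancer"]))
  # and the ranking is strong, not marginal: AUC of mean synthetic DOPU
  expect_gt(roc_and_auc(-syn_mean, lab == "cancer")$auc, 0.8)
})
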