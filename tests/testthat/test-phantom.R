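test_that("layer stacks partition the depth axis and honour class ranges", {
  cfg <- small_config()
  set.seed(1)
  st <- simulate_layer_stack(cfg, "normal")
  expect_s3_class(st, "layer_stack")
  expect_identical(sum(st$layers$thickness), cfg$image_height)
  expect_true(all(st$layers$dn >= cfg$birefringence_range_normal[1]))
  expect_true(all(st$layers$dn <= cfg$birefringence_range_normal[2]))
  expect_null(st$lesions)

  # degenerate birefringence intervals pin every layer's delta-n
  cfg1 <- small_config(birefringence_range_normal = c(1e-3, 1e-3))
  st1 <- simulate_layer_stack(cfg1, "normal")
  expect_true(all(st1$layers$dn == 1e-3))
  cfg0 <- small_config(birefringence_range_cancer = c(0, 0))
  st0 <- simulate_layer_stack(cfg0, "cancer")
  expect_true(all(st0$layers$dn == 0))
  expect_gt(nrow(st0$lesions), 0)

  # determinism under a fixed seed
  set.seed(7); a <- simulate_layer_stack(cfg, "cancer")
  set.seed(7); b <- simulate_layer_stack(cfg, "cancer")
  expect_identical(a, b)

  # degenerate configs are rejected
  expect_error(phantom_config(n_layers_range = c(5L, 3L)), "n_layers_range")
  expect_error(phantom_config(image_height = 3L), "height")
  expect_error(phantom_config(depol_noise_sigma_ret = 0.05), "exceed")
  expect_error(phantom_config(dopu_kernel = 4L), "odd")
  expect_error(phantom_config(birefringence_range_cancer = c(0, 1e-3)),
               "below")
})

test_that("cumulative retardation matches a per-pixel sum oracle and folds", {
  cfg <- phantom_config(image_height = 150L, image_width = 4L,
                        pixel_depth_um = 5, wavelength_um = 1.3)
  stack <- structure(list(
    layers = data.frame(thickness = c(50L, 50L, 50L),
                        dn = c(1e-3, 0, 2e-3),
                        amp = rep(0.8, 3), atten = rep(0.005, 3)),
    lesions = NULL, label = "normal", height = 150L, width = 4L),
    class = "layer_stack")
  ret <- cumulative_retardation(stack, cfg)
  # brute-force oracle: accumulate pixel by pixel, double, fold
  dn_px <- rep(c(1e-3, 0, 2e-3), each = 50)
  acc <- 0
  oracle <- numeric(150)
  for (z in 1:150) {
    acc <- acc + dn_px[z] * 5
    d <- 2 * (2 * pi / 1.3) * acc
    d <- d %% pi
    oracle[z] <- if (d > pi / 2) pi - d else d
  }
  expect_lt(max(abs(ret[, 1] - oracle)), 1e-10)
  expect_lt(max(abs(ret[, 4] - oracle)), 1e-10)
  # zero-birefringence layer: constant within the layer before folding,
  # hence constant after folding too
  expect_equal(ret[51, 1], ret[100, 1], tolerance = 1e-12)

  # all-zero stack gives identically zero retardation
  stack0 <- stack
  stack0$layers$dn <- 0
  expect_true(all(cumulative_retardation(stack0, cfg) == 0))

  # fold fixed point: unfolded round-trip delta of exactly pi/2
  # (single layer: 2*(2*pi/lambda)*dn*th*px = pi/2)
  th <- 100L
  dn_fix <- (pi / 2) * 1.3 / (4 * pi * th * 5)
  cfg2 <- phantom_config(image_height = th, image_width = 2L)
  stack2 <- structure(list(
    layers = data.frame(thickness = th, dn = dn_fix, amp = 1, atten = 0.01),
    lesions = NULL, label = "normal", height = th, width = 2L),
    class = "layer_stack")
  ret2 <- cumulative_retardation(stack2, cfg2)
  expect_equal(ret2[th, 1], pi / 2, tolerance = 1e-12)
})

test_that("speckled intensity follows the attenuation model", {
  cfg <- small_config(speckle_looks = 10000L)
  set.seed(3)
  st <- simulate_layer_stack(cfg, "normal")
  img <- render_speckled_intensity(st, cfg)
  # law of large numbers: near the noiseless log-compressed signal
  amp <- rep(st$layers$amp, st$layers$thickness)
  att <- rep(st$layers$atten, st$layers$thickness)
  noiseless <- polsynth:::log_compress_16bit(
    matrix(amp * exp(-cumsum(att)), cfg$image_height, cfg$image_width))
  expect_lt(max(abs(img - noiseless) / pmax(noiseless, 1)), 0.02)

  # zero attenuation, one uniform layer: constant depth profile
  cfgu <- phantom_config(image_height = 30L, image_width = 8L,
                         attenuation_coeff_range = c(0, 0),
                         n_layers_range = c(1L, 1L),
                         speckle_looks = 100000L)
  set.seed(4)
  stu <- simulate_layer_stack(cfgu, "normal")
  imgu <- render_speckled_intensity(stu, cfgu)
  expect_lte(diff(range(imgu)), 150)   # within quantization + residual look noise

  # bit-identical under a fixed seed
  set.seed(9); i1 <- render_speckled_intensity(st, cfg)
  set.seed(9); i2 <- render_speckled_intensity(st, cfg)
  expect_identical(i1, i2)
})

test_that("Stokes mapping rotates the input state and respects the bound", {
  ret0 <- matrix(0, 4, 4)
  f0 <- stokes_from_retardation(ret0, sigma = 0)
  expect_true(all(f0$q == 1) && all(f0$u == 0) && all(f0$v == 0))

  # sigma = 0: fully polarized everywhere
  set.seed(2)
  ret <- matrix(runif(16, 0, pi / 2), 4, 4)
  f <- stokes_from_retardation(ret, sigma = 0)
  dop <- sqrt(f$q^2 + f$u^2 + f$v^2) / f$i
  expect_equal(max(abs(dop - 1)), 0, tolerance = 1e-12)

  # delta = pi/4: rotation-matrix oracle, rotation by pi/2 about V
  f45 <- stokes_from_retardation(matrix(pi / 4, 1, 1), sigma = 0)
  R <- matrix(c(cos(pi / 2), -sin(pi / 2), 0,
                sin(pi / 2), cos(pi / 2), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(c(f45$q, f45$u, f45$v), drop(R %*% c(1, 0, 0)),
               tolerance = 1e-12)

  # noisy field still satisfies the physical bound
  fn <- stokes_from_retardation(ret, sigma = 0.5)
  expect_true(all(sqrt(fn$q^2 + fn$u^2 + fn$v^2) <= fn$i + 1e-12))
  expect_error(stokes_from_retardation(ret, sigma = -1), "sigma")
})

test_that("DOPU equals the explicit window-sum oracle", {
  # uniform fully polarized field: DOPU identically 1, any kernel
  f <- stokes_from_retardation(matrix(0.3, 8, 8), sigma = 0)
  expect_lt(max(abs(compute_dopu(f, 5L) - 1)), 1e-12)
  expect_lt(max(abs(compute_dopu(f, 1L) - 1)), 1e-12)

  # two antipodal populations in a 3x3 neighbourhood: explicit 9-term sum
  fld <- structure(list(i = matrix(1, 3, 3),
                        q = matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3, 3),
                        u = matrix(0, 3, 3), v = matrix(0, 3, 3)),
                   class = "stokes_field")
  d <- compute_dopu(fld, 3L)
  expect_equal(d[2, 2], abs(sum(fld$q) / 9), tolerance = 1e-14)

  # random fields against the double-loop clipped-window oracle
  set.seed(11)
  for (k in c(3L, 5L)) {
    ret <- matrix(runif(16 * 16, 0, pi / 2), 16, 16)
    fr <- stokes_from_retardation(ret, sigma = 0.4)
    expect_lt(max(abs(compute_dopu(fr, k) - bf_dopu(fr, k))), 1e-12)
  }
  expect_error(compute_dopu(f, 4L), "odd")
})

test_that("generated datasets satisfy the frame invariants", {
  cfg <- small_config()
  ds <- generate_dataset(cfg, n_frames_per_class = 4L,
                         n_cases_per_class = 2L, seed = 5)
  expect_identical(nrow(ds$manifest), 8L)
  expect_true(all(table(ds$manifest$case_id) == 2L))
  for (fr in ds$frames) validate_tissue_frame(fr)

  # determinism: identical (config, seed) gives bit-identical triplets
  ds2 <- generate_dataset(cfg, 4L, 2L, seed = 5)
  expect_identical(ds$frames, ds2$frames)

  expect_error(generate_dataset(cfg, 0L, 1L), "zero frames")
  expect_error(generate_dataset(cfg, 2L, 3L), "n_cases")
})

test_that("channel bounds hold across random configurations", {
  set.seed(42)
  for (i in 1:20) {
    sd_dopu <- runif(1, 0.02, 0.3)
    cfg <- phantom_config(
      image_height = sample(24:48, 1), image_width = sample(24:48, 1),
      n_layers_range = sort(sample(1:6, 2)),
      depol_noise_sigma_dopu = sd_dopu,
      depol_noise_sigma_ret = sd_dopu + runif(1, 0.05, 0.4),
      speckle_looks = sample(1:8, 1),
      dopu_kernel = sample(c(3L, 5L, 7L), 1))
    fr <- polsynth:::generate_frame(cfg, sample(c("cancer", "normal"), 1))
    expect_silent(validate_tissue_frame(fr))
  }
})

test_that("the retardation channel is spatially noisier than DOPU", {
  cfg <- small_config()
  set.seed(99)
  highpass_sd <- function(x) {
    sm <- polsynth:::cpp_box_mean_clipped(x, 1L)
    stats::sd(x - sm)
  }
  n <- 100
  noisier <- logical(n)
  for (i in seq_len(n)) {
    fr <- polsynth:::generate_frame(cfg,
                                    if (i %% 2 == 0) "cancer" else "normal")
    # compare on a common [0,1] scale
    noisier[i] <- highpass_sd(fr$retardation / (pi / 2)) >
      highpass_sd(fr$dopu)
  }
  expect_gte(mean(noisier), 0.95)
})

test_that("class separability: normal frames carry more retardation", {
  cfg <- small_config()
  set.seed(17)
  mr <- replicate(25, mean(polsynth:::generate_frame(cfg, "normal")$retardation))
  mc <- replicate(25, mean(polsynth:::generate_frame(cfg, "cancer")$retardation))
  expect_gt(mean(mr), mean(mc))
})
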