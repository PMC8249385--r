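#' Phantom simulator configuration
#'
#' Parameters of the layered birefringent tissue phantom that stands in
#' for a breast-tissue PS-OCT dataset. A phantom B-scan is a stack of
#' horizontal tissue slabs; each slab carries a birefringence
#' \eqn{\Delta n}, a backscatter amplitude and an attenuation
#' coefficient. "Normal" frames draw \eqn{\Delta n} from
#' `birefringence_range_normal` (organized, strongly birefringent
#' fibrous layers); "cancer" frames draw from the near-zero
#' `birefringence_range_cancer` and additionally contain lesion blobs
#' with locally scrambled polarization and altered backscatter --
#' modelling the loss and derangement of organized fibrous structure in
#' tumours. The two ranges must not overlap so the classes are separable
#' by construction.
#'
#' The retardation channel is reconstructed from a noisier Stokes field
#' than the DOPU channel (`depol_noise_sigma_ret` must exceed
#' `depol_noise_sigma_dopu`), reflecting the intrinsically higher noise
#' level of phase retardation images.
#'
#' @param image_height,image_width Frame size in pixels (depth axis
#'   first).
#' @param pixel_depth_um Micrometers per axial pixel.
#' @param wavelength_um Center wavelength in micrometers.
#' @param n_layers_range Integer interval for the number of slabs.
#' @param birefringence_range_normal,birefringence_range_cancer
#'   \eqn{\Delta n} intervals (unitless).
#' @param attenuation_coeff_range Per-pixel exponential decay interval.
#' @param speckle_looks Number of independent exponential speckle draws
#'   averaged per pixel (1 = fully developed speckle).
#' @param depol_noise_sigma_dopu,depol_noise_sigma_ret Gaussian Stokes
#'   perturbation scales for the DOPU and retardation channels.
#' @param dopu_kernel Odd side (pixels) of the DOPU averaging window.
#' @param lesion_density_cancer Expected lesion blobs per cancer frame.
#' @param rng_seed Default seed used by [generate_dataset()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 256L, image_width = 512L,
                           pixel_depth_um = 5, wavelength_um = 1.3,
                           n_layers_range = c(3L, 5L),
                           birefringence_range_normal = c(5e-4, 2e-3),
                           birefringence_range_cancer = c(0, 2e-4),
                           attenuation_coeff_range = c(0.002, 0.012),
                           speckle_looks = 4L,
                           depol_noise_sigma_dopu = 0.08,
                           depol_noise_sigma_ret = 0.25,
                           dopu_kernel = 5L,
                           lesion_density_cancer = 3,
                           rng_seed = 1L) {
  cfg <- structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pixel_depth_um = pixel_depth_um, wavelength_um = wavelength_um,
    n_layers_range = as.integer(n_layers_range),
    birefringence_range_normal = birefringence_range_normal,
    birefringence_range_cancer = birefringence_range_cancer,
    attenuation_coeff_range = attenuation_coeff_range,
    speckle_looks = as.integer(speckle_looks),
    depol_noise_sigma_dopu = depol_noise_sigma_dopu,
    depol_noise_sigma_ret = depol_noise_sigma_ret,
    dopu_kernel = as.integer(dopu_kernel),
    lesion_density_cancer = lesion_density_cancer,
    rng_seed = as.integer(rng_seed)), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$depol_noise_sigma_ret <= cfg$depol_noise_sigma_dopu)
    stop("phantom_config: retardation noise sigma must exceed DOPU's")
  if (cfg$birefringence_range_cancer[2] >= cfg$birefringence_range_normal[1])
    stop("phantom_config: cancer birefringence range must lie strictly ",
         "below the normal range")
  if (cfg$dopu_kernel %% 2L == 0L || cfg$dopu_kernel < 3L)
    stop("phantom_config: dopu_kernel must be odd and >= 3")
  if (length(cfg$n_layers_range) != 2L ||
      cfg$n_layers_range[1] > cfg$n_layers_range[2] ||
      cfg$n_layers_range[1] < 1L)
    stop("phantom_config: invalid n_layers_range")
  if (cfg$image_height < cfg$n_layers_range[2])
    stop("phantom_config: image height smaller than the number of layers")
  if (any(cfg$attenuation_coeff_range < 0))
    stop("phantom_config: attenuation coefficients must be positive")
  if (cfg$speckle_looks < 1L) stop("phantom_config: speckle_looks must be >= 1")
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("PS-OCT phantom config: %d x %d px (%g um/px, %g um)\n",
              x$image_height, x$image_width, x$pixel_depth_um,
              x$wavelength_um))
  cat(sprintf("  dn normal [%g, %g] | cancer [%g, %g] | %d-%d layers\n",
              x$birefringence_range_normal[1], x$birefringence_range_normal[2],
              x$birefringence_range_cancer[1], x$birefringence_range_cancer[2],
              x$n_layers_range[1], x$n_layers_range[2]))
  cat(sprintf("  sigma dopu %g < sigma ret %g | kernel %d | looks %d\n",
              x$depol_noise_sigma_dopu, x$depol_noise_sigma_ret,
              x$dopu_kernel, x$speckle_looks))
  invisible(x)
}

#' Draw a random slab stack for one frame
#'
#' Partitions the depth axis into slabs whose thicknesses sum exactly to
#' the image height and draws per-slab birefringence (from the
#' class-appropriate range), backscatter amplitude and attenuation.
#' Cancer frames additionally carry lesion blob descriptors (center,
#' radii, backscatter factor, depolarization boost). Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param config A [phantom_config()].
#' @param label `"normal"` or `"cancer"`.
#' @return An object of class `layer_stack`.
#' @export
simulate_layer_stack <- function(config, label = c("normal", "cancer")) {
  validate_phantom_config(config)
  label <- match.arg(label)
  H <- config$image_height
  W <- config$image_width
  n <- if (config$n_layers_range[1] == config$n_layers_range[2])
    config$n_layers_range[1] else
      sample(config$n_layers_range[1]:config$n_layers_range[2], 1L)
  # thickness partition: positive weights normalized to the full depth
  wts <- stats::runif(n, 0.5, 1.5)
  th <- floor(wts / sum(wts) * H)
  th[th < 1L] <- 1L
  th[n] <- H - sum(th[-n])
  if (th[n] < 1L) stop("simulate_layer_stack: degenerate layer partition")
  rng_dn <- if (label == "normal") config$birefringence_range_normal
            else config$birefringence_range_cancer
  layers <- data.frame(
    thickness = as.integer(th),
    dn = stats::runif(n, rng_dn[1], rng_dn[2]),
    amp = stats::runif(n, 0.45, 1),
    atten = stats::runif(n, config$attenuation_coeff_range[1],
                         config$attenuation_coeff_range[2]))
  lesions <- NULL
  if (label == "cancer") {
    # at least two blobs so every lateral half of the frame is likely
    # to carry lesion evidence; blobs are visible in BOTH channels
    # (darker backscatter, scrambled polarization), which is what makes
    # the polarization contrast inferable from intensity structure
    nl <- 2L + stats::rpois(1L, max(config$lesion_density_cancer - 2, 0))
    lesions <- data.frame(
      row = stats::runif(nl, 0.15, 0.85) * H,
      col = stats::runif(nl, 0.1, 0.9) * W,
      ry = stats::runif(nl, 0.15, 0.30) * H,
      rx = stats::runif(nl, 0.12, 0.25) * W,
      amp_factor = stats::runif(nl, 0.35, 0.60),
      depol_boost = stats::runif(nl, 0.35, 0.55))
  }
  structure(list(layers = layers, lesions = lesions, label = label,
                 height = H, width = W), class = "layer_stack")
}

# additive depolarization boost map and multiplicative backscatter map
lesion_maps <- function(stack) {
  H <- stack$height; W <- stack$width
  depol <- matrix(0, H, W)
  amp <- matrix(1, H, W)
  if (!is.null(stack$lesions)) {
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(nrow(stack$lesions))) {
      l <- stack$lesions[i, ]
      inside <- ((rr - l$row) / l$ry)^2 + ((cc - l$col) / l$rx)^2 <= 1
      depol[inside] <- pmax(depol[inside], l$depol_boost)
      amp[inside] <- pmin(amp[inside], l$amp_factor)
    }
  }
  list(depol = depol, amp = amp)
}

# fold an angle into [0, pi/2] by triangular wrapping
fold_retardation <- function(delta) {
  p <- delta %% pi
  ifelse(p > pi / 2, pi - p, p)
}

#' Depth-cumulative phase retardation of a slab stack
#'
#' Single-pass retardation accumulates as
#' \eqn{\delta(z) = (2\pi/\lambda) \sum_{z' \le z} \Delta n(z')\,\Delta z},
#' is doubled for the round trip, and folded into `[0, pi/2]` by
#' triangular wrapping (the standard single-detector display range).
#'
#' @param stack A [simulate_layer_stack()] result.
#' @param config The [phantom_config()] used to build it.
#' @return `image_height x image_width` matrix of folded retardation in
#'   radians.
#' @export
cumulative_retardation <- function(stack, config) {
  dn <- rep(stack$layers$dn, stack$layers$thickness)
  delta <- (4 * pi / config$wavelength_um) *
    cumsum(dn * config$pixel_depth_um)
  matrix(fold_retardation(delta), stack$height, stack$width)
}

#' Speckled, attenuated, log-compressed OCT intensity
#'
#' The noise-free backscatter signal of slab `l` at depth `z` is its
#' amplitude times `exp(-sum of attenuation above z)`; lesion blobs scale
#' the amplitude. Multiplicative speckle is modelled as the mean of
#' `speckle_looks` independent unit-exponential draws. The speckled
#' signal is log-compressed (`log10`, fixed display range) and linearly
#' quantized to the 16-bit unsigned range.
#'
#' @param stack,config As in [cumulative_retardation()].
#' @return Matrix of integers in `[0, 65535]`.
#' @export
render_speckled_intensity <- function(stack, config) {
  if (any(stack$layers$atten < 0))
    stop("render_speckled_intensity: attenuation must be positive")
  amp <- rep(stack$layers$amp, stack$layers$thickness)
  att <- rep(stack$layers$atten, stack$layers$thickness)
  sig <- amp * exp(-cumsum(att))
  H <- stack$height; W <- stack$width
  sigmap <- matrix(sig, H, W) * lesion_maps(stack)$amp
  k <- config$speckle_looks
  speckle <- matrix(stats::rgamma(H * W, shape = k, rate = k), H, W)
  log_compress_16bit(sigmap * speckle)
}

# fixed display range: amplitudes <= 1, floor 1e-4 -> [-4, 0.5] decades
log_compress_16bit <- function(x, lmin = -4, lmax = 0.5) {
  l <- log10(x + 1e-4)
  v <- (l - lmin) / (lmax - lmin)
  round(pmin(pmax(v, 0), 1) * 65535)
}

#' Stokes field of a retardation map
#'
#' Maps each folded retardation value \eqn{\delta} to the unit Stokes
#' vector obtained by rotating the input polarization state `(Q,U,V) =
#' (1,0,0)` by \eqn{2\delta} about the V axis, i.e. `(cos 2d, sin 2d,
#' 0)`, then perturbs (Q,U,V) with i.i.d. Gaussian noise of scale
#' `sigma` and re-clips to the physical bound `Q^2+U^2+V^2 <= I^2`.
#' `sigma` may be a scalar or a per-pixel matrix (lesions locally raise
#' it).
#'
#' @param retardation Matrix of folded retardation (radians).
#' @param sigma Non-negative noise scale (scalar or matrix).
#' @return An object of class `stokes_field` with components `i`, `q`,
#'   `u`, `v`.
#' @export
stokes_from_retardation <- function(retardation, sigma = 0) {
  if (any(sigma < 0)) stop("stokes_from_retardation: sigma must be >= 0")
  q <- cos(2 * retardation)
  u <- sin(2 * retardation)
  v <- matrix(0, nrow(retardation), ncol(retardation))
  if (any(sigma > 0)) {
    n <- length(q)
    q <- q + stats::rnorm(n) * sigma
    u <- u + stats::rnorm(n) * sigma
    v <- v + stats::rnorm(n) * sigma
  }
  nrm <- sqrt(q * q + u * u + v * v)
  scl <- ifelse(nrm > 1, 1 / nrm, 1)
  structure(list(i = matrix(1, nrow(retardation), ncol(retardation)),
                 q = q * scl, u = u * scl, v = v * scl),
            class = "stokes_field")
}

#' Degree of polarization uniformity
#'
#' Per pixel: the Stokes components (Q,U,V) are normalized by I, each
#' normalized component is averaged over a `kernel x kernel` window
#' (windows are clipped at the image borders), and DOPU is the norm of
#' the averaged vector, clipped to `[0, 1]`. Uniformly polarized regions
#' give DOPU near 1; scrambled polarization drives it towards 0.
#'
#' @param field A [stokes_from_retardation()] result.
#' @param kernel Odd window side in pixels (1 = no averaging).
#' @return Matrix of DOPU values in `[0, 1]`.
#' @export
compute_dopu <- function(field, kernel = 5L) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 1L)
    stop("compute_dopu: kernel must be odd and >= 1")
  r <- (kernel - 1L) %/% 2L
  qb <- field$q / field$i
  ub <- field$u / field$i
  vb <- field$v / field$i
  if (r > 0L) {
    qb <- cpp_box_mean_clipped(qb, r)
    ub <- cpp_box_mean_clipped(ub, r)
    vb <- cpp_box_mean_clipped(vb, r)
  }
  pmin(sqrt(qb * qb + ub * ub + vb * vb), 1)
}

# one full co-registered triplet (uses the current RNG state)
generate_frame <- function(config, label, case_id = "case01",
                           frame_id = "f0001") {
  stack <- simulate_layer_stack(config, label)
  maps <- lesion_maps(stack)
  ret_clean <- cumulative_retardation(stack, config)
  intensity <- render_speckled_intensity(stack, config)
  sig_dopu <- config$depol_noise_sigma_dopu + maps$depol
  sig_ret <- config$depol_noise_sigma_ret + maps$depol
  dopu <- compute_dopu(stokes_from_retardation(ret_clean, sig_dopu),
                       config$dopu_kernel)
  fr <- stokes_from_retardation(ret_clean, sig_ret)
  retardation <- abs(atan2(fr$u, fr$q)) / 2
  structure(list(intensity = intensity, dopu = dopu,
                 retardation = retardation, label = label,
                 case_id = case_id, frame_id = frame_id),
            class = "tissue_frame")
}

#' Check the invariants of a simulated/loaded frame
#'
#' All three channels share one shape; DOPU lies in `[0,1]`, retardation
#' in `[0, pi/2]`, intensity in the 16-bit unsigned range.
#'
#' @param frame A `tissue_frame`.
#' @return The frame, invisibly; signals an error on violation.
#' @export
validate_tissue_frame <- function(frame) {
  if (!all(dim(frame$intensity) == dim(frame$dopu)) ||
      !all(dim(frame$intensity) == dim(frame$retardation)))
    stop("tissue_frame: channel shapes differ")
  if (min(frame$dopu) < 0 || max(frame$dopu) > 1)
    stop("tissue_frame: DOPU outside [0,1]")
  if (min(frame$retardation) < 0 || max(frame$retardation) > pi / 2 + 1e-12)
    stop("tissue_frame: retardation outside [0, pi/2]")
  if (min(frame$intensity) < 0 || max(frame$intensity) > 65535 ||
      any(frame$intensity != round(frame$intensity)))
    stop("tissue_frame: intensity outside the 16-bit unsigned range")
  if (!frame$label %in% c("cancer", "normal"))
    stop("tissue_frame: unknown label")
  invisible(frame)
}

#' Generate a labelled phantom dataset
#'
#' Simulates `n_frames_per_class` co-registered triplets per class,
#' assigning frames round-robin to `n_cases_per_class` synthetic cases,
#' and returns the frames together with a manifest (frame id, case id,
#' label). Fully deterministic for a fixed `(config, seed)`.
#'
#' @param config A [phantom_config()].
#' @param n_frames_per_class,n_cases_per_class Counts per class.
#' @param seed Seed (defaults to `config$rng_seed`).
#' @return An object of class `phantom_dataset`: `list(frames, manifest)`.
#' @export
generate_dataset <- function(config, n_frames_per_class = 10L,
                             n_cases_per_class = 2L,
                             seed = config$rng_seed) {
  if (n_frames_per_class < 1L)
    stop("generate_dataset: zero frames requested")
  if (n_cases_per_class < 1L || n_frames_per_class < n_cases_per_class)
    stop("generate_dataset: need n_frames >= n_cases >= 1 per class")
  set.seed(seed)
  frames <- list()
  rows <- list()
  for (label in c("cancer", "normal")) {
    for (i in seq_len(n_frames_per_class)) {
      case <- sprintf("%s_case%02d", label,
                      (i - 1L) %% n_cases_per_class + 1L)
      fid <- sprintf("%s_f%04d", label, i)
      frames[[fid]] <- generate_frame(config, label, case, fid)
      rows[[fid]] <- data.frame(frame_id = fid, case_id = case,
                                label = label)
    }
  }
  structure(list(frames = frames,
                 manifest = do.call(rbind, c(rows, make.row.names = FALSE)),
                 config = config, seed = seed),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  tb <- table(x$manifest$label)
  cat(sprintf("phantom dataset: %d frames (%s), %d cases, seed %d\n",
              nrow(x$manifest),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", "),
              length(unique(x$manifest$case_id)), x$seed))
  invisible(x)
}
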