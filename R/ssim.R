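#' @title Structural similarity between two tiles
#' @description
#' Mean structural similarity index (SSIM) between two co-shaped
#' grayscale images on the 8-bit scale, using the standard 11-pixel
#' Gaussian window (sigma 1.5) and stabilizers `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2` with dynamic range `L`. The local SSIM map is
#' computed at every position where the full window fits inside the
#' image (no padding) and averaged. Symmetric in its arguments and equal
#' to 1 exactly when the images are identical.
#'
#' @param x,y Numeric matrices of identical shape (values on the `[0, L]`
#'   scale).
#' @param win_size Odd window side in pixels.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param dynamic_range Value range `L` (255 for 8-bit data).
#' @return A scalar in `[-1, 1]`.
#' @export
ssim_term <- function(x, y, win_size = 11L, sigma = 1.5, dynamic_range = 255) {
  st <- ssim_map(x, y, win_size = win_size, sigma = sigma,
                 dynamic_range = dynamic_range)
  mean(st$map)
}

# Local SSIM map plus the window statistics needed for masking and for
# the analytic gradient used in the generator loss.
ssim_map <- function(x, y, win_size = 11L, sigma = 1.5, dynamic_range = 255) {
  if (!is.matrix(x) || !is.matrix(y) || !all(dim(x) == dim(y)))
    stop("ssim: inputs must be two matrices of identical shape")
  k <- as.integer(win_size)
  if (k %% 2L == 0L || k < 1L) stop("ssim: window size must be odd and >= 1")
  if (nrow(x) < k || ncol(x) < k)
    stop("ssim: image smaller than the ", k, "x", k, " window")
  w <- gaussian_window(k, sigma)
  wv <- matrix(as.numeric(w), nrow = 1L)
  H <- nrow(x); W <- ncol(x)
  gf <- function(img) {
    P <- cpp_im2col(as.numeric(img), H, W, 1L, k, 1L, 0L)
    matrix(wv %*% P, H - k + 1L, W - k + 1L)
  }
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  mux <- gf(x); muy <- gf(y)
  sxx <- gf(x * x) - mux * mux
  syy <- gf(y * y) - muy * muy
  sxy <- gf(x * y) - mux * muy
  A1 <- 2 * mux * muy + C1
  A2 <- 2 * sxy + C2
  B1 <- mux * mux + muy * muy + C1
  B2 <- sxx + syy + C2
  list(map = (A1 * A2) / (B1 * B2),
       mux = mux, muy = muy, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       k = k, w = w, H = H, W = W, x = x, y = y)
}

# d(mean SSIM)/dx from the cached statistics (y held fixed)
ssim_grad_x <- function(st) {
  B12 <- st$B1 * st$B2
  S <- st$map
  T1 <- (st$A2 * 2 * st$muy - S * st$B2 * 2 * st$mux) / B12
  T2 <- -S / st$B2
  T3 <- 2 * st$A1 / B12
  k <- st$k; H <- st$H; W <- st$W
  wv <- matrix(as.numeric(st$w), ncol = 1L)
  gT <- function(m) {
    dP <- wv %*% matrix(as.numeric(m), nrow = 1L)
    matrix(cpp_col2im(dP, H, W, 1L, k, 1L, 0L), H, W)
  }
  np <- length(S)
  (gT(T1 - 2 * T2 * st$mux - T3 * st$muy) +
     2 * st$x * gT(T2) + st$y * gT(T3)) / np
}

gaussian_window <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

#' Intensity-masked structural similarity
#'
#' SSIM between a real and a synthetic contrast tile evaluated only over
#' the signal region: the local SSIM map is computed on the full pair
#' (11-pixel Gaussian window, 8-bit dynamic range) and then averaged over
#' the map positions whose co-registered OCT intensity is at or above
#' `threshold`. Pixels under the intensity threshold are omitted from the
#' average but still contribute to windows that straddle the mask
#' boundary, so raising the threshold never changes the map values, only
#' which of them are averaged.
#'
#' @param real,synthetic Contrast tiles (matrices, 8-bit scale).
#' @param intensity Co-registered intensity tile (same shape, 8-bit
#'   scale).
#' @param threshold Intensity threshold on the 8-bit scale (default 10).
#' @param win_size,sigma,dynamic_range SSIM window parameters, as in
#'   [ssim_term()].
#' @param mask_mode `"after_map"` (default): the SSIM map is computed on
#'   the untouched pair and the mask only selects which map values are
#'   averaged. `"zero_first"`: sub-threshold pixels are zeroed in both
#'   contrast tiles before the map is computed (this changes the window
#'   statistics near the mask boundary and is offered for comparison
#'   only).
#' @return Scalar masked SSIM. Signals an error when no pixel passes the
#'   threshold.
#' @seealso [ssim_term()], [evaluate_dataset()]
#' @export
masked_ssim <- function(real, synthetic, intensity, threshold = 10,
                        win_size = 11L, sigma = 1.5, dynamic_range = 255,
                        mask_mode = c("after_map", "zero_first")) {
  mask_mode <- match.arg(mask_mode)
  if (!all(dim(real) == dim(intensity)))
    stop("masked_ssim: intensity tile shape differs from contrast tiles")
  if (threshold < 0 || threshold > dynamic_range)
    stop("masked_ssim: threshold outside the intensity range")
  if (mask_mode == "zero_first") {
    real[intensity < threshold] <- 0
    synthetic[intensity < threshold] <- 0
  }
  st <- ssim_map(real, synthetic, win_size = win_size, sigma = sigma,
                 dynamic_range = dynamic_range)
  r <- (st$k - 1L) %/% 2L
  centers <- intensity[r + seq_len(nrow(st$map)), r + seq_len(ncol(st$map)),
                       drop = FALSE]
  keep <- centers >= threshold
  if (!any(keep))
    stop("masked_ssim: empty mask (no pixel reaches the intensity threshold)")
  mean(st$map[keep])
}
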