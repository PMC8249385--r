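#' Masked-SSIM evaluation over a tile set
#'
#' Computes [masked_ssim()] for every aligned (real, synthetic,
#' intensity) triple and aggregates as mean and standard deviation.
#' Tiles whose mask is empty at the given threshold are excluded and
#' counted.
#'
#' @param real,synthetic,intensity Lists of co-shaped 8-bit matrices in
#'   matching order.
#' @param threshold 8-bit intensity threshold (default 10).
#' @param contrast Label recorded in the report (`"dopu"` or
#'   `"retardation"`).
#' @return An object of class `eval_report` with fields `per_tile_ssim`,
#'   `mean`, `std`, `contrast`, `threshold`, `n_tiles`,
#'   `n_empty_mask`.
#' @export
evaluate_dataset <- function(real, synthetic, intensity, threshold = 10,
                             contrast = c("dopu", "retardation")) {
  contrast <- match.arg(contrast)
  n <- length(real)
  if (n == 0 || length(synthetic) != n || length(intensity) != n)
    stop("evaluate_dataset: tile lists must be non-empty and aligned")
  vals <- numeric(0)
  empty <- 0L
  for (i in seq_len(n)) {
    v <- tryCatch(
      masked_ssim(real[[i]], synthetic[[i]], intensity[[i]], threshold,
                  win_size = fit_win(dim(real[[i]]))),
      error = function(e) {
        if (grepl("empty mask", conditionMessage(e))) NA_real_ else stop(e)
      })
    if (is.na(v)) empty <- empty + 1L else vals <- c(vals, v)
  }
  if (length(vals) == 0) stop("evaluate_dataset: zero evaluable tiles")
  structure(list(per_tile_ssim = vals, mean = mean(vals),
                 std = stats::sd(vals), contrast = contrast,
                 threshold = threshold, n_tiles = length(vals),
                 n_empty_mask = empty),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("masked SSIM (%s, threshold %g): %.4f +/- %.4f over %d tiles",
              x$contrast, x$threshold, x$mean,
              ifelse(is.na(x$std), 0, x$std), x$n_tiles))
  if (x$n_empty_mask > 0)
    cat(sprintf(" (%d tiles skipped: empty mask)", x$n_empty_mask))
  cat("\n")
  invisible(x)
}

# standard piecewise-linear jet colormap, tabulated for bit-exactness
jet_colormap <- function(n = 256L) {
  v <- seq(0, 1, length.out = n)
  ramp <- function(x) pmin(pmax(x, 0), 1)
  r <- ramp(1.5 - abs(4 * v - 3))
  g <- ramp(1.5 - abs(4 * v - 2))
  b <- ramp(1.5 - abs(4 * v - 1))
  cbind(r = r, g = g, b = b)
}

#' Jet-colormap overlay of a contrast on an intensity image
#'
#' Pixels whose intensity is below `threshold` are rendered as plain
#' grayscale intensity (the contrast is zeroed there); pixels at or
#' above the threshold show the jet-mapped contrast alpha-blended over
#' the intensity.
#'
#' @param intensity,contrast Co-shaped 8-bit matrices.
#' @param threshold 8-bit intensity threshold.
#' @param alpha Blend weight of the contrast layer.
#' @return `H x W x 3` array of RGB values in `[0, 1]`.
#' @export
render_overlay <- function(intensity, contrast, threshold = 10,
                           alpha = 0.6) {
  if (!all(dim(intensity) == dim(contrast)))
    stop("render_overlay: shape mismatch")
  cmap <- jet_colormap()
  gray <- pmin(pmax(intensity / 255, 0), 1)
  idx <- pmin(pmax(floor(contrast / 255 * 255) + 1L, 1L), 256L)
  keep <- intensity >= threshold
  out <- array(0, c(nrow(intensity), ncol(intensity), 3L))
  for (k in 1:3) {
    layer <- gray
    layer[keep] <- (1 - alpha) * gray[keep] + alpha * cmap[idx[keep], k]
    out[, , k] <- layer
  }
  out
}
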