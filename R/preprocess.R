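#' Crop dark margins from a raw frame
#'
#' Removes leading and trailing rows and columns whose mean intensity
#' falls below `margin_threshold` times the global maximum. Interior
#' content is never removed: the crop keeps everything between the first
#' and last row (column) at or above the threshold.
#'
#' @param image Numeric matrix.
#' @param margin_threshold Fraction of the global maximum (default 0.02).
#' @return The cropped matrix, with attribute `crop_window` giving the
#'   retained row/column ranges. Signals an error if the whole image is
#'   below threshold.
#' @export
crop_dark_margins <- function(image, margin_threshold = 0.02) {
  if (!is.matrix(image)) stop("crop_dark_margins: image must be a matrix")
  if (max(image) <= 0)
    stop("crop_dark_margins: empty result (entire image below threshold)")
  thr <- margin_threshold * max(image)
  rok <- which(rowMeans(image) >= thr)
  cok <- which(colMeans(image) >= thr)
  if (length(rok) == 0 || length(cok) == 0)
    stop("crop_dark_margins: empty result (entire image below threshold)")
  out <- image[min(rok):max(rok), min(cok):max(cok), drop = FALSE]
  attr(out, "crop_window") <- c(row_first = min(rok), row_last = max(rok),
                                col_first = min(cok), col_last = max(cok))
  out
}

#' Split a cropped frame into two square tiles
#'
#' The depth axis is center-cropped to `tile_side`; the lateral axis is
#' split into left and right halves, each center-cropped to `tile_side`.
#' A 256 x 512 frame therefore yields two 202 x 202 tiles with the
#' default side. The two tiles never overlap.
#'
#' @param image Numeric matrix, at least `tile_side` tall and
#'   `2 * tile_side` wide.
#' @param tile_side Square tile side in pixels (default 202).
#' @return List of two matrices `(left, right)`; each carries an
#'   `offsets` attribute `(row0, col0)` such that
#'   `tile[i, j] == image[row0 + i, col0 + j]`.
#' @export
split_into_tiles <- function(image, tile_side = 202L) {
  s <- as.integer(tile_side)
  H <- nrow(image); W <- ncol(image)
  if (H < s || W < 2L * s)
    stop("split_into_tiles: image ", H, "x", W,
         " too small for two ", s, "x", s, " tiles")
  r0 <- (H - s) %/% 2L
  half <- W %/% 2L
  cl0 <- (half - s) %/% 2L                 # left half: columns 1..half
  cr0 <- (W - half) + ((W - half) - s) %/% 2L  # right half starts at W-half+1
  left <- image[r0 + seq_len(s), cl0 + seq_len(s), drop = FALSE]
  right <- image[r0 + seq_len(s), cr0 + seq_len(s), drop = FALSE]
  attr(left, "offsets") <- c(row0 = r0, col0 = cl0)
  attr(right, "offsets") <- c(row0 = r0, col0 = cr0)
  list(left = left, right = right)
}

#' Convert a 16-bit image to 8-bit
#'
#' Global linear mode maps `[0, 65535]` onto `[0, 255]` with
#' round-half-up (`floor(v / 257 + 0.5)`): monotone, and constant images
#' stay constant. The per-image mode stretches the observed min--max
#' range instead; it is offered as an option without any fidelity claim.
#'
#' @param image Numeric matrix with values in `[0, 65535]`.
#' @param mode `"global"` (default) or `"per_image"`.
#' @return Matrix of integers in `[0, 255]`.
#' @export
convert_to_8bit <- function(image, mode = c("global", "per_image")) {
  mode <- match.arg(mode)
  if (mode == "global") {
    out <- floor(image / 257 + 0.5)
  } else {
    rg <- range(image)
    out <- if (rg[2] > rg[1])
      floor((image - rg[1]) / (rg[2] - rg[1]) * 255 + 0.5)
    else image * 0
  }
  pmin(pmax(out, 0), 255)
}

#' Expand a frame manifest to tile level
#'
#' Each frame contributes exactly two tiles (left and right halves), so
#' the tile manifest has twice as many rows per channel as the frame
#' manifest.
#'
#' @param manifest Data frame with columns `frame_id`, `case_id`,
#'   `label`.
#' @return Data frame with columns `tile_id`, `frame_id`, `half`,
#'   `case_id`, `label`.
#' @export
tile_manifest <- function(manifest) {
  if (nrow(manifest) == 0) stop("tile_manifest: empty manifest")
  halves <- c("left", "right")
  out <- manifest[rep(seq_len(nrow(manifest)), each = 2L), , drop = FALSE]
  out$half <- rep(halves, nrow(manifest))
  out$tile_id <- paste(out$frame_id, out$half, sep = "_")
  rownames(out) <- NULL
  out[, c("tile_id", "frame_id", "half", "case_id", "label")]
}

#' Assign tiles to train / test / validation partitions
#'
#' Image-based strategy: a single seeded permutation of all tiles; test
#' and validation each receive `floor(N/10)` tiles and training the
#' remainder (so 44,144 tiles give a 4,414-tile test set). Case-based
#' strategy: whole cases go to training except one held-out case per
#' class, whose tiles are split half into test and half into validation.
#' Only the 8:1:1 family is supported.
#'
#' @param tiles Tile-level manifest ([tile_manifest()]).
#' @param ratio Must be `c(8, 1, 1)`.
#' @param strategy `"image_based"` or `"case_based"`.
#' @param seed Integer seed for the shuffle.
#' @return The manifest with an added `partition` factor column and
#'   attributes `strategy`, `seed`, `ratio`.
#' @export
assign_splits <- function(tiles, ratio = c(8, 1, 1),
                          strategy = c("image_based", "case_based"),
                          seed = 1L) {
  strategy <- match.arg(strategy)
  if (nrow(tiles) == 0) stop("assign_splits: empty manifest")
  if (length(ratio) != 3L || !all(ratio == c(8, 1, 1)))
    stop("assign_splits: only the 8:1:1 ratio family is supported")
  N <- nrow(tiles)
  part <- character(N)
  set.seed(seed)
  if (strategy == "image_based") {
    perm <- sample.int(N)
    f <- N %/% 10L
    part[perm] <- rep(c("train", "test", "validation"),
                      c(N - 2L * f, f, f))
  } else {
    for (lab in unique(tiles$label)) {
      cases <- unique(tiles$case_id[tiles$label == lab])
      if (length(cases) < 2L)
        stop("assign_splits: case_based needs >= 2 cases per class")
      held <- sample(cases, 1L)
      part[tiles$label == lab & tiles$case_id != held] <- "train"
      idx <- which(tiles$case_id == held)
      idx <- sample(idx)
      nh <- length(idx)
      part[idx[seq_len(ceiling(nh / 2))]] <- "test"
      part[idx[-seq_len(ceiling(nh / 2))]] <- "validation"
    }
  }
  tiles$partition <- factor(part, levels = c("train", "test", "validation"))
  attr(tiles, "strategy") <- strategy
  attr(tiles, "seed") <- seed
  attr(tiles, "ratio") <- ratio
  tiles
}

#' Run the full image conditioning chain on a phantom dataset
#'
#' For every frame: crop dark margins, split into two square tiles, and
#' convert each channel to 8-bit (intensity by global linear scaling;
#' DOPU and retardation are first mapped from their physical ranges
#' `[0,1]` and `[0, pi/2]` onto the 16-bit scale). Returns per-channel
#' named tile lists plus the tile manifest.
#'
#' @param dataset A [generate_dataset()] result.
#' @param tile_side Square tile side (default 202; use smaller sides for
#'   small phantom frames).
#' @param margin_threshold Passed to [crop_dark_margins()].
#' @return List with elements `tiles` (named list per channel:
#'   `intensity`, `dopu`, `retardation`; each a named list of 8-bit
#'   tiles keyed by `tile_id`) and `manifest`.
#' @export
preprocess_dataset <- function(dataset, tile_side = 202L,
                               margin_threshold = 0.02) {
  man <- tile_manifest(dataset$manifest)
  chans <- c("intensity", "dopu", "retardation")
  tiles <- stats::setNames(vector("list", 3L), chans)
  for (ch in chans) tiles[[ch]] <- vector("list", nrow(man))
  for (fi in seq_len(nrow(dataset$manifest))) {
    fr <- dataset$frames[[dataset$manifest$frame_id[fi]]]
    raw <- list(intensity = fr$intensity,
                dopu = round(fr$dopu * 65535),
                retardation = round(fr$retardation / (pi / 2) * 65535))
    cropped <- crop_dark_margins(raw$intensity, margin_threshold)
    cw <- attr(cropped, "crop_window")
    for (ch in chans) {
      img <- raw[[ch]][cw["row_first"]:cw["row_last"],
                       cw["col_first"]:cw["col_last"], drop = FALSE]
      tl <- split_into_tiles(img, tile_side)
      for (half in c("left", "right")) {
        tid <- paste(dataset$manifest$frame_id[fi], half, sep = "_")
        tiles[[ch]][[match(tid, man$tile_id)]] <- convert_to_8bit(tl[[half]])
      }
    }
  }
  for (ch in chans) names(tiles[[ch]]) <- man$tile_id
  list(tiles = tiles, manifest = man)
}
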