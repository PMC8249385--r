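#' Smooth-mapping recovery benchmark task
#'
#' A diagnostic paired-tile task for exercising the synthesis GAN at
#' desk scale: intensity tiles come from the phantom simulator, and the
#' target contrast is a smooth invertible function of the box-blurred
#' intensity (`255 * (blur(I)/255)^0.6`). Because the mapping is
#' deterministic and low-frequency, a correctly implemented generator
#' should recover it to a high masked SSIM within a few epochs, which
#' makes the task a capability probe rather than a fidelity claim about
#' tissue data.
#'
#' @param n_pairs Number of paired tiles.
#' @param side Tile side in pixels.
#' @param seed Phantom seed.
#' @return List of `list(input =, target =)` 8-bit tile pairs.
#' @export
recovery_task_pairs <- function(n_pairs = 200L, side = 32L, seed = 1L) {
  cfg <- phantom_config(image_height = side + 8L,
                        image_width = 2L * side + 8L)
  n_frames <- ceiling(n_pairs / 2)
  ds <- generate_dataset(cfg, n_frames_per_class = ceiling(n_frames / 2),
                         n_cases_per_class = 2L, seed = seed)
  pp <- preprocess_dataset(ds, tile_side = side)
  tiles <- pp$tiles$intensity[seq_len(n_pairs)]
  lapply(tiles, function(tl) {
    b <- cpp_box_mean_clipped(cpp_box_mean_clipped(tl, 2L), 2L)
    list(input = tl, target = 255 * (b / 255)^0.6)
  })
}
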