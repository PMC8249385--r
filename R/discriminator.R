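#' Discriminator architecture specification
#'
#' A patch-level conditional discriminator in the pix2pix lineage: the
#' input intensity tile and the (real or synthetic) contrast tile are
#' concatenated channel-wise and passed through exactly three strided
#' convolutional feature layers (leaky ReLU; instance norm from the
#' second layer on), followed by a 1-channel convolutional score head
#' that emits a map of patch logits. Deeper discriminators are
#' deliberately not offered: the three-layer form is the reference
#' design for this synthesis task.
#'
#' @param base_channels Channels of the first feature layer.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(base_channels = 16L) {
  structure(list(n_conv_layers = 3L, base_channels = as.integer(base_channels),
                 normalization = "instance"),
            class = "discriminator_spec")
}

#' @export
print.discriminator_spec <- function(x, ...) {
  cat("Patch discriminator: 3 conv feature layers + score head | base",
      x$base_channels, "channels\n")
  invisible(x)
}

disc_new <- function(spec, in_channels = 2L) {
  b <- spec$base_channels
  layers <- list(
    c1 = layer_conv(in_channels, b, k = 3L, stride = 2L),
    c2 = layer_conv(b, 2L * b, k = 3L, stride = 2L),
    c2_n = layer_inorm(2L * b),
    c3 = layer_conv(2L * b, 4L * b, k = 3L, stride = 2L),
    c3_n = layer_inorm(4L * b),
    head = layer_conv(4L * b, 1L, k = 3L, stride = 1L))
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$spec <- spec
  net
}

# x, y: [H, W, 1] tensors on the [-1, 1] scale; returns logit map
disc_forward <- function(net, x, y, train = TRUE) {
  h <- array(c(x, y), c(dim(x)[1], dim(x)[2], dim(x)[3] + dim(y)[3]))
  cache <- list(in_ch = c(dim(x)[3], dim(y)[3]))
  h <- lrelu_fw(conv_fw(net$layers$c1, h, train)); cache$a1 <- h
  h <- conv_fw(net$layers$c2, h, train)
  h <- lrelu_fw(inorm_fw(net$layers$c2_n, h, train)); cache$a2 <- h
  h <- conv_fw(net$layers$c3, h, train)
  h <- lrelu_fw(inorm_fw(net$layers$c3_n, h, train)); cache$a3 <- h
  if (train) net$cache <- cache
  conv_fw(net$layers$head, h, train)
}

# backward from d(loss)/d(logit map); returns gradient w.r.t. the
# contrast input y (used by the generator step)
disc_backward <- function(net, dlogits) {
  cache <- net$cache
  dh <- conv_bw(net$layers$head, dlogits)
  dh <- lrelu_bw(dh, cache$a3)
  dh <- inorm_bw(net$layers$c3_n, dh)
  dh <- conv_bw(net$layers$c3, dh)
  dh <- lrelu_bw(dh, cache$a2)
  dh <- inorm_bw(net$layers$c2_n, dh)
  dh <- conv_bw(net$layers$c2, dh)
  dh <- lrelu_bw(dh, cache$a1)
  dh <- conv_bw(net$layers$c1, dh)
  nx <- cache$in_ch[1]
  dh[, , nx + seq_len(cache$in_ch[2]), drop = FALSE]
}
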