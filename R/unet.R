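#' Generator architecture specification
#'
#' Describes the U-Net encoder--decoder used as the GAN generator: an
#' encoder of `depth` levels (each a 3x3 convolution + instance norm +
#' leaky ReLU followed by 2x2 mean pooling), a bottleneck convolution,
#' and a mirrored decoder (nearest-neighbour upsampling, concatenation
#' with the skip from the same level, convolution + instance norm + ReLU),
#' closed by a tanh-bounded output convolution mapped onto the 8-bit
#' scale. Inputs whose sides are not multiples of `2^depth` are
#' reflect-padded up and the output is cropped back, so the output always
#' matches the input shape.
#'
#' @param depth Number of downsampling levels (default 5, as used for
#'   202x202 tiles; small tiles use fewer).
#' @param base_channels Channels of the first encoder level; level `d`
#'   uses `base_channels * 2^(d-1)`.
#' @param in_channels,out_channels Image channels (grayscale: 1).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 5L, base_channels = 64L,
                           in_channels = 1L, out_channels = 1L) {
  stopifnot(depth >= 1L, base_channels >= 1L)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 normalization = "instance",
                 padding_policy = "reflect-to-2^depth"),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("U-Net generator: depth", x$depth, "| base channels", x$base_channels,
      "| instance norm | tanh output on 8-bit scale\n")
  invisible(x)
}

# build the parameterized network (uses the current RNG state for init)
unet_new <- function(spec) {
  depth <- spec$depth
  ch <- spec$base_channels * 2L^(seq_len(depth) - 1L)
  layers <- list()
  for (d in seq_len(depth)) {
    cin <- if (d == 1L) spec$in_channels else ch[d - 1L]
    layers[[paste0("enc", d)]] <- layer_conv(cin, ch[d])
    layers[[paste0("enc", d, "_n")]] <- layer_inorm(ch[d])
  }
  layers[["bott"]] <- layer_conv(ch[depth], ch[depth])
  layers[["bott_n"]] <- layer_inorm(ch[depth])
  for (d in rev(seq_len(depth))) {
    cprev <- if (d == depth) ch[depth] else ch[d + 1L]
    layers[[paste0("dec", d)]] <- layer_conv(cprev + ch[d], ch[d])
    layers[[paste0("dec", d, "_n")]] <- layer_inorm(ch[d])
  }
  layers[["final"]] <- layer_conv(ch[1L], spec$out_channels)
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$spec <- spec
  net
}

# forward pass on a [H, W, C] tensor already scaled to [-1, 1];
# returns tanh output in [-1, 1]; caches activations for unet_backward
unet_forward <- function(net, x, train = TRUE) {
  depth <- net$spec$depth
  pp <- pad_to_multiple(x, 2L^depth)
  cache <- list(pad = pp)
  h <- pp$x
  skips <- vector("list", depth)
  for (d in seq_len(depth)) {
    h <- conv_fw(net$layers[[paste0("enc", d)]], h, train)
    h <- inorm_fw(net$layers[[paste0("enc", d, "_n")]], h, train)
    h <- lrelu_fw(h)
    cache[[paste0("enc_act", d)]] <- h
    skips[[d]] <- h
    cache[[paste0("pool_in", d)]] <- dim(h)
    h <- avgpool_fw(h)
  }
  h <- conv_fw(net$layers[["bott"]], h, train)
  h <- inorm_fw(net$layers[["bott_n"]], h, train)
  h <- relu_fw(h)
  cache[["bott_act"]] <- h
  for (d in rev(seq_len(depth))) {
    h <- upsample_fw(h)
    nsk <- dim(skips[[d]])[3]
    cache[[paste0("dec_split", d)]] <- c(dim(h)[3], nsk)
    hcat <- array(c(h, skips[[d]]), c(dim(h)[1], dim(h)[2], dim(h)[3] + nsk))
    h <- conv_fw(net$layers[[paste0("dec", d)]], hcat, train)
    h <- inorm_fw(net$layers[[paste0("dec", d, "_n")]], h, train)
    h <- relu_fw(h)
    cache[[paste0("dec_act", d)]] <- h
  }
  z <- conv_fw(net$layers[["final"]], h, train)
  y <- tanh(z)
  cache[["tanh_out"]] <- y
  if (train) net$cache <- cache
  y[pp$rows, pp$cols, , drop = FALSE]
}

# backward from d(loss)/d(cropped tanh output); accumulates layer grads
unet_backward <- function(net, dy) {
  cache <- net$cache
  depth <- net$spec$depth
  y <- cache$tanh_out
  dfull <- array(0, dim(y))
  dfull[cache$pad$rows, cache$pad$cols, ] <- dy
  dz <- dfull * (1 - y * y)
  dh <- conv_bw(net$layers[["final"]], dz)
  dskip <- vector("list", depth)
  for (d in seq_len(depth)) {
    dh <- relu_bw(dh, cache[[paste0("dec_act", d)]])
    dh <- inorm_bw(net$layers[[paste0("dec", d, "_n")]], dh)
    dcat <- conv_bw(net$layers[[paste0("dec", d)]], dh)
    spl <- cache[[paste0("dec_split", d)]]
    dup <- dcat[, , seq_len(spl[1]), drop = FALSE]
    dskip[[d]] <- dcat[, , spl[1] + seq_len(spl[2]), drop = FALSE]
    dh <- upsample_bw(dup)
  }
  # dh is now the gradient flowing into the bottleneck activation
  dh <- relu_bw(dh, cache[["bott_act"]])
  dh <- inorm_bw(net$layers[["bott_n"]], dh)
  dh <- conv_bw(net$layers[["bott"]], dh)
  for (d in rev(seq_len(depth))) {
    dh <- avgpool_bw(dh)
    dh <- dh + dskip[[d]]
    dh <- lrelu_bw(dh, cache[[paste0("enc_act", d)]])
    dh <- inorm_bw(net$layers[[paste0("enc", d, "_n")]], dh)
    dh <- conv_bw(net$layers[[paste0("enc", d)]], dh)
  }
  invisible(dh)
}
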