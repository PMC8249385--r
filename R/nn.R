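# Minimal dense/conv layer machinery used by the GAN and the classifier.
#
# Image tensors are numeric arrays [H, W, C] (depth axis first, then
# lateral, then channel). All networks run at batch size 1, which matches
# instance normalization. Layers are environments carrying parameters,
# accumulated gradients and the forward cache; networks wire them together
# explicitly in unet.R / discriminator.R / classifier.R.

new_layer <- function(type, ...) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = ly)
  ly
}

#' @noRd
layer_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  # He-style init for leaky/plain ReLU fan-in
  sd <- sqrt(2 / (k * k * cin))
  new_layer("conv",
    cin = cin, cout = cout, k = as.integer(k), stride = as.integer(stride),
    pad = as.integer(pad),
    W = matrix(stats::rnorm(cout * k * k * cin, sd = sd), nrow = cout),
    b = numeric(cout))
}

#' @noRd
layer_inorm <- function(ch, eps = 1e-5) {
  new_layer("inorm", ch = ch, eps = eps, gamma = rep(1, ch), beta = numeric(ch))
}

#' @noRd
layer_linear <- function(din, dout) {
  sd <- sqrt(1 / din)
  new_layer("linear", din = din, dout = dout,
            W = matrix(stats::rnorm(dout * din, sd = sd), nrow = dout),
            b = numeric(dout))
}

layer_param_names <- function(ly) {
  switch(ly$type,
    conv = c("W", "b"),
    linear = c("W", "b"),
    inorm = c("gamma", "beta"),
    character(0))
}

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

conv_fw <- function(ly, x, train = TRUE) {
  d <- dim(x)
  P <- cpp_im2col(as.numeric(x), d[1], d[2], d[3], ly$k, ly$stride, ly$pad)
  Y <- ly$W %*% P + ly$b
  ho <- conv_out_dim(d[1], ly$k, ly$stride, ly$pad)
  wo <- conv_out_dim(d[2], ly$k, ly$stride, ly$pad)
  if (train) {
    ly$cache_P <- P
    ly$cache_dim <- d
  }
  array(t(Y), c(ho, wo, ly$cout))
}

conv_bw <- function(ly, dy) {
  d <- dim(dy)
  dYm <- matrix(dy, d[1] * d[2], ly$cout)        # (Ho*Wo) x cout
  ly$db <- ly$db + colSums(dYm)
  ly$dW <- ly$dW + t(ly$cache_P %*% dYm)
  dP <- crossprod(ly$W, t(dYm))                  # (k2*cin) x (Ho*Wo)
  dd <- ly$cache_dim
  cpp_col2im(dP, dd[1], dd[2], dd[3], ly$k, ly$stride, ly$pad)
}

inorm_fw <- function(ly, x, train = TRUE) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colSums(xc * xc) / n
  istd <- 1 / sqrt(v + ly$eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(xhat, 2, ly$gamma, `*`)
  y <- sweep(y, 2, ly$beta, `+`)
  if (train) {
    ly$cache_xhat <- xhat
    ly$cache_istd <- istd
    ly$cache_n <- n
  }
  array(y, d)
}

inorm_bw <- function(ly, dy) {
  d <- dim(dy)
  n <- ly$cache_n
  dym <- matrix(dy, n, d[3])
  xhat <- ly$cache_xhat
  ly$dbeta <- ly$dbeta + colSums(dym)
  ly$dgamma <- ly$dgamma + colSums(dym * xhat)
  g <- ly$gamma * ly$cache_istd
  m1 <- colMeans(dym)
  m2 <- colMeans(dym * xhat)
  dx <- sweep(sweep(dym, 2, m1) - sweep(xhat, 2, m2, `*`), 2, g, `*`)
  array(dx, d)
}

linear_fw <- function(ly, x, train = TRUE) {
  if (train) ly$cache_x <- x
  drop(ly$W %*% x) + ly$b
}

linear_bw <- function(ly, dy) {
  ly$db <- ly$db + dy
  ly$dW <- ly$dW + outer(dy, ly$cache_x)
  drop(crossprod(ly$W, dy))
}

lrelu_fw <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  attr(x, "neg") <- neg
  x
}

lrelu_bw <- function(dy, act, slope = 0.2) {
  neg <- attr(act, "neg")
  dy[neg] <- dy[neg] * slope
  dy
}

relu_fw <- function(x) {
  neg <- x < 0
  x[neg] <- 0
  attr(x, "neg") <- neg
  x
}

relu_bw <- function(dy, act) {
  dy[attr(act, "neg")] <- 0
  dy
}

# 2x2 mean pooling (stride 2); H and W must be even
avgpool_fw <- function(x) {
  d <- dim(x)
  io <- seq.int(1L, d[1], 2L)
  jo <- seq.int(1L, d[2], 2L)
  (x[io, jo, , drop = FALSE] + x[io + 1L, jo, , drop = FALSE] +
     x[io, jo + 1L, , drop = FALSE] + x[io + 1L, jo + 1L, , drop = FALSE]) / 4
}

avgpool_bw <- function(dy) {
  d <- dim(dy)
  dx <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  io <- seq.int(1L, 2L * d[1], 2L)
  jo <- seq.int(1L, 2L * d[2], 2L)
  q <- dy / 4
  dx[io, jo, ] <- q
  dx[io + 1L, jo, ] <- q
  dx[io, jo + 1L, ] <- q
  dx[io + 1L, jo + 1L, ] <- q
  dx
}

# nearest-neighbour 2x upsampling
upsample_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample_bw <- function(dy) {
  d <- dim(dy)
  io <- seq.int(1L, d[1], 2L)
  jo <- seq.int(1L, d[2], 2L)
  dy[io, jo, , drop = FALSE] + dy[io + 1L, jo, , drop = FALSE] +
    dy[io, jo + 1L, , drop = FALSE] + dy[io + 1L, jo + 1L, , drop = FALSE]
}

# --- parameter bookkeeping ---------------------------------------------

net_layers <- function(net) net$layers

zero_grads <- function(net) {
  for (ly in net_layers(net)) {
    for (p in layer_param_names(ly)) {
      g <- get(p, envir = ly)
      assign(paste0("d", p), if (is.matrix(g)) 0 * g else numeric(length(g)),
             envir = ly)
    }
  }
  invisible(net)
}

get_params <- function(net) {
  lapply(net_layers(net), function(ly) {
    ps <- lapply(layer_param_names(ly), get, envir = ly)
    names(ps) <- layer_param_names(ly)
    ps
  })
}

set_params <- function(net, params) {
  lys <- net_layers(net)
  stopifnot(length(lys) == length(params))
  for (i in seq_along(lys)) {
    for (p in names(params[[i]])) assign(p, params[[i]][[p]], envir = lys[[i]])
  }
  invisible(net)
}

params_checksum <- function(params) {
  sum(vapply(params, function(p) sum(vapply(p, function(v) sum(as.numeric(v)),
                                            0)), 0))
}

adam_step <- function(net, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8,
                      only = NULL) {
  net$adam_t <- (net$adam_t %||% 0L) + 1L
  t <- net$adam_t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  lys <- net_layers(net)
  idx <- if (is.null(only)) seq_along(lys) else only
  for (i in idx) {
    ly <- lys[[i]]
    for (p in layer_param_names(ly)) {
      g <- get(paste0("d", p), envir = ly)
      mname <- paste0("adam_m_", p)
      vname <- paste0("adam_v_", p)
      m <- if (exists(mname, envir = ly, inherits = FALSE))
        get(mname, envir = ly) else 0 * g
      v <- if (exists(vname, envir = ly, inherits = FALSE))
        get(vname, envir = ly) else 0 * g
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      assign(mname, m, envir = ly)
      assign(vname, v, envir = ly)
      val <- get(p, envir = ly)
      assign(p, val - lr * (m / bc1) / (sqrt(v / bc2) + eps), envir = ly)
    }
  }
  invisible(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reflect-pad an [H, W, C] tensor so both spatial sides become multiples
# of `mult`; returns the padded tensor plus the crop window
pad_to_multiple <- function(x, mult) {
  d <- dim(x)
  ph <- (mult - d[1] %% mult) %% mult
  pw <- (mult - d[2] %% mult) %% mult
  t0 <- ph %/% 2L
  l0 <- pw %/% 2L
  if (ph > 0 || pw > 0) {
    H <- d[1]; W <- d[2]
    ridx <- c(rev(seq_len(t0) + 1L), seq_len(H), H - seq_len(ph - t0))
    cidx <- c(rev(seq_len(l0) + 1L), seq_len(W), W - seq_len(pw - l0))
    x <- x[ridx, cidx, , drop = FALSE]
  }
  list(x = x, rows = seq_len(d[1]) + t0, cols = seq_len(d[2]) + l0)
}
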