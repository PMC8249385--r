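#' t-SNE embedding of penultimate activations
#'
#' Standard t-distributed stochastic neighbour embedding: per-point
#' Gaussian bandwidths are calibrated by binary search so that the
#' conditional-distribution entropy equals `log(perplexity)` (natural
#' log) to within the stated tolerance; the joint similarities are
#' symmetrized; and a 2-D embedding is optimized by gradient descent
#' with momentum, adaptive gains and an early-exaggeration phase,
#' starting from a small random Gaussian initialization. Distances are
#' Euclidean. Deterministic for a fixed seed.
#'
#' @param x `N x d` numeric matrix (rows are points).
#' @param perplexity Target perplexity (default 30). When `N - 1 <
#'   3 * perplexity` it is reduced to `floor((N - 1) / 3)` with a
#'   warning.
#' @param seed Seed for the random initialization.
#' @param max_iter Gradient-descent iterations.
#' @param learning_rate Gradient step size.
#' @param exaggeration,exaggeration_iter Early-exaggeration factor and
#'   duration.
#' @param entropy_tol Binary-search tolerance on the per-point entropy
#'   (nats).
#' @return `N x 2` matrix of embedding coordinates with attributes
#'   `kl_history` (KL divergence at 50-iteration intervals, computed
#'   against the unexaggerated similarities), `entropy` (achieved
#'   per-point entropies), and `perplexity` (the value actually used).
#' @export
tsne_embed <- function(x, perplexity = 30, seed = 1L, max_iter = 500L,
                       learning_rate = 100, exaggeration = 4,
                       exaggeration_iter = 100L, entropy_tol = 1e-5) {
  x <- as.matrix(x)
  N <- nrow(x)
  if (N < 5L) stop("tsne_embed: need at least 5 points")
  if (N - 1 < 3 * perplexity) {
    p_new <- max(2, floor((N - 1) / 3))
    if (p_new < perplexity) {
      warning("tsne_embed: perplexity reduced to ", p_new,
              " (too few points)")
      perplexity <- p_new
    }
  }
  sq <- rowSums(x * x)
  D2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(x), 0)
  diag(D2) <- 0
  target <- log(perplexity)
  Pc <- matrix(0, N, N)
  ent <- numeric(N)
  betas <- numeric(N)
  for (i in seq_len(N)) {
    di <- D2[i, -i]
    lo <- 0
    hi <- Inf
    beta <- 1 / (stats::median(di) + 1e-12)
    for (it in 1:100) {
      w <- exp(-beta * (di - min(di)))
      sw <- sum(w)
      p <- w / sw
      H <- -sum(p * log(pmax(p, 1e-300)))
      if (abs(H - target) < entropy_tol) break
      if (H > target) {          # too flat: increase beta
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    ent[i] <- H
    betas[i] <- beta
    Pc[i, -i] <- p
  }
  P <- (Pc + t(Pc)) / (2 * N)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(N * 2, sd = 1e-4), N, 2)
  dY <- matrix(0, N, 2)
  gains <- matrix(1, N, 2)
  kl_hist <- numeric(0)
  kl_of <- function(Y) {
    q <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(q) <- 0
    Q <- pmax(q / sum(q), 1e-12)
    sum(P * log(P / Q))
  }
  for (iter in seq_len(max_iter)) {
    Pit <- if (iter <= exaggeration_iter) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - learning_rate * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter %% 50L == 0L) kl_hist <- c(kl_hist, kl_of(Y))
  }
  structure(Y, kl_history = kl_hist, entropy = ent, betas = betas,
            perplexity = perplexity,
            class = c("psoct_tsne", "matrix", "array"))
}

#' @export
plot.psoct_tsne <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) 1 else as.integer(factor(labels)) + 1
  graphics::plot(x[, 1], x[, 2], col = col, pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  invisible(x)
}
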