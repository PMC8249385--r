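# Independent brute-force oracles used across the suite. These are
# deliberately written as plain double loops / closed forms so they share
# no code path with the package implementations they check.

# sliding-window Gaussian SSIM, one window at a time
bf_ssim_map <- function(x, y, k = 11, sigma = 1.5, L = 255) {
  w <- outer(exp(-((-(k - 1) / 2):((k - 1) / 2))^2 / (2 * sigma^2)),
             exp(-((-(k - 1) / 2):((k - 1) / 2))^2 / (2 * sigma^2)))
  w <- w / sum(w)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(NA_real_, H - k + 1, W - k + 1)
  for (i in seq_len(H - k + 1)) {
    for (j in seq_len(W - k + 1)) {
      px <- x[i:(i + k - 1), j:(j + k - 1)]
      py <- y[i:(i + k - 1), j:(j + k - 1)]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2
      vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      out[i, j] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
  }
  out
}

bf_ssim <- function(x, y, k = 11, ...) mean(bf_ssim_map(x, y, k, ...))

bf_masked_ssim <- function(x, y, intensity, threshold, k = 11) {
  m <- bf_ssim_map(x, y, k)
  r <- (k - 1) / 2
  keep <- intensity[r + seq_len(nrow(m)), r + seq_len(ncol(m))] >= threshold
  mean(m[keep])
}

# DOPU by explicit per-pixel window sums with border clipping
bf_dopu <- function(field, kernel) {
  r <- (kernel - 1) / 2
  H <- nrow(field$q); W <- ncol(field$q)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ii <- max(1, i - r):min(H, i + r)
      jj <- max(1, j - r):min(W, j + r)
      qm <- mean(field$q[ii, jj] / field$i[ii, jj])
      um <- mean(field$u[ii, jj] / field$i[ii, jj])
      vm <- mean(field$v[ii, jj] / field$i[ii, jj])
      out[i, j] <- min(sqrt(qm^2 + um^2 + vm^2), 1)
    }
  }
  out
}

# AUC as the Mann-Whitney pairwise statistic (ties count one half)
bf_auc <- function(scores, labels) {
  pos <- which(labels)
  neg <- which(!labels)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# mean silhouette width over two or more groups
mean_silhouette <- function(Y, labels) {
  D <- as.matrix(stats::dist(Y))
  n <- nrow(Y)
  s <- numeric(n)
  for (i in seq_len(n)) {
    a <- mean(D[i, labels == labels[i] & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small phantom config used throughout the unit tests
small_config <- function(...) {
  phantom_config(image_height = 40L, image_width = 72L, ...)
}
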