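#' Classifier architecture / training specification
#'
#' A residual-network image classifier with a 512-wide penultimate
#' activation and a fully connected 512 x 2 head (cancer vs normal).
#' The default `"reduced"` backbone has a convolutional stem and four
#' residual blocks ending at 512 channels followed by global average
#' pooling -- a small-scale capability surrogate that preserves the
#' 512-d penultimate width; `"resnet18"` builds the full 18-layer
#' topology. Transfer-learning style training freezes every backbone
#' weight and updates only the head (`trainable_scope = "head_only"`).
#' `init = "pretrained"` requires an explicit weight list (no weights
#' are bundled); the default is random initialization.
#'
#' @param backbone `"reduced"` (default) or `"resnet18"`.
#' @param trainable_scope `"head_only"` (default) or `"all"`.
#' @param init `"random"` or `"pretrained"`.
#' @param epochs Training epochs (default 24).
#' @param learning_rate Adam rate for the trainable parameters.
#' @param stem_channels Channels after the stem convolution of the
#'   reduced backbone.
#' @param weight_decay L2 penalty on the head weights under
#'   `head_only` training (the linear probe on frozen features is
#'   otherwise badly overparameterized).
#' @param normalization `"none"` (default) or `"instance"`. Batch
#'   statistics are unavailable in this per-sample pipeline, and
#'   instance normalization would discard each tile's mean contrast
#'   level -- a diagnostic signal -- so the backbone runs unnormalized
#'   by default.
#' @export
classifier_spec <- function(backbone = c("reduced", "resnet18"),
                            trainable_scope = c("head_only", "all"),
                            init = c("random", "pretrained"),
                            epochs = 24L, learning_rate = 1e-3,
                            stem_channels = 32L,
                            normalization = c("none", "instance"),
                            weight_decay = 0.05) {
  structure(list(backbone = match.arg(backbone),
                 trainable_scope = match.arg(trainable_scope),
                 init = match.arg(init), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 stem_channels = as.integer(stem_channels),
                 normalization = match.arg(normalization),
                 weight_decay = weight_decay,
                 feature_width = 512L, n_classes = 2L),
            class = "classifier_spec")
}

backbone_blocks <- function(spec) {
  if (spec$backbone == "reduced") {
    stem <- spec$stem_channels
    data.frame(cin = c(stem, 64L, 128L, 256L),
               cout = c(64L, 128L, 256L, 512L),
               stride = c(2L, 2L, 2L, 2L))
  } else {
    data.frame(cin = c(64L, 64L, 64L, 128L, 128L, 256L, 256L, 512L),
               cout = c(64L, 64L, 128L, 128L, 256L, 256L, 512L, 512L),
               stride = c(1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L))
  }
}

backbone_new <- function(spec) {
  stem_ch <- if (spec$backbone == "reduced") spec$stem_channels else 64L
  norm <- identical(spec$normalization, "instance")
  layers <- list(stem = layer_conv(1L, stem_ch))
  if (norm) layers$stem_n <- layer_inorm(stem_ch)
  bl <- backbone_blocks(spec)
  for (b in seq_len(nrow(bl))) {
    p <- paste0("b", b, "_")
    layers[[paste0(p, "c1")]] <- layer_conv(bl$cin[b], bl$cout[b],
                                            stride = bl$stride[b])
    if (norm) layers[[paste0(p, "n1")]] <- layer_inorm(bl$cout[b])
    layers[[paste0(p, "c2")]] <- layer_conv(bl$cout[b], bl$cout[b])
    if (norm) layers[[paste0(p, "n2")]] <- layer_inorm(bl$cout[b])
    if (bl$cin[b] != bl$cout[b] || bl$stride[b] != 1L) {
      layers[[paste0(p, "sc")]] <- layer_conv(bl$cin[b], bl$cout[b],
                                              k = 1L, stride = bl$stride[b],
                                              pad = 0L)
      if (norm) layers[[paste0(p, "sn")]] <- layer_inorm(bl$cout[b])
    }
  }
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$spec <- spec
  net$n_blocks <- nrow(bl)
  net
}

norm_fw <- function(net, name, h, train) {
  ly <- net$layers[[name]]
  if (is.null(ly)) h else inorm_fw(ly, h, train)
}

norm_bw <- function(net, name, dh) {
  ly <- net$layers[[name]]
  if (is.null(ly)) dh else inorm_bw(ly, dh)
}

# forward to the 512-d penultimate activation; caches for backward
backbone_forward <- function(net, x, train = FALSE) {
  cache <- list()
  h <- relu_fw(norm_fw(net, "stem_n",
                       conv_fw(net$layers$stem, x, train), train))
  cache$stem_act <- h
  for (b in seq_len(net$n_blocks)) {
    p <- paste0("b", b, "_")
    m <- conv_fw(net$layers[[paste0(p, "c1")]], h, train)
    m <- relu_fw(norm_fw(net, paste0(p, "n1"), m, train))
    cache[[paste0(p, "mid")]] <- m
    m <- conv_fw(net$layers[[paste0(p, "c2")]], m, train)
    m <- norm_fw(net, paste0(p, "n2"), m, train)
    s <- if (!is.null(net$layers[[paste0(p, "sc")]])) {
      norm_fw(net, paste0(p, "sn"),
              conv_fw(net$layers[[paste0(p, "sc")]], h, train), train)
    } else h
    h <- relu_fw(m + s)
    cache[[paste0(p, "out")]] <- h
    cache[[paste0(p, "has_sc")]] <- !is.null(net$layers[[paste0(p, "sc")]])
  }
  cache$gap_dim <- dim(h)
  if (train) net$cache <- cache
  colMeans(matrix(h, dim(h)[1] * dim(h)[2], dim(h)[3]))
}

backbone_backward <- function(net, dfeat) {
  cache <- net$cache
  d <- cache$gap_dim
  dh <- array(rep(dfeat / (d[1] * d[2]), each = d[1] * d[2]), d)
  for (b in rev(seq_len(net$n_blocks))) {
    p <- paste0("b", b, "_")
    dh <- relu_bw(dh, cache[[paste0(p, "out")]])
    dm <- norm_bw(net, paste0(p, "n2"), dh)
    dm <- conv_bw(net$layers[[paste0(p, "c2")]], dm)
    dm <- relu_bw(dm, cache[[paste0(p, "mid")]])
    dm <- norm_bw(net, paste0(p, "n1"), dm)
    dm <- conv_bw(net$layers[[paste0(p, "c1")]], dm)
    ds <- if (cache[[paste0(p, "has_sc")]]) {
      conv_bw(net$layers[[paste0(p, "sc")]],
              norm_bw(net, paste0(p, "sn"), dh))
    } else dh
    dh <- dm + ds
  }
  dh <- relu_bw(dh, cache$stem_act)
  dh <- norm_bw(net, "stem_n", dh)
  conv_bw(net$layers$stem, dh)
  invisible(NULL)
}

tile_to_tensor <- function(tile) {
  if (!is.matrix(tile)) stop("classifier: tile must be a matrix")
  array(tile / 127.5 - 1, c(nrow(tile), ncol(tile), 1L))
}

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Split labelled tiles for the downstream classifier
#'
#' Floor-based 6:3:1 partition: test receives `floor(0.3 N)` items,
#' validation `floor(0.1 N)`, training the remainder, after a seeded
#' shuffle. Partitions are disjoint and exhaustive.
#'
#' @param n Number of items, or a vector whose length is used.
#' @param ratio Must be `c(6, 3, 1)`.
#' @param seed Shuffle seed.
#' @return List of index vectors `train`, `test`, `validation`.
#' @export
split_for_classifier <- function(n, ratio = c(6, 3, 1), seed = 1L) {
  if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (n < 1L) stop("split_for_classifier: empty input")
  if (length(ratio) != 3L || !all(ratio == c(6, 3, 1)))
    stop("split_for_classifier: only the 6:3:1 ratio is supported")
  set.seed(seed)
  perm <- sample.int(n)
  ntest <- floor(0.3 * n)
  nval <- floor(0.1 * n)
  ntrain <- n - ntest - nval
  list(train = perm[seq_len(ntrain)],
       test = perm[ntrain + seq_len(ntest)],
       validation = perm[ntrain + ntest + seq_len(nval)])
}

#' Train the cancer/normal tile classifier
#'
#' Trains the residual classifier on 8-bit contrast tiles. Under
#' `trainable_scope = "head_only"` the backbone acts as a fixed feature
#' extractor: penultimate activations are computed once, standardized
#' with training-set statistics, and only the 512 x 2 head is optimized
#' (full-batch gradient descent on the softmax cross-entropy with an L2
#' penalty; the standardization is folded back into the head weights
#' afterwards). Under `"all"` every parameter is updated by per-sample
#' backpropagation with Adam. The epoch with the best validation
#' accuracy is retained.
#'
#' @param train_tiles,val_tiles Lists of 8-bit matrices.
#' @param train_labels,val_labels Character/factor labels
#'   (`"cancer"`/`"normal"`); both classes must appear in training.
#' @param spec A [classifier_spec()].
#' @param seed Seed for initialization and shuffling.
#' @param weights Optional pretrained backbone parameter list (required
#'   when `spec$init == "pretrained"`).
#' @return An object of class `psoct_classifier`.
#' @export
train_classifier <- function(train_tiles, train_labels,
                             val_tiles = list(), val_labels = character(0),
                             spec = classifier_spec(), seed = 1L,
                             weights = NULL) {
  y <- as.character(train_labels)
  if (length(train_tiles) == 0) stop("train_classifier: empty training set")
  if (length(unique(y)) < 2L)
    stop("train_classifier: training set contains a single class")
  set.seed(seed)
  net <- backbone_new(spec)
  if (spec$init == "pretrained") {
    if (is.null(weights))
      stop("train_classifier: init='pretrained' requires a weights list ",
           "(none are bundled with the package)")
    set_params(net, weights)
  }
  head <- layer_linear(spec$feature_width, spec$n_classes)
  headnet <- new.env(parent = emptyenv())
  headnet$layers <- list(head = head)
  tgt <- ifelse(y == "cancer", 2L, 1L)   # logit order: (normal, cancer)
  yv <- as.character(val_labels)
  tgtv <- ifelse(yv == "cancer", 2L, 1L)
  n <- length(train_tiles)
  head_only <- spec$trainable_scope == "head_only"
  feats <- featsv <- NULL
  # feature standardization (train-set statistics) stabilizes the
  # linear probe on the frozen random backbone
  fmu <- rep(0, spec$feature_width)
  fsd <- rep(1, spec$feature_width)
  if (head_only) {
    feats <- t(vapply(train_tiles, function(tl)
      backbone_forward(net, tile_to_tensor(tl), train = FALSE),
      numeric(spec$feature_width)))
    fmu <- colMeans(feats)
    fsd <- apply(feats, 2, stats::sd)
    fsd[fsd < 1e-8] <- 1
    feats <- sweep(sweep(feats, 2, fmu), 2, fsd, `/`)
    if (length(val_tiles) > 0) {
      featsv <- t(vapply(val_tiles, function(tl)
        backbone_forward(net, tile_to_tensor(tl), train = FALSE),
        numeric(spec$feature_width)))
      featsv <- sweep(sweep(featsv, 2, fmu), 2, fsd, `/`)
    }
  }
  hist <- vector("list", spec$epochs)
  best_acc <- -Inf
  best <- NULL
  best_epoch <- NA_integer_
  Y1 <- cbind(as.numeric(tgt == 1L), as.numeric(tgt == 2L))
  for (ep in seq_len(spec$epochs)) {
    celoss <- 0
    if (head_only) {
      # full-batch ridge-regularized softmax regression on the cached,
      # standardized features (20 gradient steps per epoch)
      for (s in 1:20) {
        Z <- feats %*% t(head$W) +
          matrix(head$b, n, 2, byrow = TRUE)
        Z <- Z - apply(Z, 1, max)
        E <- exp(Z)
        P <- E / rowSums(E)
        G <- (P - Y1) / n
        head$W <- head$W - 0.5 * (crossprod(G, feats) +
                                    spec$weight_decay * head$W)
        head$b <- head$b - 0.5 * colSums(G)
      }
      celoss <- -sum(log(pmax(P[cbind(seq_len(n), tgt)], 1e-12)))
    } else {
      ord <- sample.int(n)
      for (i in ord) {
        f <- backbone_forward(net, tile_to_tensor(train_tiles[[i]]),
                              train = TRUE)
        z <- linear_fw(head, f, train = TRUE)
        p <- softmax2(z)
        celoss <- celoss - log(max(p[tgt[i]], 1e-12))
        dz <- p
        dz[tgt[i]] <- dz[tgt[i]] - 1
        zero_grads(headnet)
        zero_grads(net)
        dfeat <- linear_bw(head, dz)
        adam_step(headnet, spec$learning_rate)
        backbone_backward(net, dfeat)
        adam_step(net, spec$learning_rate)
      }
    }
    acc <- NA_real_
    if (length(val_tiles) > 0) {
      pv <- if (head_only) featsv
            else t(vapply(val_tiles, function(tl)
              backbone_forward(net, tile_to_tensor(tl), train = FALSE),
              numeric(spec$feature_width)))
      pred <- apply(pv %*% t(head$W) +
                      matrix(head$b, nrow(pv), 2, byrow = TRUE), 1,
                    which.max)
      acc <- mean(pred == tgtv)
      if (acc > best_acc) {
        best_acc <- acc
        best <- list(head_W = head$W, head_b = head$b,
                     backbone = if (head_only) NULL else get_params(net))
        best_epoch <- ep
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_ce = celoss / n,
                             val_accuracy = acc)
  }
  if (is.null(best)) {
    best <- list(head_W = head$W, head_b = head$b,
                 backbone = if (head_only) NULL else get_params(net))
    best_epoch <- spec$epochs
    best_acc <- NA_real_
  }
  head$W <- best$head_W
  head$b <- best$head_b
  if (!is.null(best$backbone)) set_params(net, best$backbone)
  if (head_only) {
    # fold the feature standardization into the head so that
    # logits = raw_activations %*% t(W) + b downstream
    head$W <- sweep(head$W, 2, fsd, `/`)
    head$b <- head$b - drop(head$W %*% fmu)
  }
  structure(list(spec = spec, backbone = net, head = head,
                 history = do.call(rbind, hist), best_epoch = best_epoch,
                 best_val_accuracy = best_acc, seed = seed,
                 classes = c("normal", "cancer")),
            class = "psoct_classifier")
}

#' Penultimate-layer activations
#'
#' Runs each tile through the backbone and returns the 512-element
#' activation of the second-to-last layer (the global-average-pooled
#' feature vector feeding the fully connected head), one row per tile.
#' Deterministic in inference mode.
#'
#' @param classifier A [train_classifier()] result.
#' @param tiles List of 8-bit matrices.
#' @return `N x 512` matrix.
#' @export
extract_activations <- function(classifier, tiles) {
  t(vapply(tiles, function(tl)
    backbone_forward(classifier$backbone, tile_to_tensor(tl), train = FALSE),
    numeric(classifier$spec$feature_width)))
}

#' @export
#' @rdname train_classifier
#' @param object,newdata,type,... `predict` method arguments: `newdata`
#'   is a list of tiles; `type = "prob"` returns the cancer-class
#'   softmax probability used as the ROC score.
predict.psoct_classifier <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  acts <- extract_activations(object, newdata)
  z <- acts %*% t(object$head$W) +
    matrix(object$head$b, nrow(acts), 2, byrow = TRUE)
  pr <- t(apply(z, 1, softmax2))
  if (type == "prob") pr[, 2] else object$classes[apply(pr, 1, which.max)]
}

#' @export
print.psoct_classifier <- function(x, ...) {
  cat(sprintf("residual tile classifier (%s, %s, %s init): %d epochs\n",
              x$spec$backbone, x$spec$trainable_scope, x$spec$init,
              nrow(x$history)))
  if (!is.na(x$best_epoch))
    cat(sprintf("best validation accuracy %.3f at epoch %d\n",
                x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' Validation report on a test tile set
#'
#' Scores each test tile (softmax probability of the cancer class),
#' computes the ROC curve and AUC, extracts the 512-d penultimate
#' activations and optionally a 2-D t-SNE embedding of them.
#'
#' @param classifier A [train_classifier()] result.
#' @param tiles,labels Test tiles and their labels.
#' @param with_tsne Embed the activations with [tsne_embed()]?
#' @param tsne_seed,perplexity t-SNE parameters.
#' @return An object of class `validation_report` with `roc_points`,
#'   `auc`, `activations`, `tsne_embedding`, `per_item`.
#' @export
validation_report <- function(classifier, tiles, labels, with_tsne = FALSE,
                              tsne_seed = 1L, perplexity = 30) {
  acts <- extract_activations(classifier, tiles)
  z <- acts %*% t(classifier$head$W) +
    matrix(classifier$head$b, nrow(acts), 2, byrow = TRUE)
  pr <- t(apply(z, 1, softmax2))
  scores <- pr[, 2]
  lab <- as.character(labels)
  roc <- roc_and_auc(scores, lab == "cancer")
  pred <- ifelse(scores >= 0.5, "cancer", "normal")
  emb <- if (with_tsne)
    tsne_embed(acts, perplexity = perplexity, seed = tsne_seed) else NULL
  structure(list(roc_points = roc$roc_points, auc = roc$auc,
                 activations = acts, tsne_embedding = emb,
                 per_item = data.frame(score = scores, label = lab,
                                       correct = pred == lab)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation report: AUC %.4f | accuracy %.3f | %d items\n",
              x$auc, mean(x$per_item$correct), nrow(x$per_item)))
  invisible(x)
}

#' Compare real- and synthetic-trained classifiers
#'
#' Pairs two [validation_report()]s computed on the same test items and
#' summarizes their agreement: absolute AUC difference and per-item
#' agreement rate of the thresholded decisions.
#'
#' @param report_real,report_synthetic Validation reports sharing a test
#'   set (same items in the same order).
#' @return List with `auc_real`, `auc_synthetic`, `delta_auc`,
#'   `agreement`, and both ROC curves.
#' @export
compare_real_vs_synthetic <- function(report_real, report_synthetic) {
  if (nrow(report_real$per_item) != nrow(report_synthetic$per_item) ||
      !all(report_real$per_item$label == report_synthetic$per_item$label))
    stop("compare_real_vs_synthetic: reports are not on a common test set")
  agree <- mean((report_real$per_item$score >= 0.5) ==
                  (report_synthetic$per_item$score >= 0.5))
  structure(list(auc_real = report_real$auc,
                 auc_synthetic = report_synthetic$auc,
                 delta_auc = abs(report_real$auc - report_synthetic$auc),
                 agreement = agree,
                 roc_real = report_real$roc_points,
                 roc_synthetic = report_synthetic$roc_points),
            class = "psoct_comparison")
}

#' @export
print.psoct_comparison <- function(x, ...) {
  cat(sprintf("AUC real %.4f vs synthetic %.4f (|delta| = %.4f); ",
              x$auc_real, x$auc_synthetic, x$delta_auc))
  cat(sprintf("decision agreement %.3f\n", x$agreement))
  invisible(x)
}

#' @export
plot.psoct_comparison <- function(x, ...) {
  graphics::plot(x$roc_real$fpr, x$roc_real$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = "ROC: real- vs synthetic-trained")
  graphics::lines(x$roc_synthetic$fpr, x$roc_synthetic$tpr, lty = 2)
  graphics::abline(0, 1, col = "gray")
  graphics::legend("bottomright",
                   sprintf(c("real (AUC %.3f)", "synthetic (AUC %.3f)"),
                           c(x$auc_real, x$auc_synthetic)),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
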