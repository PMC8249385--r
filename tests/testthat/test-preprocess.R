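test_that("dark-margin cropping recovers the bright region exactly", {
  # constructed case: 10 all-zero columns on each side of a bright block
  img <- matrix(0, 30, 60)
  img[, 11:50] <- 1000
  out <- crop_dark_margins(img)
  expect_identical(dim(out), c(30L, 40L))

  # no sub-threshold margins: returned unchanged
  img2 <- matrix(500, 20, 20)
  expect_equal(unname(crop_dark_margins(img2)), img2, ignore_attr = TRUE)

  # randomized bright block against an exhaustive scan oracle
  set.seed(8)
  for (rep in 1:10) {
    H <- sample(20:40, 1); W <- sample(20:40, 1)
    img <- matrix(0, H, W)
    r <- sort(sample(H, 2)); c <- sort(sample(W, 2))
    img[r[1]:r[2], c[1]:c[2]] <- runif(1, 100, 1000)
    out <- crop_dark_margins(img, 0.02)
    thr <- 0.02 * max(img)
    rok <- which(sapply(seq_len(H), function(i) mean(img[i, ]) >= thr))
    cok <- which(sapply(seq_len(W), function(j) mean(img[, j]) >= thr))
    expect_identical(dim(out), c(length(min(rok):max(rok)),
                                 length(min(cok):max(cok))))
    expect_equal(unname(out), img[min(rok):max(rok), min(cok):max(cok)],
                 ignore_attr = TRUE)
  }
  expect_error(crop_dark_margins(matrix(0, 5, 5)), "empty result")
})

test_that("tiling geometry reproduces the 256x512 -> two 202x202 case", {
  img <- matrix(seq_len(256 * 512), 256, 512)
  tl <- split_into_tiles(img, 202L)
  expect_identical(dim(tl$left), c(202L, 202L))
  expect_identical(dim(tl$right), c(202L, 202L))

  # 202x404: exact halves, no row cropping
  img2 <- matrix(seq_len(202 * 404), 202, 404)
  tl2 <- split_into_tiles(img2, 202L)
  expect_equal(unname(tl2$left), img2[, 1:202], ignore_attr = TRUE)
  expect_equal(unname(tl2$right), img2[, 203:404], ignore_attr = TRUE)

  # pixel provenance on a ramp image: index-arithmetic oracle
  ramp <- outer(1:60, 1:100, function(i, j) 1000 * i + j)
  tl3 <- split_into_tiles(ramp, 40L)
  for (half in c("left", "right")) {
    off <- attr(tl3[[half]], "offsets")
    for (probe in list(c(1, 1), c(17, 23), c(40, 40))) {
      expect_identical(tl3[[half]][probe[1], probe[2]],
                       ramp[off["row0"] + probe[1], off["col0"] + probe[2]])
    }
  }
  # tiles never overlap: left columns end before right columns start
  offl <- attr(tl3$left, "offsets")
  offr <- attr(tl3$right, "offsets")
  expect_lte(offl["col0"] + 40, offr["col0"])

  expect_error(split_into_tiles(matrix(0, 100, 100), 202L), "too small")
})

test_that("16-to-8-bit conversion matches the scalar formula", {
  expect_true(all(convert_to_8bit(matrix(0, 4, 4)) == 0))
  expect_identical(convert_to_8bit(matrix(65535, 1, 1))[1, 1], 255)
  set.seed(10)
  img <- matrix(sample(0:65535, 400, replace = TRUE), 20, 20)
  expect_identical(convert_to_8bit(img), floor(img / 257 + 0.5))
  # monotone non-decreasing
  v <- sort(sample(0:65535, 100))
  cv <- convert_to_8bit(matrix(v, 1))
  expect_true(all(diff(as.numeric(cv)) >= 0))
})

test_that("tile manifests double the frame count per channel", {
  man <- data.frame(frame_id = paste0("f", 1:7),
                    case_id = rep(c("a", "b"), length.out = 7),
                    label = rep(c("cancer", "normal"), length.out = 7))
  tm <- tile_manifest(man)
  expect_identical(nrow(tm), 14L)
  expect_identical(sum(tm$half == "left"), 7L)
  expect_true(!anyDuplicated(tm$tile_id))
})

test_that("image-based splits give floor(N/10) test and validation tiles", {
  man <- data.frame(frame_id = paste0("f", seq_len(22072)),
                    case_id = "c1", label = "cancer")
  tm <- tile_manifest(man)
  expect_identical(nrow(tm), 44144L)    # two tiles per frame
  sp <- assign_splits(tm, strategy = "image_based", seed = 1)
  expect_identical(sum(sp$partition == "test"), 4414L)
  expect_identical(sum(sp$partition == "validation"), 4414L)
  expect_identical(sum(sp$partition == "train"), 44144L - 2L * 4414L)

  # N = 10 -> 8/1/1
  sp10 <- assign_splits(tm[1:10, ], strategy = "image_based", seed = 1)
  expect_identical(as.integer(table(sp10$partition)), c(8L, 1L, 1L))

  # disjoint and exhaustive for random N
  set.seed(4)
  for (N in sample(10:5000, 5)) {
    spn <- assign_splits(tm[seq_len(N), ], strategy = "image_based", seed = N)
    expect_identical(sum(as.integer(table(spn$partition))), N)
    expect_false(anyNA(spn$partition))
  }

  # determinism
  a <- assign_splits(tm[1:200, ], strategy = "image_based", seed = 33)
  b <- assign_splits(tm[1:200, ], strategy = "image_based", seed = 33)
  expect_identical(a$partition, b$partition)
  expect_error(assign_splits(tm, ratio = c(7, 2, 1)), "8:1:1")
})

test_that("case-based splits hold out one case per class", {
  man <- expand.grid(idx = 1:10, case = 1:4, label = c("cancer", "normal"),
                     stringsAsFactors = FALSE)
  man$frame_id <- sprintf("%s_c%d_f%d", man$label, man$case, man$idx)
  man$case_id <- sprintf("%s_case%d", man$label, man$case)
  tm <- tile_manifest(man[, c("frame_id", "case_id", "label")])
  sp <- assign_splits(tm, strategy = "case_based", seed = 2)
  for (lab in c("cancer", "normal")) {
    held <- unique(sp$case_id[sp$label == lab & sp$partition != "train"])
    expect_length(held, 1L)                    # one held-out case per class
    idx <- sp$case_id == held
    expect_identical(sum(sp$partition[idx] == "test"), 10L)
    expect_identical(sum(sp$partition[idx] == "validation"), 10L)
    expect_true(all(sp$partition[sp$label == lab & !idx] == "train"))
  }
  expect_error(assign_splits(tm[tm$case_id == tm$case_id[1], ],
                             strategy = "case_based", seed = 1), ">= 2 cases")
})

test_that("preprocessing keeps channel tiles paired within a partition", {
  ds <- generate_dataset(small_config(), n_frames_per_class = 5L,
                         n_cases_per_class = 2L, seed = 12)
  pp <- preprocess_dataset(ds, tile_side = 32L)
  expect_identical(nrow(pp$manifest), 2L * nrow(ds$manifest))
  for (ch in names(pp$tiles)) {
    expect_identical(names(pp$tiles[[ch]]), pp$manifest$tile_id)
    expect_true(all(vapply(pp$tiles[[ch]], function(t)
      all(dim(t) == c(32L, 32L)) && min(t) >= 0 && max(t) <= 255, TRUE)))
  }
  # channels are indexed by one manifest, so a partition assignment
  # automatically applies to all three channels of a frame-half
  sp <- assign_splits(pp$manifest, strategy = "image_based", seed = 3)
  expect_identical(sp$tile_id, names(pp$tiles$dopu))
})
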