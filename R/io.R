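#' Read or write a grayscale image
#'
#' 16-bit TIFF for raw channels and 8-bit PNG for tiles/overlays, both
#' lossless. Values are handled on their integer scales (`[0, 65535]`
#' and `[0, 255]`); float-valued contrasts are stored after scaling by
#' the factors recorded in the dataset manifest.
#'
#' @param path File path (`.tif`/`.tiff` or `.png`).
#' @param image Matrix of integer values on the scale given by
#'   `bit_depth` (writing), or missing (reading).
#' @param bit_depth 16 (TIFF) or 8 (PNG).
#' @return The image matrix (invisibly on write).
#' @export
write_image <- function(path, image, bit_depth = 16L) {
  if (bit_depth == 16L) {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
      stop("write_image: 16-bit images are written as TIFF: ", path)
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  } else if (bit_depth == 8L) {
    if (!grepl("\\.png$", path, ignore.case = TRUE))
      stop("write_image: 8-bit images are written as PNG: ", path)
    png::writePNG(image / 255, path)
  } else stop("write_image: unsupported bit depth ", bit_depth)
  invisible(image)
}

#' @rdname write_image
#' @export
read_image <- function(path, bit_depth = 16L) {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  if (bit_depth == 16L) {
    round(tiff::readTIFF(path) * 65535)
  } else if (bit_depth == 8L) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 255)
  } else stop("read_image: unsupported bit depth ", bit_depth)
}

# channel scale factors: DOPU in [0,1], retardation in [0, pi/2]
channel_scale <- c(intensity = 1, dopu = 65535, retardation = 65535 / (pi / 2))

#' Write a phantom dataset to disk
#'
#' Each frame becomes three 16-bit TIFFs (intensity raw; DOPU and
#' retardation scaled to the 16-bit range by the factors recorded in the
#' manifest), indexed by a CSV manifest with frame id, case id, label,
#' file paths and scale factors.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  for (ch in c("intensity", "dopu", "retardation"))
    man[[paste0(ch, "_path")]] <- file.path(
      dir, paste0(man$frame_id, "_", ch, ".tif"))
  man$dopu_scale <- channel_scale[["dopu"]]
  man$retardation_scale <- channel_scale[["retardation"]]
  for (i in seq_len(nrow(man))) {
    fr <- dataset$frames[[man$frame_id[i]]]
    write_image(man$intensity_path[i], fr$intensity, 16L)
    write_image(man$dopu_path[i], round(fr$dopu * man$dopu_scale[i]), 16L)
    write_image(man$retardation_path[i],
                round(fr$retardation * man$retardation_scale[i]), 16L)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("read_dataset: no manifest at ", mpath)
  man <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  frames <- list()
  for (i in seq_len(nrow(man))) {
    frames[[man$frame_id[i]]] <- structure(list(
      intensity = read_image(man$intensity_path[i], 16L),
      dopu = read_image(man$dopu_path[i], 16L) / man$dopu_scale[i],
      retardation = read_image(man$retardation_path[i], 16L) /
        man$retardation_scale[i],
      label = man$label[i], case_id = man$case_id[i],
      frame_id = man$frame_id[i]), class = "tissue_frame")
  }
  structure(list(frames = frames,
                 manifest = man[, c("frame_id", "case_id", "label")]),
            class = "phantom_dataset")
}

#' Pipeline run configuration
#'
#' Nested stage configuration for [run_pipeline()], serializable to YAML
#' without loss. The defaults describe a small desk-scale run.
#'
#' @param global_seed Master seed; per-stage seeds are derived from it
#'   deterministically (see [derive_seed()]).
#' @param output_root Artifact directory.
#' @param phantom,preprocess,gan,evaluate,validate Per-stage option
#'   lists; omitted entries keep their defaults.
#' @export
run_config <- function(global_seed = 1L, output_root = "polsynth_run",
                       phantom = list(), preprocess = list(),
                       gan = list(), evaluate = list(), validate = list()) {
  defaults <- list(
    global_seed = as.integer(global_seed),
    output_root = output_root,
    phantom = list(image_height = 40L, image_width = 72L,
                   n_frames_per_class = 30L, n_cases_per_class = 3L),
    preprocess = list(tile_side = 32L, split_strategy = "image_based"),
    gan = list(depth = 3L, base_channels = 12L, epochs = 8L,
               learning_rate = 1e-3, lambda_adv = 1, lambda_l1 = 100,
               lambda_ssim = 2550),
    evaluate = list(threshold = 10),
    validate = list(epochs = 12L, contrast = "dopu"))
  for (st in c("phantom", "preprocess", "gan", "evaluate", "validate")) {
    ov <- get(st)
    defaults[[st]][names(ov)] <- ov
  }
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`; `path` a YAML file path.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(list(global_seed = raw$global_seed,
                             output_root = raw$output_root),
                        raw[c("phantom", "preprocess", "gan", "evaluate",
                              "validate")]))
}

#' Derive a per-stage seed from the global seed
#'
#' Deterministic fan-out so every pipeline stage is independently
#' reproducible: the stage name is hashed onto a 31-bit integer and
#' mixed with the global seed.
#'
#' @param global_seed Integer master seed.
#' @param stage Stage name (string).
#' @return A positive integer below `2^31`.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 48271 + h * 16807) %% 2147483647) + 1L
}
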