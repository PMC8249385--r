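#' Run the full computational PS-OCT pipeline
#'
#' End-to-end orchestration: simulate phantom frames, condition and
#' partition them, train one contrast-synthesis GAN per contrast,
#' synthesize the test tiles, evaluate masked SSIM, train cancer/normal
#' classifiers on the real and the synthetic contrast tiles, compare
#' their ROC/AUC, and embed the penultimate activations with t-SNE.
#' Every artifact is written under `config$output_root` together with
#' the configuration and derived seeds; with `resume = TRUE`, stages
#' whose artifacts already exist are reloaded instead of recomputed.
#'
#' @param config A [run_config()].
#' @param resume Reuse existing stage artifacts?
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the evaluation reports, the classifier
#'   comparison, and the artifact directory.
#' @export
run_pipeline <- function(config = run_config(), resume = TRUE,
                         quiet = FALSE) {
  root <- config$output_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(root, "run_config.yaml"))
  say <- function(...) if (!quiet) message("[polsynth] ", ...)
  stage <- function(name, artifact, loader, builder) {
    path <- file.path(root, artifact)
    if (resume && file.exists(path)) {
      say("stage ", name, ": reusing ", artifact)
      return(loader(path))
    }
    say("stage ", name)
    out <- tryCatch(builder(path), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    out
  }

  ph <- config$phantom
  dataset <- stage("simulate", "phantom/manifest.csv",
    function(p) read_dataset(dirname(p)),
    function(p) {
      cfg <- phantom_config(image_height = ph$image_height,
                            image_width = ph$image_width,
                            rng_seed = derive_seed(config$global_seed,
                                                   "simulate"))
      ds <- generate_dataset(cfg, ph$n_frames_per_class,
                             ph$n_cases_per_class)
      write_dataset(ds, dirname(p))
      ds
    })

  pp <- config$preprocess
  prep <- stage("preprocess", "preprocess/tiles.rds",
    function(p) readRDS(p),
    function(p) {
      dir.create(dirname(p), showWarnings = FALSE)
      out <- preprocess_dataset(dataset, tile_side = pp$tile_side)
      out$splits <- assign_splits(out$manifest,
                                  strategy = pp$split_strategy,
                                  seed = derive_seed(config$global_seed,
                                                     "preprocess"))
      utils::write.csv(out$splits, file.path(dirname(p), "splits.csv"),
                       row.names = FALSE)
      saveRDS(out, p)
      out
    })

  gcfg <- config$gan
  make_pairs <- function(contrast, part) {
    ids <- prep$splits$tile_id[prep$splits$partition == part]
    lapply(ids, function(id)
      list(input = prep$tiles$intensity[[id]],
           target = prep$tiles[[contrast]][[id]]))
  }
  bundles <- list()
  for (contrast in c("dopu", "retardation")) {
    bundles[[contrast]] <- stage(
      paste0("train-gan-", contrast),
      paste0("gan/", contrast, "_bundle.rds"),
      function(p) readRDS(p),
      function(p) {
        dir.create(dirname(p), showWarnings = FALSE)
        b <- train_gan(
          make_pairs(contrast, "train"), make_pairs(contrast, "validation"),
          gen_spec = generator_spec(depth = gcfg$depth,
                                    base_channels = gcfg$base_channels),
          weights = loss_weights(gcfg$lambda_adv, gcfg$lambda_l1,
                                 gcfg$lambda_ssim),
          config = train_config(learning_rate = gcfg$learning_rate,
                                epochs = gcfg$epochs,
                                seed = derive_seed(config$global_seed,
                                                   paste0("gan_", contrast)),
                                contrast_target = contrast),
          mask_threshold = config$evaluate$threshold)
        saveRDS(b, p)
        b
      })
  }

  test_ids <- prep$splits$tile_id[prep$splits$partition == "test"]
  synth <- stage("synthesize", "synthesize/synthetic.rds",
    function(p) readRDS(p),
    function(p) {
      dir.create(dirname(p), showWarnings = FALSE)
      out <- lapply(c(dopu = "dopu", retardation = "retardation"),
                    function(ct) {
        tl <- lapply(test_ids, function(id)
          synthesize(bundles[[ct]], prep$tiles$intensity[[id]]))
        names(tl) <- test_ids
        tl
      })
      saveRDS(out, p)
      out
    })

  reports <- stage("evaluate", "evaluate/eval_reports.json",
    function(p) jsonlite::read_json(p, simplifyVector = TRUE),
    function(p) {
      dir.create(dirname(p), showWarnings = FALSE)
      rep <- lapply(c(dopu = "dopu", retardation = "retardation"),
                    function(ct) {
        r <- evaluate_dataset(prep$tiles[[ct]][test_ids], synth[[ct]],
                              prep$tiles$intensity[test_ids],
                              threshold = config$evaluate$threshold,
                              contrast = ct)
        r[c("mean", "std", "n_tiles", "threshold", "contrast")]
      })
      jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
      rep
    })

  vcfg <- config$validate
  comparison <- stage("validate", "validate/comparison.json",
    function(p) jsonlite::read_json(p, simplifyVector = TRUE),
    function(p) {
      dir.create(dirname(p), showWarnings = FALSE)
      ct <- vcfg$contrast
      labels <- prep$splits$label[match(test_ids, prep$splits$tile_id)]
      spl <- split_for_classifier(length(test_ids),
                                  seed = derive_seed(config$global_seed,
                                                     "validate"))
      spec <- classifier_spec(epochs = vcfg$epochs)
      cseed <- derive_seed(config$global_seed, "classifier")
      real_tiles <- prep$tiles[[ct]][test_ids]
      syn_tiles <- synth[[ct]]
      fit_and_report <- function(tiles) {
        clf <- train_classifier(tiles[spl$train], labels[spl$train],
                                tiles[spl$validation], labels[spl$validation],
                                spec = spec, seed = cseed)
        validation_report(clf, tiles[spl$test], labels[spl$test])
      }
      rep_real <- fit_and_report(real_tiles)
      rep_syn <- fit_and_report(syn_tiles)
      cmp <- compare_real_vs_synthetic(rep_real, rep_syn)
      npt <- nrow(rep_real$activations)
      emb <- tsne_embed(rep_real$activations,
                        perplexity = min(30, max(2, floor((npt - 1) / 3))),
                        seed = derive_seed(config$global_seed, "tsne"))
      utils::write.csv(
        data.frame(tsne1 = emb[, 1], tsne2 = emb[, 2],
                   label = labels[spl$test]),
        file.path(dirname(p), "tsne_real.csv"), row.names = FALSE)
      out <- cmp[c("auc_real", "auc_synthetic", "delta_auc", "agreement")]
      jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA)
      out
    })

  invisible(list(eval_reports = reports, comparison = comparison,
                 output_root = root))
}
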