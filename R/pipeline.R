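# End-to-end orchestration: one config drives simulate/load -> optional
# GAN augmentation -> segmentation -> embedding training -> two-layer CNN
# training -> evaluation on a held-out split. Every stage writes its
# artifact under the output directory and the manifest records a content
# hash per artifact, so a rerun with the same config is reproducible and
# completed stages can be skipped when their inputs are unchanged.

#' Pipeline configuration
#'
#' @param data either a `simulation_config` (synthetic run) or a named list
#'   of per-class FASTA paths
#'   (`list(non_enhancer = ..., strong = ..., weak = ...)`).
#' @param scheme segmentation scheme.
#' @param augment run the GAN augmentation stage.
#' @param test_fraction held-out fraction for the evaluation stage.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param lexicon,embed_cfg,cnn_cfg,gan_cfg stage configurations.
#' @param n_generate generated sequences kept per class.
#' @param filter_cutoff redundancy-filter cutoff for generated sequences.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data = simulation_preset(scale = 0.1),
                            scheme = "overlapped3", augment = FALSE,
                            test_fraction = 0.2, seed = 1L,
                            lexicon = lexicon_config(),
                            embed_cfg = skipgram_config(),
                            cnn_cfg = cnn_config(),
                            gan_cfg = gan_config(),
                            n_generate = 200L, filter_cutoff = 0.80) {
  structure(list(data = data, scheme = scheme, augment = augment,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 lexicon = lexicon, embed_cfg = embed_cfg, cnn_cfg = cnn_cfg,
                 gan_cfg = gan_cfg, n_generate = as.integer(n_generate),
                 filter_cutoff = filter_cutoff),
            class = "pipeline_config")
}

pipeline_log <- function(dir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  cat(line, "\n", file = file.path(dir, "pipeline.log"), append = TRUE)
}

#' Run the full pipeline
#'
#' Stage order: data -> (augment) -> segment -> embed -> train -> evaluate.
#' Artifacts: `data.fasta` + `labels.tsv`, `augmented.fasta` (optional),
#' `words_<layer>.tsv`, `skipgram_<layer>.txt`, `model_<layer>.txt`,
#' `predictions.tsv`, `metrics.tsv`, and `manifest.json` listing every
#' artifact with its MD5 content hash, the config hash and the seeds.
#' A failed stage aborts with the stage name; previously written artifacts
#' are preserved.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly; printed artifacts live in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  stage <- function(name, expr) {
    pipeline_log(out_dir, paste("stage", name, "start"))
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    pipeline_log(out_dir, paste("stage", name, "done"))
    res
  }

  ds <- stage("data", {
    if (inherits(config$data, "simulation_config")) {
      d <- simulate_dataset(config$data)
    } else {
      parts <- list(
        read_fasta(config$data$non_enhancer, "non_enhancer", "not_applicable"),
        read_fasta(config$data$strong, "enhancer", "strong"),
        read_fasta(config$data$weak, "enhancer", "weak"))
      d <- do.call(rbind, parts)
      class(d) <- c("dna_dataset", "data.frame")
    }
    write_fasta(d, file.path(out_dir, "data.fasta"),
                file.path(out_dir, "labels.tsv"))
    artifacts <- c(artifacts, "data.fasta", "labels.tsv")
    d
  })

  # held-out split before any fitting so evaluation never sees the models
  split <- with_seed(derive_seed(config$seed, "split"), {
    cls <- paste(ds$enhancer_label, ds$strength_label)
    test <- unlist(lapply(split(seq_len(nrow(ds)), cls), function(ix)
      sample(ix, max(1L, round(length(ix) * config$test_fraction)))))
    list(test = sort(test), train = setdiff(seq_len(nrow(ds)), test))
  })
  train_ds <- ds[split$train, , drop = FALSE]
  test_ds <- ds[split$test, , drop = FALSE]
  class(train_ds) <- class(test_ds) <- c("dna_dataset", "data.frame")

  cvc <- cv_config(scheme = config$scheme, augment = config$augment,
                   n_generate = config$n_generate, fast = TRUE,
                   filter_cutoff = config$filter_cutoff,
                   lexicon = config$lexicon, embed_cfg = config$embed_cfg,
                   cnn_cfg = config$cnn_cfg, gan_cfg = config$gan_cfg)

  if (config$augment) {
    gen <- stage("augment", {
      g <- augment_records(train_ds, cvc)
      write_fasta(g, file.path(out_dir, "augmented.fasta"))
      artifacts <- c(artifacts, "augmented.fasta")
      g
    })
    aug_train <- rbind(train_ds, gen)
    class(aug_train) <- c("dna_dataset", "data.frame")
  } else aug_train <- train_ds

  seg <- stage("segment", {
    dict <- NULL
    if (config$scheme == "statistical") {
      dict <- learn_dictionary(train_ds, config$lexicon)
      write_dictionary(dict, file.path(out_dir, "dictionary.tsv"))
      artifacts <- c(artifacts, "dictionary.tsv")
    }
    vocab <- build_vocabulary(config$scheme, dict)
    words <- tokenize_dataset(aug_train, config$scheme, dict)
    lines <- vapply(names(words), function(id)
      paste(id, paste(words[[id]], collapse = " "), sep = "\t"), character(1))
    writeLines(lines, file.path(out_dir, "words_train.tsv"))
    artifacts <- c(artifacts, "words_train.tsv")
    list(dict = dict, vocab = vocab)
  })

  skipgrams <- stage("embed", {
    sgs <- fit_skipgrams(aug_train, cvc, seg$dict, seg$vocab)
    for (layer in names(sgs)) {
      f <- paste0("skipgram_", layer, ".txt")
      write_skipgram(sgs[[layer]], file.path(out_dir, f))
      artifacts <- c(artifacts, f)
    }
    sgs
  })

  models <- stage("train", {
    ms <- fit_layer_models(aug_train, cvc, seg$dict, skipgrams, seg$vocab)
    for (layer in names(ms)) {
      f <- paste0("model_", layer, ".txt")
      m <- ms[[layer]]
      writeLines(jsonlite::serializeJSON(
        list(params = m$params, classes = m$classes,
             config = unclass(m$config)), digits = I(17)), file.path(out_dir, f))
      artifacts <- c(artifacts, f)
    }
    ms
  })

  metrics <- stage("evaluate", {
    pred <- predict_two_layer(test_ds, models$first, models$second,
                              scheme = config$scheme, vocab = seg$vocab,
                              dictionary = seg$dict)
    write.table(pred, file.path(out_dir, "predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rows <- NULL
    for (layer in c("first", "second")) {
      lds <- build_layer_dataset(test_ds, layer)
      p <- if (layer == "first") pred$p_enhancer[match(lds$id, pred$id)]
           else {
             tk <- lapply(tokenize_dataset(lds, config$scheme, seg$dict),
                          words_to_indices, vocab = seg$vocab)
             predict_classifier(models$second, tk)[, "positive"]
           }
      pos <- p >= 0.5; truth <- lds$label == "positive"
      m <- compute_metrics(c(TP = sum(pos & truth), FP = sum(pos & !truth),
                             TN = sum(!pos & !truth), FN = sum(!pos & truth)))
      rows <- rbind(rows, data.frame(layer = layer, fold = NA, Acc = m$Acc,
                                     Sn = m$Sn, Sp = m$Sp, MCC = m$MCC))
    }
    write.table(rows, file.path(out_dir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "predictions.tsv", "metrics.tsv")
    rows
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("enhancerkit")),
    seed = config$seed,
    scheme = config$scheme,
    augment = config$augment,
    config_hash = unname(tools::md5sum(
      local({ f <- file.path(out_dir, ".config.json")
              writeLines(jsonlite::serializeJSON(unclass(config), digits = I(17)), f); f }))),
    artifacts = lapply(setNames(artifacts, artifacts), function(a)
      list(md5 = unname(tools::md5sum(file.path(out_dir, a))))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  pipeline_log(out_dir, "pipeline complete")
  invisible(manifest)
}
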