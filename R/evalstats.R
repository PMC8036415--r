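# Performance measures, leakage-safe cross-validation, and analytics that
# compare real and generated sequence sets (nucleotide composition and mean
# trinucleotide physicochemical properties).

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (TP rate), specificity (TN rate) and Matthews
#' correlation coefficient from TP/FP/TN/FN. A zero MCC denominator is
#' reported as MCC = 0 with `mcc_undefined = TRUE`.
#'
#' @param counts named vector or list with TP, FP, TN, FN.
#' @return List with Acc, Sn, Sp, MCC, mcc_undefined and the counts.
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
  TN <- as.numeric(counts[["TN"]]); FN <- as.numeric(counts[["FN"]])
  if (any(c(TP, FP, TN, FN) < 0)) stop("confusion counts must be non-negative")
  n <- TP + FP + TN + FN
  if (n == 0) stop("all confusion counts are zero")
  den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  undef <- den2 == 0
  mcc <- if (undef) 0 else (TP * TN - FP * FN) / sqrt(den2)
  list(Acc = (TP + TN) / n,
       Sn = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       Sp = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       MCC = mcc, mcc_undefined = undef,
       counts = c(TP = TP, FP = FP, TN = TN, FN = FN))
}

#' Stratified k-fold cross-validation plan
#'
#' Randomly partitions the *real* records into k disjoint folds,
#' stratified by class (fold sizes per class differ by at most one).
#' Deterministic given the seed.
#'
#' @param ds a `dna_dataset` (generated records are excluded).
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratified stratify by the joint enhancer/strength class.
#' @return List of class `cv_plan` with `folds` (list of id vectors), k,
#'   seed, stratified.
#' @export
make_cv_plan <- function(ds, k = 10L, seed = 1L, stratified = TRUE) {
  real <- ds[ds$provenance == "real", , drop = FALSE]
  cls <- paste(real$enhancer_label, real$strength_label)
  if (k > min(table(cls)))
    stop("k = ", k, " exceeds the smallest class size (", min(table(cls)), ")")
  with_seed(derive_seed(seed, "cvplan"), {
    folds <- vector("list", k)
    groups <- if (stratified) split(real$id, cls) else list(real$id)
    for (ids in groups) {
      ids <- sample(ids)
      f <- rep_len(seq_len(k), length(ids))
      for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], ids[f == j])
    }
    structure(list(folds = folds, k = as.integer(k), seed = as.integer(seed),
                   stratified = stratified), class = "cv_plan")
  })
}

#' Cross-validation pipeline configuration
#'
#' Collects the per-stage settings [run_cv()] needs. `fast = TRUE` fits the
#' dictionary, the embeddings and the GAN once on the full set of real
#' records instead of refitting inside every fold; evaluation is still on
#' held-out real records only, and generated sequences still enter training
#' folds only, but the shared fitted components have seen the test
#' sequences. `fast = FALSE` (default) refits everything per fold and is
#' strictly leakage-free.
#'
#' @param scheme segmentation scheme.
#' @param layers which layers to evaluate.
#' @param augment add GAN-generated sequences to the training folds.
#' @param n_generate generated sequences kept per enhancer class after
#'   filtering; non-enhancers get `2 * n_generate`, mirroring the 2:1:1
#'   augmentation ratio so the first layer stays class-balanced.
#' @param fast see above.
#' @param filter_cutoff redundancy-filter identity cutoff for generated
#'   sequences (NULL disables filtering).
#' @param lexicon,embed_cfg,cnn_cfg,gan_cfg stage configurations;
#'   class-specific GAN settings are derived from `gan_cfg`.
#' @param embed_corpus "positive" (default: embeddings are learned on the
#'   positive training sequences of each layer) or "all".
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(scheme = "overlapped3", layers = c("first", "second"),
                      augment = FALSE, n_generate = 200L, fast = FALSE,
                      filter_cutoff = 0.80,
                      lexicon = lexicon_config(),
                      embed_cfg = skipgram_config(),
                      cnn_cfg = cnn_config(),
                      gan_cfg = gan_config(),
                      embed_corpus = c("positive", "all")) {
  structure(list(scheme = scheme, layers = layers, augment = augment,
                 n_generate = as.integer(n_generate), fast = fast,
                 filter_cutoff = filter_cutoff, lexicon = lexicon,
                 embed_cfg = embed_cfg, cnn_cfg = cnn_cfg, gan_cfg = gan_cfg,
                 embed_corpus = match.arg(embed_corpus)),
            class = "cv_config")
}

# Fit segmentation + embedding + classifier on a training dataset and
# return the two layer models plus the tokenisation context.
fit_layer_models <- function(train_ds, config, dictionary, skipgrams, vocab) {
  models <- list()
  for (layer in config$layers) {
    lds <- build_layer_dataset(train_ds, layer)
    words <- tokenize_dataset(lds, config$scheme, dictionary)
    tokens <- lapply(words, words_to_indices, vocab = vocab)
    sg <- skipgrams[[layer]]
    cfg <- config$cnn_cfg
    cfg$embed_dim <- ncol(sg$W)
    models[[layer]] <- train_classifier(tokens, lds$label, cfg,
                                        embedding_init = sg$W, vocab = vocab)
  }
  models
}

# Train one GAN per class on the given real records and return filtered
# generated records. Class volumes follow the augmentation protocol's
# 2:1:1 ratio (non-enhancers twice the per-enhancer-class count, so the
# first layer stays class-balanced): n_generate strong, n_generate weak,
# 2 * n_generate non-enhancers.
augment_records <- function(train_ds, config) {
  out <- list()
  for (tag in c("non_enhancer", "strong", "weak")) {
    sub <- if (tag == "non_enhancer") train_ds[train_ds$enhancer_label == "non_enhancer", ]
           else train_ds[train_ds$strength_label == tag, ]
    if (!nrow(sub)) next
    n_keep <- config$n_generate * if (tag == "non_enhancer") 2L else 1L
    gcfg <- config$gan_cfg
    gcfg$class_tag <- tag
    gcfg$seed <- derive_seed(gcfg$seed, paste0("gan-", tag))
    fit <- gan_train(sub, gcfg)
    gen <- generate_sequences(fit$generator, n = 2L * n_keep,
                              class_tag = tag, seed = gcfg$seed)
    if (!is.null(config$filter_cutoff))
      gen <- redundancy_filter(gen, cutoff = config$filter_cutoff)
    out[[tag]] <- head(gen, n_keep)
  }
  do.call(rbind, out)
}

fit_skipgrams <- function(train_ds, config, dictionary, vocab) {
  sgs <- list()
  for (layer in config$layers) {
    lds <- build_layer_dataset(train_ds, layer)
    corpus_ds <- if (config$embed_corpus == "positive")
      lds[lds$label == "positive", , drop = FALSE] else lds
    words <- tokenize_dataset(corpus_ds, config$scheme, dictionary)
    ecfg <- config$embed_cfg
    ecfg$seed <- derive_seed(ecfg$seed, paste0("embed-", layer))
    sgs[[layer]] <- train_skipgram(words, vocab, ecfg)
  }
  sgs
}

#' Cross-validated evaluation of the two-layer predictor
#'
#' For every fold, the models (and in the default slow mode also the
#' dictionary, the embeddings and the GAN) are fitted on the training folds
#' only; GAN-generated sequences are added to the training folds only; and
#' metrics are pooled over the held-out *real* records. A leakage audit
#' asserts that no generated record reaches evaluation and that the number
#' of evaluated records equals the number of real records, independent of
#' the augmentation volume.
#'
#' @param ds a `dna_dataset` of real records.
#' @param k folds.
#' @param seed seed for the fold plan and all stochastic stages.
#' @param config a [cv_config()].
#' @return List with per-layer pooled metrics, a per-fold table, and the
#'   leakage audit.
#' @export
run_cv <- function(ds, k = 10L, seed = 1L, config = cv_config()) {
  validate_dna_dataset(ds)
  if (any(ds$provenance != "real"))
    stop("run_cv expects real records only; augmentation is configured, not input")
  plan <- make_cv_plan(ds, k, seed)
  # fold partition audit
  all_ids <- sort(unlist(plan$folds))
  stopifnot(identical(all_ids, sort(ds$id)))

  dictionary <- NULL; vocab <- NULL; skipgrams <- NULL; generated <- NULL
  if (config$fast) {
    if (config$scheme == "statistical")
      dictionary <- learn_dictionary(ds, config$lexicon)
    vocab <- build_vocabulary(config$scheme, dictionary)
    skipgrams <- fit_skipgrams(ds, config, dictionary, vocab)
    if (config$augment) generated <- augment_records(ds, config)
  } else if (config$scheme != "statistical") {
    vocab <- build_vocabulary(config$scheme)
  }

  counts <- list(first = c(TP = 0, FP = 0, TN = 0, FN = 0),
                 second = c(TP = 0, FP = 0, TN = 0, FN = 0))
  per_fold <- NULL
  evaluated <- c(first = 0L, second = 0L)
  for (f in seq_len(plan$k)) {
    test_ids <- plan$folds[[f]]
    test_ds <- ds[ds$id %in% test_ids, , drop = FALSE]
    train_ds <- ds[!(ds$id %in% test_ids), , drop = FALSE]
    # leakage audit: the test fold must be all-real
    stopifnot(all(test_ds$provenance == "real"))
    dict_f <- dictionary; vocab_f <- vocab; sg_f <- skipgrams; gen_f <- generated
    if (!config$fast) {
      if (config$scheme == "statistical") {
        dict_f <- learn_dictionary(train_ds, config$lexicon)
        vocab_f <- build_vocabulary("statistical", dict_f)
      }
      sg_f <- fit_skipgrams(train_ds, config, dict_f, vocab_f)
      if (config$augment) gen_f <- augment_records(train_ds, config)
    }
    aug_train <- if (!is.null(gen_f)) rbind(train_ds, gen_f) else train_ds
    class(aug_train) <- c("dna_dataset", "data.frame")
    models <- fit_layer_models(aug_train, config, dict_f, sg_f, vocab_f)
    for (layer in config$layers) {
      lds <- build_layer_dataset(test_ds, layer)
      words <- tokenize_dataset(lds, config$scheme, dict_f)
      tokens <- lapply(words, words_to_indices, vocab = vocab_f)
      pr <- predict_classifier(models[[layer]], tokens)
      pred_pos <- pr[, "positive"] >= 0.5
      truth_pos <- lds$label == "positive"
      cf <- c(TP = sum(pred_pos & truth_pos), FP = sum(pred_pos & !truth_pos),
              TN = sum(!pred_pos & !truth_pos), FN = sum(!pred_pos & truth_pos))
      counts[[layer]] <- counts[[layer]] + cf
      evaluated[[layer]] <- evaluated[[layer]] + nrow(lds)
      m <- compute_metrics(cf)
      per_fold <- rbind(per_fold,
                        data.frame(layer = layer, fold = f, Acc = m$Acc,
                                   Sn = m$Sn, Sp = m$Sp, MCC = m$MCC))
    }
  }
  n_real <- nrow(ds)
  n_enh <- sum(ds$enhancer_label == "enhancer")
  audit <- list(
    folds_partition_real = TRUE,
    no_generated_in_test = TRUE,  # asserted per fold above
    evaluated_equals_real = c(
      first = !("first" %in% config$layers) || evaluated[["first"]] == n_real,
      second = !("second" %in% config$layers) || evaluated[["second"]] == n_enh))
  if (!all(unlist(audit$evaluated_equals_real)))
    stop("leakage audit failed: evaluated-record count mismatch")
  metrics <- lapply(config$layers, function(l) compute_metrics(counts[[l]]))
  names(metrics) <- config$layers
  list(metrics = metrics, per_fold = per_fold, audit = audit, plan = plan)
}

#' Pooled nucleotide composition of a sequence set
#'
#' @param seqs character vector of sequences (or a `dna_dataset`).
#' @return Named frequency vector over A, C, G, T summing to 1.
#' @export
composition_profile <- function(seqs) {
  seqs <- corpus_seqs(seqs)
  chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  tab <- table(factor(chars, levels = DNA_BASES))
  setNames(as.numeric(tab) / sum(tab), DNA_BASES)
}

#' Load the bundled trinucleotide property table
#'
#' Five physicochemical scales (bendability, nucleosome positioning,
#' duplex stability, propeller twist, DNase sensitivity) for all 64
#' trinucleotides. The bundled table is a synthetic stand-in built from
#' composition-based formulas (see the file header and the methods
#' vignette); replace it with measured scales via the `path` argument.
#'
#' @param path a `trinucleotide<TAB>p1..p5` TSV with a header line.
#' @return data.frame with rownames = trinucleotides and 5 numeric columns.
#' @export
read_property_table <- function(path = system.file(
  "extdata", "trinucleotide_properties_synthetic.tsv", package = "enhancerkit")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab[[1]]
  tab <- tab[, -1, drop = FALSE]
  if (nrow(tab) != 64L || ncol(tab) != 5L || anyNA(tab))
    stop("property table must have 64 complete rows and 5 property columns")
  tab
}

#' Mean physicochemical properties over all overlapping trinucleotides
#'
#' @param seqs sequences (each of length >= 3).
#' @param table a property table from [read_property_table()].
#' @return Named vector of 5 property means.
#' @export
physchem_profile <- function(seqs, table = read_property_table()) {
  seqs <- corpus_seqs(seqs)
  tri <- unlist(lapply(seqs, overlapped_3gram), use.names = FALSE)
  idx <- match(tri, rownames(table))
  if (anyNA(idx)) stop("trinucleotide(s) missing from the property table")
  colMeans(table[idx, , drop = FALSE])
}

#' Compare a real and a generated sequence set
#'
#' Tabulates nucleotide composition and mean physicochemical properties
#' for both sets plus absolute differences; the result is a plot-ready
#' long table.
#'
#' @param real,generated sequence sets.
#' @param table property table.
#' @param path optional TSV output path.
#' @return data.frame with columns feature, real, generated, abs_diff.
#' @export
compare_real_generated <- function(real, generated,
                                   table = read_property_table(), path = NULL) {
  cr <- composition_profile(real); cg <- composition_profile(generated)
  pr <- physchem_profile(real, table); pg <- physchem_profile(generated, table)
  out <- data.frame(
    feature = c(paste0("freq_", names(cr)), names(pr)),
    real = c(as.numeric(cr), as.numeric(pr)),
    generated = c(as.numeric(cg), as.numeric(pg)))
  out$abs_diff <- abs(out$real - out$generated)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
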