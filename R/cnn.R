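# Multi-width convolutional text classifier over DNA word sequences.
#
# Architecture: embedding lookup (rows = word vectors, zero row for
# padding) -> convolution kernels of heights {2,3,4} spanning the full
# embedding width, stride 1, ReLU -> max pooling of each feature map ->
# concatenation (128 kernels x 3 heights = 384 features by default) ->
# fully connected softmax over the two classes. The same machinery, at a
# smaller size, serves as the GAN discriminator.

#' CNN configuration
#'
#' @param kernel_heights kernel heights in words (default 2, 3, 4).
#' @param kernels_per_height kernels per height (default 128).
#' @param embed_dim embedding width N (default 300).
#' @param max_words padded input length in words.
#' @param classes number of output classes (2).
#' @param dropout dropout probability before the fully connected layer.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param val_fraction fraction of the training set held out for early
#'   stopping (0 disables early stopping).
#' @param patience epochs without validation improvement before stopping.
#' @param embedding_trainable fine-tune the embedding table (default TRUE).
#' @param seed RNG seed; training and prediction are deterministic given it.
#' @return A list of class `cnn_config`; `fc_width` is always
#'   `kernels_per_height * length(kernel_heights)`.
#' @export
cnn_config <- function(kernel_heights = c(2L, 3L, 4L), kernels_per_height = 128L,
                       embed_dim = 300L, max_words = 198L, classes = 2L,
                       dropout = 0.5, lr = 1e-3, epochs = 30L, batch_size = 64L,
                       val_fraction = 0.1, patience = 3L,
                       embedding_trainable = TRUE, seed = 1L) {
  stopifnot(all(kernel_heights >= 1L), kernels_per_height >= 1L,
            max_words >= max(kernel_heights), dropout >= 0, dropout < 1)
  structure(list(kernel_heights = as.integer(kernel_heights),
                 kernels_per_height = as.integer(kernels_per_height),
                 embed_dim = as.integer(embed_dim),
                 max_words = as.integer(max_words),
                 classes = as.integer(classes), dropout = dropout, lr = lr,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 embedding_trainable = isTRUE(embedding_trainable),
                 seed = as.integer(seed),
                 fc_width = as.integer(kernels_per_height * length(kernel_heights))),
            class = "cnn_config")
}

#' Convolution of one kernel over an embedding matrix
#'
#' Feature map `z_i = ReLU(sum(W * x[i:(i+m-1), ]) + b)` with stride 1,
#' where the kernel W spans `m` rows and the full embedding width.
#'
#' @param x embedding matrix (rows = words).
#' @param W kernel matrix, `m` x `ncol(x)`.
#' @param b scalar bias.
#' @return Numeric feature map of length `nrow(x) - m + 1`.
#' @export
conv_forward <- function(x, W, b) {
  m <- nrow(W)
  P <- nrow(x) - m + 1L
  if (P < 1L) stop("input has fewer rows than the kernel height")
  xw <- window_matrix(x, m)
  pmax(as.numeric(xw %*% as.numeric(t(W))) + b, 0)
}

# rows i..i+m-1 of x flattened row-major into row i of a P x (m*N) matrix
window_matrix <- function(x, m) {
  P <- nrow(x) - m + 1L
  do.call(cbind, lapply(seq_len(m), function(l) x[l:(l + P - 1L), , drop = FALSE]))
}

#' Max pooling of a feature map
#'
#' @param z non-empty numeric feature map.
#' @return Its maximum element.
#' @export
max_pool <- function(z) {
  if (!length(z)) stop("empty feature map")
  max(z)
}

init_cnn <- function(config, embedding_init = NULL, vocab = NULL) {
  N <- config$embed_dim
  V <- if (!is.null(embedding_init)) nrow(embedding_init) else length(vocab)
  if (is.null(V) || V < 1L) stop("need an embedding table or a vocabulary")
  emb <- rbind(0, if (!is.null(embedding_init)) embedding_init
               else matrix(runif(V * N, -0.05, 0.05), V, N))  # row 1 = padding
  params <- list(emb = emb)
  for (m in config$kernel_heights) {
    sd <- sqrt(2 / (m * N))
    params[[paste0("convW", m)]] <- matrix(rnorm(m * N * config$kernels_per_height, 0, sd),
                                           m * N, config$kernels_per_height)
    params[[paste0("convb", m)]] <- numeric(config$kernels_per_height)
  }
  F <- config$fc_width
  params$fcW <- matrix(rnorm(F * config$classes, 0, sqrt(1 / F)), F, config$classes)
  params$fcb <- numeric(config$classes)
  structure(list(params = params, config = config,
                 vocab = if (!is.null(vocab)) as.character(vocab) else NULL),
            class = "cnn_classifier")
}

# tokens: integer indices (1-based into the vocabulary), length <= max_words.
token_embedding <- function(params, tokens, max_words) {
  rows <- rep(1L, max_words)                 # padding row
  if (length(tokens)) rows[seq_along(tokens)] <- tokens + 1L
  params$emb[rows, , drop = FALSE]
}

# Forward pass from an embedding matrix; returns intermediates for backprop.
cnn_forward_mat <- function(params, config, x) {
  feats <- numeric(0)
  inter <- list()
  for (m in config$kernel_heights) {
    xw <- window_matrix(x, m)
    z <- xw %*% params[[paste0("convW", m)]] +
      rep(params[[paste0("convb", m)]], each = nrow(xw))
    z <- pmax(z, 0)
    pooled <- apply(z, 2L, max)
    argmax <- max.col(t(z), ties.method = "first")
    inter[[as.character(m)]] <- list(xw = xw, pooled = pooled, argmax = argmax)
    feats <- c(feats, pooled)
  }
  logits <- as.numeric(feats %*% params$fcW) + params$fcb
  e <- exp(logits - max(logits))
  list(probs = e / sum(e), feats = feats, inter = inter)
}

#' CNN forward pass
#'
#' Maps an embedding matrix (or a token-index vector) to class
#' probabilities; probabilities sum to 1.
#'
#' @param x embedding matrix with `max_words` rows, or an integer vector of
#'   vocabulary indices (padded internally).
#' @param model a `cnn_classifier`.
#' @return Named probability vector over classes.
#' @export
cnn_forward <- function(x, model) {
  cfg <- model$config
  if (!is.matrix(x)) x <- token_embedding(model$params, as.integer(x), cfg$max_words)
  if (nrow(x) != cfg$max_words || ncol(x) != cfg$embed_dim)
    stop("input must be ", cfg$max_words, " x ", cfg$embed_dim)
  p <- cnn_forward_mat(model$params, cfg, x)$probs
  names(p) <- model$classes %||% paste0("class", seq_along(p))
  p
}

# Backprop of one sample. Returns gradient contributions as a named list
# shaped like params (emb gradient only for the rows actually used).
cnn_backward <- function(params, config, tokens, x, fwd, dlogits, drop_mask) {
  g <- list()
  feats_dropped <- fwd$feats * drop_mask
  g$fcW <- outer(feats_dropped, dlogits)
  g$fcb <- dlogits
  dfeat <- as.numeric(params$fcW %*% dlogits) * drop_mask
  demb <- NULL
  if (config$embedding_trainable) demb <- matrix(0, config$max_words, config$embed_dim)
  off <- 0L
  K <- config$kernels_per_height
  for (m in config$kernel_heights) {
    inter <- fwd$inter[[as.character(m)]]
    dpool <- dfeat[off + seq_len(K)]
    active <- inter$pooled > 0 & dpool != 0
    Wm <- paste0("convW", m); bm <- paste0("convb", m)
    if (any(active)) {
      rows <- inter$argmax[active]
      dz <- dpool[active]
      Xr <- inter$xw[rows, , drop = FALSE] * dz  # row i scaled by dz[i]
      gW <- matrix(0, m * config$embed_dim, K)
      gW[, active] <- t(Xr)
      g[[Wm]] <- gW
      gb <- numeric(K); gb[active] <- dz
      g[[bm]] <- gb
      if (config$embedding_trainable) {
        W <- params[[Wm]]
        N <- config$embed_dim
        act_idx <- which(active)
        for (a in seq_along(act_idx)) {
          j <- act_idx[a]; r <- rows[a]
          block <- matrix(W[, j], m, N, byrow = TRUE) * dz[a]
          demb[r:(r + m - 1L), ] <- demb[r:(r + m - 1L), ] + block
        }
      }
    } else {
      g[[Wm]] <- matrix(0, m * config$embed_dim, K)
      g[[bm]] <- numeric(K)
    }
    off <- off + K
  }
  g$demb <- demb
  g
}

#' Train a convolutional word-sequence classifier
#'
#' Minimises cross-entropy with Adam over minibatches; the embedding table
#' is initialised from pre-trained skip-gram vectors when supplied and
#' fine-tuned unless `embedding_trainable = FALSE`. Inverted dropout is
#' applied to the pooled feature vector during training. With
#' `val_fraction > 0`, a stratified split is held out and training stops
#' early when validation loss fails to improve for `patience` epochs.
#' Deterministic given `config$seed`.
#'
#' @param tokens list of integer token-index vectors (1-based into the
#'   vocabulary; see [words_to_indices()]).
#' @param labels factor or character vector with exactly 2 levels;
#'   "positive" is treated as the positive class when present.
#' @param config a [cnn_config()].
#' @param embedding_init optional V x N matrix of pre-trained word vectors.
#' @param vocab optional vocabulary (needed if `embedding_init` is absent).
#' @return A `cnn_classifier` with a `history` element (per-epoch losses).
#' @export
train_classifier <- function(tokens, labels, config = cnn_config(),
                             embedding_init = NULL, vocab = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training set must contain both classes")
  if ("positive" %in% classes) classes <- c("negative", "positive")
  y <- match(labels, classes)
  stopifnot(length(tokens) == length(labels))
  cfg <- config
  with_seed(cfg$seed, {
    model <- init_cnn(cfg, embedding_init, vocab)
    model$classes <- classes
    params <- model$params
    opt <- adam_init(params)
    n <- length(tokens)
    val_idx <- integer(0)
    if (cfg$val_fraction > 0 && n >= 20L) {
      val_idx <- unlist(lapply(seq_along(classes), function(k) {
        ids <- which(y == k)
        sample(ids, max(1L, floor(length(ids) * cfg$val_fraction)))
      }))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    best_val <- Inf; best_params <- params; bad <- 0L
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        grads <- lapply(params, function(p) p * 0)
        emb_grad_rows <- list()
        for (i in b) {
          x <- token_embedding(params, tokens[[i]], cfg$max_words)
          fwd <- cnn_forward_mat(params, cfg, x)
          pr <- fwd$probs
          ep_loss <- ep_loss - log(max(pr[y[i]], 1e-12))
          dlogits <- pr; dlogits[y[i]] <- dlogits[y[i]] - 1
          dlogits <- dlogits / length(b)
          drop_mask <- if (cfg$dropout > 0)
            (runif(cfg$fc_width) >= cfg$dropout) / (1 - cfg$dropout)
          else rep(1, cfg$fc_width)
          g <- cnn_backward(params, cfg, tokens[[i]], x, fwd, dlogits, drop_mask)
          for (nm in setdiff(names(g), "demb"))
            grads[[nm]] <- grads[[nm]] + g[[nm]]
          if (cfg$embedding_trainable && !is.null(g$demb)) {
            rows <- rep(1L, cfg$max_words)
            tk <- tokens[[i]]
            if (length(tk)) rows[seq_along(tk)] <- tk + 1L
            real <- rows > 1L
            if (any(real)) {
              agg <- rowsum(g$demb[real, , drop = FALSE], rows[real])
              r <- as.integer(rownames(agg))
              grads$emb[r, ] <- grads$emb[r, , drop = FALSE] + agg
            }
          }
        }
        if (!cfg$embedding_trainable) grads$emb[] <- 0
        st <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- st$params; opt <- st$state
        params$emb[1L, ] <- 0  # padding row stays zero
      }
      ep_loss <- ep_loss / max(1L, length(tr_idx))
      vl <- NA_real_
      if (length(val_idx)) {
        vl <- 0
        for (i in val_idx) {
          pr <- cnn_forward_mat(params, cfg,
                                token_embedding(params, tokens[[i]], cfg$max_words))$probs
          vl <- vl - log(max(pr[y[i]], 1e-12))
        }
        vl <- vl / length(val_idx)
        if (vl < best_val - 1e-6) { best_val <- vl; best_params <- params; bad <- 0L }
        else bad <- bad + 1L
      }
      history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss,
                                           val_loss = vl))
      if (length(val_idx) && bad >= cfg$patience) break
    }
    model$params <- if (length(val_idx) && is.finite(best_val)) best_params else params
    model$history <- history
    model
  })
}

#' Predict class probabilities for token sequences
#'
#' @param model a trained `cnn_classifier`.
#' @param tokens list of integer token-index vectors.
#' @return Matrix of class probabilities, one row per sequence, columns
#'   named by class.
#' @export
predict_classifier <- function(model, tokens) {
  cfg <- model$config
  out <- t(vapply(tokens, function(tk) {
    cnn_forward_mat(model$params, cfg,
                    token_embedding(model$params, as.integer(tk), cfg$max_words))$probs
  }, numeric(cfg$classes)))
  colnames(out) <- model$classes %||% paste0("class", seq_len(cfg$classes))
  out
}

#' Two-layer enhancer prediction
#'
#' Layer 1 calls enhancer vs non-enhancer at the 0.5 threshold (ties go to
#' the positive class); only sequences called enhancer are passed to layer
#' 2, which grades them strong vs weak. Both probability vectors are
#' reported; `p_strong` is NA when layer 2 was not invoked.
#'
#' @param ds a `dna_dataset` (or character vector of sequences).
#' @param layer1,layer2 trained `cnn_classifier` objects whose positive
#'   classes are enhancer and strong respectively.
#' @param scheme segmentation scheme shared by both models.
#' @param vocab the scheme's vocabulary.
#' @param dictionary `unigram_dictionary` for the statistical scheme.
#' @return data.frame with id, call, p_enhancer, p_strong.
#' @export
predict_two_layer <- function(ds, layer1, layer2, scheme = "overlapped3",
                              vocab = build_vocabulary(scheme), dictionary = NULL) {
  if (!inherits(ds, "dna_dataset"))
    ds <- dna_dataset(paste0("s", seq_along(ds)), ds)
  words <- tokenize_dataset(ds, scheme, dictionary)
  tokens <- lapply(words, words_to_indices, vocab = vocab)
  p1 <- predict_classifier(layer1, tokens)
  p_enh <- p1[, "positive"]
  call <- ifelse(p_enh >= 0.5, "enhancer", "non_enhancer")
  p_str <- rep(NA_real_, nrow(ds))
  hit <- which(call == "enhancer")
  if (length(hit)) {
    p2 <- predict_classifier(layer2, tokens[hit])
    p_str[hit] <- p2[, "positive"]
    call[hit] <- ifelse(p_str[hit] >= 0.5, "strong_enhancer", "weak_enhancer")
  }
  data.frame(id = ds$id, call = call, p_enhancer = as.numeric(p_enh),
             p_strong = p_str, stringsAsFactors = FALSE)
}
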