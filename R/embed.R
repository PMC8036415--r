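# Skip-gram word embeddings with negative sampling, trained from segmented
# DNA corpora. The model keeps the classical two tables: W (V x N input
# vectors; row j is the centre-word vector of word j, and h = xW selects it
# for a one-hot x) and U (N x V context vectors; column j is theta_j). A
# positive pair (centre w, context q) is pushed up through
# log sigma(h . theta_q) and m noise words t are pushed down through
# log sigma(-h . theta_t), the logarithmic form of the product objective.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Skip-gram training configuration
#'
#' @param dim embedding dimension N (300 by default).
#' @param window total context words per centre (4 = two on each side).
#' @param negatives noise words m per positive pair (10).
#' @param epochs passes over the corpus.
#' @param alpha,alpha_min initial / final learning rate (linear decay).
#' @param noise_power exponent of the unigram noise distribution (0.75).
#' @param seed RNG seed; training is reproducible given the seed.
#' @return A list of class `skipgram_config`.
#' @export
skipgram_config <- function(dim = 300L, window = 4L, negatives = 10L,
                            epochs = 5L, alpha = 0.025, alpha_min = 1e-4,
                            noise_power = 0.75, seed = 1L) {
  stopifnot(negatives >= 1L, window >= 2L, window %% 2L == 0L, dim >= 1L)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 negatives = as.integer(negatives), epochs = as.integer(epochs),
                 alpha = alpha, alpha_min = alpha_min,
                 noise_power = noise_power, seed = as.integer(seed)),
            class = "skipgram_config")
}

word_index <- function(model, word) {
  if (is.character(word)) words_to_indices(word, model$vocab) else as.integer(word)
}

#' Softmax output probability of the full skip-gram model
#'
#' The probability that word `j` is predicted as context of `center`, i.e.
#' `exp(h . U_j) / sum_k exp(h . U_k)` with `h` the centre word's input
#' vector, computed with max subtraction.
#'
#' @param model a `skipgram_model`.
#' @param center centre word (string or index).
#' @param j context word (string or index).
#' @return Probability in (0, 1).
#' @export
softmax_probability <- function(model, center, j) {
  w <- word_index(model, center)
  jj <- word_index(model, j)
  h <- model$W[w, ]
  logits <- as.numeric(h %*% model$U)
  e <- exp(logits - max(logits))
  (e / sum(e))[jj]
}

#' Negative-sampling objective of one positive pair
#'
#' `log sigma(h . theta_q) + sum_t log sigma(-h . theta_t)` for the centre
#' word's hidden vector h, the true context q and the noise words t.
#'
#' @param model a `skipgram_model`.
#' @param center,context centre and context word (string or index).
#' @param negatives noise words (strings or indices).
#' @return Scalar objective value (non-positive).
#' @export
sgns_objective <- function(model, center, context, negatives) {
  h <- model$W[word_index(model, center), ]
  q <- word_index(model, context)
  t <- word_index(model, negatives)
  sum(log_sigmoid(sum(h * model$U[, q]))) +
    sum(log_sigmoid(-as.numeric(h %*% model$U[, t, drop = FALSE])))
}

# Analytic gradients of the pair objective w.r.t. h, theta_q and the
# theta_t's; the oracle tests check these against finite differences.
sgns_pair_gradient <- function(h, theta_q, theta_neg) {
  theta_neg <- as.matrix(theta_neg)
  sq <- sigmoid(sum(h * theta_q))
  st <- sigmoid(as.numeric(h %*% theta_neg))
  dh <- (1 - sq) * theta_q - as.numeric(theta_neg %*% st)
  dq <- (1 - sq) * h
  dneg <- -outer(h, st)
  obj <- log_sigmoid(sum(h * theta_q)) + sum(log_sigmoid(-as.numeric(h %*% theta_neg)))
  list(dh = dh, dq = dq, dneg = dneg, objective = obj)
}

# Fitted noise distribution: unigram counts ^ noise_power, normalised.
noise_distribution <- function(corpus, vocab, power) {
  cnt <- table(factor(unlist(corpus, use.names = FALSE), levels = as.character(vocab)))
  w <- as.numeric(cnt)^power
  if (sum(w) == 0) stop("corpus has no words from the vocabulary")
  w / sum(w)
}

#' Draw negative samples for a positive pair
#'
#' `m` i.i.d. draws from the fitted `unigram^power` noise distribution,
#' redrawing any draw that equals the true context word.
#'
#' @param q true context word index.
#' @param noise_cum cumulative noise distribution (from the model or
#'   [noise_distribution()]).
#' @param m number of negatives.
#' @return Integer vector of `m` word indices, none equal to `q`.
#' @export
draw_negatives <- function(q, noise_cum, m) {
  if (length(noise_cum) < 2L) stop("vocabulary too small for negative sampling")
  out <- integer(0)
  while (length(out) < m) {
    draw <- findInterval(runif(m - length(out)), noise_cum) + 1L
    out <- c(out, draw[draw != q])
  }
  out[seq_len(m)]
}

#' Train skip-gram embeddings with negative sampling
#'
#' Stochastic gradient ascent over all (centre, context) pairs within a
#' symmetric window, one pair at a time, with `negatives` noise draws per
#' pair and a linearly decaying learning rate. W and U are initialised
#' uniformly in `[-0.5/N, 0.5/N]`. Deterministic given `config$seed`.
#'
#' @param corpus list of word sequences (character vectors), e.g. from
#'   [tokenize_dataset()].
#' @param vocab a `dna_vocabulary` covering every corpus word.
#' @param config a [skipgram_config()].
#' @return A `skipgram_model`: list with W (V x N), U (N x V), vocab,
#'   config, noise_cum and the per-epoch mean pair objective.
#' @export
train_skipgram <- function(corpus, vocab, config = skipgram_config()) {
  stopifnot(length(corpus) > 0)
  V <- length(vocab)
  N <- config$dim
  idx_corpus <- lapply(corpus, words_to_indices, vocab = vocab)
  noise <- noise_distribution(corpus, vocab, config$noise_power)
  noise_cum <- cumsum(noise)
  half <- config$window %/% 2L
  # enumerate all positive pairs once (centre, context)
  centers <- integer(0); contexts <- integer(0)
  for (ids in idx_corpus) {
    n <- length(ids)
    if (n < 2L) next
    for (d in seq_len(half)) {
      if (n > d) {
        centers <- c(centers, ids[1:(n - d)], ids[(1 + d):n])
        contexts <- c(contexts, ids[(1 + d):n], ids[1:(n - d)])
      }
    }
  }
  if (!length(centers)) stop("corpus has no context pairs")
  with_seed(config$seed, {
    W <- matrix(runif(V * N, -0.5 / N, 0.5 / N), V, N)
    U <- matrix(runif(N * V, -0.5 / N, 0.5 / N), N, V)
    total <- length(centers) * config$epochs
    done <- 0
    epoch_obj <- numeric(config$epochs)
    m <- config$negatives
    for (ep in seq_len(config$epochs)) {
      obj_sum <- 0
      for (k in seq_along(centers)) {
        lr <- config$alpha + (config$alpha_min - config$alpha) * done / total
        w <- centers[k]; q <- contexts[k]
        negs <- draw_negatives(q, noise_cum, m)
        targets <- c(q, negs)
        h <- W[w, ]
        scores <- as.numeric(h %*% U[, targets, drop = FALSE])
        sg <- sigmoid(scores)
        obj_sum <- obj_sum + log_sigmoid(scores[1L]) + sum(log_sigmoid(-scores[-1L]))
        g <- c(1 - sg[1L], -sg[-1L])          # d obj / d score
        dh <- as.numeric(U[, targets, drop = FALSE] %*% g)
        U[, targets] <- U[, targets, drop = FALSE] + lr * outer(h, g)
        W[w, ] <- h + lr * dh
        done <- done + 1
      }
      epoch_obj[ep] <- obj_sum / length(centers)
    }
    structure(list(W = W, U = U, vocab = vocab, config = config,
                   noise_cum = noise_cum, epoch_objective = epoch_obj),
              class = "skipgram_model")
  })
}

#' Build the embedding matrix of one word sequence
#'
#' Stacks the words' input vectors vertically (row i = vector of word i)
#' and zero-pads to `max_words` rows; padding rows contribute zero to any
#' downstream convolution sum.
#'
#' @param words character vector of words (or integer indices).
#' @param model a `skipgram_model`.
#' @param max_words number of rows of the padded matrix.
#' @param id sequence id used in error messages.
#' @return A `max_words` x N matrix with `word_count` attribute.
#' @export
embed_sequence <- function(words, model, max_words, id = "sequence") {
  idx <- if (length(words)) word_index(model, words) else integer(0)
  if (length(idx) > max_words)
    stop(id, " has ", length(idx), " words but max_words is ", max_words)
  out <- matrix(0, max_words, ncol(model$W))
  if (length(idx)) out[seq_along(idx), ] <- model$W[idx, , drop = FALSE]
  attr(out, "word_count") <- length(idx)
  out
}

#' Mean-pooled sequence vector (debug export only)
#'
#' Collapses a word sequence to the mean of its word vectors. This loses
#' word order and position effects, so it is deliberately not accepted as
#' classifier input; it exists for inspection and sanity plots only.
#'
#' @inheritParams embed_sequence
#' @return Numeric vector of length N.
#' @export
embed_pooled_mean <- function(words, model) {
  if (!length(words)) return(numeric(ncol(model$W)))
  colMeans(model$W[word_index(model, words), , drop = FALSE])
}

#' Save / load a skip-gram model as plain text (RDS-free, bit-exact)
#'
#' @param model a `skipgram_model`.
#' @param path file path.
#' @return `path` (write) or a `skipgram_model` (read).
#' @export
write_skipgram <- function(model, path) {
  obj <- list(W = model$W, U = model$U, vocab = as.character(model$vocab),
              config = unclass(model$config), noise_cum = model$noise_cum,
              epoch_objective = model$epoch_objective)
  writeLines(jsonlite::serializeJSON(obj, digits = I(17)), path)
  invisible(path)
}

#' @rdname write_skipgram
#' @export
read_skipgram <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE), collapse = "\n"))
  structure(list(W = obj$W, U = obj$U,
                 vocab = structure(obj$vocab, class = "dna_vocabulary"),
                 config = structure(obj$config, class = "skipgram_config"),
                 noise_cum = obj$noise_cum, epoch_objective = obj$epoch_objective),
            class = "skipgram_model")
}

#' @export
print.skipgram_model <- function(x, ...) {
  cat(sprintf("<skipgram_model> V = %d, N = %d\n", nrow(x$W), ncol(x$W)))
  invisible(x)
}
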