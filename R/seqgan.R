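# Sequence GAN for data augmentation. A GRU policy generates token
# sequences (dinucleotide tokens for 200-bp DNA, horizon T = 100); a small
# convolutional discriminator scores sequences as real vs generated. The
# generator is pretrained by maximum likelihood and then updated by policy
# gradient: the reward of a finished sequence is the discriminator output,
# and rewards of intermediate states are estimated by Monte-Carlo rollout
# under a frozen copy of the policy. One independent generator is trained
# per class (non-enhancer / strong / weak).

#' Seq-GAN training configuration
#'
#' @param vocab token vocabulary (default the 16 dinucleotides).
#' @param horizon tokens per sequence T (100 tokens = 200 bp).
#' @param hidden GRU hidden size (64 at desk scale).
#' @param emb_dim generator token embedding width.
#' @param pretrain_epochs maximum-likelihood warm-start epochs.
#' @param adv_rounds adversarial rounds.
#' @param g_steps,d_steps generator / discriminator updates per round.
#' @param g_batch sequences sampled per generator update.
#' @param rollout_n Monte-Carlo rollouts N per (state, action).
#' @param g_lr policy-gradient step size alpha.
#' @param d_epochs,d_lr,d_batch discriminator update schedule.
#' @param d_hidden,d_kernels discriminator embedding width and kernels per
#'   height (heights 2 and 3).
#' @param batch_size minibatch size for MLE pretraining.
#' @param class_tag "non_enhancer", "strong" or "weak" (labels generated
#'   records).
#' @param seed RNG seed; the whole training run is deterministic given it.
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(vocab = build_vocabulary("nonoverlapped2"),
                       horizon = 100L, hidden = 64L, emb_dim = 16L,
                       pretrain_epochs = 20L, adv_rounds = 3L,
                       g_steps = 1L, d_steps = 1L, g_batch = 8L,
                       rollout_n = 16L, g_lr = 0.01,
                       d_epochs = 1L, d_lr = 1e-3, d_batch = 64L,
                       d_hidden = 8L, d_kernels = 8L,
                       batch_size = 32L,
                       class_tag = c("non_enhancer", "strong", "weak"),
                       seed = 1L) {
  class_tag <- match.arg(class_tag)
  stopifnot(horizon >= 2L, rollout_n >= 1L, g_steps >= 0L, d_steps >= 0L,
            adv_rounds >= 0L, pretrain_epochs >= 1L)
  structure(list(vocab = as.character(vocab), horizon = as.integer(horizon),
                 hidden = as.integer(hidden), emb_dim = as.integer(emb_dim),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 adv_rounds = as.integer(adv_rounds),
                 g_steps = as.integer(g_steps), d_steps = as.integer(d_steps),
                 g_batch = as.integer(g_batch), rollout_n = as.integer(rollout_n),
                 g_lr = g_lr, d_epochs = as.integer(d_epochs), d_lr = d_lr,
                 d_batch = as.integer(d_batch), d_hidden = as.integer(d_hidden),
                 d_kernels = as.integer(d_kernels),
                 batch_size = as.integer(batch_size),
                 class_tag = class_tag, seed = as.integer(seed)),
            class = "gan_config")
}

new_generator <- function(config) {
  V <- length(config$vocab)
  params <- gru_init_params(V, config$emb_dim, config$hidden)
  structure(list(params = params, vocab = config$vocab,
                 horizon = config$horizon, config = config),
            class = "generator_policy")
}

#' @export
print.generator_policy <- function(x, ...) {
  cat(sprintf("<generator_policy> |Y| = %d, T = %d, hidden = %d\n",
              length(x$vocab), x$horizon, ncol(x$params$Uz)))
  invisible(x)
}

# Discriminator probability that each row of a token matrix is real.
# Accepts a cnn_classifier (class "real" is the positive column) or a plain
# function(token_matrix) -> numeric, which the oracle tests use.
d_prob <- function(discriminator, tokens) {
  if (is.function(discriminator)) return(discriminator(tokens))
  p <- predict_classifier(discriminator,
                          lapply(seq_len(nrow(tokens)), function(i) tokens[i, ]))
  p[, "real"]
}

#' Pretrain the generator by maximum likelihood
#'
#' Teacher-forced NLL minimisation with Adam over minibatches of real token
#' sequences; the per-epoch mean NLL is recorded and must be read before
#' adversarial training (the policy-gradient stage assumes a non-degenerate
#' initial policy).
#'
#' @param real_tokens integer matrix (sequences x horizon) of token indices.
#' @param config a [gan_config()].
#' @param generator optional generator to continue training.
#' @return A `generator_policy` with an `nll` element (per-epoch NLL).
#' @export
pretrain_generator <- function(real_tokens, config = gan_config(),
                               generator = NULL) {
  stopifnot(is.matrix(real_tokens), nrow(real_tokens) >= 1L,
            ncol(real_tokens) == config$horizon)
  with_seed(derive_seed(config$seed, "pretrain"), {
    gen <- generator %||% new_generator(config)
    params <- gen$params
    opt <- adam_init(params)
    n <- nrow(real_tokens)
    nll <- numeric(config$pretrain_epochs)
    for (ep in seq_len(config$pretrain_epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        res <- gru_nll_grad(params, real_tokens[b, , drop = FALSE])
        tot <- tot + res$loss * length(b)
        st <- adam_step(params, res$grads, opt, lr = 1e-2)
        params <- st$params; opt <- st$state
      }
      nll[ep] <- tot / n
    }
    gen$params <- params
    gen$nll <- nll
    gen
  })
}

#' Monte-Carlo action value of a (state, action) pair
#'
#' For a full-length sequence (t = T) the value is the discriminator output
#' exactly, with no sampling. For t < T the prefix is completed N times by
#' the rollout policy and the value is the mean discriminator output over
#' the completions.
#'
#' @param state integer vector of tokens already emitted (may be empty).
#' @param action the candidate next token (integer index).
#' @param generator rollout policy `generator_policy` (a synced copy of the
#'   generator during training).
#' @param discriminator a `cnn_classifier` with classes fake/real, or a
#'   function mapping a token matrix to reward probabilities.
#' @param n_rollouts rollouts N.
#' @return Scalar action value Q in (0, 1).
#' @export
action_value <- function(state, action, generator, discriminator,
                         n_rollouts = 16L) {
  prefix <- c(as.integer(state), as.integer(action))
  T <- generator$horizon
  if (length(prefix) > T) stop("state/action longer than the horizon")
  if (length(prefix) == T)
    return(d_prob(discriminator, matrix(prefix, nrow = 1L)))
  params <- generator$params
  fwd <- gru_forward(params, matrix(prefix, nrow = 1L))
  H0 <- fwd$steps[[length(prefix)]]$H
  N <- as.integer(n_rollouts)
  Hrep <- matrix(rep(H0, each = N), N, ncol(H0))
  rest <- gru_sample_steps(params, N, T - length(prefix), Hrep,
                           rep(prefix[length(prefix)], N))
  full <- cbind(matrix(rep(prefix, each = N), N, length(prefix)), rest)
  mean(d_prob(discriminator, full))
}

#' Policy-gradient estimate for the generator
#'
#' Samples `batch` trajectories from the generator, computes action values
#' for every candidate token at every sampled prefix (rollouts under the
#' rollout policy for t < T, exact discriminator output at t = T) and
#' returns the gradient estimate
#' `sum_t E[sum_y grad G(y | prefix) * Q(prefix, y)]`
#' in ascent direction. Because the inner sum runs over all tokens, a
#' reward that is constant across actions yields an exactly zero gradient.
#'
#' @param generator current policy.
#' @param discriminator reward source (see [action_value()]).
#' @param batch trajectories sampled per estimate.
#' @param n_rollouts rollouts N per (state, action).
#' @param rollout_policy frozen policy used for rollouts (defaults to the
#'   generator itself).
#' @return List with `grads` (named like the parameters), `mean_reward`
#'   (mean full-sequence discriminator output) and `tokens`.
#' @export
generator_gradient <- function(generator, discriminator, batch = 8L,
                               n_rollouts = 16L, rollout_policy = generator) {
  params <- generator$params
  T <- generator$horizon
  V <- length(generator$vocab)
  B <- as.integer(batch)
  N <- as.integer(n_rollouts)
  tokens <- gru_sample(params, B, T)
  # prefix hidden states under the rollout policy
  beta <- rollout_policy$params
  fwd_beta <- gru_forward(beta, tokens)
  # teacher-forced forward under the current policy for the gradient
  fwd <- gru_forward(params, tokens)
  dlogits <- vector("list", T)
  Hdim <- ncol(beta$Uz)
  for (t in seq_len(T)) {
    Q <- matrix(0, B, V)
    if (t == T) {
      for (a in seq_len(V)) {
        full <- tokens; full[, T] <- a
        Q[, a] <- d_prob(discriminator, full)
      }
    } else {
      H0 <- if (t == 1L) matrix(0, B, Hdim) else fwd_beta$steps[[t - 1L]]$H
      # rollouts for all B prefixes x V actions at once
      Hrep <- H0[rep(seq_len(B), each = N), , drop = FALSE]
      for (a in seq_len(V)) {
        st <- gru_cell(beta, rep(a, B * N), Hrep)
        rest <- gru_sample_steps(beta, B * N, T - t, st$H, rep(a, B * N))
        pre <- if (t > 1L) tokens[rep(seq_len(B), each = N), 1:(t - 1L), drop = FALSE]
               else matrix(0L, B * N, 0L)
        full <- cbind(pre, rep(a, B * N), rest)
        r <- d_prob(discriminator, full)
        Q[, a] <- rowMeans(matrix(r, B, N, byrow = TRUE))
      }
    }
    P <- fwd$steps[[t]]$P
    expQ <- rowSums(P * Q)
    dlogits[[t]] <- P * (Q - expQ) / B   # ascent direction, batch mean
  }
  grads <- gru_backward(params, fwd, dlogits)
  mean_reward <- mean(d_prob(discriminator, tokens))
  list(grads = grads, mean_reward = mean_reward, tokens = tokens)
}

#' Discriminator objective
#'
#' `-mean log D(real) - mean log(1 - D(fake))`: the negative log-likelihood
#' the discriminator minimises.
#'
#' @param discriminator see [action_value()].
#' @param real_tokens,fake_tokens integer token matrices.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(discriminator, real_tokens, fake_tokens) {
  stopifnot(nrow(real_tokens) >= 1L, nrow(fake_tokens) >= 1L)
  pr <- d_prob(discriminator, real_tokens)
  pf <- d_prob(discriminator, fake_tokens)
  -mean(log(pmax(pr, 1e-12))) - mean(log(pmax(1 - pf, 1e-12)))
}

new_discriminator <- function(config) {
  dcfg <- cnn_config(kernel_heights = c(2L, 3L),
                     kernels_per_height = config$d_kernels,
                     embed_dim = config$d_hidden, max_words = config$horizon,
                     classes = 2L, dropout = 0, lr = config$d_lr,
                     epochs = config$d_epochs, batch_size = config$d_batch,
                     val_fraction = 0, embedding_trainable = TRUE,
                     seed = derive_seed(config$seed, "disc"))
  model <- init_cnn(dcfg, vocab = config$vocab)
  model$classes <- c("fake", "real")
  model$opt <- adam_init(model$params)
  model
}

# A few Adam epochs of discriminator training, continuing from its current
# parameters and optimiser state. tokens: list of integer vectors; y: 1 =
# fake, 2 = real.
discriminator_update <- function(disc, tokens, y, epochs, lr, batch_size) {
  cfg <- disc$config
  params <- disc$params; opt <- disc$opt
  n <- length(tokens)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      grads <- lapply(params, function(p) p * 0)
      for (i in b) {
        x <- token_embedding(params, tokens[[i]], cfg$max_words)
        fwd <- cnn_forward_mat(params, cfg, x)
        dlogits <- fwd$probs
        dlogits[y[i]] <- dlogits[y[i]] - 1
        dlogits <- dlogits / length(b)
        g <- cnn_backward(params, cfg, tokens[[i]], x, fwd, dlogits,
                          rep(1, cfg$fc_width))
        for (nm in setdiff(names(g), "demb")) grads[[nm]] <- grads[[nm]] + g[[nm]]
        if (!is.null(g$demb)) {
          rows <- rep(1L, cfg$max_words)
          tk <- tokens[[i]]
          if (length(tk)) rows[seq_along(tk)] <- tk + 1L
          agg <- rowsum(g$demb[rows > 1L, , drop = FALSE], rows[rows > 1L])
          r <- as.integer(rownames(agg))
          grads$emb[r, ] <- grads$emb[r, , drop = FALSE] + agg
        }
      }
      st <- adam_step(params, grads, opt, lr = lr)
      params <- st$params; opt <- st$state
      params$emb[1L, ] <- 0
    }
  }
  disc$params <- params; disc$opt <- opt
  disc
}

#' Adversarial training of the Seq-GAN
#'
#' Alternates `g_steps` policy-gradient generator updates (the rollout
#' policy is re-synchronised to the generator before each block) with
#' `d_steps` discriminator updates on fresh fakes. The training log records
#' the mean reward of generated batches and the discriminator loss per
#' round. Deterministic given `config$seed`; aborts if the mean reward
#' turns NaN.
#'
#' @param real_tokens integer matrix (sequences x horizon).
#' @param config a [gan_config()].
#' @param generator pretrained generator (from [pretrain_generator()]);
#'   pretrained internally when NULL.
#' @return List with `generator`, `discriminator` and a `log` data.frame
#'   (one row per adversarial round).
#' @export
adversarial_train <- function(real_tokens, config = gan_config(),
                              generator = NULL) {
  if (is.null(generator)) generator <- pretrain_generator(real_tokens, config)
  with_seed(derive_seed(config$seed, "adversarial"), {
    disc <- new_discriminator(config)
    n_real <- nrow(real_tokens)
    real_list <- lapply(seq_len(n_real), function(i) real_tokens[i, ])
    # warm up the discriminator on pretrain-quality fakes
    fakes <- gru_sample(generator$params, min(n_real, config$d_batch * 2L),
                        config$horizon)
    disc <- discriminator_update(
      disc, c(real_list, lapply(seq_len(nrow(fakes)), function(i) fakes[i, ])),
      c(rep(2L, n_real), rep(1L, nrow(fakes))),
      epochs = max(1L, config$d_epochs), lr = config$d_lr,
      batch_size = config$d_batch)
    log <- data.frame(round = integer(0), mean_reward = numeric(0),
                      d_loss = numeric(0))
    for (round in seq_len(config$adv_rounds)) {
      mean_reward <- NA_real_
      if (config$g_steps > 0L) {
        rollout_policy <- generator   # G_beta <- G_theta sync
        for (gs in seq_len(config$g_steps)) {
          est <- generator_gradient(generator, disc, batch = config$g_batch,
                                    n_rollouts = config$rollout_n,
                                    rollout_policy = rollout_policy)
          if (is.nan(est$mean_reward)) stop("GAN diverged: mean reward is NaN")
          for (nm in names(generator$params))
            generator$params[[nm]] <- generator$params[[nm]] +
              config$g_lr * est$grads[[nm]]
          mean_reward <- est$mean_reward
        }
      }
      d_loss <- NA_real_
      for (dstep in seq_len(config$d_steps)) {
        fakes <- gru_sample(generator$params, min(n_real, config$d_batch),
                            config$horizon)
        fake_list <- lapply(seq_len(nrow(fakes)), function(i) fakes[i, ])
        disc <- discriminator_update(disc, c(real_list, fake_list),
                                     c(rep(2L, n_real), rep(1L, nrow(fakes))),
                                     epochs = config$d_epochs, lr = config$d_lr,
                                     batch_size = config$d_batch)
        d_loss <- discriminator_loss(disc, real_tokens, fakes)
      }
      log <- rbind(log, data.frame(round = round, mean_reward = mean_reward,
                                   d_loss = d_loss))
    }
    list(generator = generator, discriminator = disc, log = log)
  })
}

#' Train a class-conditional Seq-GAN on DNA sequences
#'
#' Convenience wrapper: tokenises the class's sequences with the
#' non-overlapped 2-gram scheme, pretrains the generator by MLE and runs
#' adversarial training.
#'
#' @param ds a `dna_dataset` (or character vector) of one class's sequences.
#' @param config a [gan_config()].
#' @return As [adversarial_train()].
#' @export
gan_train <- function(ds, config = gan_config()) {
  seqs <- corpus_seqs(ds)
  vocab <- structure(config$vocab, class = "dna_vocabulary")
  tok <- t(vapply(seqs, function(s)
    words_to_indices(non_overlapped_2gram(s), vocab), integer(config$horizon)))
  adversarial_train(tok, config)
}

#' Generate artificial DNA sequences
#'
#' Samples `n` token sequences from a trained generator, detokenises them
#' into A/C/G/T strings (T dinucleotide tokens become a 2T-nt sequence) and
#' labels them with the generator's class tag and `provenance =
#' "generated"`.
#'
#' @param generator a trained `generator_policy`.
#' @param n number of sequences.
#' @param class_tag "non_enhancer", "strong" or "weak" (defaults to the
#'   training config's tag).
#' @param seed RNG seed.
#' @return A `dna_dataset` of generated records.
#' @export
generate_sequences <- function(generator, n,
                               class_tag = generator$config$class_tag,
                               seed = 1L) {
  with_seed(derive_seed(seed, paste0("generate-", class_tag)), {
    tok <- gru_sample(generator$params, n, generator$horizon)
    seqs <- apply(tok, 1L, function(row) paste(generator$vocab[row], collapse = ""))
    dna_dataset(sprintf("gen|%s|%05d", class_tag, seq_len(n)), seqs,
                enhancer_label = if (class_tag == "non_enhancer")
                  "non_enhancer" else "enhancer",
                strength_label = if (class_tag == "non_enhancer")
                  "not_applicable" else class_tag,
                provenance = "generated")
  })
}

#' Pairwise ungapped sequence identity
#'
#' Maximum number of matching positions over all ungapped slidings of one
#' sequence against the other, divided by the shorter length.
#'
#' @param a,b A/C/G/T strings.
#' @return Identity in `[0, 1]`.
#' @export
pair_identity <- function(a, b) {
  cpp_pair_identity(toupper(a), toupper(b))
}

#' Greedy redundancy filter (internal replacement for cd-hit-est)
#'
#' Processes sequences in input order and discards any sequence whose
#' identity to a reference sequence or an already-retained sequence reaches
#' the cutoff, so the retained set contains no pair at or above the cutoff.
#' An 8-mer sharing prefilter skips alignments between sequences with no
#' common 8-mer. With `engine = "cdhit"` the external cd-hit-est binary is
#' used instead when available.
#'
#' @param ds a `dna_dataset` or character vector of sequences.
#' @param cutoff identity cutoff in (0, 1] (default 0.80).
#' @param reference optional sequences the candidates must also be
#'   non-redundant against (e.g. the real training set).
#' @param prefilter use the 8-mer prefilter (default TRUE).
#' @param engine "internal" or "cdhit".
#' @return The retained subset, same type as the input.
#' @export
redundancy_filter <- function(ds, cutoff = 0.80, reference = NULL,
                              prefilter = TRUE, engine = c("internal", "cdhit")) {
  engine <- match.arg(engine)
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  seqs <- if (inherits(ds, "dna_dataset")) ds$seq else toupper(as.character(ds))
  refs <- if (is.null(reference)) character(0)
          else if (inherits(reference, "dna_dataset")) reference$seq
          else toupper(as.character(reference))
  if (engine == "cdhit" && nzchar(Sys.which("cd-hit-est"))) {
    keep <- cdhit_filter(seqs, cutoff)
  } else {
    keep <- cpp_redundancy_filter(seqs, cutoff, refs, prefilter)
  }
  if (inherits(ds, "dna_dataset")) ds[keep, , drop = FALSE] else seqs[keep]
}

# Shell out to cd-hit-est; returns a keep mask. Only reached when the
# binary is on the PATH.
cdhit_filter <- function(seqs, cutoff) {
  dir <- tempfile("cdhit")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  inp <- file.path(dir, "in.fasta"); outp <- file.path(dir, "out.fasta")
  ids <- sprintf("s%06d", seq_along(seqs))
  write_fasta(dna_dataset(ids, seqs), inp)
  status <- system2("cd-hit-est", c("-i", inp, "-o", outp, "-c", cutoff,
                                    "-n", "5", "-M", "0"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("cd-hit-est failed with status ", status)
  kept <- read_fasta(outp)$id
  ids %in% kept
}
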