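# Toy instances keep the policy enumerable: |Y| = 2 tokens, short horizons.

toy_gan_config <- function(T = 3L, hidden = 2L, seed = 1L, ...) {
  gan_config(vocab = c("AA", "CC"), horizon = T, hidden = hidden,
             emb_dim = 2L, pretrain_epochs = 5L, batch_size = 8L,
             seed = seed, ...)
}

test_that("generator step distributions are normalised and sequences have T tokens", {
  gen <- enhancerkit:::new_generator(toy_gan_config(T = 4L))
  fwd <- enhancerkit:::gru_forward(gen$params, matrix(c(1L, 2L, 1L, 2L), 1L))
  for (t in 1:4)
    expect_equal(rowSums(fwd$steps[[t]]$P), 1, tolerance = 1e-9)
  set.seed(1)
  toks <- enhancerkit:::gru_sample(gen$params, 7L, 4L)
  expect_equal(dim(toks), c(7L, 4L))
  expect_true(all(toks %in% 1:2))
})

test_that("MLE pretraining memorises a degenerate corpus and lowers NLL", {
  cfg <- gan_config(vocab = build_vocabulary("nonoverlapped2"), horizon = 8L,
                    hidden = 16L, emb_dim = 6L, pretrain_epochs = 60L,
                    batch_size = 8L, seed = 2L)
  target <- c(1L, 5L, 9L, 13L, 2L, 6L, 10L, 14L)
  tok <- matrix(rep(target, 15), 15, 8, byrow = TRUE)
  gen <- pretrain_generator(tok, cfg)
  expect_lt(tail(gen$nll, 1), gen$nll[1])
  expect_identical(enhancerkit:::gru_greedy(gen$params, 8L), target)
  expect_error(pretrain_generator(tok[0, , drop = FALSE], cfg))
})

test_that("action values: exact at t = T, constant under constant rewards, unbiased for t < T", {
  gen <- enhancerkit:::new_generator(toy_gan_config(T = 3L, seed = 3L))
  D <- function(tok) 0.2 + 0.6 * rowSums(tok == 1L) / ncol(tok)
  # t = T: discriminator output exactly, no sampling involved
  expect_equal(action_value(c(1L, 2L), 1L, gen, D, n_rollouts = 1L),
               D(matrix(c(1L, 2L, 1L), 1L)), tolerance = 1e-12)
  # constant discriminator
  expect_equal(action_value(1L, 2L, gen, function(m) rep(0.37, nrow(m)), 50L),
               0.37, tolerance = 1e-12)
  # t < T: rollout mean converges to the enumerated expectation
  fwd <- enhancerkit:::gru_forward(gen$params, matrix(c(1L, 2L, 1L), 1L))
  P3 <- fwd$steps[[3L]]$P[1L, ]
  exact <- sum(P3 * vapply(1:2, function(y)
    D(matrix(c(1L, 2L, y), 1L)), numeric(1)))
  set.seed(4)
  N <- 1e4
  est <- action_value(1L, 2L, gen, D, n_rollouts = N)
  # outcomes are Bernoulli-like over two values; bound the SE conservatively
  se <- 0.5 * diff(range(D(rbind(c(1,2,1), c(1,2,2))))) / sqrt(N)
  expect_lt(abs(est - exact), 3 * se + 1e-9)
})

test_that("policy gradient is exactly zero under constant reward and unbiased vs finite differences", {
  cfg <- toy_gan_config(T = 2L, hidden = 1L, seed = 5L)
  cfg$emb_dim <- 1L
  gen <- enhancerkit:::new_generator(cfg)
  expect_lte(length(enhancerkit:::flatten_params(gen$params)), 20L)
  set.seed(6)
  g0 <- generator_gradient(gen, function(m) rep(0.4, nrow(m)),
                           batch = 4L, n_rollouts = 3L)
  expect_lt(max(abs(unlist(g0$grads))), 1e-8)

  D <- function(tok) 0.1 + 0.8 * rowSums(tok == 1L) / ncol(tok)
  theta <- enhancerkit:::flatten_params(gen$params)
  exactJ <- function(th) {
    p <- enhancerkit:::unflatten_params(th, gen$params)
    grid <- as.matrix(expand.grid(1:2, 1:2))
    sum(apply(grid, 1L, function(s)
      enhancerkit:::gru_seq_prob(p, as.integer(s)) *
        D(matrix(as.integer(s), 1L))))
  }
  fd <- vapply(seq_along(theta), function(i) {
    e <- numeric(length(theta)); e[i] <- 1e-5
    (exactJ(theta + e) - exactJ(theta - e)) / 2e-5
  }, numeric(1))
  set.seed(7)
  nb <- 120L
  ests <- replicate(nb, enhancerkit:::flatten_params(
    generator_gradient(gen, D, batch = 40L, n_rollouts = 8L)$grads))
  mu <- rowMeans(ests)
  se <- apply(ests, 1L, stats::sd) / sqrt(nb)
  expect_true(all(abs(mu - fd) <= 3 * se + 1e-7))
  # determinism under a fixed RNG state
  set.seed(8); a <- generator_gradient(gen, D, batch = 5L, n_rollouts = 2L)
  set.seed(8); b <- generator_gradient(gen, D, batch = 5L, n_rollouts = 2L)
  expect_identical(a$grads, b$grads)
})

test_that("discriminator loss matches closed forms and hand computation", {
  real <- matrix(1L, 2, 4); fake <- matrix(2L, 2, 4)
  expect_equal(discriminator_loss(function(m) rep(0.5, nrow(m)), real, fake),
               2 * log(2), tolerance = 1e-12)
  expect_lt(discriminator_loss(function(m) {
    if (all(m == 1L)) rep(1 - 1e-9, nrow(m)) else rep(1e-9, nrow(m))
  }, real, fake), 1e-6)
  fixed <- function(m) if (nrow(m) == 2 && all(m == 1L)) c(0.9, 0.8) else c(0.1, 0.3)
  hand <- -mean(log(c(0.9, 0.8))) - mean(log(1 - c(0.1, 0.3)))
  expect_equal(discriminator_loss(fixed, real, fake), hand, tolerance = 1e-12)
})

test_that("adversarial training runs, logs every round, and g_steps = 0 freezes the generator", {
  cfg <- gan_config(vocab = c("AA", "CC", "GG", "TT"), horizon = 6L,
                    hidden = 6L, emb_dim = 4L, pretrain_epochs = 5L,
                    adv_rounds = 2L, g_steps = 1L, d_steps = 1L,
                    g_batch = 4L, rollout_n = 2L, batch_size = 8L, seed = 9L)
  set.seed(10)
  real <- matrix(sample(1:2, 20 * 6, TRUE), 20, 6)  # real uses tokens 1-2 only
  fit <- adversarial_train(real, cfg)
  expect_equal(nrow(fit$log), 2L)
  expect_false(any(is.nan(fit$log$mean_reward)))
  # frozen generator when g_steps = 0
  cfg0 <- cfg; cfg0$g_steps <- 0L
  gen <- pretrain_generator(real, cfg0)
  fit0 <- adversarial_train(real, cfg0, generator = gen)
  expect_identical(fit0$generator$params, gen$params)
})

test_that("generated sequences detokenise to valid DNA of the right length", {
  cfg <- gan_config(horizon = 10L, hidden = 8L, emb_dim = 4L,
                    pretrain_epochs = 2L, batch_size = 4L, seed = 11L,
                    class_tag = "strong")
  set.seed(12)
  real <- matrix(sample(1:16, 6 * 10, TRUE), 6, 10)
  gen <- pretrain_generator(real, cfg)
  gen$config <- cfg
  out <- generate_sequences(gen, 5L, seed = 13L)
  expect_equal(nrow(out), 5L)
  expect_true(all(nchar(out$seq) == 20L))
  expect_false(any(grepl("[^ACGT]", out$seq)))
  expect_true(all(out$provenance == "generated"))
  expect_true(all(out$strength_label == "strong"))
  # detokenise(tokenise_2gram(s)) = s
  s <- random_dna(1, 20, seed = 14)
  voc <- build_vocabulary("nonoverlapped2")
  idx <- words_to_indices(non_overlapped_2gram(s), voc)
  expect_identical(paste(as.character(voc)[idx], collapse = ""), s)
})

test_that("redundancy filtering removes pairs at or above the cutoff (oracle-verified)", {
  expect_equal(pair_identity("ACGTACGT", "ACGTACGT"), 1)
  a <- strsplit(random_dna(1, 200, seed = 15), "")[[1]]
  b <- a; flip <- seq(1, 200, by = 2)
  b[flip] <- vapply(b[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  b <- paste(b, collapse = ""); a <- paste(a, collapse = "")
  expect_lt(pair_identity(a, b), 0.8)
  expect_length(redundancy_filter(c(a, b), 0.8), 2L)
  expect_length(redundancy_filter(c(a, a), 0.8), 1L)
  # identity agrees with the naive oracle on random pairs
  set.seed(16)
  for (i in 1:10) {
    x <- random_dna(1, sample(20:60, 1)); y <- random_dna(1, sample(20:60, 1))
    expect_equal(pair_identity(x, y), naive_identity(x, y), tolerance = 1e-12)
  }
  # reference set removes matches against real sequences
  expect_length(redundancy_filter(c(a, b), 0.8, reference = a), 1L)
})
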