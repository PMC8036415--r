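make_toy_model <- function(V = 5L, N = 3L, seed = 1L) {
  set.seed(seed)
  words <- sort(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T")), 1, paste0,
                      collapse = ""))[seq_len(V)]
  structure(list(W = matrix(rnorm(V * N), V, N),
                 U = matrix(rnorm(N * V), N, V),
                 vocab = structure(words, class = "dna_vocabulary"),
                 config = skipgram_config(dim = N)),
            class = "skipgram_model")
}

test_that("softmax probability matches direct evaluation and normalises", {
  m <- make_toy_model(V = 5L, N = 3L, seed = 2L)
  h <- m$W[2, ]
  direct <- exp(h %*% m$U) / sum(exp(h %*% m$U))
  for (j in 1:5)
    expect_equal(softmax_probability(m, 2L, j), direct[j], tolerance = 1e-12)
  expect_equal(sum(vapply(1:5, function(j) softmax_probability(m, 3L, j),
                          numeric(1))), 1, tolerance = 1e-12)
  m$U[] <- 0
  expect_equal(softmax_probability(m, 1L, 4L), 1 / 5, tolerance = 1e-12)
})

test_that("the pair objective obeys its closed forms and both algebraic forms agree", {
  m <- make_toy_model(V = 8L, N = 4L, seed = 3L)
  m$W[] <- 0  # all dot products zero
  obj <- sgns_objective(m, 1L, 2L, 3:7)  # m = 5 negatives
  expect_equal(obj, 6 * log(0.5), tolerance = 1e-12)
  # Eq with log(1 - sigma(x)) equals the log(sigma(-x)) form
  m <- make_toy_model(V = 8L, N = 4L, seed = 4L)
  h <- m$W[1, ]
  sig <- function(x) 1 / (1 + exp(-x))
  raw <- log(sig(sum(h * m$U[, 2]))) +
    sum(log(1 - sig(as.numeric(h %*% m$U[, 3:7]))))
  expect_equal(sgns_objective(m, 1L, 2L, 3:7), raw, tolerance = 1e-12)
})

test_that("analytic pair gradients match central finite differences (V=10, N=5)", {
  set.seed(5)
  h <- rnorm(5) * 0.5; tq <- rnorm(5) * 0.5; tn <- matrix(rnorm(5 * 9) * 0.5, 5, 9)
  g <- enhancerkit:::sgns_pair_gradient(h, tq, tn)
  eps <- 1e-6
  fd <- function(f, x) vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
  relerr <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-6))
  expect_lt(relerr(g$dh, fd(function(x)
    enhancerkit:::sgns_pair_gradient(x, tq, tn)$objective, h)), 1e-4)
  expect_lt(relerr(g$dq, fd(function(x)
    enhancerkit:::sgns_pair_gradient(h, x, tn)$objective, tq)), 1e-4)
  fdn <- matrix(vapply(seq_along(tn), function(i) {
    e <- tn; e[i] <- e[i] + eps
    e2 <- tn; e2[i] <- e2[i] - eps
    (enhancerkit:::sgns_pair_gradient(h, tq, e)$objective -
       enhancerkit:::sgns_pair_gradient(h, tq, e2)$objective) / (2 * eps)
  }, numeric(1)), 5, 9)
  expect_lt(relerr(g$dneg, fdn), 1e-4)
})

test_that("negative draws follow the powered unigram law and never hit the context", {
  corpus <- list(rep(c("AAA", "AAC"), c(3, 1)))
  voc <- structure(c("AAA", "AAC"), class = "dna_vocabulary")
  noise <- enhancerkit:::noise_distribution(corpus, voc, power = 1)
  set.seed(6)
  draws <- draw_negatives(1L, cumsum(noise), 50L)
  expect_true(all(draws == 2L))  # only the other word survives rejection

  big <- simulate_token_corpus(vocab_size = 6L, n = 30L, length = 50L, seed = 7L)
  voc6 <- attr(big, "vocab")
  noise6 <- enhancerkit:::noise_distribution(big, voc6, power = 0.75)
  set.seed(8)
  n_draws <- 1e5
  got <- table(factor(draw_negatives(7L, cumsum(noise6), n_draws),
                      levels = 1:6))  # q = 7 never drawn -> plain multinomial
  for (j in 1:6) {
    se <- sqrt(n_draws * noise6[j] * (1 - noise6[j]))
    expect_lt(abs(got[j] - n_draws * noise6[j]), 3 * se + 1e-9)
  }
  set.seed(9)
  expect_false(any(draw_negatives(3L, cumsum(noise6), 2000L) == 3L))
})

test_that("training is seed-reproducible, ascends the objective and separates co-occurring words", {
  corp <- simulate_token_corpus(vocab_size = 4L, n = 150L, length = 20L,
                                p_cooccur = 1, pair = c(1L, 2L),
                                structure = "blocks", seed = 1105L)
  voc <- attr(corp, "vocab")
  cfg <- skipgram_config(dim = 8L, epochs = 15L, negatives = 5L,
                         alpha = 0.08, alpha_min = 0.02, seed = 7L)
  m1 <- train_skipgram(corp, voc, cfg)
  m2 <- train_skipgram(corp, voc, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$U, m2$U)
  expect_gt(tail(m1$epoch_objective, 1), m1$epoch_objective[1])
  # P (word 1) co-occurs with Q (word 2); R (word 4) is in the other block
  expect_gt(cosine(m1$W[1, ], m1$W[2, ]), cosine(m1$W[1, ], m1$W[4, ]))
})

test_that("embedding matrices are exact lookups with zero padding", {
  m <- make_toy_model(V = 6L, N = 4L, seed = 14L)
  words <- as.character(m$vocab)[c(3, 5)]
  E <- embed_sequence(words, m, max_words = 4L)
  expect_identical(E[1, ], m$W[3, ])
  expect_identical(E[2, ], m$W[5, ])
  expect_true(all(E[3:4, ] == 0))
  expect_equal(attr(E, "word_count"), 2L)
  E0 <- embed_sequence(character(0), m, max_words = 3L)
  expect_true(all(E0 == 0))
  expect_equal(attr(E0, "word_count"), 0L)
  expect_error(embed_sequence(rep(words, 3), m, max_words = 4L, id = "seq9"),
               "seq9")
})

test_that("model checkpoints reload bit-exactly", {
  corp <- simulate_token_corpus(vocab_size = 4L, n = 10L, length = 10L, seed = 15L)
  m <- train_skipgram(corp, attr(corp, "vocab"),
                      skipgram_config(dim = 4L, epochs = 1L, negatives = 2L))
  f <- withr::local_tempfile(fileext = ".txt")
  write_skipgram(m, f)
  back <- read_skipgram(f)
  expect_identical(back$W, m$W)
  expect_identical(back$U, m$U)
  expect_identical(as.character(back$vocab), as.character(m$vocab))
})
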