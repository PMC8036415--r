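test_that("conv_forward implements the windowed sum with ReLU", {
  x <- matrix(1, 3, 2); W <- matrix(1, 2, 2)
  expect_equal(conv_forward(x, W, 0), c(4, 4))
  expect_equal(conv_forward(x, W, -5), c(0, 0))
  set.seed(1)
  x <- matrix(rnorm(24), 6, 4); W <- matrix(rnorm(12), 3, 4); b <- rnorm(1)
  expect_equal(conv_forward(x, W, b), pmax(naive_conv(x, W, b), 0),
               tolerance = 1e-12)
  expect_error(conv_forward(matrix(1, 2, 4), W, 0), "fewer rows")
})

test_that("max_pool returns the maximum and rejects empty maps", {
  expect_equal(max_pool(c(0, 4, 2)), 4)
  expect_equal(max_pool(numeric(3)), 0)
  expect_error(max_pool(numeric(0)), "empty")
  set.seed(2)
  z <- runif(17)
  expect_true(all(max_pool(z) >= z))
})

test_that("the default architecture pools into a 384-vector with normalised softmax", {
  cfg <- cnn_config()  # 3 heights x 128 kernels, N = 300
  expect_equal(cfg$fc_width, 384L)
  set.seed(3)
  model <- enhancerkit:::init_cnn(cfg, vocab = build_vocabulary("overlapped3"))
  model$classes <- c("negative", "positive")
  x <- matrix(rnorm(198 * 300, sd = 0.1), 198, 300)
  fwd <- enhancerkit:::cnn_forward_mat(model$params, cfg, x)
  expect_length(fwd$feats, 384L)
  expect_equal(sum(fwd$probs), 1, tolerance = 1e-9)
  # all-zero input: output depends only on biases, identical across inputs
  p0a <- cnn_forward(matrix(0, 198, 300), model)
  p0b <- cnn_forward(matrix(0, 198, 300), model)
  expect_identical(p0a, p0b)
  expect_equal(sum(p0a), 1, tolerance = 1e-9)
})

test_that("zero-padding only affects windows that include padding rows", {
  cfg <- cnn_config(kernel_heights = 3L, kernels_per_height = 4L,
                    embed_dim = 5L, max_words = 10L, seed = 4L)
  set.seed(4)
  model <- enhancerkit:::init_cnn(cfg, vocab = build_vocabulary("nonoverlapped2"))
  x <- rbind(matrix(rnorm(7 * 5), 7, 5), matrix(0, 3, 5))
  W <- model$params$convW3
  zfull <- enhancerkit:::window_matrix(x, 3L) %*% W
  zreal <- enhancerkit:::window_matrix(x[1:7, ], 3L) %*% W
  # windows 1..5 lie fully inside real rows and agree exactly
  expect_equal(zfull[1:5, ], zreal, tolerance = 1e-12)
})

test_that("training separates a separable fixture, is deterministic, and loss decreases", {
  set.seed(5)
  voc <- build_vocabulary("nonoverlapped2")
  tokens <- lapply(1:40, function(i) sample(if (i <= 20) 1:8 else 9:16, 12, TRUE))
  labels <- rep(c("positive", "negative"), each = 20)
  cfg <- cnn_config(kernel_heights = c(2L, 3L), kernels_per_height = 8L,
                    embed_dim = 8L, max_words = 12L, epochs = 25L,
                    batch_size = 10L, dropout = 0.2, val_fraction = 0,
                    lr = 5e-3, seed = 6L)
  m <- train_classifier(tokens, labels, cfg, vocab = voc)
  pr <- predict_classifier(m, tokens)
  expect_equal(mean((pr[, "positive"] >= 0.5) == (labels == "positive")), 1)
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  m2 <- train_classifier(tokens, labels, cfg, vocab = voc)
  expect_identical(predict_classifier(m2, tokens), pr)
  expect_error(train_classifier(tokens[1:20], labels[1:20], cfg, vocab = voc),
               "both classes")
})

test_that("two-layer prediction gates layer 2 on the layer-1 call", {
  set.seed(7)
  voc <- build_vocabulary("overlapped3")
  # layer 1 separates AT-rich from GC-rich; layer 2 splits enhancers by CA content
  mk <- function(comp, n) vapply(seq_len(n), function(i)
    paste(sample(comp, 30, TRUE), collapse = ""), character(1))
  enh_strong <- mk(c("C", "A"), 10); enh_weak <- mk(c("G", "A"), 10)
  non <- mk(c("T", "A"), 10)
  tok <- function(seqs) lapply(seqs, function(s)
    words_to_indices(overlapped_3gram(s), voc))
  cfg <- cnn_config(kernel_heights = c(2L, 3L), kernels_per_height = 8L,
                    embed_dim = 8L, max_words = 28L, epochs = 20L,
                    batch_size = 8L, dropout = 0, val_fraction = 0,
                    lr = 5e-3, seed = 8L)
  l1 <- train_classifier(c(tok(enh_strong), tok(enh_weak), tok(non)),
                         rep(c("positive", "negative"), c(20, 10)), cfg, vocab = voc)
  l2 <- train_classifier(c(tok(enh_strong), tok(enh_weak)),
                         rep(c("positive", "negative"), c(10, 10)), cfg, vocab = voc)
  ds <- dna_dataset(paste0("q", 1:6), c(enh_strong[1:2], enh_weak[1:2], non[1:2]))
  out <- predict_two_layer(ds, l1, l2, scheme = "overlapped3", vocab = voc)
  expect_equal(nrow(out), 6L)
  expect_true(all(is.na(out$p_strong[out$call == "non_enhancer"])))
  expect_true(all(!is.na(out$p_strong[out$call != "non_enhancer"])))
  expect_true(all(out$call %in% c("non_enhancer", "weak_enhancer", "strong_enhancer")))
})
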