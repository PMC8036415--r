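test_that("simulated datasets have the requested shape and are seed-deterministic", {
  cfg <- simulation_config(n_non = 10L, n_strong = 5L, n_weak = 5L, seed = 1L)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds), 20L)
  expect_equal(sum(ds$enhancer_label == "non_enhancer"), 10L)
  expect_equal(sum(ds$strength_label == "strong"), 5L)
  expect_true(all(nchar(ds$seq) == 200L))
  expect_identical(simulate_dataset(cfg), ds)
  expect_false(identical(simulate_dataset(simulation_config(
    n_non = 10L, n_strong = 5L, n_weak = 5L, seed = 2L)), ds))
})

test_that("negative-class composition matches the configured A/T bias within 3 sigma", {
  cfg <- simulation_config(n_non = 300L, n_strong = 1L, n_weak = 1L,
                           length = 200L, seed = 3L)
  ds <- simulate_dataset(cfg)
  non <- ds[ds$enhancer_label == "non_enhancer", ]
  n_bases <- 300L * 200L
  p <- composition_profile(non)
  for (b in names(p)) {
    p0 <- cfg$at_bias[[b]]
    se <- sqrt(p0 * (1 - p0) / n_bases)
    expect_lt(abs(p[[b]] - p0), 3 * se + 1e-9)
  }
})

test_that("planted motif dosage is respected", {
  motifs <- c("ACGTACGT", "TTGACCAA")
  cfg <- simulation_config(n_non = 2L, n_strong = 30L, n_weak = 30L,
                           motif_words = motifs, strong_dosage = 8L,
                           weak_dosage = 1L, seed = 4L)
  ds <- simulate_dataset(cfg)
  count_hits <- function(s) sum(vapply(motifs, function(m) {
    hits <- gregexpr(m, s, fixed = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }, integer(1)))
  strong_hits <- vapply(ds$seq[ds$strength_label == "strong"], count_hits,
                        integer(1))
  weak_hits <- vapply(ds$seq[ds$strength_label == "weak"], count_hits,
                      integer(1))
  expect_true(all(strong_hits >= 8L))
  expect_true(all(weak_hits >= 1L))
  expect_error(simulate_dataset(simulation_config(
    n_non = 1L, n_strong = 1L, n_weak = 1L, length = 20L,
    motif_words = motifs, strong_dosage = 3L, weak_dosage = 0L, seed = 1L)),
    "exceeds")
})

test_that("the benchmark preset mirrors the benchmark class sizes", {
  cfg <- simulation_preset("benchmark")
  expect_equal(c(cfg$n_non, cfg$n_strong, cfg$n_weak), c(1484L, 742L, 742L))
  scaled <- simulation_preset("benchmark", scale = 400 / 2968)
  expect_equal(c(scaled$n_non, scaled$n_strong, scaled$n_weak),
               c(200L, 100L, 100L))
})

test_that("token corpora honour co-occurrence structure and determinism", {
  corp <- simulate_token_corpus(vocab_size = 8L, n = 20L, length = 30L,
                                p_cooccur = 1, pair = c(1L, 2L), seed = 5L)
  voc <- attr(corp, "vocab")
  expect_length(corp, 20L)
  expect_true(all(lengths(corp) == 30L))
  P <- as.character(voc)[1]; Q <- as.character(voc)[2]
  for (s in corp) {
    after_p <- s[which(head(s, -1) == P) + 1L]
    expect_true(all(after_p == Q))
  }
  expect_identical(simulate_token_corpus(vocab_size = 8L, n = 20L, length = 30L,
                                         p_cooccur = 1, pair = c(1L, 2L), seed = 5L),
                   corp)
  blocks <- simulate_token_corpus(vocab_size = 8L, n = 30L, length = 20L,
                                  structure = "blocks", seed = 6L)
  w <- as.character(attr(blocks, "vocab"))
  for (s in blocks) {
    idx <- match(s, w)
    expect_true(all(idx <= 4L) || all(idx >= 5L))
  }
})
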