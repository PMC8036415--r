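test_that("bpe_seed merges the most frequent pair and normalises", {
  d <- bpe_seed("ATATAT", lexicon_config(seed_size = 5L, target_size = 4L))
  expect_true("AT" %in% names(d$p))      # AT (3 occurrences) beats TA (2)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)

  d2 <- bpe_seed("AAAA", lexicon_config(seed_size = 5L, target_size = 4L))
  expect_true(all(c("A", "C", "G", "T", "AA") %in% names(d2$p)))
  expect_error(bpe_seed("A", lexicon_config(seed_size = 5L, target_size = 4L)),
               "at least 2")
})

test_that("marginal likelihood matches closed forms and enumeration", {
  d <- unigram_dictionary(c(A = 0.5, T = 0.2, AT = 0.3))
  expect_equal(as.numeric(marginal_log_likelihood("AT", d)), log(0.4),
               tolerance = 1e-12)
  expect_equal(as.numeric(marginal_log_likelihood("A", d)), log(0.5),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:30) {
    dict <- random_dictionary()
    s <- random_dna(1, sample(1:10, 1))
    expect_equal(as.numeric(marginal_log_likelihood(s, dict)),
                 enum_loglik(s, dict), tolerance = 1e-10)
  }
})

test_that("EM matches the single-segmentation closed form and an enumeration EM", {
  # mononucleotide-only dictionary: fixed point = empirical base frequencies
  corpus <- c("ACGT", "AACC", "GGGA")
  d0 <- unigram_dictionary(c(A = .25, C = .25, G = .25, T = .25))
  fit <- em_fit(corpus, d0)
  emp <- table(factor(strsplit(paste(corpus, collapse = ""), "")[[1]],
                      levels = c("A", "C", "G", "T")))
  expect_equal(unname(fit$p[c("A", "C", "G", "T")]),
               as.numeric(emp / sum(emp)), tolerance = 1e-6)

  # ambiguous dictionary vs brute-force EM over enumerated segmentations
  corpus2 <- rep("ATAT", 100)
  d1 <- unigram_dictionary(c(A = 0.4, T = 0.4, AT = 0.2))
  cfg <- lexicon_config(em_max_iter = 25L, em_tol = 0)
  fit2 <- suppressWarnings(em_fit(corpus2, d1, cfg))  # A,T counts underflow-floor
  oracle <- enum_em(corpus2, c(A = 0.4, T = 0.4, AT = 0.2), 25L)
  expect_equal(unname(fit2$p[names(oracle)]), unname(oracle), tolerance = 1e-8)

  # monotone likelihood trace
  tr <- attr(fit2, "loglik_trace")
  expect_true(all(diff(tr) >= -1e-9))
})

test_that("prune_step keeps the top 70 percent plus protected mononucleotides", {
  set.seed(21)
  corpus <- random_dna(30, 40)
  dict <- bpe_seed(corpus, lexicon_config(seed_size = 112L, target_size = 10L))
  dict <- em_fit(corpus, dict)
  np <- sum(!(names(dict$p) %in% c("A", "C", "G", "T")))
  pruned <- prune_step(corpus, dict)
  expect_length(pruned$p, ceiling(0.7 * np) + 4L)
  expect_true(all(c("A", "C", "G", "T") %in% names(pruned$p)))
  expect_equal(sum(pruned$p), 1, tolerance = 1e-12)
})

test_that("learn_dictionary hits the target size exactly and is deterministic", {
  set.seed(5)
  corpus <- random_dna(60, 60)
  cfg <- lexicon_config(target_size = 20L, seed_size = 80L)
  d1 <- suppressWarnings(learn_dictionary(corpus, cfg))
  d2 <- suppressWarnings(learn_dictionary(corpus, cfg))
  expect_length(d1$p, 20L)
  expect_identical(d1, d2)
  expect_equal(sum(d1$p), 1, tolerance = 1e-9)
  # degenerate corpus collapses to the protected floor
  d3 <- suppressWarnings(
    learn_dictionary("ACGT", lexicon_config(target_size = 4L, seed_size = 10L)))
  expect_setequal(names(d3$p), c("A", "C", "G", "T"))
})

test_that("viterbi_segment equals enumeration argmax and reconstructs input", {
  d <- unigram_dictionary(c(A = 0.5, T = 0.2, AT = 0.3))
  expect_identical(viterbi_segment("AT", d), "AT")
  expect_identical(viterbi_segment("ATAT", d), c("AT", "AT"))
  dm <- unigram_dictionary(c(A = .25, C = .25, G = .25, T = .25))
  expect_identical(viterbi_segment("GATTACA", dm),
                   strsplit("GATTACA", "")[[1]])
  set.seed(31)
  for (i in 1:50) {
    dict <- random_dictionary()
    s <- random_dna(1, sample(4:12, 1))
    got <- viterbi_segment(s, dict)
    expect_identical(got, enum_viterbi(s, dict))
    expect_identical(paste(got, collapse = ""), s)
  }
})

test_that("dictionary TSV round-trips bit-exactly", {
  set.seed(41)
  dict <- em_fit(random_dna(10, 30), random_dictionary())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(dict, f)
  back <- read_dictionary(f)
  expect_identical(back$p[sort(names(back$p))], dict$p[sort(names(dict$p))])
})
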