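test_that("metrics match hand-computed values and handle degenerate columns", {
  m <- compute_metrics(c(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(c(m$Acc, m$Sn, m$Sp, m$MCC), c(1, 1, 1, 1))

  m <- compute_metrics(c(TP = 3, FP = 1, TN = 2, FN = 2))
  expect_equal(m$Acc, 0.625)
  expect_equal(m$Sn, 0.6)
  expect_equal(m$Sp, 2 / 3)
  expect_equal(m$MCC, 4 / sqrt(240), tolerance = 1e-12)

  m <- compute_metrics(c(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_equal(m$Sn, 0)
  expect_equal(m$Sp, 1)
  expect_equal(m$MCC, 0)
  expect_true(m$mcc_undefined)
  expect_error(compute_metrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

test_that("Acc equals the prevalence-weighted combination of Sn and Sp", {
  set.seed(1)
  for (i in 1:20) {
    cnt <- c(TP = sample(0:20, 1), FP = sample(0:20, 1),
             TN = sample(0:20, 1), FN = sample(0:20, 1))
    if (sum(cnt) == 0) next
    m <- compute_metrics(cnt)
    P <- cnt["TP"] + cnt["FN"]; N <- cnt["TN"] + cnt["FP"]
    if (P > 0 && N > 0)
      expect_equal(m$Acc, unname((m$Sn * P + m$Sp * N) / (P + N)),
                   tolerance = 1e-12)
    expect_gte(m$MCC, -1); expect_lte(m$MCC, 1)
  }
})

test_that("cv plans partition records, stratify, and are seed-deterministic", {
  ds <- simulate_dataset(simulation_config(n_non = 50L, n_strong = 25L,
                                           n_weak = 25L, length = 40L,
                                           motif_length = 6L, strong_dosage = 3L,
                                           weak_dosage = 1L, seed = 2L))
  plan <- make_cv_plan(ds, k = 10L, seed = 3L)
  expect_length(plan$folds, 10L)
  ids <- unlist(plan$folds)
  expect_setequal(ids, ds$id)
  expect_equal(anyDuplicated(ids), 0L)
  # per-class counts across folds differ by at most 1 (stratification)
  cls <- ds$strength_label
  for (cl in unique(cls)) {
    per_fold <- vapply(plan$folds, function(f)
      sum(cls[match(f, ds$id)] == cl), integer(1))
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
  plan2 <- make_cv_plan(ds, k = 10L, seed = 3L)
  expect_identical(plan, plan2)
  expect_error(make_cv_plan(ds, k = 30L, seed = 1L), "smallest class")
})

test_that("composition profiles pool counts and sum to one", {
  p <- composition_profile("AATT")
  expect_equal(unname(p), c(0.5, 0, 0, 0.5))
  set.seed(4)
  seqs <- random_dna(5, 60)
  expect_equal(sum(composition_profile(seqs)), 1, tolerance = 1e-12)
  # pooled profile of equal-length sequences = mean of individual profiles
  two <- random_dna(2, 50)
  expect_equal(composition_profile(two),
               (composition_profile(two[1]) + composition_profile(two[2])) / 2,
               tolerance = 1e-12)
})

test_that("physicochemical profiles average over all overlapping trinucleotides", {
  tab <- read_property_table()
  expect_equal(dim(tab), c(64L, 5L))
  const <- tab; const[] <- 3.14
  expect_equal(unname(physchem_profile("ACGTT", const)), rep(3.14, 5))
  expect_equal(physchem_profile("ACGT", tab),
               colMeans(tab[c("ACG", "CGT"), ]), tolerance = 1e-12)
  set.seed(5)
  seqs <- random_dna(4, 30)
  naive <- colMeans(tab[unlist(lapply(seqs, function(s)
    substring(s, 1:(nchar(s) - 2), 3:nchar(s)))), ])
  expect_equal(physchem_profile(seqs, tab), naive, tolerance = 1e-12)
})

test_that("real-vs-generated reports have the documented shape and symmetry", {
  set.seed(6)
  real <- random_dna(5, 40); gen <- random_dna(5, 40)
  rep1 <- compare_real_generated(real, gen)
  expect_equal(nrow(rep1), 9L)  # 4 composition + 5 properties
  expect_equal(rep1$abs_diff, abs(rep1$real - rep1$generated))
  rep2 <- compare_real_generated(gen, real)
  expect_equal(rep1$abs_diff, rep2$abs_diff, tolerance = 1e-12)
  same <- compare_real_generated(real, real)
  expect_true(all(same$abs_diff == 0))
})

test_that("run_cv evaluates every real record once, without augmentation, on separable data", {
  # widen the compositional gap so the fixture is trivially separable
  ds <- simulate_dataset(simulation_config(
    n_non = 30L, n_strong = 15L, n_weak = 15L, length = 60L,
    at_bias = c(A = 0.40, C = 0.10, G = 0.10, T = 0.40),
    motif_length = 6L, strong_dosage = 4L, weak_dosage = 1L, seed = 7L))
  cfg <- cv_config(
    scheme = "overlapped3", layers = "first", augment = FALSE, fast = TRUE,
    embed_cfg = skipgram_config(dim = 8L, epochs = 2L, negatives = 3L, seed = 8L),
    cnn_cfg = cnn_config(kernel_heights = c(2L, 3L), kernels_per_height = 8L,
                         embed_dim = 8L, max_words = 58L, epochs = 15L,
                         batch_size = 16L, dropout = 0.2, val_fraction = 0,
                         lr = 5e-3, seed = 9L))
  res <- run_cv(ds, k = 5L, seed = 10L, config = cfg)
  expect_equal(nrow(res$per_fold), 5L)
  expect_true(all(unlist(res$audit)))
  expect_gt(res$metrics$first$Acc, 0.95)
  fake <- dna_dataset("g1", random_dna(1, 60), "enhancer", "strong",
                      provenance = "generated")
  both <- rbind(ds, fake)
  class(both) <- c("dna_dataset", "data.frame")
  expect_error(run_cv(both, k = 5L, seed = 1L, config = cfg),
               "real records only")
})
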