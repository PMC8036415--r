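# Fixture builders and independent oracles. Oracles are deliberately naive
# (enumeration, double loops) and never share code with the implementation
# paths they check.

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = ""),
    character(1))
}

# A random dictionary over words of length 1..3 that always contains the
# four mononucleotides (so every sequence is segmentable).
random_dictionary <- function(extra_words = 6L) {
  kmers2 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T")),
                  1, paste0, collapse = "")
  kmers3 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste0, collapse = "")
  words <- c("A", "C", "G", "T",
             sample(c(kmers2, kmers3), extra_words))
  p <- runif(length(words), 0.05, 1)
  unigram_dictionary(setNames(p, words))
}

# All segmentations of a sequence into dictionary words (list of character
# vectors), by exhaustive recursion.
enumerate_segmentations <- function(seq, words) {
  n <- nchar(seq)
  if (n == 0L) return(list(character(0)))
  out <- list()
  for (w in words) {
    lw <- nchar(w)
    if (lw <= n && substr(seq, 1L, lw) == w) {
      for (rest in enumerate_segmentations(substr(seq, lw + 1L, n), words))
        out[[length(out) + 1L]] <- c(w, rest)
    }
  }
  out
}

# Brute-force marginal log-likelihood by full enumeration.
enum_loglik <- function(seq, dict) {
  segs <- enumerate_segmentations(seq, names(dict$p))
  if (!length(segs)) return(-Inf)
  log(sum(vapply(segs, function(s) prod(dict$p[s]), numeric(1))))
}

# Brute-force best segmentation with the implementation's tie-break rules
# (max probability, then fewest words, then lexicographically smallest
# word sequence) applied over the explicit enumeration.
enum_viterbi <- function(seq, dict) {
  segs <- enumerate_segmentations(seq, names(dict$p))
  scores <- vapply(segs, function(s) sum(log(dict$p[s])), numeric(1))
  best <- which(scores > max(scores) - 1e-9)  # same tie margin as the DP
  cand <- segs[best]
  nw <- lengths(cand)
  cand <- cand[nw == min(nw)]
  keys <- vapply(cand, paste, character(1), collapse = " ")
  cand[[order(keys)[1L]]]
}

# Brute-force EM over explicitly enumerated segmentations.
enum_em <- function(corpus, p0, iters) {
  p <- p0 / sum(p0)
  for (it in seq_len(iters)) {
    cnt <- setNames(numeric(length(p)), names(p))
    for (s in corpus) {
      segs <- enumerate_segmentations(s, names(p))
      wts <- vapply(segs, function(sg) prod(p[sg]), numeric(1))
      wts <- wts / sum(wts)
      for (k in seq_along(segs))
        for (w in segs[[k]]) cnt[w] <- cnt[w] + wts[k]
    }
    p <- cnt / sum(cnt)
  }
  p
}

# Naive double-loop convolution oracle (no ReLU).
naive_conv <- function(x, W, b) {
  m <- nrow(W)
  vapply(seq_len(nrow(x) - m + 1L), function(i) {
    acc <- 0
    for (r in seq_len(m)) for (c in seq_len(ncol(x)))
      acc <- acc + W[r, c] * x[i + r - 1L, c]
    acc + b
  }, numeric(1))
}

# O(L^2) sliding ungapped identity oracle.
naive_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- 0L
  for (shift in -(lb - 1L):(la - 1L)) {
    i <- max(1L, 1L + shift):min(la, lb + shift)
    m <- sum(av[i] == bv[i - shift])
    if (m > best) best <- m
  }
  best / min(la, lb)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Small labelled dataset used across seq_io tests.
toy_dataset <- function() {
  dna_dataset(
    id = paste0("s", 1:9),
    seq = random_dna(9, 30, seed = 42),
    enhancer_label = rep(c("enhancer", "enhancer", "non_enhancer"), c(3, 2, 4)),
    strength_label = rep(c("strong", "weak", "not_applicable"), c(3, 2, 4)))
}
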