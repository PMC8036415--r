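# Benchmark-shaped synthetic data. The generator emulates the statistical
# structure of the enhancer benchmark: 200-bp sequences over {A,C,G,T}, a
# negative class with elevated A/T frequency, a positive class with
# near-uniform composition, and a strength signal encoded as the dosage of
# planted motif words (strong enhancers carry more planted occurrences
# than weak ones). Strength-as-dosage is a documented stand-in: the real
# benchmark gives no generative description of strong vs weak.

#' Simulation configuration
#'
#' Defaults mirror the benchmark shape: 1484 non-enhancers and 742 strong +
#' 742 weak enhancers of 200 bp; negatives drawn with A = T = 0.30,
#' C = G = 0.20 and enhancers with uniform base composition. Motif words
#' default to two 8-mers drawn from the simulation seed (so tests cannot
#' overfit to a fixed motif); strong enhancers carry 8 planted occurrences
#' per sequence and weak enhancers 1.
#'
#' @param n_non,n_strong,n_weak class sizes.
#' @param length sequence length in nucleotides.
#' @param at_bias named base distribution of the negative class.
#' @param positive_comp base distribution of the positive class.
#' @param motif_words planted words (NULL = derive from seed).
#' @param n_motifs number of derived motif words.
#' @param motif_length length of derived motif words.
#' @param strong_dosage,weak_dosage planted occurrences per sequence.
#' @param seed RNG seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_non = 1484L, n_strong = 742L, n_weak = 742L,
                              length = 200L,
                              at_bias = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
                              positive_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                              motif_words = NULL, n_motifs = 2L,
                              motif_length = 8L,
                              strong_dosage = 8L, weak_dosage = 1L,
                              seed = 1L) {
  stopifnot(abs(sum(at_bias) - 1) < 1e-9, abs(sum(positive_comp) - 1) < 1e-9,
            strong_dosage > weak_dosage, weak_dosage >= 0L)
  if (!is.null(motif_words)) motif_words <- toupper(as.character(motif_words))
  structure(list(n_non = as.integer(n_non), n_strong = as.integer(n_strong),
                 n_weak = as.integer(n_weak), length = as.integer(length),
                 at_bias = at_bias[DNA_BASES], positive_comp = positive_comp[DNA_BASES],
                 motif_words = motif_words, n_motifs = as.integer(n_motifs),
                 motif_length = as.integer(motif_length),
                 strong_dosage = as.integer(strong_dosage),
                 weak_dosage = as.integer(weak_dosage),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Benchmark-shaped preset
#'
#' `preset = "benchmark"` reproduces the benchmark class sizes
#' (1484 non-enhancers, 742 strong, 742 weak); `scale` shrinks all three
#' proportionally (e.g. `scale = 400/2968` for a 400-record first layer).
#'
#' @param preset currently only "benchmark".
#' @param scale total-size multiplier.
#' @param ... overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
simulation_preset <- function(preset = "benchmark", scale = 1, ...) {
  stopifnot(preset == "benchmark")
  simulation_config(n_non = max(1L, round(1484L * scale)),
                    n_strong = max(1L, round(742L * scale)),
                    n_weak = max(1L, round(742L * scale)), ...)
}

random_seq <- function(n, len, comp) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE, prob = comp), collapse = ""),
    character(1))
}

# Non-overlapping uniform-random start positions for `dosage` planted
# words of length w in a sequence of length L (rejection sampling).
plant_positions <- function(dosage, w, L) {
  if (dosage == 0L) return(integer(0))
  if (dosage * w > L) stop("dosage x motif length exceeds the sequence length")
  repeat {
    pos <- sort(sample.int(L - w + 1L, dosage))
    if (dosage == 1L || all(diff(pos) >= w)) return(pos)
  }
}

#' Simulate a benchmark-shaped labelled dataset
#'
#' Negatives are i.i.d. draws from the A/T-biased composition; enhancers
#' are drawn from the near-uniform composition and receive `strong_dosage`
#' (strong) or `weak_dosage` (weak) planted motif words at non-overlapping
#' uniform-random positions. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A `dna_dataset` with ground-truth labels; the motif words used
#'   are attached as the `"motif_words"` attribute.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  with_seed(config$seed, {
    motifs <- config$motif_words %||%
      random_seq(config$n_motifs, config$motif_length, c(.25, .25, .25, .25))
    w <- nchar(motifs[1])
    if (!all(nchar(motifs) == w)) stop("motif words must share one length")
    plant <- function(seqs, dosage) {
      vapply(seqs, function(s) {
        for (p in plant_positions(dosage, w, nchar(s)))
          substr(s, p, p + w - 1L) <- sample(motifs, 1L)
        s
      }, character(1), USE.NAMES = FALSE)
    }
    non <- random_seq(config$n_non, config$length, config$at_bias)
    strong <- plant(random_seq(config$n_strong, config$length, config$positive_comp),
                    config$strong_dosage)
    weak <- plant(random_seq(config$n_weak, config$length, config$positive_comp),
                  config$weak_dosage)
    ds <- dna_dataset(
      id = c(sprintf("non_%05d", seq_len(config$n_non)),
             sprintf("strong_%05d", seq_len(config$n_strong)),
             sprintf("weak_%05d", seq_len(config$n_weak))),
      seq = c(non, strong, weak),
      enhancer_label = rep(c("non_enhancer", "enhancer", "enhancer"),
                           c(config$n_non, config$n_strong, config$n_weak)),
      strength_label = rep(c("not_applicable", "strong", "weak"),
                           c(config$n_non, config$n_strong, config$n_weak)))
    attr(ds, "motif_words") <- motifs
    ds
  })
}

#' Simulate a token corpus with controlled co-occurrence structure
#'
#' Fixture generator for embedding and GAN unit tests.
#' `structure = "uniform"`: words drawn uniformly, except that whenever the
#' designated word P is emitted, Q follows with probability `p_cooccur`.
#' `structure = "blocks"`: each sequence draws only from the first or the
#' second half of the vocabulary (chosen at random), so words from
#' different halves *never* co-occur, while the (P, Q) adjacency rule still
#' applies within the first half — the fixture for the
#' "co-occurring pairs embed closer than non-co-occurring pairs" property.
#'
#' @param vocab_size vocabulary size (words are the first `vocab_size`
#'   trinucleotides).
#' @param n number of sequences.
#' @param length words per sequence.
#' @param p_cooccur probability that Q follows P.
#' @param pair indices of (P, Q) in the vocabulary.
#' @param structure "uniform" or "blocks".
#' @param seed RNG seed.
#' @return List of word sequences with the vocabulary as attribute
#'   `"vocab"`.
#' @export
simulate_token_corpus <- function(vocab_size = 16L, n = 50L, length = 40L,
                                  p_cooccur = 0, pair = c(1L, 2L),
                                  structure = c("uniform", "blocks"),
                                  seed = 1L) {
  structure_kind <- match.arg(structure)
  words <- sort(all_kmers(3L))[seq_len(vocab_size)]
  half <- vocab_size %/% 2L
  with_seed(seed, {
    corpus <- lapply(seq_len(n), function(i) {
      pool <- switch(structure_kind,
        uniform = seq_len(vocab_size),
        blocks = if (runif(1) < 0.5) seq_len(half)
                 else (half + 1L):vocab_size)
      idx <- sample(pool, length, replace = TRUE)
      if (p_cooccur > 0 && pair[1L] %in% pool) {
        for (t in seq_len(length - 1L)) {
          if (idx[t] == pair[1L] && runif(1) < p_cooccur) idx[t + 1L] <- pair[2L]
        }
      }
      words[idx]
    })
    attr(corpus, "vocab") <- base::structure(words, class = "dna_vocabulary")
    corpus
  })
}
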