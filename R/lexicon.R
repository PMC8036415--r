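# Statistics-based word segmentation: a unigram language model over DNA
# words. The dictionary is seeded by byte-pair encoding, its probabilities
# are fitted by EM over the marginal likelihood of all segmentations, low-
# value words are pruned by their likelihood loss, and sequences are
# segmented by the maximum-probability path of the segmentation lattice
# (Viterbi). The four mononucleotides are protected so every A/C/G/T
# sequence remains segmentable.

#' Construct a unigram word dictionary
#'
#' Builds the word -> probability table driving statistical segmentation.
#' Probabilities are normalised to sum to 1. Dictionaries produced by
#' [learn_dictionary()] always contain the four mononucleotides (so every
#' sequence stays segmentable); hand-built dictionaries may omit them, in
#' which case segmentation of some sequences can fail.
#'
#' @param p named numeric vector of positive word weights.
#' @param l_max maximum word length considered when matching.
#' @return A `unigram_dictionary`.
#' @export
unigram_dictionary <- function(p, l_max = 8L) {
  stopifnot(is.numeric(p), !is.null(names(p)), all(p > 0),
            all(grepl("^[ACGT]+$", names(p))), !anyDuplicated(names(p)))
  p <- p / sum(p)
  structure(list(p = p, l_max = as.integer(max(l_max, nchar(names(p))))),
            class = "unigram_dictionary")
}

new_unigram_dictionary <- unigram_dictionary

#' Lexicon training configuration
#'
#' @param target_size final dictionary size (150 by default, giving the
#'   statistical scheme its 150-word vocabulary).
#' @param keep_fraction fraction of non-protected words retained per
#'   pruning round (0.70).
#' @param seed_size BPE seed dictionary size before pruning (default 1000).
#' @param l_max maximum word length in nucleotides (default 8).
#' @param em_tol relative log-likelihood convergence tolerance for EM.
#' @param em_max_iter EM iteration cap.
#' @return A list of class `lexicon_config`.
#' @export
lexicon_config <- function(target_size = 150L, keep_fraction = 0.70,
                           seed_size = 1000L, l_max = 8L,
                           em_tol = 1e-6, em_max_iter = 50L) {
  stopifnot(target_size >= 4L, keep_fraction > 0, keep_fraction < 1,
            seed_size >= target_size, l_max >= 1L)
  structure(list(target_size = as.integer(target_size),
                 keep_fraction = keep_fraction,
                 seed_size = as.integer(seed_size),
                 l_max = as.integer(l_max),
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter)),
            class = "lexicon_config")
}

check_dictionary <- function(dict, require_bases = FALSE) {
  stopifnot(inherits(dict, "unigram_dictionary"))
  if (abs(sum(dict$p) - 1) > 1e-9) stop("dictionary probabilities must sum to 1")
  if (any(dict$p <= 0)) stop("dictionary probabilities must be positive")
  if (require_bases && !all(DNA_BASES %in% names(dict$p)))
    stop("dictionary must contain all four mononucleotides")
  invisible(dict)
}

# floor tiny probabilities so log() stays finite; warn once per call
floor_probs <- function(p) {
  if (any(p < 1e-300)) {
    warning("probabilities below 1e-300 floored")
    p <- pmax(p, 1e-300)
  }
  p / sum(p)
}

#' Seed a unigram dictionary by byte-pair encoding
#'
#' Starting from the four mononucleotides, the most frequent adjacent
#' symbol pair is merged repeatedly (ties broken lexicographically, merged
#' symbols capped at `l_max` characters) until `seed_size` symbols exist or
#' no pair occurs at least twice. Initial probabilities are proportional to
#' the add-one-smoothed token counts of each symbol in the final merge
#' tokenisation, so protected symbols that were merged away keep a small
#' positive probability.
#'
#' @param corpus character vector of A/C/G/T sequences (or a `dna_dataset`).
#' @param config a [lexicon_config()].
#' @return A `unigram_dictionary`.
#' @export
bpe_seed <- function(corpus, config = lexicon_config()) {
  seqs <- corpus_seqs(corpus)
  if (sum(nchar(seqs)) < 2L) stop("corpus must contain at least 2 nucleotides")
  res <- cpp_bpe_seed(seqs, config$seed_size, config$l_max)
  p <- setNames(res$counts + 1, res$words)
  new_unigram_dictionary(p[order(names(p))], config$l_max)
}

corpus_seqs <- function(corpus) {
  if (inherits(corpus, "dna_dataset")) corpus <- corpus$seq
  seqs <- toupper(as.character(corpus))
  if (!length(seqs)) stop("empty corpus")
  if (any(grepl("[^ACGT]", seqs))) stop("corpus contains non-ACGT characters")
  seqs
}

#' Marginal log-likelihood of a corpus under a unigram dictionary
#'
#' For each sequence, sums the probabilities of *all* its segmentations
#' (each segmentation's probability is the product of its word
#' probabilities) by a forward pass over the segmentation lattice in log
#' space, and returns the total log value across the corpus.
#'
#' @param corpus sequences (character vector or `dna_dataset`).
#' @param dict a `unigram_dictionary`.
#' @return Total log-likelihood (scalar); per-sequence values as the
#'   `"per_sequence"` attribute.
#' @export
marginal_log_likelihood <- function(corpus, dict) {
  check_dictionary(dict)
  seqs <- corpus_seqs(corpus)
  ll <- cpp_corpus_loglik(seqs, names(dict$p), log(dict$p), dict$l_max)
  if (any(!is.finite(ll))) stop("unsegmentable sequence in corpus")
  structure(sum(ll), per_sequence = ll)
}

#' Fit word probabilities by EM over all segmentations
#'
#' E-step: expected word counts from forward-backward posteriors over each
#' sequence's segmentation lattice (every segmentation weighted by its
#' probability, not Viterbi-only). M-step: probabilities proportional to
#' expected counts. Iterates until the relative log-likelihood improvement
#' drops below `em_tol` or `em_max_iter` is hit; the likelihood is
#' non-decreasing along the way.
#'
#' @param corpus sequences (character vector or `dna_dataset`).
#' @param dict starting `unigram_dictionary`.
#' @param config a [lexicon_config()].
#' @return The fitted dictionary, with the log-likelihood trace in the
#'   `"loglik_trace"` attribute.
#' @export
em_fit <- function(corpus, dict, config = lexicon_config()) {
  check_dictionary(dict)
  seqs <- corpus_seqs(corpus)
  words <- names(dict$p)
  p <- dict$p
  trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(config$em_max_iter)) {
    es <- cpp_expected_counts(seqs, words, log(p), dict$l_max)
    trace <- c(trace, es$loglik)
    cnt <- es$counts
    p_new <- floor_probs(setNames(cnt, words))
    rel <- abs(es$loglik - prev) / max(1, abs(es$loglik))
    p <- p_new
    if (is.finite(prev) && rel < config$em_tol) break
    prev <- es$loglik
  }
  out <- new_unigram_dictionary(p, dict$l_max)
  attr(out, "loglik_trace") <- trace
  out
}

#' One loss-ranked pruning round
#'
#' For every non-protected word, computes `loss = L(dict) - L(dict without
#' the word, renormalised)` against the current fitted probabilities
#' (without per-candidate EM refits). Words are ranked by loss descending
#' and the top `keep_fraction` of the non-protected words are retained,
#' together with the four mononucleotides; ties break by higher
#' probability, then lexicographically. `min_keep` (used by
#' [learn_dictionary()]) clamps the retained count so the final round lands
#' exactly on the target size.
#'
#' @param corpus sequences.
#' @param dict fitted `unigram_dictionary`.
#' @param config a [lexicon_config()].
#' @param min_keep lower clamp for the number of retained non-protected words.
#' @return The pruned, renormalised dictionary.
#' @export
prune_step <- function(corpus, dict, config = lexicon_config(), min_keep = 0L) {
  check_dictionary(dict)
  seqs <- corpus_seqs(corpus)
  words <- names(dict$p)
  prot <- words %in% DNA_BASES
  loss <- cpp_prune_losses(seqs, words, log(dict$p), dict$l_max, prot)
  np <- which(!prot)
  n_keep <- min(length(np), max(ceiling(config$keep_fraction * length(np)), min_keep))
  ord <- np[order(-loss[np], -dict$p[np], words[np])]
  keep <- sort(c(which(prot), ord[seq_len(n_keep)]))
  new_unigram_dictionary(floor_probs(dict$p[keep]), dict$l_max)
}

#' Learn a unigram segmentation dictionary from a corpus
#'
#' BPE seeding, then alternating EM fits and loss-ranked pruning rounds
#' until the dictionary reaches `target_size` (the last round clamps to the
#' target exactly), followed by one final EM fit. Deterministic given the
#' corpus and config.
#'
#' @param corpus sequences (character vector or `dna_dataset`).
#' @param config a [lexicon_config()].
#' @return A `unigram_dictionary` of exactly `target_size` words.
#' @export
learn_dictionary <- function(corpus, config = lexicon_config()) {
  seqs <- corpus_seqs(corpus)
  dict <- bpe_seed(seqs, config)
  target <- config$target_size
  while (length(dict$p) > target) {
    dict <- em_fit(seqs, dict, config)
    dict <- prune_step(seqs, dict, config, min_keep = target - 4L)
  }
  dict <- em_fit(seqs, dict, config)
  dict
}

#' Viterbi segmentation of a sequence
#'
#' Returns the segmentation maximising the sum of log word probabilities
#' over all lattice paths. Ties are broken towards fewer words, then the
#' lexicographically smallest word sequence. The words concatenate back to
#' the input.
#'
#' @param seq a single A/C/G/T string.
#' @param dict a `unigram_dictionary`.
#' @return Character vector of words.
#' @export
viterbi_segment <- function(seq, dict) {
  check_dictionary(dict)
  seq <- check_dna_string(seq)
  cpp_viterbi(seq, names(dict$p), log(dict$p), dict$l_max)
}

#' Write / read a dictionary as a `word<TAB>probability` TSV
#'
#' Probabilities are written with 17 significant digits so a reload is
#' bit-exact.
#'
#' @param dict a `unigram_dictionary`.
#' @param path file path.
#' @return `path` (write) or a `unigram_dictionary` (read).
#' @export
write_dictionary <- function(dict, path) {
  check_dictionary(dict)
  writeLines(sprintf("%s\t%.17g", names(dict$p), dict$p), path)
  invisible(path)
}

#' @rdname write_dictionary
#' @param l_max maximum word length recorded with the reloaded dictionary.
#' @export
read_dictionary <- function(path, l_max = NULL) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("word", "p"))
  if (is.null(l_max)) l_max <- max(nchar(tab$word))
  structure(list(p = setNames(tab$p, tab$word), l_max = as.integer(l_max)),
            class = "unigram_dictionary")
}

#' @export
print.unigram_dictionary <- function(x, ...) {
  cat(sprintf("<unigram_dictionary> %d words, max length %d\n",
              length(x$p), x$l_max))
  invisible(x)
}
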