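# Deterministic n-gram word segmentation of DNA sequences.
#
# Three schemes are used downstream:
#   * overlapped 3-gram  (stride 1): classifier/embedding input, V = 64
#   * non-overlapped 3-gram with offsets 1..3: classifier/embedding input,
#     dictionary = 4 mono + 16 di + 64 trinucleotides, V = 84
#   * non-overlapped 2-gram: pre-segmentation for the sequence GAN, V = 16
# Word sequences are plain character vectors; a sequence's words always
# concatenate back to its residues under the non-overlapped schemes.

check_dna_string <- function(seq) {
  if (length(seq) != 1L || is.na(seq)) stop("expected a single DNA string")
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence contains characters outside {A,C,G,T}")
  seq
}

#' Overlapped 3-gram segmentation
#'
#' Slides a window of width 3 with stride 1, producing `nchar(seq) - 2`
#' trinucleotide words.
#'
#' @param seq a single A/C/G/T string of length >= 3.
#' @return Character vector of words.
#' @export
overlapped_3gram <- function(seq) {
  seq <- check_dna_string(seq)
  n <- nchar(seq)
  if (n < 3L) stop("overlapped 3-gram needs length >= 3")
  substring(seq, 1:(n - 2L), 3:n)
}

#' Non-overlapped 3-gram segmentation at offsets 1..3
#'
#' Windows of width 3 move with stride 3 starting at position k (k = 1, 2, 3).
#' For k > 1 the leading k-1 residues are emitted as a short word, and any
#' trailing 1- or 2-residue fragment is emitted as well, so each offset's
#' words concatenate back to the sequence. Emitted word lengths are always
#' in {1, 2, 3}, which is what makes the 4 + 16 + 64 = 84-word dictionary
#' cover every word.
#'
#' @param seq a single A/C/G/T string of length >= 3.
#' @param offsets "concat" (default) joins the three offset segmentations
#'   in order 1, 2, 3 into one word sequence; "separate" returns a list of
#'   the three word sequences.
#' @return Character vector ("concat") or list of three character vectors.
#' @export
non_overlapped_3gram <- function(seq, offsets = c("concat", "separate")) {
  offsets <- match.arg(offsets)
  seq <- check_dna_string(seq)
  n <- nchar(seq)
  if (n < 3L) stop("non-overlapped 3-gram needs length >= 3")
  one <- function(k) {
    words <- character(0)
    if (k > 1L) words <- substr(seq, 1L, k - 1L)
    m <- (n - k + 1L) %/% 3L
    if (m > 0L) {
      starts <- k + 3L * (seq_len(m) - 1L)
      words <- c(words, substring(seq, starts, starts + 2L))
    }
    rest <- (n - k + 1L) %% 3L
    if (rest > 0L) words <- c(words, substr(seq, n - rest + 1L, n))
    words
  }
  out <- lapply(1:3, one)
  if (offsets == "concat") unlist(out) else out
}

#' Non-overlapped 2-gram segmentation
#'
#' Dinucleotide tokens with stride 2; odd-length sequences end in a single
#' trailing mononucleotide token. This is the pre-segmentation used by the
#' sequence GAN (a 200-bp sequence becomes 100 tokens).
#'
#' @param seq a single A/C/G/T string of length >= 2.
#' @return Character vector of tokens.
#' @export
non_overlapped_2gram <- function(seq) {
  seq <- check_dna_string(seq)
  n <- nchar(seq)
  if (n < 2L) stop("non-overlapped 2-gram needs length >= 2")
  starts <- seq(1L, n, by = 2L)
  substring(seq, starts, pmin(starts + 1L, n))
}

all_kmers <- function(k) {
  if (k == 1L) return(DNA_BASES)
  apply(expand.grid(rev(replicate(k, DNA_BASES, simplify = FALSE)))[, k:1, drop = FALSE],
        1L, paste0, collapse = "")
}

#' Build the word vocabulary of a segmentation scheme
#'
#' Fixed-size vocabularies are enumerated lexicographically: 64 words for
#' the overlapped 3-gram scheme, 84 (4 mono- + 16 di- + 64 trinucleotides)
#' for the non-overlapped 3-gram scheme, and 16 dinucleotides for the
#' 2-gram GAN tokens. The statistical scheme takes its words from a learned
#' unigram dictionary (150 words by default).
#'
#' @param scheme one of "overlapped3", "nonoverlapped3", "nonoverlapped2",
#'   "statistical".
#' @param dictionary a `unigram_dictionary`, required for the statistical
#'   scheme.
#' @return A `dna_vocabulary`: a character vector of words whose position is
#'   the word index.
#' @export
build_vocabulary <- function(scheme = c("overlapped3", "nonoverlapped3",
                                        "nonoverlapped2", "statistical"),
                             dictionary = NULL) {
  scheme <- match.arg(scheme)
  words <- switch(scheme,
    overlapped3 = sort(all_kmers(3L)),
    nonoverlapped3 = c(sort(all_kmers(1L)), sort(all_kmers(2L)), sort(all_kmers(3L))),
    nonoverlapped2 = sort(all_kmers(2L)),
    statistical = {
      if (is.null(dictionary)) stop("the statistical scheme needs a learned dictionary")
      sort(names(dictionary$p))
    })
  structure(words, class = "dna_vocabulary", scheme = scheme)
}

#' Map words to vocabulary indices
#'
#' @param words character vector of words.
#' @param vocab a `dna_vocabulary`.
#' @return Integer indices in 1..length(vocab); unknown words are an error.
#' @export
words_to_indices <- function(words, vocab) {
  idx <- match(words, vocab)
  if (anyNA(idx))
    stop("word(s) outside the vocabulary: ",
         paste(unique(words[is.na(idx)]), collapse = ", "))
  idx
}

#' Write / read a vocabulary as a `word<TAB>index` TSV
#'
#' @param vocab a `dna_vocabulary`.
#' @param path file path.
#' @return `path` (write) or a `dna_vocabulary` (read).
#' @export
write_vocabulary <- function(vocab, path) {
  write.table(data.frame(word = as.character(vocab), index = seq_along(vocab)),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("word", "index"))
  structure(tab$word[order(tab$index)], class = "dna_vocabulary")
}

#' @export
print.dna_vocabulary <- function(x, ...) {
  cat(sprintf("<dna_vocabulary> V = %d (%s)\n", length(x),
              attr(x, "scheme") %||% "custom"))
  invisible(x)
}

#' Tokenize every sequence of a dataset
#'
#' @param ds a `dna_dataset`.
#' @param scheme segmentation scheme (see [build_vocabulary()]); for
#'   "statistical" a `dictionary` must be supplied.
#' @param dictionary a `unigram_dictionary` for the statistical scheme.
#' @return Named list of word sequences (character vectors), one per record.
#' @export
tokenize_dataset <- function(ds, scheme = "overlapped3", dictionary = NULL) {
  f <- switch(scheme,
    overlapped3 = overlapped_3gram,
    nonoverlapped3 = function(s) non_overlapped_3gram(s, "concat"),
    nonoverlapped2 = non_overlapped_2gram,
    statistical = {
      if (is.null(dictionary)) stop("the statistical scheme needs a dictionary")
      function(s) viterbi_segment(s, dictionary)
    },
    stop("unknown scheme: ", scheme))
  setNames(lapply(ds$seq, f), ds$id)
}
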