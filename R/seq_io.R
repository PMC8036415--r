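# Reading, writing and validating labelled DNA datasets.
#
# A dataset is a plain data.frame with class "dna_dataset" and columns
#   id, seq, enhancer_label, strength_label, provenance
# enhancer_label in {"enhancer","non_enhancer"}, strength_label in
# {"strong","weak","not_applicable"}, provenance in {"real","generated"}.

ENHANCER_LABELS <- c("enhancer", "non_enhancer")
STRENGTH_LABELS <- c("strong", "weak", "not_applicable")
PROVENANCE_LABELS <- c("real", "generated")

#' Construct a labelled DNA dataset
#'
#' Builds and validates the container used throughout the package: one row
#' per sequence, with a two-layer label (enhancer vs non-enhancer, and for
#' enhancers strong vs weak) and a provenance flag separating real records
#' from GAN-generated ones. Generated records are never counted by the
#' evaluation code.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of A/C/G/T strings (lowercase accepted).
#' @param enhancer_label "enhancer" or "non_enhancer" (recycled).
#' @param strength_label "strong", "weak" or "not_applicable" (recycled);
#'   must be "not_applicable" exactly when the record is a non-enhancer.
#' @param provenance "real" or "generated" (recycled).
#' @return A `dna_dataset` (a data.frame).
#' @export
dna_dataset <- function(id, seq,
                        enhancer_label = "non_enhancer",
                        strength_label = "not_applicable",
                        provenance = "real") {
  n <- length(seq)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  ds <- data.frame(
    id = id,
    seq = seq,
    enhancer_label = rep_len(as.character(enhancer_label), n),
    strength_label = rep_len(as.character(strength_label), n),
    provenance = rep_len(as.character(provenance), n),
    stringsAsFactors = FALSE
  )
  class(ds) <- c("dna_dataset", "data.frame")
  validate_dna_dataset(ds)
  ds
}

#' Validate a DNA dataset
#'
#' Checks the container invariants: a strict A/C/G/T alphabet (ambiguity
#' codes such as N are rejected, not dropped, because every downstream
#' vocabulary assumes a 4-letter alphabet), unique non-empty ids, and label
#' consistency (a strength label only applies to enhancers).
#'
#' @param ds a `dna_dataset`.
#' @return `ds`, invisibly, if valid; otherwise an error.
#' @export
validate_dna_dataset <- function(ds) {
  stopifnot(is.data.frame(ds))
  if (nrow(ds) == 0L) return(invisible(ds))
  if (any(is.na(ds$id) | !nzchar(ds$id)))
    stop("all sequence ids must be non-empty")
  dup <- ds$id[duplicated(ds$id)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  bad <- grepl("[^ACGT]", ds$seq) | !nzchar(ds$seq)
  if (any(bad))
    stop("sequence(s) with characters outside {A,C,G,T} (or empty): ",
         paste(ds$id[bad], collapse = ", "))
  if (!all(ds$enhancer_label %in% ENHANCER_LABELS))
    stop("enhancer_label must be one of: ", paste(ENHANCER_LABELS, collapse = ", "))
  if (!all(ds$strength_label %in% STRENGTH_LABELS))
    stop("strength_label must be one of: ", paste(STRENGTH_LABELS, collapse = ", "))
  if (!all(ds$provenance %in% PROVENANCE_LABELS))
    stop("provenance must be one of: ", paste(PROVENANCE_LABELS, collapse = ", "))
  mism <- (ds$enhancer_label == "enhancer") != (ds$strength_label != "not_applicable")
  if (any(mism))
    stop("strength_label must be strong/weak for enhancers and ",
         "not_applicable for non-enhancers; offending id(s): ",
         paste(ds$id[mism], collapse = ", "))
  invisible(ds)
}

#' Read a FASTA file into a labelled dataset
#'
#' Parses a (possibly multi-line) FASTA file, normalises residues to upper
#' case and attaches class labels. Labels can be given directly (the usual
#' case: the benchmark is distributed as one file per class) or through a
#' TSV table `id<TAB>enhancer_label<TAB>strength_label`.
#'
#' @param path FASTA file path.
#' @param enhancer_label,strength_label labels applied to every record
#'   (ignored when `labels` is given).
#' @param labels optional path to a labels TSV, or a data.frame with
#'   columns id, enhancer_label, strength_label.
#' @param provenance provenance flag for all records (default "real").
#' @return A `dna_dataset`; record order follows the file.
#' @export
read_fasta <- function(path, enhancer_label = "non_enhancer",
                       strength_label = "not_applicable",
                       labels = NULL, provenance = "real") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) {
    return(dna_dataset(character(0), character(0)))
  }
  first <- keep[1L]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA: expected '>' header at line ", first, " of ", path)
  hdr <- startsWith(lines, ">")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)  # id = first whitespace-delimited token
  if (any(!nzchar(ids))) {
    at <- which(hdr)[!nzchar(ids)][1L]
    stop("malformed FASTA: empty header at line ", at, " of ", path)
  }
  grp <- cumsum(hdr)
  body <- !hdr & nzchar(trimws(lines))
  seqs <- vapply(seq_along(ids), function(i) {
    paste(gsub("\\s", "", lines[body & grp == i]), collapse = "")
  }, character(1))
  if (is.null(labels)) {
    ds <- dna_dataset(ids, seqs, enhancer_label, strength_label, provenance)
  } else {
    if (is.character(labels)) {
      labels <- read.delim(labels, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "enhancer_label", "strength_label"))
    }
    m <- match(ids, labels$id)
    if (anyNA(m))
      stop("labels table is missing id(s): ", paste(ids[is.na(m)], collapse = ", "))
    ds <- dna_dataset(ids, seqs, labels$enhancer_label[m],
                      labels$strength_label[m], provenance)
  }
  ds
}

#' Write a dataset to FASTA (and optionally a labels TSV)
#'
#' Bodies are wrapped at 60 characters per line. The round trip
#' `read_fasta(write_fasta(ds))` reproduces ids and residues exactly.
#'
#' @param ds a `dna_dataset`.
#' @param path output FASTA path.
#' @param labels_path optional path for a `id<TAB>enhancer_label<TAB>strength_label` TSV.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path, labels_path = NULL) {
  validate_dna_dataset(ds)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ds))) {
    writeLines(paste0(">", ds$id[i]), con)
    s <- ds$seq[i]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  if (!is.null(labels_path)) {
    write.table(ds[, c("id", "enhancer_label", "strength_label")],
                labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Assemble the first- or second-layer classification dataset
#'
#' Layer "first" keeps every record and targets enhancer vs non-enhancer;
#' layer "second" keeps only enhancers and targets strong vs weak. The
#' binary target is attached as a `label` column ("positive"/"negative").
#'
#' @param ds a `dna_dataset` with complete labels.
#' @param layer "first" or "second".
#' @return A `dna_dataset` with an extra `label` column and a `layer` attribute.
#' @export
build_layer_dataset <- function(ds, layer = c("first", "second")) {
  layer <- match.arg(layer)
  validate_dna_dataset(ds)
  if (layer == "first") {
    out <- ds
    out$label <- ifelse(out$enhancer_label == "enhancer", "positive", "negative")
  } else {
    out <- ds[ds$enhancer_label == "enhancer", , drop = FALSE]
    if (nrow(out) == 0L) stop("second layer requested but the dataset has no enhancers")
    out$label <- ifelse(out$strength_label == "strong", "positive", "negative")
  }
  rownames(out) <- NULL
  class(out) <- c("dna_dataset", "data.frame")
  attr(out, "layer") <- layer
  out
}

#' @export
print.dna_dataset <- function(x, ...) {
  cat(sprintf("<dna_dataset> %d record(s)", nrow(x)))
  if (nrow(x)) {
    cat(": ", sum(x$enhancer_label == "enhancer"), " enhancer (",
        sum(x$strength_label == "strong"), " strong / ",
        sum(x$strength_label == "weak"), " weak), ",
        sum(x$enhancer_label == "non_enhancer"), " non-enhancer; ",
        sum(x$provenance == "generated"), " generated\n", sep = "")
  } else cat("\n")
  invisible(x)
}
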