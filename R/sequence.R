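## Ancestral sequences: FASTA I/O, imputation, context counting, generation --

#' Construct an ancestral sequence
#'
#' A thin container for a single chromosome-scale ancestral nucleotide
#' sequence over the alphabet `{A, C, G, T, N}`, with a label and an on-demand
#' base composition.
#'
#' @param bases Character scalar of bases (uppercased; anything outside
#'   ACGTN is mapped to N).
#' @param label Identifier for the sequence.
#' @return An object of class `ancestral_sequence`.
#' @examples
#' s <- ancestral_sequence("ACGTacgn", "toy")
#' seq_length(s)
#' base_composition(s)
#' @export
ancestral_sequence <- function(bases, label = "seq") {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  bases <- gsub("[^ACGTN]", "N", bases)
  structure(list(bases = bases, label = label), class = "ancestral_sequence")
}

#' @export
print.ancestral_sequence <- function(x, ...) {
  n <- seq_length(x)
  miss <- missing_count(x)
  cat(sprintf("<ancestral_sequence '%s': %d bp, %d missing (N)>\n",
              x$label, n, miss))
  if (n > 0) {
    shown <- substr(x$bases, 1L, min(60L, n))
    cat(sprintf("  %s%s\n", shown, if (n > 60L) "..." else ""))
  }
  invisible(x)
}

#' @rdname ancestral_sequence
#' @export
seq_length <- function(x) nchar(x$bases)

missing_count <- function(x) {
  seq_length(x) - sum(base_counts(x))
}

# Counts of A, C, G, T among non-missing sites.
base_counts <- function(x) {
  dna <- Biostrings::DNAString(x$bases)
  freq <- Biostrings::alphabetFrequency(dna)
  freq[.BASES]
}

#' Base composition of an ancestral sequence
#'
#' Relative frequencies of A, C, G, T among the non-missing sites.
#'
#' @param x An [ancestral_sequence()].
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
base_composition <- function(x) {
  counts <- base_counts(x)
  total <- sum(counts)
  if (total == 0L) stop("sequence has no non-missing bases")
  counts / total
}

#' Read and write ancestral sequences as FASTA
#'
#' `load_fasta()` reads a single-record FASTA file (multi-record files are an
#' error unless `record` selects one); bases are uppercased and characters
#' outside ACGTN mapped to N. `write_fasta()` writes the sequence back out
#' for record-keeping.
#'
#' @param path FASTA file path.
#' @param record Optional record name or index for multi-record files.
#' @param x An [ancestral_sequence()].
#' @return `load_fasta()` returns an [ancestral_sequence()].
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' write_fasta(ancestral_sequence("ACGT", "toy"), tf)
#' load_fasta(tf)
#' @export
load_fasta <- function(path, record = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) > 1L && is.null(record)) {
    stop(sprintf(
      "FASTA file has %d records; pass `record` to select one", length(set)))
  }
  if (!is.null(record)) set <- set[record]
  ancestral_sequence(as.character(set[[1L]]), label = names(set)[1L])
}

#' @rdname load_fasta
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "ancestral_sequence"))
  set <- Biostrings::DNAStringSet(x$bases)
  names(set) <- x$label
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Impute missing sites from the chromosome-wide base composition
#'
#' Replaces every N independently with a base drawn from the relative
#' frequencies of A, C, G, T among the sequence's non-missing sites (the
#' composition is computed chromosome-wide). Deterministic given `seed`; only
#' N positions are changed.
#'
#' @param x An [ancestral_sequence()] with at least one non-missing base.
#' @param seed Integer seed (or NULL to use the current RNG stream).
#' @return An [ancestral_sequence()] without missing sites.
#' @examples
#' impute_missing(ancestral_sequence("AAANA"), seed = 1)$bases  # "AAAAA"
#' @export
impute_missing <- function(x, seed = NULL) {
  stopifnot(inherits(x, "ancestral_sequence"))
  comp <- base_composition(x)  # errors on all-missing input
  chars <- strsplit(x$bases, "", fixed = TRUE)[[1L]]
  idx <- which(chars == "N")
  if (length(idx)) {
    repl <- with_seed(seed,
      sample(.BASES, length(idx), replace = TRUE, prob = comp))
    chars[idx] <- repl
  }
  ancestral_sequence(paste(chars, collapse = ""), label = x$label)
}

#' Count overlapping trinucleotides
#'
#' Counts every overlapping 3-mer of the sequence; with a sequence of length
#' L the counts total L - 2 (one triplet centred on each interior site).
#'
#' @param x An [ancestral_sequence()] without missing bases, length >= 3.
#' @return Named integer vector over the 64 triplets.
#' @examples
#' context_counts(ancestral_sequence("ACGTA"))[c("ACG", "CGT", "GTA")]
#' @export
context_counts <- function(x) {
  stopifnot(inherits(x, "ancestral_sequence"))
  if (seq_length(x) < 3L) stop("sequence shorter than 3 bases")
  if (missing_count(x) > 0L) {
    stop("sequence contains missing (N) sites; impute first")
  }
  counts <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(x$bases))
  counts[.TRIPLETS]
}

#' Generate a synthetic ancestral sequence
#'
#' Draws i.i.d. bases with the given composition — the package's stand-in for
#' a real reference chromosome (emulating it by base composition only).
#' Deterministic given `seed`.
#'
#' @param length Number of bases.
#' @param composition Named (or A,C,G,T-ordered) non-negative numeric vector
#'   summing to 1.
#' @param seed Integer seed (or NULL).
#' @param label Sequence label.
#' @return An [ancestral_sequence()].
#' @examples
#' generate_sequence(10, c(A = 1, C = 0, G = 0, T = 0), seed = 1)$bases
#' @export
generate_sequence <- function(length,
                              composition = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                              seed = NULL, label = "synthetic") {
  if (!is.null(names(composition))) {
    if (!all(.BASES %in% names(composition))) {
      stop("named `composition` must cover A, C, G, T")
    }
    composition <- as.numeric(composition[.BASES])
  } else {
    if (length(composition) != 4L) {
      stop("`composition` must have 4 entries (A, C, G, T)")
    }
    composition <- as.numeric(composition)
  }
  if (anyNA(composition) || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-8) {
    stop("`composition` must be 4 non-negative values summing to 1")
  }
  bases <- with_seed(seed,
    sample(.BASES, length, replace = TRUE, prob = composition))
  ancestral_sequence(paste(bases, collapse = ""), label = label)
}

## Internal helpers for window-level work --------------------------------------

# Integer base codes (1..4 = A,C,G,T) for positions `from..to` (1-based,
# inclusive). Errors on N.
seq_base_codes <- function(x, from = 1L, to = seq_length(x)) {
  chars <- strsplit(substr(x$bases, from, to), "", fixed = TRUE)[[1L]]
  codes <- match(chars, .BASES)
  if (anyNA(codes)) stop("sequence window contains missing (N) sites")
  codes
}

# Triplet index (1..64, lexicographic) for each interior position in
# `positions` (1-based positions of the middle base; all must have both
# neighbours within the sequence).
position_triplet_index <- function(x, positions) {
  if (any(positions < 2L) || any(positions > seq_length(x) - 1L)) {
    stop("positions must be interior (both neighbours present)")
  }
  lo <- min(positions) - 1L
  hi <- max(positions) + 1L
  codes <- seq_base_codes(x, lo, hi)
  off <- positions - lo + 1L  # index of middle base within `codes`
  16L * (codes[off - 1L] - 1L) + 4L * (codes[off] - 1L) + codes[off + 1L]
}
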