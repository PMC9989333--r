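## Context-specific mutation rate matrices (192 entries) ----------------------

# A rate matrix is a data.frame with the 192 rows of mutation_types() plus a
# `rate` column (per site per generation), carrying attributes:
#   normalized  - TRUE once normalize_overall_rate() has fixed the
#                 sequence-averaged total per-site rate,
#   overall_rate - that target rate (NA until normalized).

new_rate_matrix <- function(rate, normalized = FALSE, overall_rate = NA_real_) {
  stopifnot(length(rate) == 192L, all(rate >= 0), all(is.finite(rate)))
  out <- cbind(mutation_types(), rate = as.numeric(rate))
  attr(out, "normalized") <- normalized
  attr(out, "overall_rate") <- overall_rate
  class(out) <- c("rate_matrix", "data.frame")
  out
}

is_normalized <- function(m) isTRUE(attr(m, "normalized"))

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix: 192 mutation types, %s>\n",
              if (is_normalized(x)) {
                sprintf("normalized to overall rate %g /bp/generation",
                        attr(x, "overall_rate"))
              } else "unnormalized"))
  print.data.frame(head(as.data.frame(x), 4L))
  cat("  ...\n")
  invisible(x)
}

#' Jukes-Cantor (uniform) rate matrix
#'
#' All 192 context-specific entries equal: every nucleotide mutates to every
#' other nucleotide with the same probability, regardless of flanking
#' context. Entries are on an arbitrary scale until
#' [normalize_overall_rate()] pins the sequence-averaged per-site rate
#' (conventionally 1e-8 per bp per generation).
#'
#' @return A `rate_matrix` (unnormalized).
#' @examples
#' m <- build_uniform_matrix()
#' length(unique(m$rate)) == 1
#' @export
build_uniform_matrix <- function() {
  new_rate_matrix(rep(1, 192L))
}

#' Read and write a rate matrix table
#'
#' Tab-separated, three columns `triplet`, `derived`, `rate`, exactly 192
#' rows (one per mutation type, any order); `#` lines are comments. Example
#' tables ship under `system.file("extdata/matrices", package = "mutspectra")`.
#'
#' @param path File path.
#' @param x A `rate_matrix`.
#' @return `load_matrix()` returns a validated `rate_matrix` (unnormalized).
#' @export
load_matrix <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  required <- c("triplet", "derived", "rate")
  if (!all(required %in% names(tab))) {
    stop("matrix table needs columns: ", paste(required, collapse = ", "))
  }
  key <- paste0(tab$triplet, ">", tab$derived)
  if (anyDuplicated(key)) {
    stop("matrix table has duplicated mutation types: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  want <- mutation_types()$label
  if (nrow(tab) != 192L || !setequal(key, want)) {
    stop(sprintf(
      "matrix table must contain exactly the 192 mutation types (got %d rows, %d recognized)",
      nrow(tab), sum(key %in% want)))
  }
  if (any(!is.finite(tab$rate)) || any(tab$rate < 0)) {
    stop("matrix table has negative or non-finite rates")
  }
  new_rate_matrix(tab$rate[match(want, key)])
}

#' @rdname load_matrix
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "rate_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mutspectra rate matrix; normalized=%s overall_rate=%s",
                     is_normalized(x), format(attr(x, "overall_rate"))), con)
  utils::write.table(as.data.frame(x)[c("triplet", "derived", "rate")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Multiply the rate of one mutation type by a fold factor
#'
#' Scales the named entry by `fold`, leaving the other 191 entries unchanged
#' (renormalization of the overall rate, if wanted, is a separate explicit
#' step via [normalize_overall_rate()]). With `both_strands = TRUE` the
#' reverse-complement entry is scaled as well — a strand-symmetric rate
#' change, which is what a biological shift of, say, TCC>T means on
#' double-stranded DNA and what the fine-scale power experiments use.
#'
#' @param x A `rate_matrix`.
#' @param type Mutation type as a `"TCC>T"`-style label (or a list with
#'   `triplet` and `derived`).
#' @param fold Positive multiplier (1 = no change; the published experiments
#'   span 0.9- to 2.0-fold).
#' @param both_strands Also scale the reverse-complement entry
#'   (default FALSE, matching the one-entry contract).
#' @return A `rate_matrix`, marked unnormalized.
#' @examples
#' m <- apply_fold_shift(build_uniform_matrix(), "TCC>T", 2)
#' m$rate[m$label == "TCC>T"]
#' @export
apply_fold_shift <- function(x, type, fold, both_strands = FALSE) {
  stopifnot(inherits(x, "rate_matrix"))
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 0) {
    stop("`fold` must be a positive number")
  }
  label <- type_label(type)
  targets <- label
  if (both_strands) targets <- unique(c(label, revcomp_type(label)))
  hit <- x$label %in% targets
  if (!any(hit)) stop("unknown mutation type: ", label)
  rate <- x$rate
  rate[hit] <- rate[hit] * fold
  new_rate_matrix(rate)
}

type_label <- function(type) {
  if (is.list(type)) {
    label <- paste0(type$triplet, ">", type$derived)
  } else {
    label <- as.character(type)
  }
  if (!label %in% mutation_types()$label) {
    stop("not a valid mutation type: ", label,
         " (derived base must differ from the triplet's middle base)")
  }
  label
}

#' Normalize a matrix to a target sequence-averaged mutation rate
#'
#' Scales all 192 entries by a single constant so that the average total
#' per-site mutation rate over the interior sites of `seq` equals
#' `target_rate` (the broad- and fine-scale experiments keep this at 1e-8
#' per bp per generation). Idempotent. Triplet-rich contexts keep their
#' relative elevation; only the sequence-wide mean is pinned.
#'
#' @param x A `rate_matrix` (not all zero unless `target_rate` is 0).
#' @param seq An [ancestral_sequence()] without missing sites.
#' @param target_rate Target mean per-site per-generation rate.
#' @return A normalized `rate_matrix`.
#' @examples
#' s <- generate_sequence(1000, seed = 1)
#' m <- normalize_overall_rate(build_uniform_matrix(), s, 1e-8)
#' attr(m, "overall_rate")
#' @export
normalize_overall_rate <- function(x, seq, target_rate = 1e-8) {
  stopifnot(inherits(x, "rate_matrix"), inherits(seq, "ancestral_sequence"),
            target_rate >= 0)
  if (target_rate == 0) {
    return(new_rate_matrix(rep(0, 192L), normalized = TRUE, overall_rate = 0))
  }
  counts <- context_counts(seq)                      # errors on N / short seq
  totals <- triplet_total_rates(x)                   # 64 per-triplet totals
  mean_rate <- sum(counts * totals) / sum(counts)
  if (mean_rate == 0) stop("cannot normalize an all-zero rate matrix")
  new_rate_matrix(x$rate * (target_rate / mean_rate),
                  normalized = TRUE, overall_rate = target_rate)
}

# Total mutation rate per triplet context (named 64-vector): sum of the three
# derived-base entries.
triplet_total_rates <- function(x) {
  totals <- rowsum(x$rate, group = x$triplet, reorder = FALSE)
  stats::setNames(as.numeric(totals), rownames(totals))[.TRIPLETS]
}

# 64 x 4 matrix of conditional derived-base probabilities given the triplet
# (zero at the middle base; rows with zero total rate are left at 0).
triplet_conditional <- function(x) {
  m <- matrix(0, nrow = 64L, ncol = 4L, dimnames = list(.TRIPLETS, .BASES))
  m[cbind(match(x$triplet, .TRIPLETS), match(x$derived, .BASES))] <- x$rate
  tot <- rowSums(m)
  nz <- tot > 0
  m[nz, ] <- m[nz, ] / tot[nz]
  m
}

#' Per-site mutation rate and derived-base distribution
#'
#' For an interior position of `seq` (both neighbours present), the total
#' per-generation mutation rate is the sum of the three matrix entries for
#' the site's ancestral triplet, and the derived base is drawn from those
#' entries in proportion.
#'
#' @param seq An [ancestral_sequence()] without missing sites.
#' @param position 1-based position (must be interior).
#' @param x A `rate_matrix`.
#' @return A list with `total` (numeric) and `conditional` (named
#'   3-probability vector over the non-ancestral bases).
#' @examples
#' s <- generate_sequence(100, seed = 1)
#' site_rate(s, 50, normalize_overall_rate(build_uniform_matrix(), s))
#' @export
site_rate <- function(seq, position, x) {
  stopifnot(inherits(seq, "ancestral_sequence"), inherits(x, "rate_matrix"))
  if (length(position) != 1L || position < 2L ||
      position > seq_length(seq) - 1L) {
    stop("`position` must be a single interior position (2 .. length-1)")
  }
  ti <- position_triplet_index(seq, position)
  trip <- .TRIPLETS[ti]
  rows <- x[x$triplet == trip, ]
  total <- sum(rows$rate)
  cond <- if (total > 0) rows$rate / total else rep(NA_real_, 3L)
  list(triplet = trip, total = total,
       conditional = stats::setNames(cond, rows$derived))
}
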