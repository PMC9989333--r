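## Population-private SNPs and mutational spectra ------------------------------

#' Extract population-private segregating variants
#'
#' Keeps the rows segregating in the focal population (derived count strictly
#' between 0 and the focal haplotype count) while every other population in
#' the table is fixed for the ancestral allele (derived count 0) — the
#' standard definition of population-specific SNPs for spectrum analyses.
#'
#' @param x A [variant_table()] with at least two populations.
#' @param focal Population identifier present in the table.
#' @return A filtered [variant_table()].
#' @export
private_segregating <- function(x, focal) {
  stopifnot(inherits(x, "variant_table"))
  counts <- allele_counts(x)
  pops <- colnames(counts)
  if (!(focal %in% pops)) stop("focal population not in table: ", focal)
  if (length(pops) < 2L) {
    stop("private variants need at least two populations in the table")
  }
  hap_n <- attr(counts, "hap_counts")[focal]
  cf <- counts[, focal]
  others <- counts[, setdiff(pops, focal), drop = FALSE]
  keep <- cf > 0L & cf < hap_n & rowSums(others) == 0L
  filter_variants(x, keep)
}

#' Classify variants into mutation types
#'
#' Maps (ancestral triplet, derived base) to one of the 192 stranded
#' categories, e.g. `("TCC", "T")` to `"TCC>T"` (the 5' TCC 3' to 5' TTC 3'
#' change).
#'
#' @param triplet Ancestral triplets (character), or a [variant_table()].
#' @param derived Derived bases (ignored when `triplet` is a table).
#' @return Character vector of type labels.
#' @examples
#' classify_mutation("TCC", "T")
#' @export
classify_mutation <- function(triplet, derived = NULL) {
  if (inherits(triplet, "variant_table")) {
    derived <- triplet$variants$derived
    triplet <- triplet$variants$triplet
  }
  if (!all(triplet %in% .TRIPLETS)) {
    stop("invalid ancestral triplet(s): ",
         paste(unique(triplet[!triplet %in% .TRIPLETS]), collapse = ", "))
  }
  bad <- derived == substr(triplet, 2L, 2L)
  if (any(bad)) {
    stop("derived base equals the ancestral middle base at ",
         sum(bad), " variant(s)")
  }
  if (!all(derived %in% .BASES)) stop("invalid derived base(s)")
  paste0(triplet, ">", derived)
}

#' Compute a mutational spectrum
#'
#' Counts variants in each of the 192 stranded categories (or directly in the
#' 96 strand-collapsed space) and normalizes to proportions. The spectrum of
#' a population is this distribution computed over its private segregating
#' variants.
#'
#' @param x A [variant_table()] (typically after [private_segregating()]).
#' @param space `"stranded192"` or `"collapsed96"`.
#' @return An object of class `spectrum`: data frame with `category`,
#'   `count`, `proportion`, plus attributes `space` and `total`. With an
#'   empty table all counts are zero and proportions `NA` (flagged via
#'   `attr(, "empty")`).
#' @export
compute_spectrum <- function(x, space = c("stranded192", "collapsed96")) {
  space <- match.arg(space)
  stopifnot(inherits(x, "variant_table"))
  labels <- if (n_variants(x) > 0) classify_mutation(x) else character(0)
  if (space == "collapsed96") {
    labels <- unname(.COLLAPSE_MAP[labels])
    levels <- .COLLAPSED_TYPES
  } else {
    levels <- mutation_types()$label
  }
  counts <- as.integer(table(factor(labels, levels = levels)))
  new_spectrum(levels, counts, space)
}

new_spectrum <- function(categories, counts, space) {
  total <- sum(counts)
  out <- data.frame(category = categories, count = counts,
                    proportion = if (total > 0) counts / total else
                      rep(NA_real_, length(counts)))
  attr(out, "space") <- space
  attr(out, "total") <- total
  attr(out, "empty") <- total == 0L
  class(out) <- c("spectrum", "data.frame")
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d variant(s)%s>\n", attr(x, "space"),
              attr(x, "total"),
              if (isTRUE(attr(x, "empty"))) " [empty: proportions undefined]"
              else ""))
  top <- as.data.frame(x)[order(-x$count), ][1:5, ]
  print(top)
  cat("  ...\n")
  invisible(x)
}

#' Collapse a stranded spectrum onto the 96 pyrimidine-centred categories
#'
#' Merges each mutation type with its reverse complement (e.g. `TCC>T` with
#' `GGA>A`) into the representative whose central ancestral base is C or T.
#' Counts are conserved. Applying it to an already collapsed spectrum is an
#' error.
#'
#' @param x A `spectrum` in the `stranded192` space.
#' @return A `spectrum` in the `collapsed96` space.
#' @export
collapse_strands <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  if (attr(x, "space") != "stranded192") {
    stop("spectrum is already strand-collapsed")
  }
  rep_lab <- unname(.COLLAPSE_MAP[x$category])
  counts <- rowsum(x$count, group = rep_lab)
  counts <- stats::setNames(as.integer(counts), rownames(counts))
  new_spectrum(.COLLAPSED_TYPES, unname(counts[.COLLAPSED_TYPES]),
               "collapsed96")
}

#' Read and write spectra as TSV
#'
#' Columns `category`, `count`, `proportion`; the space and total ride along
#' as `#` header comments.
#'
#' @param x A `spectrum`.
#' @param path File path.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mutspectra spectrum; space=%s total=%d",
                     attr(x, "space"), attr(x, "total")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  header <- readLines(path, n = 1L)
  space <- sub(".*space=(\\S+).*", "\\1", header)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  new_spectrum(tab$category, tab$count, space)
}
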