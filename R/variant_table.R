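## VariantTable: biallelic simulated sites with genotypes ----------------------

#' Construct a variant table
#'
#' The container produced by the simulators: one row per biallelic site with
#' its ancestral trinucleotide context and derived base, plus a sparse 0/1
#' genotype matrix over the sampled haplotypes. Haplotypes are grouped into
#' diploid individuals (consecutive pairs within each population).
#'
#' @param variants Data frame with columns `pos`, `triplet`, `derived`.
#' @param genotypes A sparse (`Matrix::sparseMatrix`) or dense 0/1 matrix,
#'   `nrow(variants)` rows by number-of-haplotypes columns.
#' @param haplotypes Data frame with columns `hap`, `population`,
#'   `individual`.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(variants, genotypes, haplotypes) {
  stopifnot(is.data.frame(variants),
            all(c("pos", "triplet", "derived") %in% names(variants)),
            is.data.frame(haplotypes),
            all(c("hap", "population", "individual") %in% names(haplotypes)))
  genotypes <- methods::as(methods::as(genotypes, "CsparseMatrix"),
                           "generalMatrix")
  stopifnot(nrow(genotypes) == nrow(variants),
            ncol(genotypes) == nrow(haplotypes))
  rownames(variants) <- NULL
  rownames(haplotypes) <- NULL
  structure(list(variants = variants, genotypes = genotypes,
                 haplotypes = haplotypes),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  tab <- table(x$haplotypes$population)
  cat(sprintf("<variant_table: %d biallelic site(s), %d haplotype(s) [%s]>\n",
              n_variants(x), nrow(x$haplotypes),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  if (n_variants(x) > 0) print(utils::head(x$variants, 5L))
  invisible(x)
}

#' @rdname variant_table
#' @export
n_variants <- function(x) nrow(x$variants)

#' Per-population derived-allele counts
#'
#' @param x A [variant_table()].
#' @return Integer matrix, one row per variant and one column per population,
#'   with attribute `hap_counts` (sampled haplotypes per population).
#' @export
allele_counts <- function(x) {
  pops <- unique(x$haplotypes$population)
  ind <- Matrix::sparseMatrix(
    i = seq_len(nrow(x$haplotypes)),
    j = match(x$haplotypes$population, pops),
    x = 1,
    dims = c(nrow(x$haplotypes), length(pops))
  )
  counts <- as.matrix(x$genotypes %*% ind)
  colnames(counts) <- pops
  storage.mode(counts) <- "integer"
  attr(counts, "hap_counts") <-
    stats::setNames(as.integer(table(factor(x$haplotypes$population,
                                            levels = pops))), pops)
  counts
}

# Row-bind variant tables sharing the same haplotype frame.
combine_variant_tables <- function(tables) {
  tables <- Filter(Negate(is.null), tables)
  stopifnot(length(tables) >= 1L)
  if (length(tables) == 1L) return(tables[[1L]])
  hap <- tables[[1L]]$haplotypes
  for (t in tables[-1L]) stopifnot(identical(t$haplotypes, hap))
  variants <- do.call(rbind, lapply(tables, `[[`, "variants"))
  genotypes <- do.call(rbind, lapply(tables, `[[`, "genotypes"))
  ord <- order(variants$pos)
  variant_table(variants[ord, , drop = FALSE], genotypes[ord, , drop = FALSE],
                hap)
}

# Subset rows of a variant table.
filter_variants <- function(x, keep) {
  variant_table(x$variants[keep, , drop = FALSE],
                x$genotypes[keep, , drop = FALSE],
                x$haplotypes)
}

# Standard haplotype frame: haplotypes numbered 1..n in the order populations
# appear in `samples` (haplotype counts); consecutive pairs form individuals.
haplotype_frame <- function(samples) {
  samples <- samples[samples > 0]
  data.frame(
    hap = seq_len(sum(samples)),
    population = rep(names(samples), samples),
    individual = unlist(lapply(samples, function(k) ceiling(seq_len(k) / 2)),
                        use.names = FALSE)
  )
}
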