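## Variant table import/export -------------------------------------------------

#' Export a variant table as minimal VCF
#'
#' CHROM/POS/REF/ALT plus phased diploid GT columns (consecutive haplotype
#' pairs form individuals, named `<population>_<individual>`). REF is the
#' ancestral middle base of the triplet; positions are 1-based.
#'
#' @param x A [variant_table()] whose populations all have even haplotype
#'   counts.
#' @param path Output path.
#' @param chrom CHROM field value (default `"1"`).
#' @return The path, invisibly.
#' @export
write_variant_vcf <- function(x, path, chrom = "1") {
  stopifnot(inherits(x, "variant_table"))
  hap <- x$haplotypes
  key <- paste(hap$population, hap$individual, sep = "_")
  ind <- unique(key)
  if (nrow(hap) != 2L * length(ind)) {
    stop("haplotypes do not pair into diploid individuals")
  }
  g <- as.matrix(x$genotypes)
  first <- match(ind, key)
  gt <- matrix("", nrow = nrow(g), ncol = length(ind))
  if (nrow(g) > 0) {
    for (j in seq_along(ind)) {
      cols <- which(key == ind[j])
      gt[, j] <- paste(g[, cols[1L]], g[, cols[2L]], sep = "|")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mutspectra",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind), collapse = "\t")
  ), con)
  if (nrow(g) > 0) {
    ref <- substr(x$variants$triplet, 2L, 2L)
    body <- cbind(chrom, x$variants$pos, ".", ref, x$variants$derived,
                  ".", "PASS", paste0("TRIPLET=", x$variants$triplet),
                  "GT", gt)
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Export/import a variant table as TSV
#'
#' A lossless plain-text round trip: header comments carry the haplotype
#' frame (`hap population individual` triples); rows carry `pos`, `triplet`,
#' `derived` and the carrier haplotype indices as a comma-separated list.
#'
#' @param x A [variant_table()].
#' @param path File path.
#' @return `read_variant_tsv()` returns a [variant_table()].
#' @export
write_variant_tsv <- function(x, path) {
  stopifnot(inherits(x, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# mutspectra variant table", con)
  hap <- x$haplotypes
  writeLines(sprintf("# haplotype\t%d\t%s\t%d",
                     hap$hap, hap$population, hap$individual), con)
  carriers <- apply_carriers(x)
  tab <- data.frame(pos = x$variants$pos, triplet = x$variants$triplet,
                    derived = x$variants$derived,
                    carriers = vapply(carriers, paste, character(1),
                                      collapse = ","))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Carrier haplotype indices per variant row.
apply_carriers <- function(x) {
  g <- methods::as(x$genotypes, "TsparseMatrix")
  split(g@j + 1L, factor(g@i + 1L, levels = seq_len(nrow(g))))
}

#' @rdname write_variant_tsv
#' @export
read_variant_tsv <- function(path) {
  lines <- readLines(path)
  hl <- grep("^# haplotype\t", lines, value = TRUE)
  if (length(hl) == 0L) stop("not a mutspectra variant TSV: ", path)
  parts <- strsplit(sub("^# haplotype\t", "", hl), "\t", fixed = TRUE)
  hap <- data.frame(
    hap = as.integer(vapply(parts, `[[`, character(1), 1L)),
    population = vapply(parts, `[[`, character(1), 2L),
    individual = as.integer(vapply(parts, `[[`, character(1), 3L))
  )
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c("integer", "character",
                                          "character", "character"))
  carriers <- strsplit(tab$carriers, ",", fixed = TRUE)
  sizes <- vapply(carriers, length, integer(1))
  g <- Matrix::sparseMatrix(
    i = rep.int(seq_len(nrow(tab)), sizes),
    j = as.integer(unlist(carriers, use.names = FALSE)),
    x = 1, dims = c(nrow(tab), nrow(hap)))
  variant_table(tab[c("pos", "triplet", "derived")], g, hap)
}
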