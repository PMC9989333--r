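## Subsampling experiments: spectrum convergence with sample size --------------

#' Subsampling schemes
#'
#' `default_scheme()` is the published broad-scale grid: 5-200 individuals in
#' steps of 5, 300-1,000 in steps of 100, and 2,000-10,000 in steps of 1,000
#' (57 sizes), with five independent replicates per size.
#' `sampling_scheme()` builds custom grids.
#'
#' @param sizes Strictly increasing diploid sample sizes.
#' @param replicates_per_size Replicate draws per size (>= 1).
#' @return An object of class `sampling_scheme`.
#' @examples
#' length(default_scheme()$sizes)  # 57
#' @export
sampling_scheme <- function(sizes, replicates_per_size = 5) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(diff(sizes) <= 0) || any(sizes < 1L)) {
    stop("`sizes` must be strictly increasing positive integers")
  }
  if (replicates_per_size < 1L) stop("`replicates_per_size` must be >= 1")
  structure(list(sizes = sizes,
                 replicates_per_size = as.integer(replicates_per_size)),
            class = "sampling_scheme")
}

#' @rdname sampling_scheme
#' @export
default_scheme <- function() {
  sampling_scheme(c(seq(5L, 200L, by = 5L),
                    seq(300L, 1000L, by = 100L),
                    seq(2000L, 10000L, by = 1000L)),
                  replicates_per_size = 5)
}

#' Subsample diploid individuals from one population
#'
#' Draws `size` diploid individuals (pairs of haplotypes) from the focal
#' population — with replacement by default, so sizes beyond the simulated
#' population are allowed — rebuilds the genotype matrix with the drawn
#' haplotype columns (duplicates count multiply), and drops rows that are no
#' longer segregating in the focal subsample. Other populations' genotypes
#' are untouched, so privacy continues to be evaluated against their full
#' samples.
#'
#' @param x A [variant_table()] whose focal population has an even haplotype
#'   count (diploid individuals).
#' @param focal Population identifier.
#' @param size Number of diploid individuals to draw (>= 1).
#' @param seed Integer seed (or NULL).
#' @param replace Draw with replacement (default TRUE; `FALSE` gives the
#'   identity control at `size` = the full population).
#' @return A [variant_table()].
#' @export
subsample_individuals <- function(x, focal, size, seed = NULL,
                                  replace = TRUE) {
  stopifnot(inherits(x, "variant_table"))
  if (size < 1L) stop("`size` must be >= 1")
  hap <- x$haplotypes
  if (!(focal %in% hap$population)) {
    stop("focal population not in table: ", focal)
  }
  focal_rows <- which(hap$population == focal)
  inds <- unique(hap$individual[focal_rows])
  if (length(focal_rows) %% 2L != 0L) {
    stop("focal population does not consist of whole diploid individuals")
  }
  if (!replace && size > length(inds)) {
    stop("`size` exceeds the population; use replace = TRUE")
  }
  chosen <- with_seed(seed,
    inds[sample.int(length(inds), size, replace = replace)])
  # Haplotype columns of the chosen individuals, duplicates preserved.
  ind_cols <- split(focal_rows, hap$individual[focal_rows])
  cols <- unlist(ind_cols[as.character(chosen)], use.names = FALSE)
  other_rows <- which(hap$population != focal)
  g <- cbind(x$genotypes[, other_rows, drop = FALSE],
             x$genotypes[, cols, drop = FALSE])
  new_hap <- rbind(
    hap[other_rows, c("population", "individual")],
    data.frame(population = focal,
               individual = rep(seq_len(size), each = 2L))
  )
  new_hap <- data.frame(hap = seq_len(nrow(new_hap)), new_hap,
                        row.names = NULL)
  out <- variant_table(x$variants, g, new_hap)
  cf <- allele_counts(out)[, focal]
  filter_variants(out, cf > 0L & cf < 2L * size)
}

#' Total difference between two spectra
#'
#' The sum over categories of absolute differences between the two spectra's
#' proportions (twice the total variation distance): 0 for identical spectra,
#' 2 for disjoint support. Signed differences would cancel to zero
#' identically, so the absolute value is what makes the statistic
#' informative.
#'
#' @param sub,full Two `spectrum` objects in the same category space, both
#'   non-empty.
#' @return A number in `[0, 2]`.
#' @examples
#' # identical spectra differ by 0; see convergence_curve() for use
#' @export
total_difference <- function(sub, full) {
  stopifnot(inherits(sub, "spectrum"), inherits(full, "spectrum"))
  if (!identical(attr(sub, "space"), attr(full, "space"))) {
    stop("spectra are in different category spaces")
  }
  if (isTRUE(attr(sub, "empty")) || isTRUE(attr(full, "empty"))) {
    stop("total_difference of an empty spectrum is undefined")
  }
  sum(abs(sub$proportion - full$proportion))
}

#' Spectrum convergence under subsampling
#'
#' The broad-scale experiment for one population: compute its full-sample
#' private-SNP spectrum, then for every (size, replicate) cell of the scheme
#' subsample individuals with replacement, recompute the private spectrum,
#' and record the total difference to the full spectrum. Each cell draws its
#' own reproducible stream from `(seed, size, replicate)`.
#'
#' @param x A [variant_table()] with at least two populations.
#' @param focal Population identifier.
#' @param scheme A [sampling_scheme()].
#' @param seed Integer master seed (or NULL).
#' @param space Spectrum space (default `"stranded192"`).
#' @return Data frame with columns `size`, `replicate`, `total_difference`,
#'   `percent`.
#' @export
convergence_curve <- function(x, focal, scheme = default_scheme(),
                              seed = NULL, space = "stranded192") {
  stopifnot(inherits(scheme, "sampling_scheme"))
  full <- compute_spectrum(private_segregating(x, focal), space = space)
  if (isTRUE(attr(full, "empty"))) {
    stop("no private variants in the focal population; nothing to compare")
  }
  grid <- expand.grid(replicate = seq_len(scheme$replicates_per_size),
                      size = scheme$sizes)
  td <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- if (is.null(seed)) NULL else
      seed_stream(seed, "subsample", grid$size[i], grid$replicate[i])
    sub <- subsample_individuals(x, focal, grid$size[i], seed = s)
    spec <- compute_spectrum(private_segregating(sub, focal), space = space)
    td[i] <- if (isTRUE(attr(spec, "empty"))) NA_real_
      else total_difference(spec, full)
  }
  data.frame(size = grid$size, replicate = grid$replicate,
             total_difference = td, percent = 100 * td)
}
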