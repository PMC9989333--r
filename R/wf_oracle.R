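## Forward Wright-Fisher oracle ------------------------------------------------

#' Small forward-in-time Wright-Fisher simulator (engine cross-check)
#'
#' A brute-force discrete-generation diploid Wright-Fisher simulation with
#' per-site context-dependent mutation, used to validate the coalescent
#' engine at small population sizes. Starts with a 10 Ne burn-in of the root
#' population (mutation-drift equilibrium), plays splits forward
#' (founding each child population from its parent's current generation), and
#' samples haplotypes at present. The output contract matches
#' [place_mutations()]: ancestral-context mutation, biallelic sites only,
#' sites segregating in the total sample.
#'
#' Supported models: constant-size epochs (instantaneous size changes),
#' splits, no migration, all sizes at most `max_n` — the oracle is a
#' validation tool, not a production simulator.
#'
#' @param model A valid [population_model()] within the guards above.
#' @param samples Named haplotype counts per population.
#' @param seq An [ancestral_sequence()] without missing sites.
#' @param matrix A normalized `rate_matrix`.
#' @param seed Integer seed (or NULL).
#' @param start,end Interior window (defaults to the whole interior).
#' @param max_n Guard on all diploid sizes (default 500).
#' @return A [variant_table()].
#' @export
forward_wf_oracle <- function(model, samples, seq, matrix, seed = NULL,
                              start = NULL, end = NULL, max_n = 500) {
  cm <- compile_model(model)
  if (!is.null(cm$routes)) {
    stop("forward_wf_oracle does not support migration")
  }
  if (any(unlist(cm$ep_rate) != 0)) {
    stop("forward_wf_oracle supports constant-size epochs only")
  }
  sizes <- unlist(cm$ep_size)
  if (any(sizes > max_n)) {
    stop(sprintf("population size %g exceeds the oracle guard (%g)",
                 max(sizes), max_n))
  }
  if (!inherits(matrix, "rate_matrix") || !is_normalized(matrix)) {
    stop("rate matrix must be normalized (see normalize_overall_rate)")
  }
  samples <- samples[samples > 0]
  if (!all(names(samples) %in% cm$pops)) {
    stop("`samples` must be named by populations of the model")
  }
  L <- seq_length(seq)
  if (is.null(start)) start <- 2L
  if (is.null(end)) end <- L - 1L

  positions <- start:end
  trip_idx <- position_triplet_index(seq, positions)
  n_t <- tabulate(trip_idx, 64L)
  totals <- triplet_total_rates(matrix)
  cond <- triplet_conditional(matrix)
  cat_w <- n_t * totals
  rate_hap <- sum(cat_w)  # mutation rate per haplotype per generation
  pos_by_trip <- split(positions, factor(trip_idx, levels = 1:64))

  root <- which(!is.finite(cm$split_time))
  t_oldest <- max(0, unlist(cm$ep_start),
                  cm$split_time[is.finite(cm$split_time)])
  burn_in <- 10 * cm$ep_size[[root]][length(cm$ep_size[[root]])]
  t_start <- ceiling(burn_in + t_oldest)

  size2n_at <- function(p, tau) {
    i <- findInterval(tau, cm$ep_start[[p]])
    2L * as.integer(cm$ep_size[[p]][i])
  }

  with_seed(seed, {
    # Mutation registry.
    mut_pos <- integer(0); mut_der <- integer(0)
    new_mutations <- function(k) {
      tcat <- sample.int(64L, k, replace = TRUE, prob = cat_w)
      pos <- integer(k); der <- integer(k)
      for (u in unique(tcat)) {
        sel <- which(tcat == u)
        cand <- pos_by_trip[[u]]
        pos[sel] <- cand[sample.int(length(cand), length(sel), replace = TRUE)]
        der[sel] <- sample.int(4L, length(sel), replace = TRUE,
                               prob = cond[u, ])
      }
      first <- length(mut_pos)
      mut_pos <<- c(mut_pos, pos); mut_der <<- c(mut_der, der)
      first + seq_len(k)  # new mutation ids
    }

    # geno[[p]]: list of integer vectors (mutation ids) per haplotype;
    # populations come alive as the forward clock crosses their split time.
    geno <- vector("list", cm$P)
    geno[[root]] <- rep(list(integer(0)), size2n_at(root, t_start))

    tau <- t_start
    while (tau > 0) {
      tau_new <- tau - 1
      for (p in seq_len(cm$P)) {
        born_now <- is.finite(cm$split_time[p]) &&
          cm$split_time[p] <= tau && cm$split_time[p] > tau_new
        if (is.null(geno[[p]]) && !born_now) next
        source_pool <- if (born_now) geno[[cm$split_parent[p]]] else geno[[p]]
        k2n <- size2n_at(p, tau_new)
        parents <- sample.int(length(source_pool), k2n, replace = TRUE)
        gen_new <- source_pool[parents]
        if (rate_hap > 0) {
          m <- stats::rpois(1L, k2n * rate_hap)
          if (m > 0L) {
            ids <- new_mutations(m)
            haps <- sample.int(k2n, m, replace = TRUE)
            for (j in seq_len(m)) {
              h <- haps[j]
              gen_new[[h]] <- c(gen_new[[h]], ids[j])
            }
          }
        }
        geno[[p]] <- gen_new
      }
      tau <- tau_new
    }

    # Drop mutations fixed in the whole metapopulation: they are
    # substitutions, invisible below the sample MRCA in the coalescent view.
    all_ids <- unlist(geno, use.names = FALSE)
    total_haps <- sum(vapply(geno, length, integer(1)))
    id_counts <- tabulate(all_ids, nbins = length(mut_pos))
    fixed <- which(id_counts == total_haps)

    # Sample haplotypes at present.
    hap_sets <- vector("list", sum(samples))
    h <- 0L
    for (pn in names(samples)) {
      p <- match(pn, cm$pops)
      if (is.null(geno[[p]])) stop("population never born: ", pn)
      pick <- sample.int(length(geno[[p]]), samples[[pn]])
      for (i in pick) {
        h <- h + 1L
        hap_sets[[h]] <- setdiff(geno[[p]][[i]], fixed)
      }
    }
    n_total <- length(hap_sets)

    samp_ids <- unlist(hap_sets, use.names = FALSE)
    counts <- tabulate(samp_ids, nbins = length(mut_pos))
    seg <- which(counts > 0L & counts < n_total)
    # Biallelic filter: positions carrying more than one segregating mutation.
    keep_pos <- mut_pos[seg]
    multi <- unique(keep_pos[duplicated(keep_pos)])
    seg <- seg[!(keep_pos %in% multi)]

    hap <- haplotype_frame(samples)
    ord <- seg[order(mut_pos[seg])]
    variants <- data.frame(pos = mut_pos[ord],
                           triplet = .TRIPLETS[trip_idx[mut_pos[ord] - start + 1L]],
                           derived = .BASES[mut_der[ord]])
    if (length(ord) == 0L) {
      g <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0L, n_total))
      return(variant_table(variants, g, hap))
    }
    row_of <- integer(length(mut_pos))
    row_of[ord] <- seq_along(ord)
    ii <- jj <- vector("list", n_total)
    for (hh in seq_len(n_total)) {
      ids <- hap_sets[[hh]]
      ids <- ids[ids %in% ord]
      ii[[hh]] <- row_of[ids]
      jj[[hh]] <- rep.int(hh, length(ids))
    }
    g <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                              dims = c(length(ord), n_total))
    variant_table(variants, g, hap)
  })
}
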