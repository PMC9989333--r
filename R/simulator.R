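## Structured coalescent engine ------------------------------------------------

# Internal compiled view of a population_model used by the event loop.
compile_model <- function(model) {
  v <- validate_model(model)
  if (length(v)) {
    stop("model failed validation:\n  ", paste(v, collapse = "\n  "))
  }
  pops <- names(model$populations)
  P <- length(pops)
  ep_start <- ep_size <- ep_rate <- vector("list", P)
  for (i in seq_len(P)) {
    eps <- model$populations[[i]]
    ep_start[[i]] <- vapply(eps, `[[`, numeric(1), "start_time")
    ep_size[[i]] <- vapply(eps, `[[`, numeric(1), "size")
    ep_rate[[i]] <- vapply(eps, `[[`, numeric(1), "growth_rate")
  }
  st <- split_time_of(model)
  split_time <- vapply(pops, function(p) st[[p]], numeric(1))
  split_parent <- rep(NA_integer_, P)
  for (s in model$splits) {
    split_parent[match(s$child, pops)] <- match(s$parent, pops)
  }
  routes <- NULL
  if (length(model$migrations)) {
    routes <- data.frame(
      pop = match(vapply(model$migrations, `[[`, character(1), "to"), pops),
      dest = match(vapply(model$migrations, `[[`, character(1), "from"), pops),
      rate = vapply(model$migrations, migration_backward_rate,
                    numeric(1), model = model),
      start = vapply(model$migrations, `[[`, numeric(1), "start"),
      end = vapply(model$migrations, `[[`, numeric(1), "end")
    )
    routes <- routes[routes$rate > 0, , drop = FALSE]
    if (nrow(routes) == 0L) routes <- NULL
  }
  boundaries <- sort(unique(c(
    unlist(ep_start), split_time[is.finite(split_time)],
    if (!is.null(routes)) c(routes$start, routes$end[is.finite(routes$end)])
  )))
  boundaries <- boundaries[boundaries > 0]
  list(pops = pops, P = P,
       ep_start = ep_start, ep_size = ep_size, ep_rate = ep_rate,
       split_time = split_time, split_parent = split_parent,
       routes = routes, boundaries = boundaries)
}

# Size parameters of population p at time t: returns c(N_t, r) where the size
# u >= 0 generations further back is N_t * exp(-r * u) (until the next epoch).
epoch_at <- function(cm, p, t) {
  i <- findInterval(t, cm$ep_start[[p]])
  r <- cm$ep_rate[[p]][i]
  n_t <- cm$ep_size[[p]][i] * exp(-r * (t - cm$ep_start[[p]][i]))
  c(n_t, r)
}

# Waiting time to the next coalescence among k lineages in a population of
# current size N_t with backward size N_t * exp(-r u): inverse of the
# cumulative hazard of an exponentially time-rescaled coalescent.
draw_coalescence_time <- function(k, n_t, r) {
  a <- k * (k - 1) / 2 / (2 * n_t)
  e <- stats::rexp(1L)
  if (r == 0) return(e / a)
  arg <- 1 + r * e / a
  if (arg <= 0) return(Inf)  # shrinking hazard; no event within this epoch
  log(arg) / r
}

#' Simulate a genealogy under the structured coalescent
#'
#' Draws the genealogy of haplotypes sampled at present from the populations
#' of `model`, backward in time: within each population, pairs of lineages
#' coalesce at rate `1/(2N(t))` (with exponential epochs integrated exactly
#' via time rescaling); at split times all of the child population's lineages
#' move into the parent; migration relocates single lineages at the
#' configured backward rates. Deterministic given `seed`.
#'
#' @param model A valid [population_model()].
#' @param samples Named integer vector: haplotypes sampled per population
#'   (total at least 2). Use twice the number of diploid individuals.
#' @param seed Integer seed (or NULL).
#' @return An object of class `genealogy`: leaf populations, node times
#'   (generations), child/parent pointers, and per-branch population
#'   occupancy segments (used for population-specific mutation rates).
#' @examples
#' g <- simulate_genealogy(build_basic_model("constant"),
#'                         c(ancestral = 4, derived = 4), seed = 1)
#' tmrca(g)
#' @export
simulate_genealogy <- function(model, samples, seed = NULL) {
  cm <- compile_model(model)
  samples <- samples[samples > 0]
  if (is.null(names(samples)) || !all(names(samples) %in% cm$pops)) {
    stop("`samples` must be named by populations of the model")
  }
  n <- sum(samples)
  if (n < 2L) stop("need at least 2 sampled haplotypes for a coalescent")

  with_seed(seed, {
    n_nodes <- 2L * n - 1L
    node_time <- numeric(n_nodes)
    child1 <- integer(n_nodes)
    child2 <- integer(n_nodes)

    leaf_pop <- rep(match(names(samples), cm$pops), samples)
    active <- seq_len(n)          # node ids of live lineages
    act_pop <- leaf_pop           # population index per live lineage
    seg_open <- numeric(n)        # time each lineage entered its current pop
    next_node <- n

    # Growable branch-segment log.
    cap <- 4L * n
    seg_node <- integer(cap); seg_pop <- integer(cap)
    seg_a <- numeric(cap); seg_b <- numeric(cap)
    n_seg <- 0L
    push_seg <- function(node, pop, a, b) {
      if (b <= a) return(invisible(NULL))
      n_seg <<- n_seg + 1L
      if (n_seg > cap) {
        cap <<- 2L * cap
        length(seg_node) <<- cap; length(seg_pop) <<- cap
        length(seg_a) <<- cap; length(seg_b) <<- cap
      }
      seg_node[n_seg] <<- node; seg_pop[n_seg] <<- pop
      seg_a[n_seg] <<- a; seg_b[n_seg] <<- b
      invisible(NULL)
    }

    t <- 0
    b_idx <- 1L  # pointer into cm$boundaries
    repeat {
      if (length(active) == 1L) break
      while (b_idx <= length(cm$boundaries) && cm$boundaries[b_idx] <= t) {
        b_idx <- b_idx + 1L
      }
      t_next <- if (b_idx <= length(cm$boundaries)) cm$boundaries[b_idx] else Inf

      # Candidate coalescence per population.
      k <- tabulate(act_pop, cm$P)
      s_coal <- rep(Inf, cm$P)
      for (p in which(k >= 2L)) {
        er <- epoch_at(cm, p, t)
        s_coal[p] <- draw_coalescence_time(k[p], er[1L], er[2L])
      }

      # Candidate migration (rates constant within the phase).
      s_mig <- Inf
      mig_w <- NULL
      mig_rows <- integer(0)
      if (!is.null(cm$routes)) {
        act_rt <- which(cm$routes$start <= t & cm$routes$end > t &
                          k[cm$routes$pop] > 0L)
        if (length(act_rt)) {
          mig_w <- k[cm$routes$pop[act_rt]] * cm$routes$rate[act_rt]
          mig_rows <- act_rt
          s_mig <- stats::rexp(1L, rate = sum(mig_w))
        }
      }

      s_star <- min(min(s_coal), s_mig)
      if (t + s_star >= t_next) {
        if (is.infinite(t_next)) {
          stop("lineages cannot all coalesce: disconnected populations ",
               "with no migration or future splits")
        }
        t <- t_next
        # Apply any splits whose time has been reached: child lineages move
        # into the parent (transitively, if several splits coincide).
        repeat {
          moved <- FALSE
          for (i in seq_along(active)) {
            p <- act_pop[i]
            if (is.finite(cm$split_time[p]) && cm$split_time[p] <= t) {
              push_seg(active[i], p, seg_open[i], t)
              act_pop[i] <- cm$split_parent[p]
              seg_open[i] <- t
              moved <- TRUE
            }
          }
          if (!moved) break
        }
        next
      }

      t <- t + s_star
      if (s_mig < min(s_coal)) {
        # Migration: relocate one lineage.
        rt <- mig_rows[if (length(mig_rows) == 1L) 1L else
          sample.int(length(mig_rows), 1L, prob = mig_w)]
        from_pop <- cm$routes$pop[rt]
        cand <- which(act_pop == from_pop)
        i <- cand[if (length(cand) == 1L) 1L else
          sample.int(length(cand), 1L)]
        push_seg(active[i], from_pop, seg_open[i], t)
        act_pop[i] <- cm$routes$dest[rt]
        seg_open[i] <- t
      } else {
        # Coalescence in the population with the smallest waiting time.
        p <- which.min(s_coal)
        cand <- which(act_pop == p)
        pair <- cand[sample.int(length(cand), 2L)]
        for (i in pair) push_seg(active[i], p, seg_open[i], t)
        next_node <- next_node + 1L
        node_time[next_node] <- t
        child1[next_node] <- active[pair[1L]]
        child2[next_node] <- active[pair[2L]]
        active <- c(active[-pair], next_node)
        act_pop <- c(act_pop[-pair], p)
        seg_open <- c(seg_open[-pair], t)
      }
    }

    parent <- integer(n_nodes)
    parent[child1[child1 > 0L]] <- which(child1 > 0L)
    parent[child2[child2 > 0L]] <- which(child2 > 0L)

    structure(list(
      n = n, leaf_pop = leaf_pop, pops = cm$pops,
      node_time = node_time, child1 = child1, child2 = child2,
      parent = parent,
      segments = data.frame(node = seg_node[seq_len(n_seg)],
                            pop = seg_pop[seq_len(n_seg)],
                            start = seg_a[seq_len(n_seg)],
                            end = seg_b[seq_len(n_seg)]),
      samples = samples
    ), class = "genealogy")
  })
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy: %d leaves, TMRCA %.1f generations, total length %.1f>\n",
              x$n, tmrca(x), total_branch_length(x)))
  invisible(x)
}

#' Genealogy summaries
#'
#' `tmrca()` returns the time (generations) of the sample's most recent
#' common ancestor; `total_branch_length()` the summed branch lengths.
#'
#' @param x A `genealogy`.
#' @export
tmrca <- function(x) max(x$node_time)

#' @rdname tmrca
#' @export
total_branch_length <- function(x) {
  non_root <- which(x$parent > 0L)
  sum(x$node_time[x$parent[non_root]] - x$node_time[non_root])
}

# Descendant leaf sets per node (children precede parents in node order).
leaf_sets <- function(gen) {
  n_nodes <- 2L * gen$n - 1L
  ls <- vector("list", n_nodes)
  for (i in seq_len(gen$n)) ls[[i]] <- i
  if (n_nodes > gen$n) {
    for (m in (gen$n + 1L):n_nodes) {
      ls[[m]] <- c(ls[[gen$child1[m]]], ls[[gen$child2[m]]])
    }
  }
  ls
}

## Mutation placement ----------------------------------------------------------

#' Drop mutations onto a genealogy under a context-specific rate model
#'
#' For every branch and site, the number of mutations is Poisson with mean
#' branch-length x site total rate; the derived base is drawn from the site's
#' conditional distribution (the three matrix entries for its ancestral
#' triplet). Sites struck more than once anywhere on the genealogy are
#' discarded, keeping only biallelic sites. Contexts are always the ancestral
#' triplets of `seq`.
#'
#' Population-specific mutation models are supported by passing a named list
#' of matrices (one per population of the genealogy's model): each branch
#' segment mutates at the rate of the population it occupied.
#'
#' @param gen A [simulate_genealogy()] result.
#' @param seq An [ancestral_sequence()] without missing sites.
#' @param matrix A normalized `rate_matrix`, or a named list of them covering
#'   every population.
#' @param seed Integer seed (or NULL).
#' @param start,end 1-based interior window (defaults: the whole interior,
#'   `2 .. length(seq)-1`).
#' @return A [variant_table()].
#' @export
place_mutations <- function(gen, seq, matrix, seed = NULL,
                            start = NULL, end = NULL) {
  stopifnot(inherits(gen, "genealogy"), inherits(seq, "ancestral_sequence"))
  L <- seq_length(seq)
  if (is.null(start)) start <- 2L
  if (is.null(end)) end <- L - 1L
  if (start < 2L || end > L - 1L || end < start) {
    stop("window must lie within the sequence interior (2 .. length-1)")
  }
  pop_mats <- resolve_pop_matrices(matrix, gen$pops)

  positions <- start:end
  trip_idx <- position_triplet_index(seq, positions)
  n_t <- tabulate(trip_idx, 64L)
  pos_by_trip <- split(positions, factor(trip_idx, levels = 1:64))

  with_seed(seed, {
    mut_node <- integer(0); mut_pos <- integer(0)
    mut_trip <- integer(0); mut_der <- integer(0)

    for (p in seq_along(gen$pops)) {
      segs <- gen$segments[gen$segments$pop == p, , drop = FALSE]
      if (nrow(segs) == 0L) next
      mat <- pop_mats[[p]]
      totals <- triplet_total_rates(mat)
      cat_w <- n_t * totals
      rate_window <- sum(cat_w)
      if (rate_window == 0) next
      w <- segs$end - segs$start
      m <- stats::rpois(1L, sum(w) * rate_window)
      if (m == 0L) next

      seg_pick <- sample.int(nrow(segs), m, replace = TRUE, prob = w)
      tcat <- sample.int(64L, m, replace = TRUE, prob = cat_w)
      pos <- integer(m)
      der <- integer(m)
      cond <- triplet_conditional(mat)
      for (u in unique(tcat)) {
        sel <- which(tcat == u)
        cand <- pos_by_trip[[u]]
        pos[sel] <- cand[sample.int(length(cand), length(sel), replace = TRUE)]
        der[sel] <- sample.int(4L, length(sel), replace = TRUE, prob = cond[u, ])
      }
      mut_node <- c(mut_node, segs$node[seg_pick])
      mut_pos <- c(mut_pos, pos)
      mut_trip <- c(mut_trip, tcat)
      mut_der <- c(mut_der, der)
    }

    # Biallelic filter: discard every site hit more than once.
    multi <- unique(mut_pos[duplicated(mut_pos)])
    keep <- !(mut_pos %in% multi)
    mut_node <- mut_node[keep]; mut_pos <- mut_pos[keep]
    mut_trip <- mut_trip[keep]; mut_der <- mut_der[keep]

    hap <- haplotype_frame(gen$samples)
    ord <- order(mut_pos)
    variants <- data.frame(pos = mut_pos[ord],
                           triplet = .TRIPLETS[mut_trip[ord]],
                           derived = .BASES[mut_der[ord]])
    if (nrow(variants) == 0L) {
      g <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0L, gen$n))
      return(variant_table(variants, g, hap))
    }
    ls <- leaf_sets(gen)
    carriers <- ls[mut_node[ord]]
    sizes <- lengths(carriers)
    g <- Matrix::sparseMatrix(i = rep.int(seq_along(carriers), sizes),
                              j = unlist(carriers, use.names = FALSE),
                              x = 1,
                              dims = c(length(carriers), gen$n))
    variant_table(variants, g, hap)
  })
}

# Normalize `matrix` into one rate_matrix per population (indexed like pops).
resolve_pop_matrices <- function(matrix, pops) {
  if (inherits(matrix, "rate_matrix")) {
    if (!is_normalized(matrix)) {
      stop("rate matrix must be normalized (see normalize_overall_rate)")
    }
    return(rep(list(matrix), length(pops)))
  }
  if (is.list(matrix)) {
    if (!all(pops %in% names(matrix))) {
      stop("per-population matrix list must cover populations: ",
           paste(setdiff(pops, names(matrix)), collapse = ", "))
    }
    out <- matrix[pops]
    for (m in out) {
      if (!inherits(m, "rate_matrix") || !is_normalized(m)) {
        stop("all per-population matrices must be normalized rate_matrix objects")
      }
    }
    return(out)
  }
  stop("`matrix` must be a rate_matrix or a named list of them")
}

## Windowed chromosome simulation ---------------------------------------------

#' Simulate a variant data set over a sequence
#'
#' Partitions the sequence interior into non-recombining windows (default
#' 10 kb), simulates an independent genealogy per window — the package's
#' free-recombination-between / no-recombination-within approximation to a
#' constant crossover rate — places mutations, and returns the union of the
#' per-window tables with global coordinates. Fully reproducible given
#' `seed`: each window draws its own stream via [seed_stream()].
#'
#' @param model A valid [population_model()].
#' @param seq An [ancestral_sequence()] without missing sites.
#' @param matrix A normalized `rate_matrix` or named per-population list.
#' @param samples Named haplotype counts per population.
#' @param window_length Window size in bp (default 10000).
#' @param seed Integer seed (or NULL).
#' @return A [variant_table()].
#' @examples
#' s <- generate_sequence(20002, seed = 1)
#' m <- normalize_overall_rate(build_uniform_matrix(), s, 1e-7)
#' simulate_dataset(build_basic_model("constant"), s, m,
#'                  c(ancestral = 4, derived = 4), seed = 1)
#' @export
simulate_dataset <- function(model, seq, matrix, samples,
                             window_length = 10000, seed = NULL) {
  L <- seq_length(seq)
  if (window_length > L) stop("`window_length` exceeds the sequence length")
  starts <- seq.int(2L, L - 1L, by = window_length)
  tables <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    a <- starts[w]
    b <- min(a + window_length - 1L, L - 1L)
    tseed <- if (is.null(seed)) NULL else seed_stream(seed, "tree", w)
    mseed <- if (is.null(seed)) NULL else seed_stream(seed, "mutations", w)
    gen <- simulate_genealogy(model, samples, seed = tseed)
    tables[[w]] <- place_mutations(gen, seq, matrix, seed = mseed,
                                   start = a, end = b)
  }
  combine_variant_tables(tables)
}
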