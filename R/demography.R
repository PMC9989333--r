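## Demographic models: populations with size epochs, splits, migration -------

#' Build the pieces of a demographic model
#'
#' A [population_model()] describes one or more populations backward in time.
#' Each population has a list of size epochs; populations are joined, looking
#' backward, by split events (the child's lineages move into the parent), and
#' may exchange migrants.
#'
#' `epoch(start_time, size, growth_rate)` describes a population-size phase
#' beginning `start_time` generations before present and extending into the
#' past until the next epoch (or the population's split). `size` is the
#' number of diploid individuals N at `start_time` (the epoch's most recent
#' boundary); with exponential forward growth rate `r = growth_rate` per
#' generation, the size `t >= start_time` generations before present is
#' `N * exp(-r * (t - start_time))`. The pairwise coalescence rate is
#' `1 / (2 N(t))` per generation (diploid convention).
#'
#' `split_event(time, child, parent)` declares that, `time` generations
#' before present, population `child` originated from `parent`: backward in
#' time all of the child's lineages move into the parent.
#'
#' `migration(from, to, rate, migrants, start, end)` declares forward-in-time
#' migration from population `from` into `to`: `rate` is the fraction of `to`
#' replaced by immigrants from `from` each generation (equal, backward in
#' time, to the per-lineage rate at which lineages in `to` trace their parent
#' to `from`). Alternatively supply `migrants`, the expected number M of
#' diploid immigrant individuals per generation, converted internally via
#' `m = M / (2 N_to)` using the destination size in the epoch containing
#' `start`. The flow is `active` over `[start, end]` generations before
#' present.
#'
#' @param start_time Generations before present at which the epoch begins.
#' @param size Diploid population size N at `start_time`.
#' @param growth_rate Forward per-generation exponential growth rate
#'   (0 = constant size).
#' @param time Generations before present of the split.
#' @param child,parent Population identifiers.
#' @param from,to Population identifiers (forward-in-time direction).
#' @param rate Per-generation migration fraction in `[0, 1]`.
#' @param migrants Expected diploid migrant individuals per generation
#'   (alternative to `rate`).
#' @param start,end Generations before present bounding the active interval.
#' @return `epoch()`, `split_event()` and `migration()` return small tagged
#'   lists consumed by [population_model()].
#' @seealso [population_model()], [build_basic_model()], [load_model()]
#' @examples
#' epoch(0, 10000)
#' split_event(4000, "derived", "ancestral")
#' migration("AFR", "EUR", rate = 2.5e-5)
#' @export
epoch <- function(start_time, size, growth_rate = 0) {
  structure(list(start_time = as.numeric(start_time),
                 size = as.numeric(size),
                 growth_rate = as.numeric(growth_rate)),
            class = "ms_epoch")
}

#' @rdname epoch
#' @export
split_event <- function(time, child, parent) {
  structure(list(time = as.numeric(time),
                 child = as.character(child),
                 parent = as.character(parent)),
            class = "ms_split")
}

#' @rdname epoch
#' @export
migration <- function(from, to, rate = NULL, migrants = NULL,
                      start = 0, end = Inf) {
  if (is.null(rate) && is.null(migrants)) {
    stop("supply either `rate` or `migrants`")
  }
  structure(list(from = as.character(from), to = as.character(to),
                 rate = if (is.null(rate)) NULL else as.numeric(rate),
                 migrants = if (is.null(migrants)) NULL else as.numeric(migrants),
                 start = as.numeric(start), end = as.numeric(end)),
            class = "ms_migration")
}

#' Assemble a demographic model
#'
#' @param populations Named list: one entry per population, each a list of
#'   [epoch()]s (time-ordered or not; they are sorted).
#' @param splits List of [split_event()]s. Every population except one (the
#'   root) must be the child of exactly one split.
#' @param migrations List of [migration()]s (may be empty).
#' @param species One of `"human"`, `"chimpanzee"`, `"generic"`.
#' @param generation_time_years Years per generation, used by
#'   [years_to_generations()] (25 for human, 20 for chimpanzee by convention).
#' @return An object of class `population_model`.
#' @examples
#' m <- population_model(
#'   populations = list(anc = list(epoch(0, 10000)),
#'                      der = list(epoch(0, 1000))),
#'   splits = list(split_event(4000, "der", "anc"))
#' )
#' validate_model(m)
#' @export
population_model <- function(populations, splits = list(), migrations = list(),
                             species = "generic", generation_time_years = 25) {
  stopifnot(is.list(populations), length(populations) >= 1L,
            !is.null(names(populations)), all(nzchar(names(populations))))
  populations <- lapply(populations, function(eps) {
    if (inherits(eps, "ms_epoch")) eps <- list(eps)
    eps[order(vapply(eps, `[[`, numeric(1), "start_time"))]
  })
  if (inherits(splits, "ms_split")) splits <- list(splits)
  if (inherits(migrations, "ms_migration")) migrations <- list(migrations)
  structure(list(populations = populations, splits = splits,
                 migrations = migrations, species = species,
                 generation_time_years = as.numeric(generation_time_years)),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model: %s, %d population(s), generation time %g y>\n",
              x$species, length(x$populations), x$generation_time_years))
  for (p in names(x$populations)) {
    eps <- x$populations[[p]]
    cat(sprintf("  %s: %s\n", p, paste(vapply(eps, function(e) {
      sprintf("N=%g@%gg%s", e$size, e$start_time,
              if (e$growth_rate != 0) sprintf(" r=%g", e$growth_rate) else "")
    }, character(1)), collapse = ", ")))
  }
  for (s in x$splits) {
    cat(sprintf("  split: %s from %s at %g generations\n",
                s$child, s$parent, s$time))
  }
  if (length(x$migrations)) {
    cat(sprintf("  %d migration route(s)\n", length(x$migrations)))
  }
  invisible(x)
}

## Validation -----------------------------------------------------------------

#' Validate a demographic model
#'
#' Checks all structural invariants: positive sizes, non-negative times,
#' ordered non-overlapping epochs starting at 0, migration rates in `[0, 1]`,
#' known population identifiers, and that the split events form a tree (every
#' non-root population is the child of exactly one split) so that backward in
#' time all lineages can reach a common ancestor.
#'
#' @param model A [population_model()].
#' @return Character vector of violation descriptions; empty if valid.
#' @examples
#' validate_model(build_basic_model("constant"))
#' @export
validate_model <- function(model) {
  v <- character(0)
  if (!inherits(model, "population_model")) {
    return("not a population_model object")
  }
  pops <- names(model$populations)
  if (anyDuplicated(pops)) v <- c(v, "duplicated population identifiers")
  split_time <- split_time_of(model)

  for (p in pops) {
    eps <- model$populations[[p]]
    st <- vapply(eps, `[[`, numeric(1), "start_time")
    sz <- vapply(eps, `[[`, numeric(1), "size")
    if (any(sz <= 0)) {
      v <- c(v, sprintf("population '%s': population_size must be > 0", p))
    }
    if (any(st < 0)) {
      v <- c(v, sprintf("population '%s': epoch start_time must be >= 0", p))
    }
    if (length(st) == 0L || st[1] != 0) {
      v <- c(v, sprintf("population '%s': needs an epoch starting at time 0", p))
    }
    if (anyDuplicated(st)) {
      v <- c(v, sprintf("population '%s': overlapping epochs", p))
    }
    tsp <- split_time[[p]]
    if (is.finite(tsp) && any(st >= tsp)) {
      v <- c(v, sprintf(
        "population '%s': epoch starts at or beyond its split time (%g)",
        p, tsp))
    }
  }

  n_child <- table(factor(vapply(model$splits, `[[`, character(1), "child"),
                          levels = pops))
  roots <- pops[n_child == 0]
  if (any(n_child > 1)) {
    v <- c(v, sprintf("population(s) %s are the child of more than one split",
                      paste(pops[n_child > 1], collapse = ", ")))
  }
  if (length(pops) > 1L && length(roots) != 1L) {
    v <- c(v, sprintf(
      "splits must join all populations into one tree (found %d root(s))",
      length(roots)))
  }
  for (s in model$splits) {
    if (!(s$child %in% pops) || !(s$parent %in% pops)) {
      v <- c(v, sprintf("split %s->%s references unknown population",
                        s$child, s$parent))
    } else {
      if (s$child == s$parent) {
        v <- c(v, sprintf("split at %g: child equals parent ('%s')",
                          s$time, s$child))
      }
      if (!(s$time > 0)) {
        v <- c(v, sprintf("split %s->%s: time must be > 0", s$child, s$parent))
      }
      # The parent must still exist (not yet merged away) at the split time.
      tp <- split_time[[s$parent]]
      if (is.finite(tp) && tp <= s$time) {
        v <- c(v, sprintf(
          "split %s->%s at %g: parent has already merged away (at %g)",
          s$child, s$parent, s$time, tp))
      }
    }
  }
  # Cycle check: walk each population rootward.
  if (length(pops) > 1L && length(roots) == 1L) {
    parent_of <- stats::setNames(
      vapply(model$splits, `[[`, character(1), "parent"),
      vapply(model$splits, `[[`, character(1), "child"))
    for (p in pops) {
      seen <- character(0)
      q <- p
      while (q %in% names(parent_of)) {
        if (q %in% seen) {
          v <- c(v, "split events contain a cycle")
          break
        }
        seen <- c(seen, q)
        q <- parent_of[[q]]
      }
    }
    v <- unique(v)
  }

  for (m in model$migrations) {
    if (!(m$from %in% pops) || !(m$to %in% pops)) {
      v <- c(v, sprintf("migration %s->%s references unknown population",
                        m$from, m$to))
      next
    }
    r <- migration_backward_rate(m, model)
    if (is.na(r) || r < 0 || r > 1) {
      v <- c(v, sprintf("migration %s->%s: rate must lie in [0, 1] (got %g)",
                        m$from, m$to, r))
    }
    if (m$start < 0 || m$end < m$start) {
      v <- c(v, sprintf("migration %s->%s: invalid active interval [%g, %g]",
                        m$from, m$to, m$start, m$end))
    }
  }
  v
}

# Split time of each population (Inf for the root), as a named list.
split_time_of <- function(model) {
  out <- as.list(rep(Inf, length(model$populations)))
  names(out) <- names(model$populations)
  for (s in model$splits) {
    if (s$child %in% names(out)) out[[s$child]] <- s$time
  }
  out
}

# Population size of `pop` at `time` generations before present.
population_size_at <- function(model, pop, time) {
  eps <- model$populations[[pop]]
  st <- vapply(eps, `[[`, numeric(1), "start_time")
  i <- max(which(st <= time))
  e <- eps[[i]]
  e$size * exp(-e$growth_rate * (time - e$start_time))
}

# Backward per-lineage rate of a migration route: lineages in `to` move to
# `from` at this rate per generation.
migration_backward_rate <- function(m, model) {
  if (!is.null(m$rate)) return(m$rate)
  n_to <- population_size_at(model, m$to, m$start)
  m$migrants / (2 * n_to)
}

## Basic models ---------------------------------------------------------------

#' Basic two-population demographic models
#'
#' Three textbook histories used to isolate the effect of a size change: an
#' ancestral population of 10,000 diploid individuals from which a derived
#' population splits and then either stays at 10,000 (`"constant"`), declines
#' instantaneously to 1,000 (`"decline"`), or grows instantaneously to
#' 100,000 (`"growth"`). No migration. The forward-simulation burn-in
#' convention for these models is 10 Ne = 100,000 generations; the coalescent
#' engine needs no burn-in (the root epoch extends indefinitely).
#'
#' The split-to-sampling interval is not part of the published description;
#' the default of 4,000 generations is long enough for private variation to
#' accumulate yet short relative to Ne, and can be overridden.
#'
#' @param variant One of `"constant"`, `"decline"`, `"growth"`.
#' @param split_time Generations before present of the split (default 4000).
#' @param ancestral_size Diploid size of the ancestral population
#'   (default 10000).
#' @return A validated [population_model()] with populations `"ancestral"`
#'   and `"derived"`.
#' @examples
#' build_basic_model("decline")$populations$derived[[1]]$size  # 1000
#' @export
build_basic_model <- function(variant = c("constant", "decline", "growth"),
                              split_time = 4000, ancestral_size = 10000) {
  variant <- match.arg(variant)
  derived_size <- switch(variant,
                         constant = 10000,
                         decline = 1000,
                         growth = 100000)
  m <- population_model(
    populations = list(
      ancestral = list(epoch(0, ancestral_size)),
      derived = list(epoch(0, derived_size))
    ),
    splits = list(split_event(split_time, "derived", "ancestral")),
    migrations = list(),
    species = "generic",
    generation_time_years = 25
  )
  stopifnot(length(validate_model(m)) == 0L)
  m
}

## Config I/O ----------------------------------------------------------------

#' Load a demographic model from a JSON configuration
#'
#' The schema mirrors [population_model()]: top-level keys `populations`
#' (each with `id` and `epochs`), `splits`, `migrations`, `species`,
#' `generation_time_years`, and `time_units` (`"generations"` or `"years"`;
#' with `"years"`, all `start_time`, split `time` and migration `start`/`end`
#' values are divided by the generation time; growth rates are always per
#' generation). Sizes are diploid individuals. Migration entries give either
#' `rate` (per-generation fraction) or `migrants` (diploid migrants per
#' generation, converted via m = M / (2 N_to)).
#'
#' Two configurations ship with the package (see
#' `system.file("extdata/models", package = "mutspectra")`): a
#' three-population human out-of-Africa history and a four-subspecies
#' chimpanzee history.
#'
#' @param config Path to a JSON file, a JSON string, or an already-parsed
#'   list.
#' @return A validated [population_model()].
#' @examples
#' path <- system.file("extdata/models/human_ooa3.json", package = "mutspectra")
#' human <- load_model(path)
#' names(human$populations)
#' @export
load_model <- function(config) {
  doc <- if (is.list(config)) {
    config
  } else if (is.character(config) && length(config) == 1L) {
    jsonlite::fromJSON(config, simplifyVector = FALSE)
  } else {
    stop("`config` must be a file path, JSON string, or list")
  }
  if (length(doc) == 0L || is.null(doc$populations) ||
      length(doc$populations) == 0L) {
    stop("model config: missing or empty `populations` section")
  }
  gt <- if (is.null(doc$generation_time_years)) 25 else
    as.numeric(doc$generation_time_years)
  units <- if (is.null(doc$time_units)) "generations" else doc$time_units
  if (!units %in% c("generations", "years")) {
    stop("model config: `time_units` must be 'generations' or 'years'")
  }
  tconv <- if (units == "years") function(t) t / gt else identity

  pops <- list()
  for (p in doc$populations) {
    if (is.null(p$id) || is.null(p$epochs) || length(p$epochs) == 0L) {
      stop("model config: each population needs `id` and non-empty `epochs`")
    }
    pops[[p$id]] <- lapply(p$epochs, function(e) {
      if (is.null(e$size)) stop("model config: epoch without `size`")
      epoch(start_time = tconv(if (is.null(e$start_time)) 0 else e$start_time),
            size = e$size,
            growth_rate = if (is.null(e$growth_rate)) 0 else e$growth_rate)
    })
  }
  splits <- lapply(doc$splits %||% list(), function(s) {
    if (is.null(s$time) || is.null(s$child) || is.null(s$parent)) {
      stop("model config: split needs `time`, `child`, `parent`")
    }
    split_event(tconv(s$time), s$child, s$parent)
  })
  migrations <- lapply(doc$migrations %||% list(), function(m) {
    if (is.null(m$from) || is.null(m$to)) {
      stop("model config: migration needs `from` and `to`")
    }
    migration(m$from, m$to, rate = m$rate, migrants = m$migrants,
              start = tconv(m$start %||% 0),
              end = if (is.null(m$end)) Inf else tconv(m$end))
  })
  model <- population_model(
    populations = pops, splits = splits, migrations = migrations,
    species = doc$species %||% "generic",
    generation_time_years = gt
  )
  v <- validate_model(model)
  if (length(v)) {
    stop("model config failed validation:\n  ", paste(v, collapse = "\n  "))
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Time-unit conversion -------------------------------------------------------

#' Convert between years and generations
#'
#' Uses the model's `generation_time_years` (25 for the shipped human model,
#' 20 for chimpanzee).
#'
#' @param years,generations Non-negative numeric vector.
#' @param model A [population_model()].
#' @return Numeric vector of generations (resp. years).
#' @examples
#' m <- build_basic_model("constant")  # generation time 25 y
#' years_to_generations(100, m)        # 4
#' @export
years_to_generations <- function(years, model) {
  stopifnot(inherits(model, "population_model"),
            model$generation_time_years > 0)
  if (any(years < 0)) stop("`years` must be non-negative")
  years / model$generation_time_years
}

#' @rdname years_to_generations
#' @export
generations_to_years <- function(generations, model) {
  stopifnot(inherits(model, "population_model"),
            model$generation_time_years > 0)
  if (any(generations < 0)) stop("`generations` must be non-negative")
  generations * model$generation_time_years
}
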