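## Packaged experiments: broad-scale convergence, fine-scale power --------------

#' Build an experiment configuration
#'
#' A validated list of everything the two experiment drivers need. `model`
#' may be a [population_model()], a path to a JSON model config, or a string
#' `"basic:constant"` / `"basic:decline"` / `"basic:growth"`. Defaults are
#' desk-scale (a 100 kb chromosome stand-in, 20 replicates); the published
#' cluster-scale settings (46 Mb chromosome, 1,000 replicates, 1 Mb regions)
#' are reachable purely through configuration.
#'
#' @param model Model specification (see above).
#' @param sequence_length Synthetic ancestral sequence length in bp.
#' @param composition Base composition for the synthetic sequence.
#' @param matrix `NULL` for the uniform (Jukes-Cantor) matrix, or a path to a
#'   192-row matrix table for [load_matrix()].
#' @param overall_rate Sequence-averaged mutation rate per bp per generation.
#' @param samples Named vector: diploid individuals sampled per population
#'   (the "whole population" stand-in for broad-scale runs).
#' @param scheme A [sampling_scheme()] for broad-scale subsampling.
#' @param replicates Chromosome replicates (broad-scale) or regions per
#'   scenario (fine-scale).
#' @param window_length Non-recombining window length in bp.
#' @param pair,types,folds,sizes Fine-scale grid (pair of populations, focal
#'   mutation types, fold shifts, diploid sizes).
#' @param alpha Two-tailed test level.
#' @param space Spectrum space.
#' @param seed Master seed.
#' @param out_dir Output directory for TSVs, or `NULL` to skip writing.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(model = "basic:constant",
                              sequence_length = 1e5,
                              composition = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                              matrix = NULL,
                              overall_rate = 1e-8,
                              samples = NULL,
                              scheme = sampling_scheme(c(5L, 10L, 20L, 50L,
                                                         100L),
                                                       replicates_per_size = 5),
                              replicates = 20,
                              window_length = 10000,
                              pair = NULL, types = "TCC>T",
                              folds = c(1, 1.5, 2), sizes = c(2, 10, 50),
                              alpha = 0.05, space = "stranded192",
                              seed = 1, out_dir = NULL) {
  cfg <- list(model = model, sequence_length = sequence_length,
              composition = composition, matrix = matrix,
              overall_rate = overall_rate, samples = samples,
              scheme = scheme, replicates = replicates,
              window_length = window_length, pair = pair, types = types,
              folds = folds, sizes = sizes, alpha = alpha, space = space,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "experiment_config"
  cfg
}

#' Load an experiment configuration from JSON
#'
#' Keys mirror [experiment_config()] arguments; `scheme` is given as
#' `{"sizes": [...], "replicates_per_size": n}`.
#'
#' @param path JSON file path.
#' @return An `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- doc[intersect(names(doc), names(formals(experiment_config)))]
  if (!is.null(args$scheme)) {
    args$scheme <- sampling_scheme(args$scheme$sizes,
                                   args$scheme$replicates_per_size %||% 5)
  }
  if (!is.null(args$composition)) {
    args$composition <- unlist(args$composition)
  }
  if (!is.null(args$samples)) args$samples <- unlist(args$samples)
  do.call(experiment_config, args)
}

resolve_model <- function(model) {
  if (inherits(model, "population_model")) return(model)
  if (is.character(model) && length(model) == 1L) {
    if (startsWith(model, "basic:")) {
      return(build_basic_model(sub("^basic:", "", model)))
    }
    return(load_model(model))
  }
  stop("cannot interpret `model` specification")
}

resolve_matrix <- function(matrix) {
  if (is.null(matrix)) return(build_uniform_matrix())
  if (inherits(matrix, "rate_matrix")) return(matrix)
  load_matrix(matrix)
}

# Short fingerprint of a configuration, recorded in output headers. The hash
# is an unsigned 32-bit value carried in a double, so it is formatted in two
# 16-bit halves (sprintf("%x") only accepts values below 2^31).
config_hash <- function(cfg) {
  key <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  h <- fnv1a32(key)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_tsv_output <- function(df, path, cfg, extra = character(0)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mutspectra output; config=%s seed=%s",
                       config_hash(cfg), format(cfg$seed)),
               extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Broad-scale experiment: spectrum convergence with sample size
#'
#' For each chromosome replicate: simulate the configured populations over a
#' synthetic ancestral sequence, and for each population compute the
#' full-sample private-SNP spectrum and the subsampling convergence curve
#' ([convergence_curve()]). Writes one TSV per population (plus a log) when
#' `out_dir` is set; identical configuration and seed give byte-identical
#' outputs.
#'
#' @param config An [experiment_config()]. `samples` defaults to 50 diploid
#'   individuals per model population.
#' @return Invisibly, a list with `curves` (data frame: population,
#'   replicate, size, replicate draw, total_difference, percent) and `config`.
#' @export
run_broad_scale <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  model <- resolve_model(config$model)
  pops <- names(model$populations)
  samples_ind <- config$samples %||%
    stats::setNames(rep(50L, length(pops)), pops)
  samples_hap <- stats::setNames(2L * as.integer(samples_ind),
                                 names(samples_ind))
  base_matrix <- resolve_matrix(config$matrix)

  curves <- vector("list", 0L)
  for (rep_i in seq_len(config$replicates)) {
    seq <- generate_sequence(config$sequence_length,
                             config$composition,
                             seed = seed_stream(config$seed, "chromosome",
                                                rep_i),
                             label = sprintf("chromosome%d", rep_i))
    mat <- normalize_overall_rate(base_matrix, seq, config$overall_rate)
    tab <- simulate_dataset(model, seq, mat, samples_hap,
                            window_length = config$window_length,
                            seed = seed_stream(config$seed, "dataset", rep_i))
    for (p in names(samples_hap)) {
      cc <- convergence_curve(tab, p, config$scheme,
                              seed = seed_stream(config$seed, "curve",
                                                 rep_i, p),
                              space = config$space)
      curves[[length(curves) + 1L]] <-
        cbind(population = p, chromosome_replicate = rep_i, cc)
    }
  }
  curves <- do.call(rbind, curves)

  if (!is.null(config$out_dir)) {
    for (p in unique(curves$population)) {
      write_tsv_output(curves[curves$population == p, ],
                       file.path(config$out_dir,
                                 sprintf("convergence_%s.tsv", p)),
                       config)
    }
    write_tsv_output(
      data.frame(stage = "broad_scale",
                 populations = paste(pops, collapse = ","),
                 replicates = config$replicates,
                 sequence_length = config$sequence_length,
                 seed = config$seed),
      file.path(config$out_dir, "broad_scale_log.tsv"), config)
  }
  invisible(list(curves = curves, config = config))
}

#' Fine-scale experiment: power to detect a single-type shift
#'
#' Runs [power_surface()] for the configured population pair over the fold
#' and size grids. Writes `power_surface.tsv` and `power_min.tsv` when
#' `out_dir` is set.
#'
#' @param config An [experiment_config()] with `pair` set (defaults to the
#'   model's first two populations).
#' @return Invisibly, a list with `surface`, `minimum` and `config`.
#' @export
run_fine_scale <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  model <- resolve_model(config$model)
  pair <- config$pair %||% names(model$populations)[1:2]
  surface <- power_surface(
    model, pair, folds = config$folds, sizes = config$sizes,
    types = config$types, region_length = config$sequence_length,
    replicates = config$replicates, alpha = config$alpha,
    seed = config$seed, space = if (config$space == "stranded192")
      "stranded192" else "collapsed96",
    window_length = config$window_length,
    overall_rate = config$overall_rate)
  minimum <- report_min_power(surface)
  if (!is.null(config$out_dir)) {
    write_tsv_output(surface, file.path(config$out_dir, "power_surface.tsv"),
                     config)
    write_tsv_output(minimum, file.path(config$out_dir, "power_min.tsv"),
                     config)
  }
  invisible(list(surface = surface, minimum = minimum, config = config))
}
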