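#' Full run configuration
#'
#' Collects every tunable of the prediction pipeline with the standard
#' defaults: population 300, 100 iterations, `c1 = c2 = 2`, inertia
#' 0.9 -> 0.4, stagnation patience 5 with half the swarm complemented,
#' GGF criteria, candidate lengths 200-2000 bp, 10 kb windows with 2 kb
#' overlap, merge gap threshold 200 bp, and the merge refinement enabled.
#'
#' @param population,iterations,c1,c2,w_max,w_min,v_max,patience,replace_fraction,mode
#'   Swarm parameters; see [swarm_config()].
#' @param criteria Criteria preset name (`"ggf"` or `"tj"`) or a
#'   [cpg_criteria()] object.
#' @param len_lo,len_hi Candidate island length band (bp).
#' @param window_size,overlap Window tiling (bp).
#' @param restarts_per_window Deflation reruns per window.
#' @param gap_threshold Merge gap threshold (bp).
#' @param rl_enabled Run the merge refinement after extraction.
#' @param seed RNG seed; recorded in the run and set by [cpg_predict()].
#' @return A list of class `cpg_run_config`.
#' @export
run_config <- function(population = 300L, iterations = 100L, c1 = 2, c2 = 2,
                       w_max = 0.9, w_min = 0.4, v_max = NULL,
                       patience = 5L, replace_fraction = 0.5,
                       mode = c("cpso", "pso"),
                       criteria = "ggf", len_lo = 200L, len_hi = 2000L,
                       window_size = 10000L, overlap = 2000L,
                       restarts_per_window = 5L,
                       gap_threshold = 200L, rl_enabled = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  crit <- if (inherits(criteria, "cpg_criteria")) criteria else cpg_criteria(criteria)
  structure(
    list(
      swarm = swarm_config(population, iterations, c1, c2, w_max, w_min,
                           v_max, patience, replace_fraction, mode),
      fitness = fitness_config(crit, len_lo, len_hi),
      window_size = as.integer(window_size), overlap = as.integer(overlap),
      restarts_per_window = as.integer(restarts_per_window),
      gap_threshold = as.integer(gap_threshold),
      rl_enabled = isTRUE(rl_enabled), seed = as.integer(seed)
    ),
    class = "cpg_run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Accepts a flat mapping with any subset of the [run_config()] keys
#' (`population`, `iterations`, `c1`, `c2`, `w_max`, `w_min`, `v_max`,
#' `patience`, `replace_fraction`, `mode`, `criteria`, `min_length`,
#' `min_gc`, `min_oe`, `len_lo`, `len_hi`, `window_size`, `overlap`,
#' `restarts_per_window`, `gap_threshold`, `rl_enabled`, `seed`);
#' unspecified keys keep their defaults.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A `cpg_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  crit_keys <- intersect(names(raw), c("min_length", "min_gc", "min_oe"))
  criteria <- do.call(cpg_criteria, c(list(preset = raw$criteria %||% "ggf"),
                                      raw[crit_keys]))
  args <- raw[intersect(names(raw), setdiff(names(formals(run_config)), "criteria"))]
  do.call(run_config, c(args, list(criteria = criteria)))
}

#' Predict CpG islands in a genome
#'
#' The main pipeline: for each sequence, optionally mask supplied repeat
#' (Alu) intervals, tile it into windows, run the swarm per window with
#' deflation restarts, then merge-refine the pooled islands.  When `alu`
#' intervals are given the criteria switch to the Takai-Jones preset (the
#' convention for repeat-masked prediction) unless the configuration
#' already names a criteria set other than the default GGF.
#'
#' @param genome Genome tibble from [read_fasta()] or
#'   [simulate_cpg_genome()] (columns `name`, `length`, `seq`).
#' @param config A [run_config()].
#' @param alu Optional repeat-interval tibble (`chrom`, `start`, `end`) to
#'   mask before prediction.
#' @return An object of class `cpg_prediction` with elements `islands`
#'   (tibble: `chrom`, `start`, `end`, `length`, `gc`, `oe`, `fitness`),
#'   `config`, and `genome_info`.  [tidy()] returns the island tibble,
#'   [glance()] a one-row genome summary, [autoplot()] an island map.
#' @examples
#' \donttest{
#' set.seed(11)
#' sim <- simulate_cpg_genome(length = 30000,
#'   island_specs = example_island_specs()[c(3, 6), ])
#' fit <- cpg_predict(sim$genome, run_config(population = 80, seed = 11))
#' tidy(fit)
#' }
#' @export
cpg_predict <- function(genome, config = run_config(), alu = NULL) {
  stopifnot(inherits(config, "cpg_run_config"))
  if (!is.null(alu) && config$fitness$criteria$preset == "ggf") {
    config$fitness <- fitness_config(cpg_criteria("tj"),
                                     config$fitness$len_lo, config$fitness$len_hi)
  }
  set.seed(config$seed)
  islands <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    s <- genome$seq[i]
    if (!is.null(alu)) {
      m <- if ("chrom" %in% names(alu)) {
        alu[alu$chrom == genome$name[i], , drop = FALSE]
      } else {
        alu
      }
      if (nrow(m) > 0) s <- mask_intervals(s, m)
    }
    isl <- extract_islands(
      s, config$swarm, config$fitness,
      window_size = config$window_size, overlap = config$overlap,
      restarts_per_window = config$restarts_per_window
    )
    if (config$rl_enabled && nrow(isl) > 1) {
      isl <- refine_islands(isl, s, config$gap_threshold, config$fitness$criteria)
    }
    mutate(isl, chrom = genome$name[i], .before = 1)
  })
  structure(
    list(
      islands = islands,
      config = config,
      genome_info = select(genome, "name", "length")
    ),
    class = "cpg_prediction"
  )
}

#' @export
print.cpg_prediction <- function(x, ...) {
  cat(sprintf(
    "<cpg_prediction> %d island(s) on %d sequence(s) [%s criteria, mode %s, seed %d]\n",
    nrow(x$islands), nrow(x$genome_info),
    x$config$fitness$criteria$preset, x$config$swarm$mode, x$config$seed
  ))
  print(x$islands, ...)
  invisible(x)
}

#' @rdname cpg_predict
#' @param x A `cpg_prediction` object.
#' @param ... Unused.
#' @export
tidy.cpg_prediction <- function(x, ...) {
  x$islands
}

#' @rdname cpg_predict
#' @export
glance.cpg_prediction <- function(x, ...) {
  rep <- island_report(x$islands, x$genome_info)
  select(rep, "n_islands", "total_length", "avg_length",
         "coverage_pct", "gc_mean", "oe_mean")
}
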