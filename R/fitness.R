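#' Fitness configuration for candidate islands
#'
#' Bundles the criteria set with the length band a particle may propose.
#' The band 200-2000 bp reflects the typical extent of CpG islands; the
#' merge-refinement pass may later join islands into spans longer than
#' `len_hi`, but no single particle proposes one.
#'
#' @param criteria A [cpg_criteria()] object.
#' @param len_lo,len_hi Lower/upper bounds (bp) of the candidate length
#'   band, also the anchors of the length normalisation.
#' @return A list of class `cpg_fitness_config`.
#' @export
fitness_config <- function(criteria = cpg_criteria("ggf"),
                           len_lo = 200L, len_hi = 2000L) {
  stopifnot(len_lo < len_hi, len_lo > 0)
  structure(
    list(criteria = criteria, len_lo = as.integer(len_lo), len_hi = as.integer(len_hi)),
    class = "cpg_fitness_config"
  )
}

#' Normalised length score
#'
#' Linearly rescales an island length onto `[0, 1]` between the
#' configured band ends and clips outside it, so length contributes to the
#' fitness on the same scale as GC content and O/E ratio.
#'
#' @param length Length(s) in bp.
#' @param config A [fitness_config()].
#' @return Values in `[0, 1]`.
#' @examples
#' length_score(c(200, 1100, 2000), fitness_config())
#' @export
length_score <- function(length, config = fitness_config()) {
  pmin(pmax((length - config$len_lo) / (config$len_hi - config$len_lo), 0), 1)
}

## penalty per satisfied component for infeasible candidates: keeps the
## infeasible band [0, 0.3] strictly below the feasible floor (1.1) while
## preserving a gradient toward feasibility.
PENALTY_SCALE <- 0.1

## internal vectorised core shared by the optimizer (prefix-sum path) and
## the exported particle_fitness.
fitness_from_stats <- function(gc, oe, length, n_eff, config) {
  ls <- length_score(length, config)
  crit <- config$criteria
  len_ok <- length >= crit$min_length
  gc_ok <- !is.na(gc) & gc >= crit$min_gc
  oe_ok <- !is.na(oe) & oe >= crit$min_oe
  gc0 <- ifelse(is.na(gc), 0, gc)
  oe0 <- ifelse(is.na(oe), 0, oe)
  out <- ifelse(len_ok & gc_ok & oe_ok,
    gc0 + oe0 + ls,
    PENALTY_SCALE * (len_ok + gc_ok + oe_ok)
  )
  # an all-N candidate carries no evidence at all
  ifelse(n_eff == 0, 0, out)
}

#' Fitness of a candidate island
#'
#' The scalar score the swarm maximises.  When a candidate satisfies all
#' three island criteria (length, GC, O/E) its fitness is the sum
#' `gc + oe + length_score`, so better composition and greater length are
#' both rewarded; an infeasible candidate instead scores
#' `0.1 * (number of satisfied criteria)`, which keeps every infeasible
#' candidate strictly below every feasible one (max 0.3 < min 1.1) while
#' still grading progress toward feasibility.  All-`N` candidates score 0.
#'
#' @param counts Counts tibble from [count_nucleotides()] (vectorised over
#'   rows).
#' @param length Interval length(s) in bp (including any `N`s).
#' @param config A [fitness_config()].
#' @return Non-negative fitness value(s).
#' @export
particle_fitness <- function(counts, length, config = fitness_config()) {
  gc <- suppressWarnings(gc_content(counts))
  oe <- suppressWarnings(oe_ratio(counts))
  fitness_from_stats(gc, oe, length, counts$n_eff, config)
}
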