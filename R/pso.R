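#' Swarm configuration
#'
#' Parameters of the particle swarm: population 300, 100 iterations and
#' acceleration constants `c1 = c2 = 2`, with the inertia weight annealed
#' linearly from 0.9 to 0.4 over the run.  `v_max` bounds the per-dimension
#' velocity in bp; left `NULL` it is resolved to one fifth of the window
#' length at run time (bp-scale coordinates diverge without a bound).
#'
#' @param population Number of particles.
#' @param iterations Number of update iterations per window.
#' @param c1,c2 Cognitive/social acceleration constants.
#' @param w_max,w_min Initial and final inertia weights.
#' @param v_max Velocity bound in bp per dimension, or `NULL` to derive
#'   from the window length.
#' @param patience Consecutive non-improving iterations tolerated before a
#'   complementary restart (CPSO mode).
#' @param replace_fraction Fraction of the swarm repositioned by a
#'   complementary restart.
#' @param mode `"cpso"` (with complementary restarts) or `"pso"` (plain).
#' @return A list of class `cpg_swarm_config`.
#' @export
swarm_config <- function(population = 300L, iterations = 100L,
                         c1 = 2, c2 = 2, w_max = 0.9, w_min = 0.4,
                         v_max = NULL, patience = 5L, replace_fraction = 0.5,
                         mode = c("cpso", "pso")) {
  mode <- match.arg(mode)
  stopifnot(
    population > 1, iterations >= 1, w_min <= w_max,
    is.null(v_max) || v_max > 0,
    patience >= 1, replace_fraction > 0, replace_fraction < 1
  )
  structure(
    list(
      population = as.integer(population), iterations = as.integer(iterations),
      c1 = c1, c2 = c2, w_max = w_max, w_min = w_min, v_max = v_max,
      patience = as.integer(patience), replace_fraction = replace_fraction,
      mode = mode
    ),
    class = "cpg_swarm_config"
  )
}

#' Linearly annealed inertia weight
#'
#' @param move_i Current iteration (0-based; `0` gives `w_max`,
#'   `move_max` gives `w_min`).
#' @param move_max Total number of iterations.
#' @param config A [swarm_config()].
#' @return The inertia weight for this iteration.
#' @examples
#' inertia_weight(50, 100) # midpoint of the 0.9 -> 0.4 schedule
#' @export
inertia_weight <- function(move_i, move_max, config = swarm_config()) {
  if (move_max <= 0) abort("move_max must be positive", class = "cpgswarm_param_error")
  config$w_max - (config$w_max - config$w_min) * move_i / move_max
}

#' Particle velocity update
#'
#' The canonical update: inertia times the old velocity plus random
#' attractions toward the particle's personal best and the swarm's global
#' best, then clipped componentwise to `[-v_max, v_max]`.
#' `r1`/`r2` are drawn fresh per particle and dimension unless supplied
#' (supplying them makes the rule unit-testable).
#'
#' @param v,x,pbest_x Velocity, position and personal-best matrices
#'   (particles x dimensions), or vectors for a single particle.
#' @param gbest_x Global-best position (recycled across particles).
#' @param w Inertia weight for this iteration.
#' @param config A [swarm_config()].
#' @param v_max Velocity bound; defaults to `config$v_max` (unbounded if
#'   that is `NULL`).
#' @param r1,r2 Optional uniform draws in `(0, 1)`, same shape as `v`.
#' @return The new velocity, same shape as `v`.
#' @export
update_velocity <- function(v, x, pbest_x, gbest_x, w, config = swarm_config(),
                            v_max = config$v_max, r1 = NULL, r2 = NULL) {
  v <- as_row_matrix(v); x <- as_row_matrix(x); pbest_x <- as_row_matrix(pbest_x)
  if (is.null(r1)) r1 <- matrix(runif(length(v)), nrow(v))
  if (is.null(r2)) r2 <- matrix(runif(length(v)), nrow(v))
  gb <- matrix(gbest_x, nrow(v), ncol(v), byrow = TRUE)
  vn <- w * v + config$c1 * r1 * (pbest_x - x) + config$c2 * r2 * (gb - x)
  if (!is.null(v_max)) vn <- pmin(pmax(vn, -v_max), v_max)
  vn
}

#' Particle position update
#'
#' Adds the velocity, rounds to integer bp, and repairs the candidate:
#' length is clamped to the configured band and the start is clamped so
#' the interval stays inside the window.  (During a swarm run positions
#' are kept real-valued between iterations; this rounding/repair is what
#' the fitness evaluation sees.)
#'
#' @param x Position matrix (columns `fs`, `fl`) or length-2 vector.
#' @param v Velocity, same shape.
#' @param window_length Window length in bp.
#' @param config A [fitness_config()].
#' @return Integer position matrix with the same shape as `x`.
#' @export
update_position <- function(x, v, window_length, config = fitness_config()) {
  x <- as_row_matrix(x); v <- as_row_matrix(v)
  xn <- round(x + v)
  fl <- pmin(pmax(xn[, 2], config$len_lo), min(config$len_hi, window_length))
  fs <- pmin(pmax(xn[, 1], 0), window_length - fl)
  cbind(fs = fs, fl = fl)
}

## vectors are particle rows, not column matrices
as_row_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

## internal: round + repair real positions, then score them on the profile.
## window coordinates are offsets from wstart.
eval_particles <- function(prof, wstart, wlen, x, fit_cfg) {
  fl <- pmin(pmax(round(x[, 2]), fit_cfg$len_lo), min(fit_cfg$len_hi, wlen))
  fs <- pmin(pmax(round(x[, 1]), 0), wlen - fl)
  gs <- as.integer(wstart + fs)
  ge <- as.integer(gs + fl)
  cts <- profile_counts(prof, gs, ge)
  n_eff <- cts$n_a + cts$n_t + cts$n_c + cts$n_g
  gc <- ifelse(n_eff > 0, (cts$n_c + cts$n_g) / n_eff, NA_real_)
  cg <- cts$n_c * cts$n_g
  oe <- ifelse(n_eff > 0, ifelse(cg > 0, cts$n_cpg * n_eff / cg, 0), NA_real_)
  list(
    fs = fs, fl = fl, gc = gc, oe = oe,
    fit = fitness_from_stats(gc, oe, fl, n_eff, fit_cfg)
  )
}

#' Initialise a swarm inside a window
#'
#' Particles encode a candidate island as `(fs, fl)`: the start offset
#' within the window and the island length, with the end derived as
#' `fs + fl`.  Starts are uniform over the window, lengths uniform over
#' the candidate band clamped to the window, velocities zero; personal
#' bests are the initial positions and the global best is the best of
#' those.
#'
#' @param seq Residue string.
#' @param window_start,window_end 0-based half-open window bounds.
#' @param config A [swarm_config()].
#' @param fit_config A [fitness_config()].
#' @param init_ranges Optional list with elements `fs` and/or `fl`, each a
#'   length-2 range restricting where particles are seeded (diagnostic
#'   use, e.g. basin-escape experiments).
#' @return A swarm state list (positions, velocities, bests, bounds).
#' @export
initialize_swarm <- function(seq, window_start = 0L, window_end = nchar(seq),
                             config = swarm_config(),
                             fit_config = fitness_config(),
                             init_ranges = NULL) {
  prof <- seq_profile(seq)
  swarm_init(prof, window_start, window_end, config, fit_config, init_ranges)
}

swarm_init <- function(prof, wstart, wend, cfg, fit_cfg, init_ranges = NULL) {
  wlen <- wend - wstart
  if (wlen < fit_cfg$len_lo) {
    message(sprintf(
      "window [%d, %d) shorter than minimum island length %d; skipped",
      wstart, wend, fit_cfg$len_lo
    ))
    return(NULL)
  }
  n <- cfg$population
  fl_hi <- min(fit_cfg$len_hi, wlen)
  fs_hi <- wlen - fit_cfg$len_lo
  fs_rng <- init_ranges$fs %||% c(0, fs_hi)
  fl_rng <- init_ranges$fl %||% c(fit_cfg$len_lo, fl_hi)
  x <- cbind(
    fs = runif(n, max(0, fs_rng[1]), min(fs_hi, fs_rng[2])),
    fl = runif(n, max(fit_cfg$len_lo, fl_rng[1]), min(fl_hi, fl_rng[2]))
  )
  ev <- eval_particles(prof, wstart, wlen, x, fit_cfg)
  best <- which.max(ev$fit)
  list(
    x = x, v = matrix(0, n, 2), fit = ev$fit,
    pbest_x = x, pbest_fit = ev$fit,
    gbest_x = x[best, ], gbest_fit = ev$fit[best],
    lower = c(0, fit_cfg$len_lo), upper = c(fs_hi, fl_hi),
    window = c(wstart, wend), stagnation = 0L
  )
}

## internal single-window optimisation over a prebuilt profile.
run_window_profile <- function(prof, wstart, wend, cfg, fit_cfg,
                               init_ranges = NULL, trace = FALSE) {
  sw <- swarm_init(prof, wstart, wend, cfg, fit_cfg, init_ranges)
  if (is.null(sw)) return(NULL)
  wlen <- wend - wstart
  v_max <- cfg$v_max %||% (wlen / 5)
  tr <- if (trace) numeric(cfg$iterations) else NULL
  for (i in seq_len(cfg$iterations)) {
    w <- inertia_weight(i, cfg$iterations, cfg)
    sw$v <- update_velocity(sw$v, sw$x, sw$pbest_x, sw$gbest_x, w, cfg, v_max = v_max)
    sw$x <- sw$x + sw$v
    # clamp real-valued positions to the search box
    sw$x[, 1] <- pmin(pmax(sw$x[, 1], sw$lower[1]), sw$upper[1])
    sw$x[, 2] <- pmin(pmax(sw$x[, 2], sw$lower[2]), sw$upper[2])
    ev <- eval_particles(prof, wstart, wlen, sw$x, fit_cfg)
    sw$fit <- ev$fit
    better <- ev$fit > sw$pbest_fit
    sw$pbest_x[better, ] <- sw$x[better, ]
    sw$pbest_fit[better] <- ev$fit[better]
    prev <- sw$gbest_fit
    best <- which.max(sw$pbest_fit)
    sw$gbest_x <- sw$pbest_x[best, ]
    sw$gbest_fit <- sw$pbest_fit[best]
    st <- stagnation_update(sw$stagnation, prev, sw$gbest_fit, cfg$patience)
    sw$stagnation <- st$counter
    if (cfg$mode == "cpso" && st$triggered) {
      sw <- complement_swarm(sw, cfg$replace_fraction)
    }
    if (trace) tr[i] <- sw$gbest_fit
  }
  # score the final global best at integer resolution
  ev <- eval_particles(prof, wstart, wlen, matrix(sw$gbest_x, 1), fit_cfg)
  feasible <- meets_criteria(ev$fl, ev$gc, ev$oe, fit_cfg$criteria)
  island <- if (isTRUE(feasible)) {
    tibble(
      start = as.integer(wstart + ev$fs), end = as.integer(wstart + ev$fs + ev$fl),
      length = as.integer(ev$fl), gc = ev$gc, oe = ev$oe, fitness = ev$fit
    )
  } else {
    NULL
  }
  list(island = island, gbest_fit = ev$fit, trace = tr)
}

#' Optimise one window with the swarm
#'
#' Runs the configured number of iterations (velocity, position, fitness,
#' best updates, and in CPSO mode complementary restarts on stagnation)
#' and returns the global best as an island if it satisfies the criteria.
#'
#' @inheritParams initialize_swarm
#' @param trace If `TRUE`, record the global-best fitness after every
#'   iteration (returned as `$trace`).
#' @return A list with `island` (one-row tibble in global coordinates, or
#'   `NULL` if the best candidate is infeasible), `gbest_fit`, and
#'   `trace`; `NULL` for a window shorter than the minimum island length.
#' @examples
#' \donttest{
#' set.seed(1)
#' sim <- simulate_cpg_genome(
#'   length = 4000,
#'   island_specs = tibble::tibble(length = 800, gc = 0.62, oe = 0.85, position = 1500)
#' )
#' run_swarm_window(sim$genome$seq, config = swarm_config(population = 60))$island
#' }
#' @export
run_swarm_window <- function(seq, window_start = 0L, window_end = nchar(seq),
                             config = swarm_config(),
                             fit_config = fitness_config(),
                             init_ranges = NULL, trace = FALSE) {
  run_window_profile(
    seq_profile(seq), window_start, window_end,
    config, fit_config, init_ranges, trace
  )
}

#' Extract all islands from a sequence
#'
#' The window-level driver: tiles the sequence, runs one swarm per window,
#' and on success masks the found island and reruns the window (deflation)
#' so multiple islands per window are recovered, up to
#' `restarts_per_window` extra runs.  Masking is shared across windows, so
#' an island found in a window seam is not re-found in the overlapping
#' neighbour; any remaining overlaps are unioned and island statistics are
#' recomputed on the original (unmasked) sequence.
#'
#' @param seq Residue string.
#' @param config A [swarm_config()].
#' @param fit_config A [fitness_config()].
#' @param window_size,overlap Window tiling parameters (bp); see
#'   [partition_windows()].
#' @param restarts_per_window Maximum deflation reruns per window after
#'   the first.
#' @return Tibble of islands (`start`, `end`, `length`, `gc`, `oe`,
#'   `fitness`) sorted by start, non-overlapping.
#' @export
extract_islands <- function(seq, config = swarm_config(),
                            fit_config = fitness_config(),
                            window_size = 10000L, overlap = 2000L,
                            restarts_per_window = 5L) {
  L <- nchar(seq)
  if (L < fit_config$len_lo) return(empty_islands())
  windows <- partition_windows(L, min(window_size, max(L, fit_config$len_lo)),
                               if (L <= window_size) 0L else overlap)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  work <- chars
  prof <- profile_from_chars(work)
  found <- list()
  for (k in seq_len(nrow(windows))) {
    ws <- windows$start[k]; we <- windows$end[k]
    for (r in seq_len(restarts_per_window + 1L)) {
      res <- run_window_profile(prof, ws, we, config, fit_config)
      if (is.null(res) || is.null(res$island)) break
      found[[length(found) + 1L]] <- res$island
      work[(res$island$start + 1L):res$island$end] <- "N"
      prof <- profile_from_chars(work)
    }
  }
  if (length(found) == 0) return(empty_islands())
  islands <- bind_rows(found)
  # union strictly overlapping finds from window seams (adjacent islands stay
  # separate: joining across gaps is the refinement pass's decision)
  ir <- IRanges::reduce(IRanges::IRanges(islands$start + 1L, islands$end),
                        min.gapwidth = 0L)
  island_stats(
    tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir)),
    seq_profile(seq), fit_config
  )
}

empty_islands <- function() {
  tibble(
    start = integer(), end = integer(), length = integer(),
    gc = numeric(), oe = numeric(), fitness = numeric()
  )
}

profile_from_chars <- function(v) {
  L <- length(v)
  isC <- v == "C"
  isG <- v == "G"
  cpg <- if (L >= 2) c(isC[-L] & isG[-1], FALSE) else rep(FALSE, L)
  list(
    length = L,
    cA = cumsum(v == "A"), cT = cumsum(v == "T"),
    cC = cumsum(isC), cG = cumsum(isG),
    cCpG = cumsum(cpg)
  )
}

## internal: (re)compute per-island composition, length and fitness.
island_stats <- function(iv, prof, fit_cfg) {
  if (nrow(iv) == 0) return(empty_islands())
  cts <- profile_counts(prof, as.integer(iv$start), as.integer(iv$end))
  n_eff <- cts$n_a + cts$n_t + cts$n_c + cts$n_g
  gc <- ifelse(n_eff > 0, (cts$n_c + cts$n_g) / n_eff, NA_real_)
  cg <- cts$n_c * cts$n_g
  oe <- ifelse(n_eff > 0, ifelse(cg > 0, cts$n_cpg * n_eff / cg, 0), NA_real_)
  len <- as.integer(iv$end - iv$start)
  tibble(
    start = as.integer(iv$start), end = as.integer(iv$end), length = len,
    gc = gc, oe = oe,
    fitness = fitness_from_stats(gc, oe, len, n_eff, fit_cfg)
  ) |> arrange(.data$start)
}
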