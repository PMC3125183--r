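#' Update the stagnation counter
#'
#' The swarm is considered stagnated when the global-best fitness has not
#' changed (exact equality; positions are integer bp at evaluation so the
#' fitness value is exactly reproducible) for `patience` consecutive
#' iterations.  The counter resets to zero on any improvement and after a
#' trigger.
#'
#' @param counter Current consecutive-unchanged count.
#' @param prev_fit,new_fit Global-best fitness before/after this iteration.
#' @param patience Iterations tolerated before triggering.
#' @return List with the updated `counter` and logical `triggered`.
#' @examples
#' stagnation_update(4, 1.8, 1.8, patience = 5) # fifth unchanged -> trigger
#' @export
stagnation_update <- function(counter, prev_fit, new_fit, patience = 5L) {
  if (identical(as.numeric(new_fit), as.numeric(prev_fit))) {
    counter <- counter + 1L
  } else {
    counter <- 0L
  }
  if (counter >= patience) {
    list(counter = 0L, triggered = TRUE)
  } else {
    list(counter = counter, triggered = FALSE)
  }
}

#' Opposition (complementary) positions
#'
#' Reflects positions through the midpoint of the search box:
#' `x_complement = upper + lower - x`, componentwise.  An involution that
#' maps the box onto itself, it relocates trapped particles to the
#' unexplored side of the window so the swarm can escape a local optimum.
#'
#' @param x Position matrix (particles x dimensions) or vector.
#' @param lower,upper Per-dimension box bounds (recycled across rows).
#' @return Complemented positions, same shape as `x`.
#' @examples
#' complement_positions(30, lower = 0, upper = 100)
#' @export
complement_positions <- function(x, lower, upper) {
  x <- as_row_matrix(x)
  lo <- matrix(lower, nrow(x), ncol(x), byrow = TRUE)
  hi <- matrix(upper, nrow(x), ncol(x), byrow = TRUE)
  hi + lo - x
}

## internal: complementary restart of a stagnated swarm.  A random half of
## the particles (never the gbest holder) jump to their opposition points
## with zero velocity; personal bests and the global best are retained, so
## the restarted particles are still attracted by the original gbest.
complement_swarm <- function(sw, replace_fraction = 0.5) {
  n <- nrow(sw$x)
  if (n < 2) {
    message("population < 2: complementary restart skipped")
    return(sw)
  }
  k <- floor(replace_fraction * n)
  if (k < 1) return(sw)
  holder <- which.max(sw$pbest_fit)
  pool <- setdiff(seq_len(n), holder)
  sel <- if (length(pool) == 1) pool else sample(pool, min(k, length(pool)))
  sw$x[sel, ] <- complement_positions(sw$x[sel, , drop = FALSE], sw$lower, sw$upper)
  sw$v[sel, ] <- 0
  sw
}
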