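#' One merge pass over adjacent islands
#'
#' Scans the islands left to right and, for each adjacent pair whose gap
#' (`next start - previous end`) is smaller than `gap_threshold`,
#' tentatively merges them into the spanning interval including the gap
#' sequence.  The merge is kept (rewarded) only if the spanning interval
#' still satisfies the criteria; otherwise it is rejected and both islands
#' stand.  An accepted merge is immediately eligible to absorb the next
#' island, and composition statistics are recomputed on every accepted
#' span.
#'
#' @param islands Island tibble (`start`, `end`, ...), sorted by start and
#'   non-overlapping.
#' @param seq Residue string the islands were called on.
#' @param gap_threshold Maximum gap (bp, exclusive) eligible for merging.
#' @param criteria A [cpg_criteria()] object the merged span must satisfy.
#' @return Island tibble with statistics recomputed for merged spans.
#' @export
merge_pass <- function(islands, seq, gap_threshold = 200L,
                       criteria = cpg_criteria("ggf")) {
  validate_islands(islands)
  if (nrow(islands) < 2) return(islands)
  prof <- seq_profile(seq)
  fit_cfg <- fitness_config(criteria = criteria)
  cur <- c(islands$start[1], islands$end[1])
  out <- list()
  for (i in 2:nrow(islands)) {
    nxt <- c(islands$start[i], islands$end[i])
    gap <- nxt[1] - cur[2]
    merged <- FALSE
    if (gap < gap_threshold) {
      span <- island_stats(tibble(start = cur[1], end = nxt[2]), prof, fit_cfg)
      if (meets_criteria(span$length, span$gc, span$oe, criteria)) {
        cur <- c(cur[1], nxt[2]) # reward: keep the span, try to extend further
        merged <- TRUE
      }
    }
    if (!merged) { # penalty: keep both islands as they are
      out[[length(out) + 1L]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1L]] <- cur
  iv <- tibble(
    start = vapply(out, `[`, numeric(1), 1),
    end = vapply(out, `[`, numeric(1), 2)
  )
  island_stats(iv, prof, fit_cfg)
}

#' Merge islands to a fixed point
#'
#' Applies [merge_pass()] repeatedly until a whole pass changes nothing.
#' The result is idempotent, sorted, non-overlapping, and every island
#' satisfies the criteria (single-pass output already does, but the fixed
#' point also catches merges enabled by earlier merges).  Merging never
#' increases the island count and never decreases the total covered
#' length, since accepted merges absorb the gap bases.
#'
#' @inheritParams merge_pass
#' @return Island tibble at the merge fixed point.
#' @export
refine_islands <- function(islands, seq, gap_threshold = 200L,
                           criteria = cpg_criteria("ggf")) {
  repeat {
    merged <- merge_pass(islands, seq, gap_threshold, criteria)
    if (nrow(merged) == nrow(islands)) return(merged)
    islands <- merged
  }
}

validate_islands <- function(islands) {
  if (nrow(islands) < 2) return(invisible(islands))
  if (is.unsorted(islands$start)) {
    abort("islands must be sorted by start", class = "cpgswarm_contract_error")
  }
  if (any(islands$start[-1] < islands$end[-nrow(islands)])) {
    abort("islands must be non-overlapping", class = "cpgswarm_contract_error")
  }
  invisible(islands)
}
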