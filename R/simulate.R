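## First-order Markov sequence with controllable GC and CpG depletion.
## All transition rows equal the stationary-ish base distribution except
## the C row, where P(G|C) is multiplied by `suppression` and the row
## renormalised -- so the realised O/E ratio tracks `suppression`.
markov_sequence <- function(L, gc, suppression) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rows <- rbind(p, p, p, p)
  rows[2, "G"] <- p[["G"]] * suppression
  rows[2, ] <- rows[2, ] / sum(rows[2, ])
  cp <- t(apply(rows, 1, cumsum))
  c1 <- cp[, 1]; c2 <- cp[, 2]; c3 <- cp[, 3]
  u <- runif(L)
  out <- integer(L)
  cp0 <- cumsum(p)
  cur <- 1L + (u[1] > cp0[1]) + (u[1] > cp0[2]) + (u[1] > cp0[3])
  out[1] <- cur
  for (i in seq_len(L - 1L) + 1L) {
    r <- u[i]
    cur <- 1L + (r > c1[cur]) + (r > c2[cur]) + (r > c3[cur])
    out[i] <- cur
  }
  paste(c("A", "C", "G", "T")[out], collapse = "")
}

#' Generate CpG-depleted background sequence
#'
#' Simulates the genomic backdrop the predictor works against: a
#' first-order Markov chain with stationary GC content near `gc` and the
#' `C -> G` transition probability multiplied by `cpg_suppression` (then
#' renormalised), so the realised CpG O/E ratio is approximately the
#' suppression factor.  Defaults model a mammalian-like, CpG-poor genome.
#'
#' @param length Sequence length in bp.
#' @param gc Target stationary GC fraction.
#' @param cpg_suppression CpG depletion factor in `[0, 1]`; 1 gives an
#'   i.i.d.-like sequence with O/E near 1.
#' @return A residue string of the requested length.
#' @export
generate_background <- function(length, gc = 0.41, cpg_suppression = 0.25) {
  stopifnot(length > 0, gc > 0, gc < 1, cpg_suppression >= 0, cpg_suppression <= 1)
  markov_sequence(length, gc, cpg_suppression)
}

## one island segment matching its composition targets to +/- tol,
## by rejection sampling from the Markov generator.
island_segment <- function(length, gc, oe, tol = 0.03, max_attempts = 2000L) {
  for (i in seq_len(max_attempts)) {
    seg <- markov_sequence(length, gc, oe)
    cts <- count_nucleotides(seg)
    if (abs(gc_content(cts) - gc) <= tol && abs(oe_ratio(cts) - oe) <= tol) {
      return(seg)
    }
  }
  abort(
    sprintf("could not realise island (length %d, GC %.2f, O/E %.2f) within +/-%.2f",
            length, gc, oe, tol),
    class = "cpgswarm_placement_error"
  )
}

#' Plant islands into a background sequence
#'
#' Splices generated island segments into a background sequence and
#' returns the ground truth.  Each segment is rejection-sampled until its
#' empirical GC content and O/E ratio are within 0.03 of the requested targets,
#' so the truth intervals are guaranteed to satisfy the GGF criteria for
#' any feasible spec.  Islands with `position = NA` are placed uniformly
#' at random subject to pairwise gaps of at least `min_gap`.
#'
#' @param background Background residue string (see
#'   [generate_background()]).
#' @param specs Tibble with columns `length` (bp), `gc`, `oe` and
#'   `position` (0-based start, or `NA` for random placement).
#' @param min_gap Minimum gap (bp) between islands and to the sequence
#'   ends.
#' @return List with `seq` (the sequence with islands spliced in) and
#'   `truth` (island tibble with realised `gc`/`oe`).
#' @export
plant_islands <- function(background, specs, min_gap = 1000L) {
  L <- nchar(background)
  if (nrow(specs) == 0) {
    return(list(seq = background, truth = empty_islands()[, c("start", "end", "length", "gc", "oe")]))
  }
  starts <- as.numeric(specs$position)
  fixed <- which(!is.na(starts))
  free <- which(is.na(starts))
  ok_placement <- function(s, len, placed) {
    if (s < min_gap || s + len > L - min_gap) return(FALSE)
    all(s >= placed$end + min_gap | s + len <= placed$start - min_gap)
  }
  placed <- tibble(start = starts[fixed], end = starts[fixed] + specs$length[fixed])
  for (i in free) {
    len <- specs$length[i]
    if (L - 2 * min_gap < len) {
      abort("island longer than the background minus its end gaps",
        class = "cpgswarm_placement_error"
      )
    }
    done <- FALSE
    for (try in seq_len(2000L)) {
      s <- floor(runif(1, min_gap, L - min_gap - len))
      if (ok_placement(s, len, placed)) {
        starts[i] <- s
        placed <- bind_rows(placed, tibble(start = s, end = s + len))
        done <- TRUE
        break
      }
    }
    if (!done) {
      abort("could not place all islands with the requested gaps",
        class = "cpgswarm_placement_error"
      )
    }
  }
  ends <- starts + specs$length
  if (any(starts < 0) || any(ends > L)) {
    abort("island specs do not fit in the background", class = "cpgswarm_placement_error")
  }
  o <- order(starts)
  if (any(starts[o][-1] - ends[o][-length(o)] < min_gap)) {
    abort("island placements violate min_gap", class = "cpgswarm_placement_error")
  }
  v <- strsplit(background, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(specs))) {
    seg <- island_segment(specs$length[i], specs$gc[i], specs$oe[i])
    v[(starts[i] + 1L):ends[i]] <- strsplit(seg, "", fixed = TRUE)[[1]]
  }
  seq <- paste(v, collapse = "")
  prof <- seq_profile(seq)
  truth <- island_stats(
    tibble(start = starts[o], end = ends[o]),
    prof, fitness_config()
  ) |> select(-"fitness")
  list(seq = seq, truth = truth)
}

#' Canonical planted-island specifications
#'
#' The package's standard benchmark layout: eight islands spanning the
#' biologically typical ranges of length (300-1800 bp), GC content
#' (0.55-0.65) and O/E ratio (0.70-0.90), placed at random positions.
#'
#' @return A specs tibble for [plant_islands()] / [simulate_cpg_genome()].
#' @export
example_island_specs <- function() {
  tibble(
    length = c(300L, 500L, 700L, 900L, 1100L, 1300L, 1600L, 1800L),
    gc = seq(0.55, 0.65, length.out = 8),
    oe = seq(0.70, 0.90, length.out = 8),
    position = NA_integer_
  )
}

#' Simulate a genome with planted CpG islands
#'
#' End-to-end fixture generator: CpG-depleted background, planted islands
#' with ground truth, and optional methylation and TSS tracks.
#' Methylation sites are drawn at CpG dinucleotide positions with
#' different retention rates inside and outside islands (islands are
#' hypomethylated in real genomes, hence the lower default inside rate).
#' TSSs are placed just inside each island's 5' end plus a handful of
#' island-free background TSSs.
#'
#' @param length Genome length in bp.
#' @param gc,cpg_suppression Background composition; see
#'   [generate_background()].
#' @param island_specs Specs tibble; see [plant_islands()].
#' @param min_gap Minimum island separation in bp.
#' @param name Sequence name used in the output tibbles.
#' @param methylation If `TRUE`, emit a methylation-site track.
#' @param meth_rate_in,meth_rate_out Probability that a CpG site carries a
#'   methylation call inside / outside islands.
#' @param tss If `TRUE`, emit a TSS track.
#' @return List with `genome` (tibble `name`, `length`, `seq`), `truth`
#'   (island tibble with `chrom`), and optionally `methylation` and `tss`
#'   tibbles.
#' @examples
#' set.seed(7)
#' sim <- simulate_cpg_genome(length = 20000,
#'   island_specs = example_island_specs()[1:2, ])
#' sim$truth
#' @export
simulate_cpg_genome <- function(length = 100000L, gc = 0.41, cpg_suppression = 0.25,
                                island_specs = example_island_specs(),
                                min_gap = 2000L, name = "synth",
                                methylation = FALSE,
                                meth_rate_in = 0.1, meth_rate_out = 0.8,
                                tss = FALSE) {
  bg <- generate_background(length, gc, cpg_suppression)
  planted <- plant_islands(bg, island_specs, min_gap)
  genome <- tibble(name = name, length = nchar(planted$seq), seq = planted$seq)
  truth <- mutate(planted$truth, chrom = name, .before = 1)
  out <- list(genome = genome, truth = truth)
  if (methylation) {
    v <- strsplit(planted$seq, "", fixed = TRUE)[[1]]
    cpg_pos <- which(v[-length(v)] == "C" & v[-1] == "G") - 1L # 0-based C position
    inside <- rep(FALSE, base::length(cpg_pos))
    for (i in seq_len(nrow(truth))) {
      inside <- inside | (cpg_pos >= truth$start[i] & cpg_pos < truth$end[i])
    }
    keep <- runif(base::length(cpg_pos)) < ifelse(inside, meth_rate_in, meth_rate_out)
    out$methylation <- tibble(chrom = name, pos = cpg_pos[keep])
  }
  if (tss) {
    isl_tss <- tibble(
      chrom = name,
      pos = truth$start + pmin(50L, truth$length %/% 4L),
      strand = sample(c("+", "-"), nrow(truth), replace = TRUE)
    )
    n_bg <- 5L
    bg_pos <- floor(runif(n_bg, 0, length))
    out$tss <- bind_rows(
      isl_tss,
      tibble(chrom = name, pos = as.integer(bg_pos),
             strand = sample(c("+", "-"), n_bg, replace = TRUE))
    ) |> arrange(.data$pos)
  }
  out
}

#' Exhaustive best-segment oracle
#'
#' Brute-force global maximiser of [particle_fitness()] over every
#' `(start, length)` candidate with length in the configured band, using
#' incremental prefix-sum counts.  Quadratic in the sequence length, so
#' refuses sequences longer than `guard` bp; intended as an independent
#' optimum for validating the swarm on small instances.  Ties are broken
#' by smaller start, then smaller length.
#'
#' @param seq Residue string.
#' @param fit_config A [fitness_config()].
#' @param guard Maximum sequence length accepted (bp).
#' @return One-row island tibble (`start`, `end`, `length`, `gc`, `oe`,
#'   `fitness`).
#' @export
exhaustive_best_segment <- function(seq, fit_config = fitness_config(), guard = 5000L) {
  L <- nchar(seq)
  if (L > guard) {
    abort(sprintf("sequence length %d exceeds oracle guard %d", L, guard),
      class = "cpgswarm_size_error"
    )
  }
  if (L < fit_config$len_lo) {
    abort("sequence shorter than the minimum island length", class = "cpgswarm_size_error")
  }
  prof <- seq_profile(seq)
  best_fit <- -Inf
  best_start <- NA_integer_
  best_len <- NA_integer_
  for (len in fit_config$len_lo:min(fit_config$len_hi, L)) {
    starts <- 0:(L - len)
    cts <- profile_counts(prof, starts, starts + len)
    n_eff <- cts$n_a + cts$n_t + cts$n_c + cts$n_g
    gc <- ifelse(n_eff > 0, (cts$n_c + cts$n_g) / n_eff, NA_real_)
    cg <- cts$n_c * cts$n_g
    oe <- ifelse(n_eff > 0, ifelse(cg > 0, cts$n_cpg * n_eff / cg, 0), NA_real_)
    fit <- fitness_from_stats(gc, oe, len, n_eff, fit_config)
    m <- max(fit)
    s <- starts[which(fit == m)[1]] # smallest start among ties at this length
    if (m > best_fit || (m == best_fit && s < best_start)) {
      best_fit <- m
      best_start <- s
      best_len <- len
    }
  }
  island_stats(
    tibble(start = best_start, end = best_start + best_len),
    prof, fit_config
  )
}

#' Sliding-window baseline scanner
#'
#' The classic fixed-window comparator: every `window`-bp window meeting
#' the criteria is marked, overlapping marked windows are merged, and
#' maximal runs are emitted as islands.  Serves as a simple reference
#' method for benchmarking the swarm predictor.
#'
#' @param seq Residue string.
#' @param criteria A [cpg_criteria()] object.
#' @param window Window width in bp.
#' @param step Step between window starts in bp.
#' @return Island tibble (merged marked windows, statistics recomputed).
#' @export
sliding_window_baseline <- function(seq, criteria = cpg_criteria("ggf"),
                                    window = 200L, step = 1L) {
  L <- nchar(seq)
  if (L < window) return(empty_islands())
  prof <- seq_profile(seq)
  starts <- seq(0L, L - window, by = step)
  cts <- profile_counts(prof, starts, starts + window)
  n_eff <- cts$n_a + cts$n_t + cts$n_c + cts$n_g
  gc <- ifelse(n_eff > 0, (cts$n_c + cts$n_g) / n_eff, NA_real_)
  cg <- cts$n_c * cts$n_g
  oe <- ifelse(n_eff > 0, ifelse(cg > 0, cts$n_cpg * n_eff / cg, 0), NA_real_)
  ok <- meets_criteria(window, gc, oe, criteria)
  if (!any(ok)) return(empty_islands())
  ir <- IRanges::reduce(IRanges::IRanges(starts[ok] + 1L, starts[ok] + window))
  island_stats(
    tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir)),
    prof, fitness_config(criteria = criteria)
  )
}
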