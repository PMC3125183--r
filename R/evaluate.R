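## ---- interval plumbing -----------------------------------------------------

## Normalise interval tibbles and sequence lengths to a common shape:
## intervals get a `chrom` column (single unnamed sequence -> "seq") and
## lengths become a named vector.
norm_lengths <- function(seq_lengths) {
  if (is.data.frame(seq_lengths)) {
    return(setNames(seq_lengths$length, seq_lengths$name))
  }
  if (is.null(names(seq_lengths))) {
    if (length(seq_lengths) != 1) {
      abort("unnamed seq_lengths must be a single value", class = "cpgswarm_param_error")
    }
    return(setNames(seq_lengths, "seq"))
  }
  seq_lengths
}

norm_intervals <- function(x, lengths) {
  if (is.null(x) || nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  if (!"chrom" %in% names(x)) x <- mutate(x, chrom = names(lengths)[1])
  bad <- !x$chrom %in% names(lengths)
  if (any(bad)) {
    abort(
      paste0("chromosome(s) not present in sequence set: ",
             paste(unique(x$chrom[bad]), collapse = ", ")),
      class = "cpgswarm_chrom_error"
    )
  }
  L <- lengths[x$chrom]
  if (any(x$start < 0) || any(x$end > L) || any(x$start >= x$end)) {
    abort("interval out of sequence bounds", class = "cpgswarm_coord_error")
  }
  select(x, "chrom", "start", "end")
}

## reduced IRanges per chromosome
reduced_by_chrom <- function(iv, chroms) {
  lapply(setNames(chroms, chroms), function(ch) {
    z <- iv[iv$chrom == ch, ]
    IRanges::reduce(IRanges::IRanges(z$start + 1L, z$end))
  })
}

## ---- confusion counts and metrics ------------------------------------------

#' Per-nucleotide confusion counts
#'
#' Labels every base of the evaluated sequence(s): `TP` inside both the
#' predicted and reference islands, `FP` predicted only, `FN` reference
#' only, `TN` neither.  Computed by interval arithmetic (intersection of
#' reduced interval sets), which the test suite checks against an explicit
#' per-base bitmap.
#'
#' @param predicted,reference Interval tibbles (`start`, `end`, optional
#'   `chrom`), 0-based half-open.
#' @param seq_lengths Single length, named vector, or tibble
#'   (`name`, `length`) giving the evaluated sequence length(s).
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn` (bp, summed over
#'   chromosomes); the four always add up to the total length.
#' @examples
#' confusion_counts(
#'   tibble::tibble(start = 0, end = 10),
#'   tibble::tibble(start = 5, end = 15), 20
#' )
#' @export
confusion_counts <- function(predicted, reference, seq_lengths) {
  lens <- norm_lengths(seq_lengths)
  pred <- norm_intervals(predicted, lens)
  ref <- norm_intervals(reference, lens)
  chroms <- names(lens)
  p <- reduced_by_chrom(pred, chroms)
  r <- reduced_by_chrom(ref, chroms)
  tp <- fp <- fn <- 0
  for (ch in chroms) {
    itp <- sum(IRanges::width(IRanges::intersect(p[[ch]], r[[ch]])))
    tp <- tp + itp
    fp <- fp + sum(IRanges::width(p[[ch]])) - itp
    fn <- fn + sum(IRanges::width(r[[ch]])) - itp
  }
  total <- sum(lens)
  tibble(tp = tp, fp = fp, tn = total - tp - fp - fn, fn = fn)
}

#' Prediction metrics from confusion counts
#'
#' The five per-nucleotide criteria: sensitivity `SN = TP/(TP+FN)`,
#' specificity `SP = TN/(TN+FP)`, accuracy `ACC = (TP+TN)/total`,
#' performance coefficient `PC = TP/(TP+FN+FP)` and the Matthews-style
#' correlation coefficient
#' `CC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` rather than
#' raising an error.
#'
#' @param counts One-row tibble from [confusion_counts()].
#' @return One-row tibble with columns `sn`, `sp`, `acc`, `pc`, `cc`.
#' @export
island_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  cc_den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  tibble(
    sn = div(tp, tp + fn),
    sp = div(tn, tn + fp),
    acc = div(tp + tn, tp + fp + tn + fn),
    pc = div(tp, tp + fn + fp),
    cc = ifelse(cc_den > 0, (tp * tn - fn * fp) / cc_den, NA_real_)
  )
}

#' Evaluate predicted islands against a reference annotation
#'
#' Convenience wrapper producing a `cpg_evaluation` object holding both
#' the per-base confusion counts and the five metrics; [tidy()] returns
#' the metrics in long form and [glance()] a one-row summary.
#'
#' @inheritParams confusion_counts
#' @return An object of class `cpg_evaluation`.
#' @export
evaluate_islands <- function(predicted, reference, seq_lengths) {
  counts <- confusion_counts(predicted, reference, seq_lengths)
  structure(
    list(counts = counts, metrics = island_metrics(counts)),
    class = "cpg_evaluation"
  )
}

#' @export
print.cpg_evaluation <- function(x, ...) {
  cat("<cpg_evaluation>\n")
  cat(sprintf(
    "  TP %s  FP %s  TN %s  FN %s bp\n",
    x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn
  ))
  m <- x$metrics
  cat(sprintf(
    "  SN %.4f  SP %.4f  ACC %.4f  PC %.4f  CC %.4f\n",
    m$sn, m$sp, m$acc, m$pc, m$cc
  ))
  invisible(x)
}

#' @rdname evaluate_islands
#' @param x A `cpg_evaluation` object.
#' @param ... Unused.
#' @export
tidy.cpg_evaluation <- function(x, ...) {
  tibble(
    metric = c("sn", "sp", "acc", "pc", "cc"),
    value = as.numeric(x$metrics[1, ])
  )
}

#' @rdname evaluate_islands
#' @export
glance.cpg_evaluation <- function(x, ...) {
  dplyr::bind_cols(x$counts, x$metrics)
}

## ---- ROC -------------------------------------------------------------------

#' ROC points by sweeping the island-fitness threshold
#'
#' For each threshold, islands with `fitness >= threshold` form the
#' prediction set, and one (FPR, TPR) point is emitted.  TPR and FPR both
#' shrink (weakly) as the threshold rises.
#'
#' @param islands Island tibble with a `fitness` column.
#' @param reference Reference interval tibble.
#' @param seq_lengths As in [confusion_counts()].
#' @param thresholds Numeric thresholds; defaults to the unique island
#'   fitness values plus one above the maximum (the empty prediction).
#' @return Tibble (`threshold`, `fpr`, `tpr`) sorted by `fpr`.
#' @export
roc_points <- function(islands, reference, seq_lengths, thresholds = NULL) {
  if (is.null(thresholds)) {
    fits <- sort(unique(islands$fitness))
    thresholds <- c(fits, if (length(fits)) max(fits) + 1 else 1)
  }
  if (length(thresholds) < 2) {
    abort("at least two thresholds are required", class = "cpgswarm_param_error")
  }
  pts <- purrr::map_dfr(thresholds, function(th) {
    cc <- confusion_counts(
      islands[islands$fitness >= th, , drop = FALSE],
      reference, seq_lengths
    )
    tibble(
      threshold = th,
      fpr = ifelse(cc$fp + cc$tn > 0, cc$fp / (cc$fp + cc$tn), NA_real_),
      tpr = ifelse(cc$tp + cc$fn > 0, cc$tp / (cc$tp + cc$fn), NA_real_)
    )
  })
  arrange(pts, .data$fpr, .data$tpr)
}

#' Trapezoidal area under ROC points
#'
#' @param points Tibble from [roc_points()].
#' @return Area under the curve, with (0,0) and (1,1) anchors added.
#' @export
roc_auc <- function(points) {
  x <- c(0, points$fpr, 1)
  y <- c(0, points$tpr, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

## ---- report arithmetic -----------------------------------------------------

#' Sequence coverage of predicted islands
#'
#' @param total_island_length Total island length in bp.
#' @param seq_length Sequence length in bp.
#' @return Percentage `100 * total / L` at full precision (display
#'   convention is one decimal).
#' @examples
#' coverage_pct(1607472, 46944329)
#' @export
coverage_pct <- function(total_island_length, seq_length) {
  if (seq_length <= 0) abort("seq_length must be positive", class = "cpgswarm_param_error")
  if (total_island_length < 0 || total_island_length > seq_length) {
    abort("total island length must lie in [0, seq_length]", class = "cpgswarm_param_error")
  }
  100 * total_island_length / seq_length
}

#' Count point sites falling inside islands
#'
#' @param sites Tibble with a 0-based `pos` column (optional `chrom`).
#' @param islands Island tibble (`start`, `end`, optional `chrom`).
#' @return Number of sites inside any island.
#' @export
sites_in_islands <- function(sites, islands) {
  if (is.null(sites) || nrow(sites) == 0 || nrow(islands) == 0) return(0L)
  if (!"chrom" %in% names(sites)) sites <- mutate(sites, chrom = "seq")
  if (!"chrom" %in% names(islands)) islands <- mutate(islands, chrom = "seq")
  total <- 0L
  for (ch in unique(sites$chrom)) {
    isl <- islands[islands$chrom == ch, ]
    if (nrow(isl) == 0) next
    ir <- IRanges::reduce(IRanges::IRanges(isl$start + 1L, isl$end))
    pos <- sites$pos[sites$chrom == ch] + 1L
    total <- total + sum(IRanges::countOverlaps(IRanges::IRanges(pos, pos), ir) > 0)
  }
  as.integer(total)
}

#' Methylation density of predicted islands
#'
#' Methylation sites inside predicted islands per bp of predicted island,
#' as a percentage (display convention: two decimals).
#'
#' @param sites_inside Number of methylation sites inside islands.
#' @param total_island_length Total predicted island length in bp.
#' @return Percentage, or `NA` when there is no island sequence.
#' @examples
#' methylation_density_pct(111172, 1607472)
#' @export
methylation_density_pct <- function(sites_inside, total_island_length) {
  if (total_island_length <= 0) {
    warn("methylation density undefined: zero island length")
    return(NA_real_)
  }
  100 * sites_inside / total_island_length
}

#' TSS and promoter overlap with islands
#'
#' Counts transcription start sites falling inside an island, and TSSs
#' whose promoter region overlaps an island by at least 1 bp.  The
#' promoter is defined as 1500 bp upstream to 500 bp downstream of the
#' TSS, orientation-flipped on the minus strand.
#'
#' @param islands Island tibble (`start`, `end`, optional `chrom`).
#' @param tss Tibble with 0-based `pos`, optional `strand` (`"+"`/`"-"`,
#'   default `"+"`) and optional `chrom`.
#' @param upstream,downstream Promoter extent in bp relative to the TSS.
#' @return One-row tibble (`tss_count`, `promoter_count`).
#' @export
tss_promoter_overlap <- function(islands, tss, upstream = 1500L, downstream = 500L) {
  if (is.null(tss) || nrow(tss) == 0 || nrow(islands) == 0) {
    return(tibble(tss_count = 0L, promoter_count = 0L))
  }
  if (!"strand" %in% names(tss)) tss <- mutate(tss, strand = "+")
  if (!"chrom" %in% names(tss)) tss <- mutate(tss, chrom = "seq")
  if (!"chrom" %in% names(islands)) islands <- mutate(islands, chrom = "seq")
  tss_count <- sites_in_islands(tss, islands)
  promoter_count <- 0L
  for (ch in unique(tss$chrom)) {
    isl <- islands[islands$chrom == ch, ]
    if (nrow(isl) == 0) next
    ir <- IRanges::reduce(IRanges::IRanges(isl$start + 1L, isl$end))
    z <- tss[tss$chrom == ch, ]
    plus <- z$strand != "-"
    # 0-based half-open promoter, mirrored around the TSS on minus strand
    pstart <- ifelse(plus, z$pos - upstream, z$pos - downstream + 1L)
    pend <- ifelse(plus, z$pos + downstream, z$pos + upstream + 1L)
    prom <- IRanges::IRanges(pstart + 1L, pmax(pend, pstart + 1L))
    promoter_count <- promoter_count +
      sum(IRanges::countOverlaps(prom, ir) > 0)
  }
  tibble(tss_count = as.integer(tss_count), promoter_count = as.integer(promoter_count))
}

#' Summary report over a set of predicted islands
#'
#' The per-genome summary: island count, total/average/min/max length,
#' sequence coverage, mean and population standard deviation of per-island
#' GC content and O/E ratio, and optional methylation density and
#' TSS/promoter overlap when those tracks are supplied.
#'
#' @param islands Island tibble with `start`, `end`, `gc`, `oe` columns
#'   (as produced by [cpg_predict()] or [extract_islands()]).
#' @param seq_lengths Evaluated sequence length(s), as in
#'   [confusion_counts()].
#' @param methylation Optional methylation-site tibble (`pos`, optional
#'   `chrom`).
#' @param tss Optional TSS tibble (`pos`, optional `strand`, `chrom`).
#' @return One-row tibble; count/length fields are zero and statistics
#'   `NA` when there are no islands.  Values are kept at full precision
#'   (display conventions: coverage one decimal, density two).
#' @export
island_report <- function(islands, seq_lengths, methylation = NULL, tss = NULL) {
  lens <- norm_lengths(seq_lengths)
  total <- sum(islands$end - islands$start)
  n <- nrow(islands)
  pop_sd <- function(x) if (length(x) == 0) NA_real_ else sqrt(mean((x - mean(x))^2))
  rep <- tibble(
    n_islands = n,
    total_length = as.numeric(total),
    avg_length = if (n > 0) total / n else NA_real_,
    min_length = if (n > 0) min(islands$end - islands$start) else NA_real_,
    max_length = if (n > 0) max(islands$end - islands$start) else NA_real_,
    coverage_pct = coverage_pct(total, sum(lens)),
    gc_mean = if (n > 0) mean(islands$gc) else NA_real_,
    gc_sd = pop_sd(islands$gc),
    oe_mean = if (n > 0) mean(islands$oe) else NA_real_,
    oe_sd = pop_sd(islands$oe)
  )
  if (!is.null(methylation)) {
    rep$methylation_sites <- sites_in_islands(methylation, islands)
    rep$methylation_density_pct <- methylation_density_pct(rep$methylation_sites, total)
  }
  if (!is.null(tss)) {
    ov <- tss_promoter_overlap(islands, tss)
    rep$tss_count <- ov$tss_count
    rep$promoter_count <- ov$promoter_count
  }
  rep
}
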