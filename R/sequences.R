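#' Read a FASTA file into a genome tibble
#'
#' Reads any multi-record FASTA file.  Residues are uppercased and every
#' character outside `A`, `C`, `G`, `T` (ambiguity codes, gaps, stray
#' symbols) is mapped to `N`, so downstream composition statistics never
#' mistake an ambiguous call for real sequence.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `name` (first word
#'   of the header), `length` (bp) and `seq` (the residue string over
#'   `ACGTN`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "acgtACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "cpgswarm_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    abort(paste0("empty FASTA file: ", path), class = "cpgswarm_format_error")
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(
      paste0("malformed FASTA: line ", first, " is not a '>' header in ", path),
      class = "cpgswarm_format_error"
    )
  }
  recs <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(recs))
  seqs <- gsub("[^ACGT]", "N", seqs, perl = TRUE)
  tibble(
    name = sub("\\s.*$", "", names(recs)),
    length = unname(nchar(seqs)),
    seq = unname(seqs)
  )
}

#' Write a genome tibble to FASTA
#'
#' @param genome Tibble with columns `name` and `seq` (as from
#'   [read_fasta()] or [simulate_cpg_genome()]).
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  purrr::walk2(genome$name, genome$seq, function(nm, s) {
    writeLines(paste0(">", nm), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  })
  invisible(path)
}

#' Tile a sequence with overlapping windows
#'
#' Produces the fixed tiling of `[0, seq_length)` that the optimizer works
#' through: windows advance by `window_size - overlap` and the final window
#' is truncated at the sequence end, so every base is covered at least
#' once.  The default overlap exceeds the maximum island length a particle
#' may propose, so an island crossing a window seam lies wholly inside the
#' neighbouring window.
#'
#' @param seq_length Sequence length in bp.
#' @param window_size Window width in bp.
#' @param overlap Overlap between consecutive windows in bp; must be
#'   smaller than `window_size`.
#' @return Tibble of 0-based half-open intervals with columns `start`, `end`.
#' @examples
#' partition_windows(25000, window_size = 10000, overlap = 2000)
#' @export
partition_windows <- function(seq_length, window_size = 10000L, overlap = 2000L) {
  if (overlap < 0 || window_size <= overlap) {
    abort("window_size must exceed overlap and overlap must be >= 0",
      class = "cpgswarm_param_error"
    )
  }
  if (seq_length <= 0) {
    abort("seq_length must be positive", class = "cpgswarm_param_error")
  }
  step <- window_size - overlap
  starts <- seq(0, max(0, seq_length - overlap - 1), by = step)
  tibble(start = starts, end = pmin(starts + window_size, seq_length))
}

## internal: O(1)-queryable prefix-sum profile over a residue string.
## cumulative counts are 1-based: cum[i] = count in residues 1..i;
## dimer cum counts CG dimers *starting* at positions 1..i.
seq_profile <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
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

## internal, vectorised over (start, end): counts inside 0-based half-open
## intervals.  Returns a list of integer vectors.
profile_counts <- function(prof, start, end) {
  at <- function(cs, i) ifelse(i > 0, cs[pmax(i, 1L)], 0L)
  list(
    n_a = at(prof$cA, end) - at(prof$cA, start),
    n_t = at(prof$cT, end) - at(prof$cT, start),
    n_c = at(prof$cC, end) - at(prof$cC, start),
    n_g = at(prof$cG, end) - at(prof$cG, start),
    # dimers fully inside [start, end): 1-based start positions start+1 .. end-1
    n_cpg = at(prof$cCpG, end - 1L) - at(prof$cCpG, start)
  )
}

#' Count nucleotides and CpG dinucleotides in an interval
#'
#' Tallies `A`, `C`, `G`, `T` and `CG` dimers inside a 0-based half-open
#' interval of a sequence.  `N` residues are excluded from the effective
#' length `n_eff` and break dimers (a `CG` spanning an `N` is not counted),
#' so assembly gaps never masquerade as AT-rich sequence.
#'
#' @param seq Residue string over `ACGTN`.
#' @param start,end 0-based half-open interval bounds; default the whole
#'   sequence.
#' @return One-row tibble with columns `n_a`, `n_t`, `n_c`, `n_g`, `n_cpg`,
#'   `n_eff` (= `n_a + n_t + n_c + n_g`) and `length` (= `end - start`).
#' @examples
#' count_nucleotides("CGCGCG")
#' count_nucleotides("CNG") # the N breaks the dimer
#' @export
count_nucleotides <- function(seq, start = 0L, end = nchar(seq)) {
  L <- nchar(seq)
  if (start < 0 || end > L || start >= end) {
    abort(
      sprintf("interval [%s, %s) out of bounds for sequence of length %s", start, end, L),
      class = "cpgswarm_coord_error"
    )
  }
  prof <- seq_profile(seq)
  cts <- profile_counts(prof, as.integer(start), as.integer(end))
  tibble(
    n_a = cts$n_a, n_t = cts$n_t, n_c = cts$n_c, n_g = cts$n_g,
    n_cpg = cts$n_cpg,
    n_eff = cts$n_a + cts$n_t + cts$n_c + cts$n_g,
    length = as.integer(end - start)
  )
}

#' GC content of a counted interval
#'
#' @param counts Tibble of counts from [count_nucleotides()] (any number
#'   of rows).
#' @return `(n_c + n_g) / n_eff`, a fraction in `[0, 1]`; `NA` for an
#'   interval whose effective length is zero (all `N`).
#' @export
gc_content <- function(counts) {
  out <- ifelse(counts$n_eff > 0, (counts$n_c + counts$n_g) / counts$n_eff, NA_real_)
  if (anyNA(out)) warn("gc_content undefined for all-N interval(s); returning NA")
  out
}

#' CpG observed/expected ratio of a counted interval
#'
#' The classic dinucleotide enrichment statistic: observed `CG` dimers
#' divided by the count expected under base-composition independence,
#' `n_cpg * n_eff / (n_c * n_g)`.  Defined as 0 when the interval contains
#' no `C` or no `G` (no dimer is possible, and none was observed).
#'
#' @inheritParams gc_content
#' @return Non-negative ratio; `NA` for an all-`N` interval.
#' @export
oe_ratio <- function(counts) {
  cg <- counts$n_c * counts$n_g
  out <- ifelse(counts$n_eff > 0,
    ifelse(cg > 0, counts$n_cpg * counts$n_eff / cg, 0),
    NA_real_
  )
  if (anyNA(out)) warn("oe_ratio undefined for all-N interval(s); returning NA")
  out
}

#' Island criteria presets
#'
#' The two standard rule sets for calling a segment a CpG island: the
#' Gardiner-Garden/Frommer thresholds (`"ggf"`: length >= 200 bp,
#' GC >= 0.50, O/E >= 0.60) and the stricter Takai-Jones thresholds
#' (`"tj"`: length >= 500 bp, GC >= 0.55, O/E >= 0.65) used when Alu
#' repeats are masked.  All boundaries are inclusive.
#'
#' @param preset `"ggf"` or `"tj"`.
#' @param min_length,min_gc,min_oe Optional overrides of the preset values.
#' @return A list of class `cpg_criteria` with fields `min_length`,
#'   `min_gc`, `min_oe` and `preset`.
#' @examples
#' cpg_criteria("tj")
#' @export
cpg_criteria <- function(preset = c("ggf", "tj"),
                         min_length = NULL, min_gc = NULL, min_oe = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    ggf = list(min_length = 200L, min_gc = 0.50, min_oe = 0.60),
    tj = list(min_length = 500L, min_gc = 0.55, min_oe = 0.65)
  )
  out <- list(
    min_length = as.integer(min_length %||% base$min_length),
    min_gc = min_gc %||% base$min_gc,
    min_oe = min_oe %||% base$min_oe,
    preset = preset
  )
  stopifnot(out$min_length > 0, out$min_gc > 0, out$min_gc < 1, out$min_oe > 0)
  structure(out, class = "cpg_criteria")
}

#' @export
print.cpg_criteria <- function(x, ...) {
  cat(sprintf(
    "<cpg_criteria '%s'> length >= %d bp, GC >= %.2f, O/E >= %.2f\n",
    x$preset, x$min_length, x$min_gc, x$min_oe
  ))
  invisible(x)
}

#' Test intervals against an island criteria set
#'
#' @param length Interval length(s) in bp.
#' @param gc GC fraction(s).
#' @param oe O/E ratio(s).
#' @param criteria A [cpg_criteria()] object.
#' @return Logical vector: `TRUE` where all three thresholds are met
#'   (boundaries inclusive).  `NA` statistics fail the test.
#' @export
meets_criteria <- function(length, gc, oe, criteria = cpg_criteria("ggf")) {
  ok <- length >= criteria$min_length & gc >= criteria$min_gc & oe >= criteria$min_oe
  ok & !is.na(ok)
}

#' Mask intervals of a sequence with N
#'
#' Replaces every residue inside the given intervals with `N`, which
#' removes those positions from base tallies and breaks any CpG dimer
#' crossing the mask boundary.  Coordinates are preserved.  Used for the
#' Alu-masked (Takai-Jones) prediction mode, where repeat annotations are
#' supplied as BED intervals.
#'
#' @param seq Residue string.
#' @param mask Tibble of 0-based half-open intervals (`start`, `end`);
#'   may overlap.
#' @return The masked residue string.
#' @examples
#' mask_intervals("CGCGAA", tibble::tibble(start = 0, end = 4))
#' @export
mask_intervals <- function(seq, mask) {
  if (nrow(mask) == 0) return(seq)
  L <- nchar(seq)
  if (any(mask$start < 0) || any(mask$end > L) || any(mask$start >= mask$end)) {
    abort("mask interval out of sequence bounds", class = "cpgswarm_coord_error")
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(mask))) {
    v[(mask$start[i] + 1L):mask$end[i]] <- "N"
  }
  paste(v, collapse = "")
}
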