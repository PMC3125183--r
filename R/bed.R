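#' Read a BED file of intervals
#'
#' Reads BED3+ (tab-separated, 0-based half-open).  `track`/`browser`
#' header lines and `#` comments are skipped.  Column 4 becomes `name`,
#' column 5 `score` and column 6 `strand` when present.
#'
#' @param path Path to a BED file.
#' @return Interval tibble with `chrom`, `start`, `end` and any optional
#'   columns found.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  x <- readr::read_tsv(I(lines[keep]), col_names = FALSE,
                       show_col_types = FALSE, progress = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6))] <- cols[seq_len(min(ncol(x), 6))]
  x <- mutate(x, start = as.integer(.data$start), end = as.integer(.data$end))
  if (any(x$start < 0) || any(x$end <= x$start)) {
    abort("invalid BED interval (end <= start or negative start)",
      class = "cpgswarm_format_error"
    )
  }
  as_tibble(x)
}

#' Write intervals to a BED file
#'
#' Emits BED with 0-based half-open coordinates, sorted by
#' (`chrom`, `start`).  For island tibbles the name column packs the
#' per-island statistics as `gc=..;oe=..;fit=..` so a prediction BED is
#' self-describing.
#'
#' @param x Interval tibble (`start`, `end`, optional `chrom`, `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @param track Optional track line to prepend.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, track = NULL) {
  if (!"chrom" %in% names(x)) x <- mutate(x, chrom = "seq")
  if (!"name" %in% names(x)) {
    x <- if (all(c("gc", "oe", "fitness") %in% names(x))) {
      mutate(x, name = sprintf("gc=%.4f;oe=%.4f;fit=%.4f",
                               .data$gc, .data$oe, .data$fitness))
    } else {
      mutate(x, name = ".")
    }
  }
  x <- arrange(x, .data$chrom, .data$start)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track)) writeLines(track, con)
  writeLines(
    sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end, x$name),
    con
  )
  invisible(path)
}

#' Read point positions (methylation sites, TSSs) from BED or a position list
#'
#' A BED file yields `pos = start` per record (strand kept when present);
#' a bare one-column file is read as 0-based positions.
#'
#' @param path Path to a BED file or one-column position list.
#' @return Tibble with `chrom` (defaulting to `"seq"` for bare lists),
#'   `pos`, and `strand` when available.
#' @export
read_positions <- function(path) {
  first <- readLines(path, n = 50, warn = FALSE)
  first <- first[nzchar(trimws(first)) & !grepl("^(track|browser|#)", first)]
  if (length(first) && !grepl("\t", first[1])) {
    pos <- as.integer(readLines(path, warn = FALSE))
    return(tibble(chrom = "seq", pos = pos[!is.na(pos)]))
  }
  bed <- read_bed(path)
  out <- tibble(chrom = bed$chrom, pos = bed$start)
  if ("strand" %in% names(bed)) out$strand <- bed$strand
  out
}
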