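# Deterministic sequence snippets --------------------------------------------

at_run <- function(n) strrep("AT", ceiling(n / 2)) |> substr(1, n)
cg_run <- function(n) strrep("CG", ceiling(n / 2)) |> substr(1, n)

# a sequence with one hand-placed block spliced into a host string
splice <- function(host, block, at) {
  paste0(substr(host, 1, at), block, substr(host, at + nchar(block) + 1, nchar(host)))
}

# per-base bitmap oracle for confusion counts (single sequence)
bitmap_confusion <- function(pred, ref, L) {
  p <- logical(L)
  r <- logical(L)
  for (i in seq_len(nrow(pred))) p[(pred$start[i] + 1):pred$end[i]] <- TRUE
  for (i in seq_len(nrow(ref))) r[(ref$start[i] + 1):ref$end[i]] <- TRUE
  tibble::tibble(
    tp = sum(p & r), fp = sum(p & !r), tn = sum(!p & !r), fn = sum(!p & r)
  )
}

# random non-degenerate interval set over [0, L)
random_intervals <- function(n, L) {
  s <- sort(sample.int(L - 1, n))
  e <- pmin(s + sample.int(max(4, L %/% 10), n, replace = TRUE), L)
  tibble::tibble(start = s, end = e)
}

# direct per-character count oracle honouring a mask
scan_counts <- function(chars, keep = rep(TRUE, length(chars))) {
  v <- ifelse(keep, chars, "N")
  n <- length(v)
  cpg <- if (n >= 2) sum(v[-n] == "C" & v[-1] == "G") else 0L
  tibble::tibble(
    n_a = sum(v == "A"), n_t = sum(v == "T"),
    n_c = sum(v == "C"), n_g = sum(v == "G"),
    n_cpg = cpg
  )
}

reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# small planted fixture reused by optimizer tests: one 800 bp island in 2 kb
planted_2kb <- function(seed = 1) {
  set.seed(seed)
  sim <- simulate_cpg_genome(
    length = 2000, gc = 0.40, cpg_suppression = 0.25,
    island_specs = tibble::tibble(length = 800L, gc = 0.62, oe = 0.85, position = 600L),
    min_gap = 200L
  )
  sim
}

# an island pair whose merged span (3700 bp) exceeds the candidate length
# cap, separated by a CpG-free G/C gap: joining it is only worthwhile for
# the merge-refinement pass, never for a single candidate
split_island_pair <- function(seed) {
  set.seed(seed)
  bg <- generate_background(20000)
  out <- plant_islands(
    bg,
    tibble::tibble(length = c(1800L, 1800L), gc = 0.60, oe = 0.85,
                   position = c(4000L, 5900L)),
    min_gap = 50L
  )
  s <- paste0(
    substr(out$seq, 1, 5800), strrep("G", 50), strrep("C", 50),
    substr(out$seq, 5901, nchar(out$seq))
  )
  list(
    genome = tibble::tibble(name = "synth", length = nchar(s), seq = s),
    truth = out$truth
  )
}

# two-basin escape fixture: a weak island near the left edge and a much
# better one near the right edge of a single 6 kb window
two_bump_fixture <- function(seed = 99) {
  set.seed(seed)
  sim <- simulate_cpg_genome(
    length = 6000, gc = 0.40, cpg_suppression = 0.25,
    island_specs = tibble::tibble(
      length = c(400L, 1500L), gc = c(0.55, 0.62), oe = c(0.70, 0.85),
      position = c(500L, 4200L)
    ),
    min_gap = 300L
  )
  sim
}
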