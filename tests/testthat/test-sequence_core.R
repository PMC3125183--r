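test_that("read_fasta parses, case-folds and maps ambiguity codes to N", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT"), fa)
  g <- read_fasta(fa)
  expect_equal(g$name, "x")
  expect_equal(g$length, 4L)

  writeLines(c(">x desc here", "acgt", "ACGT"), fa)
  expect_equal(read_fasta(fa)$seq, "ACGTACGT")

  writeLines(c(">x", "ACRT"), fa)
  expect_equal(read_fasta(fa)$seq, "ACNT")

  writeLines(c(">a", "ACGT", ">b", "ttttt"), fa)
  g <- read_fasta(fa)
  expect_equal(g$name, c("a", "b"))
  expect_equal(g$length, c(4L, 5L))
})

test_that("read_fasta rejects empty and malformed input with the offending line", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), fa)
  expect_error(read_fasta(fa), class = "cpgswarm_format_error")
  writeLines(c("ACGT", ">x", "ACGT"), fa)
  expect_error(read_fasta(fa), "line 1", class = "cpgswarm_format_error")
})

test_that("partition_windows tiles the sequence with the documented step", {
  w <- partition_windows(25000, 10000, 2000)
  expect_equal(w$start, c(0, 8000, 16000))
  expect_equal(w$end, c(10000, 18000, 25000))

  w <- partition_windows(5000, 10000, 2000)
  expect_equal(nrow(w), 1L)
  expect_equal(w$end, 5000)

  w <- partition_windows(20000, 10000, 0)
  expect_equal(nrow(w), 2L)

  expect_error(partition_windows(100, 50, 50), class = "cpgswarm_param_error")
})

test_that("every base is covered by some window", {
  for (L in c(1000, 9999, 10000, 10001, 25000, 31007)) {
    w <- partition_windows(L, 10000, 2000)
    covered <- logical(L)
    for (i in seq_len(nrow(w))) covered[(w$start[i] + 1):w$end[i]] <- TRUE
    expect_true(all(covered), info = paste("L =", L))
    expect_true(all(w$end <= L))
  }
})

test_that("count_nucleotides tallies bases and in-bounds CpG dimers", {
  c1 <- count_nucleotides("CGCGCG")
  expect_equal(c(c1$n_c, c1$n_g, c1$n_cpg, c1$n_eff), c(3L, 3L, 3L, 6L))

  c2 <- count_nucleotides("AAAA")
  expect_equal(c(c2$n_a, c2$n_cpg), c(4L, 0L))

  c3 <- count_nucleotides("CNG")
  expect_equal(c(c3$n_c, c3$n_g, c3$n_cpg, c3$n_eff), c(1L, 1L, 0L, 2L))

  # dimers crossing the interval boundary are not counted
  expect_equal(count_nucleotides("ACGT", 0, 2)$n_cpg, 0L)
  expect_equal(count_nucleotides("ACGT", 1, 3)$n_cpg, 1L)

  expect_error(count_nucleotides("ACGT", 0, 5), class = "cpgswarm_coord_error")
  expect_error(count_nucleotides("ACGT", 2, 2), class = "cpgswarm_coord_error")
})

test_that("gc_content and oe_ratio follow their definitions", {
  expect_equal(gc_content(count_nucleotides("GCGC")), 1)
  expect_equal(gc_content(count_nucleotides("ATAT")), 0)
  expect_equal(gc_content(count_nucleotides("ACGT")), 0.5)

  expect_equal(oe_ratio(count_nucleotides("CGCGCG")), 2)
  expect_equal(oe_ratio(count_nucleotides("CCGG")), 1)
  expect_equal(oe_ratio(count_nucleotides("AATT")), 0)

  expect_warning(res <- gc_content(count_nucleotides("NNNN")), "all-N")
  expect_true(is.na(res))
  expect_warning(res <- oe_ratio(count_nucleotides("NN")), "all-N")
  expect_true(is.na(res))
})

test_that("criteria boundaries are inclusive for both presets", {
  expect_true(meets_criteria(200, 0.50, 0.60, cpg_criteria("ggf")))
  expect_false(meets_criteria(199, 0.99, 2.0, cpg_criteria("ggf")))
  expect_true(meets_criteria(500, 0.55, 0.65, cpg_criteria("tj")))
  expect_false(meets_criteria(499, 0.55, 0.65, cpg_criteria("tj")))
  expect_false(meets_criteria(500, 0.549, 0.65, cpg_criteria("tj")))
  expect_false(meets_criteria(1000, NA, 0.9, cpg_criteria("ggf")))
})

test_that("mask_intervals replaces residues with N and preserves coordinates", {
  expect_equal(mask_intervals("CGCGAA", tibble::tibble(start = 0, end = 4)), "NNNNAA")
  expect_equal(
    mask_intervals("ACGT", tibble::tibble(start = integer(), end = integer())),
    "ACGT"
  )
  # overlapping mask intervals behave like their union
  s <- "ACGTACGTACGT"
  m1 <- tibble::tibble(start = c(2, 4), end = c(6, 8))
  m2 <- tibble::tibble(start = 2, end = 8)
  expect_equal(mask_intervals(s, m1), mask_intervals(s, m2))
  expect_error(
    mask_intervals("ACGT", tibble::tibble(start = 0, end = 5)),
    class = "cpgswarm_coord_error"
  )
})

test_that("counts are additive over partitions, with dimer-splitting caveat", {
  set.seed(42)
  for (rep in 1:20) {
    chars <- sample(c("A", "C", "G", "T", "N"), 200, replace = TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.15, 0.05))
    s <- paste(chars, collapse = "")
    cut <- sample(50:150, 1)
    whole <- count_nucleotides(s)
    left <- count_nucleotides(s, 0, cut)
    right <- count_nucleotides(s, cut, 200)
    for (col in c("n_a", "n_t", "n_c", "n_g")) {
      expect_equal(whole[[col]], left[[col]] + right[[col]])
    }
    expect_gte(whole$n_cpg, left$n_cpg + right$n_cpg)
    expect_lte(whole$n_cpg - (left$n_cpg + right$n_cpg), 1L)
  }
})

test_that("oe_ratio is invariant under reverse complement for N-free sequences", {
  set.seed(7)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    expect_equal(
      oe_ratio(count_nucleotides(s)),
      oe_ratio(count_nucleotides(reverse_complement(s)))
    )
  }
})

test_that("masking agrees with a direct masked-scan oracle", {
  set.seed(13)
  for (rep in 1:20) {
    chars <- sample(c("A", "C", "G", "T"), 150, replace = TRUE)
    s <- paste(chars, collapse = "")
    mask <- random_intervals(3, 150)
    masked <- mask_intervals(s, mask)
    keep <- rep(TRUE, 150)
    for (i in seq_len(nrow(mask))) keep[(mask$start[i] + 1):mask$end[i]] <- FALSE
    got <- count_nucleotides(masked)
    want <- scan_counts(chars, keep)
    for (col in names(want)) expect_equal(got[[col]], want[[col]])
  }
})
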