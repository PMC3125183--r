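test_that("confusion counts match the worked example and edge cases", {
  cc <- confusion_counts(
    tibble::tibble(start = 0, end = 10),
    tibble::tibble(start = 5, end = 15), 20
  )
  expect_equal(as.numeric(cc), c(5, 5, 5, 5))

  ref <- tibble::tibble(start = c(2, 12), end = c(7, 18))
  same <- confusion_counts(ref, ref, 20)
  expect_equal(c(same$fp, same$fn), c(0, 0))

  none <- confusion_counts(tibble::tibble(start = integer(), end = integer()), ref, 20)
  expect_equal(c(none$tp, none$fp, none$fn), c(0, 0, 11))

  expect_error(
    confusion_counts(tibble::tibble(start = 0, end = 30), ref, 20),
    class = "cpgswarm_coord_error"
  )
})

test_that("interval arithmetic equals the per-base bitmap on random instances", {
  set.seed(90)
  for (rep in 1:60) {
    L <- sample(200:10000, 1)
    pred <- random_intervals(sample(1:8, 1), L)
    ref <- random_intervals(sample(1:8, 1), L)
    got <- confusion_counts(pred, ref, L)
    want <- bitmap_confusion(pred, ref, L)
    expect_equal(got, want)
    expect_equal(got$tp + got$fp + got$tn + got$fn, L)
  }
})

test_that("the five metrics follow their formulas", {
  m <- island_metrics(tibble::tibble(tp = 5, fp = 5, tn = 5, fn = 5))
  expect_equal(as.numeric(m), c(0.5, 0.5, 0.5, 1 / 3, 0))

  perfect <- island_metrics(tibble::tibble(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_equal(as.numeric(perfect), c(1, 1, 1, 1, 1))

  anti <- island_metrics(tibble::tibble(tp = 0, fp = 10, tn = 0, fn = 10))
  expect_equal(anti$cc, -1)

  undef <- island_metrics(tibble::tibble(tp = 0, fp = 0, tn = 20, fn = 0))
  expect_true(is.na(undef$sn))
  expect_equal(undef$sp, 1)
})

test_that("metric identities hold on random counts", {
  set.seed(91)
  for (rep in 1:50) {
    c4 <- as.list(sample(0:500, 4, replace = TRUE))
    names(c4) <- c("tp", "fp", "tn", "fn")
    cts <- tibble::as_tibble(c4)
    m <- island_metrics(cts)
    L <- sum(unlist(c4))
    if (L > 0) expect_equal(m$acc, (cts$tp + cts$tn) / L)
    if (!is.na(m$cc) && cts$tp * cts$tn == cts$fn * cts$fp) {
      expect_equal(m$cc, 0)
    }
    if (!is.na(m$pc) && !is.na(m$sn)) expect_lte(m$pc, m$sn + 1e-12)
  }
})

test_that("ROC rates shrink as the threshold rises and a random scorer is near chance", {
  set.seed(92)
  L <- 20000
  islands <- random_intervals(30, L)
  islands$fitness <- runif(30, 1, 3)
  ref <- random_intervals(30, L)
  pts <- roc_points(islands, ref, L)
  ord <- order(pts$threshold)
  expect_true(all(diff(pts$tpr[ord]) <= 1e-12))
  expect_true(all(diff(pts$fpr[ord]) <= 1e-12))
  # top threshold predicts nothing
  expect_equal(pts$tpr[which.max(pts$threshold)], 0)
  expect_equal(pts$fpr[which.max(pts$threshold)], 0)
  # scores independent of the reference: AUC near 1/2
  expect_lt(abs(roc_auc(pts) - 0.5), 0.1)
})

test_that("report arithmetic reproduces published-scale derived values", {
  # chromosome-scale worked examples: printed totals give the printed ratios
  expect_equal(round(coverage_pct(1607472, 46944329), 1), 3.4)
  expect_lt(abs(coverage_pct(2907983, 49691432) - 5.85), 0.005)
  expect_lt(abs(methylation_density_pct(111172, 1607472) - 6.91), 0.01)
  expect_lt(abs(methylation_density_pct(185324, 2907983) - 6.37), 0.005)
  expect_equal(floor(1607472 / 2813), 571)
  expect_equal(coverage_pct(0, 100), 0)
  expect_error(coverage_pct(10, 0), class = "cpgswarm_param_error")
  expect_warning(res <- methylation_density_pct(5, 0), "undefined")
  expect_true(is.na(res))
})

test_that("TSS and promoter overlap honours strand and the -1500/+500 window", {
  islands <- tibble::tibble(start = 1000L, end = 2000L)
  # TSS inside the island counts in both tallies
  ov <- tss_promoter_overlap(islands, tibble::tibble(pos = 1500L, strand = "+"))
  expect_equal(as.integer(ov), c(1L, 1L))
  # TSS 1 kb downstream on + strand: only the promoter reaches back
  ov <- tss_promoter_overlap(islands, tibble::tibble(pos = 3000L, strand = "+"))
  expect_equal(as.integer(ov), c(0L, 1L))
  # same position on - strand: promoter extends downstream only, no overlap
  ov <- tss_promoter_overlap(islands, tibble::tibble(pos = 3000L, strand = "-"))
  expect_equal(as.integer(ov), c(0L, 0L))
  # upstream TSS on - strand reaches the island through its flipped promoter
  ov <- tss_promoter_overlap(islands, tibble::tibble(pos = 500L, strand = "-"))
  expect_equal(as.integer(ov), c(0L, 1L))
  # no islands
  ov <- tss_promoter_overlap(islands[0, ], tibble::tibble(pos = 1500L))
  expect_equal(as.integer(ov), c(0L, 0L))
})

test_that("island_report aggregates lengths, composition and optional tracks", {
  islands <- tibble::tibble(
    start = c(0L, 1000L), end = c(400L, 1600L),
    gc = c(0.55, 0.65), oe = c(0.7, 0.9)
  )
  rep <- island_report(islands, 10000,
    methylation = tibble::tibble(pos = c(10L, 1100L, 5000L))
  )
  expect_equal(rep$n_islands, 2L)
  expect_equal(rep$total_length, 1000)
  expect_equal(rep$avg_length, 500)
  expect_equal(rep$min_length, 400)
  expect_equal(rep$max_length, 600)
  expect_equal(rep$coverage_pct, 10)
  expect_equal(rep$gc_mean, 0.6)
  expect_equal(rep$gc_sd, 0.05) # population SD
  expect_equal(rep$methylation_sites, 2L)
  expect_equal(rep$methylation_density_pct, 0.2)

  single <- island_report(islands[1, ], 10000)
  expect_equal(single$gc_sd, 0)

  none <- island_report(islands[0, ], 10000)
  expect_equal(none$n_islands, 0L)
  expect_true(is.na(none$avg_length))
})

test_that("evaluate_islands wraps counts and metrics with tidy/glance", {
  pred <- tibble::tibble(start = 0, end = 10)
  ref <- tibble::tibble(start = 5, end = 15)
  ev <- evaluate_islands(pred, ref, 20)
  expect_s3_class(ev, "cpg_evaluation")
  td <- tidy(ev)
  expect_equal(td$metric, c("sn", "sp", "acc", "pc", "cc"))
  expect_equal(td$value[1], 0.5)
  gl <- glance(ev)
  expect_equal(gl$tp, 5)
  expect_equal(gl$pc, 1 / 3)
})
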