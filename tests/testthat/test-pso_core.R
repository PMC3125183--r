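test_that("inertia weight anneals linearly from w_max to w_min", {
  expect_equal(inertia_weight(0, 100), 0.9)
  expect_equal(inertia_weight(100, 100), 0.4)
  expect_equal(inertia_weight(50, 100), 0.65)
  expect_error(inertia_weight(0, 0), class = "cpgswarm_param_error")
})

test_that("velocity update follows the canonical rule and clips at v_max", {
  cfg <- swarm_config()
  v <- matrix(c(10, -4), 1)
  x <- matrix(c(100, 300), 1)
  zero <- matrix(0, 1, 2)
  # no attraction: pure inertia
  vn <- update_velocity(v, x, x, c(100, 300), w = 0.5, cfg,
                        v_max = NULL, r1 = zero, r2 = zero)
  expect_equal(as.numeric(vn), c(5, -2))
  # equilibrium: at both bests with zero velocity
  vn <- update_velocity(zero, x, x, c(100, 300), w = 0.9, cfg, v_max = NULL)
  expect_equal(as.numeric(vn), c(0, 0))
  # clipping
  one <- matrix(1, 1, 2)
  vn <- update_velocity(v, x, x + 1000, c(5000, 5000), w = 1, cfg,
                        v_max = 50, r1 = one, r2 = one)
  expect_true(all(abs(vn) <= 50))
})

test_that("position update rounds and repairs into the window", {
  cfg <- fitness_config()
  p <- update_position(c(100, 300), c(50, -50), window_length = 10000, cfg)
  expect_equal(as.numeric(p), c(150, 250))
  # length clamped up to len_lo, start pulled back so the island fits
  p <- update_position(c(9900, 100), c(0, 0), window_length = 10000, cfg)
  expect_equal(as.numeric(p), c(9800, 200))
  # Fe pushed past the window end: start reduced to window - length
  p <- update_position(c(9500, 900), c(400, 0), window_length = 10000, cfg)
  expect_equal(as.numeric(p), c(9100, 900))
  # zero velocity leaves an in-bounds position unchanged
  p <- update_position(c(100, 300), c(0, 0), window_length = 10000, cfg)
  expect_equal(as.numeric(p), c(100, 300))
})

test_that("swarm initialisation respects bounds and is seed-deterministic", {
  sim <- planted_2kb()
  cfg <- swarm_config(population = 50)
  set.seed(5)
  sw1 <- initialize_swarm(sim$genome$seq, config = cfg)
  set.seed(5)
  sw2 <- initialize_swarm(sim$genome$seq, config = cfg)
  expect_identical(sw1, sw2)
  expect_true(all(sw1$x[, 2] >= 200 & sw1$x[, 2] <= 2000))
  expect_true(all(sw1$x[, 1] >= 0 & sw1$x[, 1] <= 2000 - 200))
  expect_equal(sw1$gbest_fit, max(sw1$pbest_fit))
  # lengths clamp to a short window
  set.seed(5)
  sw3 <- initialize_swarm(strrep("ACGT", 75), config = cfg) # 300 bp
  expect_true(all(sw3$x[, 2] >= 200 & sw3$x[, 2] <= 300))
  # a window shorter than the minimum island length is skipped with a notice
  expect_message(
    res <- initialize_swarm(strrep("ACGT", 10), config = cfg),
    "skipped"
  )
  expect_null(res)
})

test_that("a planted island is recovered and gbest never decreases", {
  sim <- planted_2kb()
  set.seed(21)
  res <- run_swarm_window(sim$genome$seq, config = swarm_config(), trace = TRUE)
  expect_false(is.null(res$island))
  crit <- cpg_criteria("ggf")
  expect_true(meets_criteria(res$island$length, res$island$gc, res$island$oe, crit))
  expect_true(all(diff(res$trace) >= 0))
  # recovered island overlaps the planted truth
  expect_lt(max(res$island$start, sim$truth$start),
            min(res$island$end, sim$truth$end))
})

test_that("a feature-free window yields no island", {
  set.seed(3)
  res <- run_swarm_window(at_run(2000), config = swarm_config(population = 60))
  expect_null(res$island)
  expect_lte(res$gbest_fit, 0.3)
})

test_that("deflation recovers multiple islands and reruns are identical", {
  set.seed(17)
  sim <- simulate_cpg_genome(
    length = 10000, island_specs = tibble::tibble(
      length = c(700L, 900L), gc = c(0.60, 0.63), oe = c(0.8, 0.85),
      position = c(1500L, 6000L)
    ),
    min_gap = 1000L
  )
  cfg <- swarm_config(population = 150)
  set.seed(8)
  isl1 <- extract_islands(sim$genome$seq, cfg, restarts_per_window = 5)
  set.seed(8)
  isl2 <- extract_islands(sim$genome$seq, cfg, restarts_per_window = 5)
  expect_identical(isl1, isl2)
  expect_gte(nrow(isl1), 2)
  # both planted islands are hit
  for (i in 1:2) {
    hit <- any(pmax(isl1$start, sim$truth$start[i]) <
                 pmin(isl1$end, sim$truth$end[i]))
    expect_true(hit, info = paste("island", i))
  }
  # output is sorted and non-overlapping (seam duplicates unioned)
  expect_false(is.unsorted(isl1$start))
  if (nrow(isl1) > 1) {
    expect_true(all(isl1$start[-1] >= isl1$end[-nrow(isl1)]))
  }
})

test_that("swarm search approaches the exhaustive optimum on a small fixture", {
  sim <- planted_2kb()
  oracle <- exhaustive_best_segment(sim$genome$seq)
  set.seed(14)
  res <- run_swarm_window(sim$genome$seq, config = swarm_config())
  expect_gte(res$gbest_fit, 0.95 * oracle$fitness)
})
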