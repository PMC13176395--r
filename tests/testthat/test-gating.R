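test_that("fixed-offset gating places windows by arithmetic on the mean period", {
  cs <- toy_cycle_set(1, period = 4)          # one cycle on [0, 4)
  ev <- manual_events(seq(0.05, 3.95, by = 0.1))
  m <- gate_method1_qpg(cs, ev, offset_fraction = 0.25, duty_fraction = 0.5)
  expect_equal(m$windows$t0, 1.0)
  expect_equal(m$windows$t1, 3.0)
  expect_equal(sum(m$retained), sum(ev$times >= 1 & ev$times < 3))

  # duty 1 retains everything
  full <- gate_method1_qpg(cs, ev, offset_fraction = 0, duty_fraction = 1)
  expect_equal(full$retained_fraction, 1)

  expect_error(gate_method1_qpg(cs, ev, offset_fraction = 1), "offset")
  expect_error(gate_method1_qpg(cs, ev, duty_fraction = 0), "duty")
})

test_that("amplitude-driven gating centres its window on a symmetric trough", {
  # symmetric triangular cycle on [0, 4) between peaks, uniform events
  t <- seq(0, 8, by = 0.05)
  a <- 5 * abs(t - 4) / 4
  tr <- respiratory_trace(t, pmin(a, 5))
  cs <- toy_cycle_set(1, period = 8)
  cs$cycles$min_amp_time <- 4
  ev <- manual_events(seq(0.025, 7.975, by = 0.05))
  m <- gate_method2_adaptive(cs, tr, ev, duty_fraction = 0.5)
  centre <- (m$windows$t0 + m$windows$t1) / 2
  expect_lt(abs(centre - 4), 0.1)
  expect_lt(abs((m$windows$t1 - m$windows$t0) - 4), 0.15)
})

test_that("greedy expansion reproduces the worked toy cycle", {
  a <- c(5, 3, 1, 0, 1, 2, 4, 6)
  counts <- rep(1, 8)
  g <- greedy_quiescent_window(a, counts, duty_fraction = 0.5)
  expect_equal(g[1:2], c(3L, 6L))   # samples with amplitudes 1,0,1,2
  expect_equal(g[3], 4)
  expect_equal(oracle_min_window(a, counts, 0.5, which.min(a)), c(3, 6))
})

test_that("greedy window equals the exhaustive minimal-window oracle on valleys", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:25, 1)
    a <- random_valley(n, integer_amps = (i %% 3 == 0))
    counts <- rep(1, n)
    duty <- runif(1, 0.2, 0.9)
    anchor <- which.min(a)
    g <- greedy_quiescent_window(a, counts, duty, anchor)
    expect_equal(g[1:2], oracle_min_window(a, counts, duty, anchor),
                 info = sprintf("case %d", i))
  }
})

test_that("with uneven counts the greedy window is amplitude-level optimal", {
  # no contiguous window with a strictly lower amplitude ceiling can reach
  # the duty target: the maximal run below the greedy ceiling is infeasible
  set.seed(43)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    a <- random_valley(n)
    counts <- rpois(n, 3) + (i %% 2)
    if (sum(counts) == 0) counts[sample(n, 1)] <- 1
    duty <- runif(1, 0.3, 0.9)
    anchor <- which.min(a)
    g <- greedy_quiescent_window(a, counts, duty, anchor)
    target <- duty * sum(counts)
    expect_gte(g[3] + 1e-9, min(target, sum(counts)))
    level <- max(a[g[1]:g[2]])
    below <- a < level
    if (any(below)) {
      run <- suppressWarnings(
        range(which(cumsum(!below) == cumsum(!below)[anchor] & below)))
      if (all(is.finite(run)) && run[1] <= anchor && anchor <= run[2]) {
        expect_lt(sum(counts[run[1]:run[2]]), target)
      }
    }
  }
})

test_that("both methods converge to the duty fraction on regular breathing", {
  sc <- sim_scan(jitter = 0.1, seed = 21, duration = 120, rate = 1000)
  m1 <- gate_method1_qpg(sc$cycles, sc$events)
  m2 <- gate_method2_adaptive(sc$cycles, sc$trace, sc$events)
  # per-cycle windows hold the duty fraction of in-cycle events
  in_cycle <- sum(sc$events$times >= min(sc$cycles$cycles$start_time) &
                    sc$events$times < max(sc$cycles$cycles$end_time))
  expect_lt(abs(sum(m1$retained) / in_cycle - 0.5), 0.02)
  expect_lt(abs(sum(m2$retained) / in_cycle - 0.5), 0.025)
  expect_true(all(m2$params$achieved >= 0.5, na.rm = TRUE))
  # a different duty setting is honoured too
  m1d <- gate_method1_qpg(sc$cycles, sc$events, duty_fraction = 0.3)
  expect_lt(abs(sum(m1d$retained) / in_cycle - 0.3), 0.02)
})

test_that("cycles without events produce empty windows with a warning", {
  cs <- toy_cycle_set(2, period = 4)          # cycles [0,4) and [4,8)
  tr <- sine_trace(freq = 0.25, duration = 8)
  ev <- manual_events(seq(0.1, 3.9, by = 0.1))  # all in the first cycle
  expect_warning(m <- gate_method2_adaptive(cs, tr, ev), "no events")
  expect_equal(nrow(m$windows), 1)
})

test_that("overlap satisfies its identities and symmetry", {
  sc <- sim_scan(jitter = 0.8, seed = 31, duration = 60, rate = 200)
  m1 <- gate_method1_qpg(sc$cycles, sc$events)
  m2 <- gate_method2_adaptive(sc$cycles, sc$trace, sc$events)
  expect_equal(compute_overlap(m1, m1, sc$events)$overlap, 1)
  ab <- compute_overlap(m1, m2, sc$events)
  ba <- compute_overlap(m2, m1, sc$events)
  expect_equal(ab$overlap, ba$overlap)
  expect_gte(ab$overlap, 0)
  expect_lte(ab$overlap, 1)

  # equal-size shifted masks: events 1-100 vs 51-150 -> overlap 0.5
  ev <- manual_events(seq_len(150))
  wa <- data.frame(cycle_index = 1, t0 = 0.5, t1 = 100.5)
  wb <- data.frame(cycle_index = 1, t0 = 50.5, t1 = 150.5)
  ma <- m1; ma$windows <- wa; ma$retained <- ev$times >= 0.5 & ev$times < 100.5
  mb <- m1; mb$windows <- wb; mb$retained <- ev$times >= 50.5 & ev$times < 150.5
  expect_equal(compute_overlap(ma, mb, ev)$overlap, 0.5)
  # disjoint equal-size masks -> 0
  mb$retained <- ev$times > 100.5
  mb$retained[1:50] <- FALSE
  expect_equal(compute_overlap(ma, mb, ev)$intersection_counts, 0)
})

test_that("R value separates breathing-like from broadband traces", {
  breathing <- sine_trace(freq = 0.25, amplitude = 15, duration = 120)
  set.seed(99)
  noisy <- respiratory_trace(breathing$times,
                             breathing$amplitudes + rnorm(3001, 0, 1))
  rv <- compute_r_value(noisy)
  expect_gt(rv$r, 15)
  expect_true(rv$passes_threshold)
  expect_equal(rv$peak_frequency, 0.25, tolerance = 0.01)

  # white noise stays below threshold in >= 95% of 200 seeds
  below <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    wn <- respiratory_trace(seq(0, 40, 0.04), rnorm(1001))
    compute_r_value(wn)$r < 15
  }, logical(1))
  expect_gte(mean(below), 0.95)

  expect_error(compute_r_value(sine_trace(duration = 20)), "30 s")
  flat <- respiratory_trace(seq(0, 40, 0.04), rep(1, 1001))
  expect_error(compute_r_value(flat), "variance")
})

test_that("within-gate residual motion: adaptive gating beats fixed offset on irregular breathing", {
  worse <- 0
  for (s in 1:15) {
    sc <- sim_scan(jitter = 1.2, seed = 300 + s, duration = 120, rate = 300)
    m1 <- gate_method1_qpg(sc$cycles, sc$events)
    m2 <- gate_method2_adaptive(sc$cycles, sc$trace, sc$events)
    sd1 <- sd(sc$events$displacements[m1$retained])
    sd2 <- sd(sc$events$displacements[m2$retained])
    if (sd2 > sd1) worse <- worse + 1
  }
  expect_lte(worse, 1)  # Method 2 narrower residual motion in >= 14/15 scans
})
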