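test_that("segment scores match a direct OLS oracle", {
  t <- seq(0, 297, by = 3)
  # perfectly linear flow: zero residuals on any sub-segment
  lin <- flow_trace(t, flow = 2 + 0.01 * t)
  expect_lt(abs(segment_score(lin, 1, 100)), 1e-10)
  expect_lt(abs(segment_score(lin, 20, 60)), 1e-10)

  # a two-level step scores worse than either level alone
  step <- flow_trace(t, flow = rep(c(2, 8), each = 50))
  expect_lt(segment_score(step, 1, 100),
            min(segment_score(step, 1, 50), segment_score(step, 51, 100)))

  set.seed(11)
  for (rep in 1:10) {
    y <- rnorm(10)
    tr <- flow_trace(t[1:10], flow = y)
    fit <- lm(y ~ t[1:10])
    expect_equal(segment_score(tr, 1, 10),
                 -sum(resid(fit)^2) / 10, tolerance = 1e-9)
  }
  expect_error(segment_score(lin, 1, 2), "min_seg_points")
})

test_that("dp_segment finds forced optima on noiseless traces", {
  t <- seq(0, 297, by = 3)
  const <- flow_trace(t, flow = rep(5, 100))
  expect_equal(nrow(dp_segment(const, segmentation_config(penalty_P = 0.1))), 1L)

  step <- flow_trace(t, flow = rep(c(2, 8), each = 50))
  seg <- dp_segment(step, segmentation_config(penalty_P = 0.01))
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$end_idx[1], 50L)
  # brute force over all single breakpoints agrees on the split position
  sc <- sapply(3:97, function(b)
    segment_score(step, 1, b) + segment_score(step, b + 1, 100))
  expect_equal((3:97)[which.max(sc)], 50L)

  expect_equal(nrow(dp_segment(step, segmentation_config(penalty_P = 1e6))), 1L)
  expect_error(dp_segment(flow_trace(0:2, flow = 1:3),
                          segmentation_config(min_seg_points = 4)),
               "data error")
})

test_that("dp_segment matches exhaustive enumeration on small traces", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(6:15, 1)
    t <- seq(0, by = 3, length.out = n)
    y <- rnorm(n) + sample(c(0, 3), 1) * (seq_len(n) > n / 2)
    P <- runif(1, 0.01, 1)
    tr <- flow_trace(t, flow = y)
    seg <- dp_segment(tr, segmentation_config(penalty_P = P))
    expect_equal(achieved_score(seg, P), brute_force_best(t, y, P),
                 tolerance = 1e-9)
  }
})

test_that("segmentations tile the trace and respect min_seg_points", {
  set.seed(31)
  for (rep in 1:5) {
    sim <- simulate_flow(trace_spec(duration_s = 1200, osc_amplitude = 0.1,
                                    osc_period_s = 300, seed = 100 + rep))
    seg <- dp_segment(sim$trace)
    expect_equal(seg$start_idx[1], 1L)
    expect_equal(seg$end_idx[nrow(seg)], n_samples(sim$trace))
    if (nrow(seg) > 1)
      expect_equal(seg$start_idx[-1], seg$end_idx[-nrow(seg)] + 1L)
    expect_true(all(seg$n >= 3))
  }
})

test_that("segment count is non-increasing in the break-point penalty", {
  sim <- simulate_flow(trace_spec(duration_s = 1800, osc_amplitude = 0.15,
                                  osc_period_s = 400, seed = 8))
  counts <- sapply(c(0.001, 0.01, 0.05, 0.2, 1, 10), function(P)
    nrow(dp_segment(sim$trace, segmentation_config(penalty_P = P))))
  expect_true(all(diff(counts) <= 0))
})

test_that("sub-minute segments dissolve into their better neighbor", {
  # 20 min at level 2, 40 s outlier burst, 18 min at level 8
  t <- seq(0, by = 3, length.out = 400 + 14 + 360)
  y <- c(rep(2, 400), rep(30, 14), rep(8, 360))
  tr <- flow_trace(t, flow = y)
  seg <- dp_segment(tr, segmentation_config(penalty_P = 0.01))
  expect_gte(nrow(seg), 3L)
  merged <- merge_invalid_segments(seg, tr, segmentation_config())
  expect_equal(nrow(merged), 2L)
  expect_true(all(merged$duration_s >= 60))
  # tiling preserved after merge
  expect_equal(merged$start_idx[1], 1L)
  expect_equal(merged$end_idx[2], length(y))

  # identity when nothing is invalid
  two <- dp_segment(flow_trace(seq(0, 597, 3), flow = rep(c(2, 8), each = 100)),
                    segmentation_config(penalty_P = 0.01))
  expect_identical(nrow(merge_invalid_segments(two,
    flow_trace(seq(0, 597, 3), flow = rep(c(2, 8), each = 100)),
    segmentation_config())), 2L)
  one <- dp_segment(flow_trace(seq(0, 297, 3), flow = rep(1, 100)),
                    segmentation_config())
  expect_identical(nrow(merge_invalid_segments(one,
    flow_trace(seq(0, 297, 3), flow = rep(1, 100)),
    segmentation_config())), 1L)
})

test_that("slope p-values match lm and honor degenerate conventions", {
  set.seed(41)
  t <- seq(0, 897, by = 3)
  for (rep in 1:10) {
    y <- 5 + rnorm(300, sd = 0.2) + runif(1, -1e-3, 1e-3) * t
    tr <- flow_trace(t, flow = y)
    fit <- summary(lm(y ~ t))$coefficients
    expect_equal(slope_p_value(tr, 1:300), fit[2, 4], tolerance = 1e-9)
  }
  rising <- flow_trace(t, flow = 1 + 0.01 * t)
  expect_equal(slope_p_value(rising, 1:300), 0)
  flat <- flow_trace(t, flow = rep(3, 300))
  expect_equal(slope_p_value(flat, 1:300), 1)
  expect_error(slope_p_value(flat, 1:2), "fewer than 3")
  # thinning keeps only every k-th sample
  expect_equal(slope_p_value(flat, 1:300, thin_by = 20), 1)
})

test_that("steadiness classes follow the curve taxonomy", {
  # steady plateau -> D with an E-extraction window of ~300 points
  simD <- simulate_flow(trace_spec(seed = 1))
  stD <- classify_trace(simD$trace)
  expect_true(stD$steady)
  expect_identical(stD$curve_class, "D")
  expect_equal(diff(stD$steady_window) + 1L,
               steady_window_points(900, 3))
  expect_gte(stD$last_segment_duration_s, 900)
  expect_gt(stD$slope_p_value, 0.001)

  # run truncated before 15 min of plateau -> C, no p-value
  simC <- simulate_flow(trace_spec(duration_s = 840, rise_tau_s = 90,
                                   seed = 2))
  stC <- classify_trace(simC$trace)
  expect_identical(stC$curve_class, "C")
  expect_false(stC$steady)
  expect_true(is.na(stC$slope_p_value))

  # post-peak decline -> B; oscillation -> A
  simB <- simulate_flow(trace_spec(decline_rate = 2e-4, seed = 3))
  expect_identical(classify_trace(simB$trace)$curve_class, "B")
  simA <- simulate_flow(trace_spec(osc_amplitude = 0.15, osc_period_s = 900,
                                   seed = 4))
  stA <- classify_trace(simA$trace)
  expect_identical(stA$curve_class, "A")
  expect_gte(stA$sign_changes, 2L)
})

test_that("classification is invariant to uniform flow rescaling", {
  for (sp in list(trace_spec(seed = 5),
                  trace_spec(decline_rate = 2e-4, seed = 6))) {
    sim <- simulate_flow(sp)
    st1 <- classify_trace(sim$trace)
    scaled <- sim$trace
    scaled$flow <- scaled$flow * 17
    st2 <- classify_trace(scaled)
    expect_identical(st1$curve_class, st2$curve_class)
    expect_equal(st1$slope_p_value, st2$slope_p_value, tolerance = 1e-9)
  }
})
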