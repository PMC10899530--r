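test_that("divide normalization maps the floor window to exactly 1", {
  sched <- tiny_schedule()
  tr <- make_trace(sched$times, rep(4, sched$n_frames))
  norm <- normalize_traces(tr, sched, mode = "divide")
  expect_equal(norm$activity, rep(1, sched$n_frames))
})

test_that("subtract normalization maps the floor window to exactly 0", {
  sched <- tiny_schedule()
  act <- ifelse(sched$times <= sched$meki_time, 2, 1)
  tr <- make_trace(sched$times, act)
  norm <- normalize_traces(tr, sched, mode = "subtract", floor_window = 6)
  expect_equal(norm$activity, act - 1)
})

test_that("per-cell floor mean is exactly 1 after divide on an ensemble", {
  sched <- acquisition_schedule()
  sim <- simulate_trace_ensemble(sim_params(n_cells = 15, noise_sigma = 0),
                                 sched, seed = 3)
  norm <- normalize_traces(sim$traces, sched, mode = "divide")
  fw <- 0.4 * sched$meki_window
  floor_f <- norm$time_min >= sched$end_time - fw
  means <- tapply(norm$activity[floor_f], norm$cell_id[floor_f], mean)
  expect_equal(as.numeric(means), rep(1, length(means)), tolerance = 1e-12)
})

test_that("cells with a non-positive floor are dropped with a warning", {
  sched <- tiny_schedule()
  good <- make_trace(sched$times, rep(2, sched$n_frames), cell_id = 1L)
  bad <- make_trace(sched$times, rep(-1, sched$n_frames), cell_id = 2L)
  tr <- rbind(good, bad)
  expect_warning(norm <- normalize_traces(tr, sched, mode = "divide"), "floor")
  expect_equal(unique(norm$cell_id), 1L)
})

test_that("identical pre and post signals are not called responders", {
  sched <- tiny_schedule()
  tr <- make_trace(sched$times, rep(1.5, sched$n_frames))
  calls <- call_responders(tr, sched)
  expect_false(calls$is_responder)
  expect_equal(calls$p_value, 1)   # zero-variance differences
})

test_that("the paired t-test matches the t-distribution oracle", {
  sched <- tiny_schedule()
  d <- c(1.0, 1.1, 0.9, 1.0, 1.0)
  act <- rep(1, sched$n_frames)
  post_idx <- which(sched$times > 30 & sched$times <= 60)
  act[post_idx] <- 1 + d
  tr <- make_trace(sched$times, act)
  w <- analysis_windows(pre_window = 30, post_window = 30,
                        amplitude_window = 30, auc_window = 60)
  calls <- call_responders(tr, sched, w)
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(5))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = 4)
  expect_equal(calls$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(calls$p_value, p_oracle, tolerance = 1e-12)
  expect_gt(t_oracle, 31)   # ~31.6 with these differences
  expect_true(calls$is_responder)
  expect_equal(calls$direction, "increase")
})

test_that("the increase-only policy rejects significant decreases", {
  sched <- tiny_schedule()
  act <- rep(2, sched$n_frames)
  post_idx <- which(sched$times > 30 & sched$times <= 60)
  act[post_idx] <- 2 - c(1.0, 1.1, 0.9, 1.0, 1.0)
  tr <- make_trace(sched$times, act)
  w <- analysis_windows(pre_window = 30, post_window = 30)
  calls <- call_responders(tr, sched, w)
  expect_false(calls$is_responder)
  w_any <- analysis_windows(pre_window = 30, post_window = 30,
                            direction_policy = "any")
  calls_any <- call_responders(tr, sched, w_any)
  expect_true(calls_any$is_responder)
  expect_equal(calls_any$direction, "decrease")
})

test_that("cells with too few valid frames are flagged indeterminate", {
  sched <- tiny_schedule()
  valid <- sched$times > 30   # no valid pre-treatment frames
  tr <- make_trace(sched$times, rep(1, sched$n_frames), valid = valid)
  calls <- call_responders(tr, sched)
  expect_true(calls$indeterminate)
  expect_false(calls$is_responder)
})

test_that("amplitude features match windowed-maximum oracles", {
  sched <- acquisition_schedule()
  w <- analysis_windows()
  flat <- make_trace(sched$times, rep(1, sched$n_frames))
  expect_equal(max_amplitude(flat, sched, w), 0)
  # step from 1.0 to 2.5 at treatment
  step <- make_trace(sched$times,
                     ifelse(sched$times > sched$treatment_time, 2.5, 1))
  expect_equal(max_amplitude(step, sched, w), 1.5)
  # ramp peaking at 90 min post-treatment: the 1 h window caps the max
  rel <- sched$times - sched$treatment_time
  ramp_act <- 1 + pmax(0, pmin(rel, 90) / 90) * ifelse(rel > 0, 1, 0)
  ramp <- make_trace(sched$times, ramp_act)
  expect_equal(max_amplitude(ramp, sched, w), 60 / 90, tolerance = 1e-12)
})

test_that("AUC matches rectangle and analytic-pulse oracles", {
  sched <- acquisition_schedule()
  w <- analysis_windows()
  flat <- make_trace(sched$times, rep(1.3, sched$n_frames))
  expect_equal(as.numeric(auc_12h(flat, sched, w)), 0)
  # constant elevation of 1 above baseline across the full 12 h window
  elev <- make_trace(sched$times,
                     1 + as.numeric(sched$times > sched$treatment_time))
  a <- auc_12h(elev, sched, w)
  # trapezoid at the step loses half a frame interval relative to 12 h
  expect_equal(as.numeric(a), 12 - 0.05, tolerance = 1e-9)
  # class-1 pulse, A = 1, tau_r = 30 min: compare to numeric quadrature
  tau <- 30
  act <- 1 + response_shape(sched$times - sched$treatment_time, 1, tau, 120)
  pulse <- make_trace(sched$times, act)
  a1 <- as.numeric(auc_12h(pulse, sched, w))
  oracle <- stats::integrate(function(t) (t / tau) * exp(1 - t / tau),
                             0, 720)$value / 60
  expect_lt(abs(a1 - oracle) / oracle, 0.01)
})

test_that("AUC is linear in amplitude for a fixed noiseless shape", {
  sched <- acquisition_schedule()
  w <- analysis_windows()
  shape <- response_shape(sched$times - sched$treatment_time, 2, 12, 300)
  a1 <- as.numeric(auc_12h(make_trace(sched$times, 1 + shape), sched, w))
  a2 <- as.numeric(auc_12h(make_trace(sched$times, 1 + 2 * shape), sched, w))
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
})

test_that("invalid frames inside the AUC window are interpolated and flagged", {
  sched <- acquisition_schedule()
  w <- analysis_windows()
  act <- 1 + as.numeric(sched$times > sched$treatment_time)
  in_win <- sched$times > sched$treatment_time + 60 &
    sched$times <= sched$treatment_time + 420
  valid <- !in_win   # 50% of the window invalid
  tr <- make_trace(sched$times, act, valid = valid)
  a <- auc_12h(tr, sched, w)
  expect_true(attr(a, "low_confidence"))
  expect_equal(as.numeric(a), 12 - 0.05, tolerance = 1e-9)
})

test_that("responder fraction and Wilson interval behave correctly", {
  calls <- tibble::tibble(is_responder = rep(c(TRUE, FALSE), c(600, 400)),
                          indeterminate = FALSE)
  fr <- responder_fraction(calls)
  expect_equal(fr$fraction, 0.6)
  # cross-check Wilson score interval against prop.test without continuity
  pt <- stats::prop.test(600, 1000, correct = FALSE)
  expect_equal(fr$ci_low, pt$conf.int[1], tolerance = 1e-9)
  expect_equal(fr$ci_high, pt$conf.int[2], tolerance = 1e-9)
  expect_true(fr$ci_low <= fr$fraction && fr$fraction <= fr$ci_high)
  none <- tibble::tibble(is_responder = rep(FALSE, 100), indeterminate = FALSE)
  expect_equal(responder_fraction(none)$fraction, 0)
  expect_error(responder_fraction(tibble::tibble(is_responder = logical(0),
                                                 indeterminate = logical(0))),
               "determinate")
})

test_that("simulated ensembles recover the true responder fraction", {
  sched <- acquisition_schedule()
  p <- sim_params(response_class = 3, responder_pmax = 0.8, responder_ec50 = 10,
                  responder_hill = 1, dose = 30, n_cells = 1000)
  sim <- simulate_trace_ensemble(p, sched, seed = 21)
  norm <- normalize_traces(sim$traces, sched)
  calls <- call_responders(norm, sched)
  fr <- responder_fraction(calls)
  expect_lt(abs(fr$fraction - 0.6), 0.05)
})

test_that("ensemble classification recovers the generating class", {
  sched <- acquisition_schedule()
  for (cls in 1:3) {
    p <- sim_params(response_class = cls, responder_pmax = 1, n_cells = 25)
    sim <- simulate_trace_ensemble(p, sched, seed = 30 + cls)
    norm <- normalize_traces(sim$traces, sched)
    got <- classify_response_class(norm, sched)
    expect_equal(got$response_class, cls)
  }
  expect_error(
    classify_response_class(make_trace(sched$times, rep(1, sched$n_frames)),
                            sched),
    "20")
})
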