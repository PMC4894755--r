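test_that("presets validate their invariants", {
  expect_error(turn_preset(p_ret_act = 0.5, p_pro_act = 0.5, p_none = 0.1),
               "must equal 1")
  expect_error(turn_preset(sd_period = -0.1), "sd_period")
  expect_error(turn_preset(mean_period = 0), "mean_period")
  expect_error(turn_preset(duty_fraction = 1), "duty_fraction")
  expect_error(get_preset("no-such-preset"), "unknown preset")
  lib <- preset_library()
  expect_setequal(names(lib),
                  c("fl-inside", "fl-outside", "ml-inside", "ml-outside",
                    "pilo-quiet", "pilo-stepping", "load-inside", "load-outside"))
  # JSON round trip preserves every field
  path <- tempfile(fileext = ".json")
  write_presets(lib, path)
  back <- read_presets(path)
  expect_equal(lapply(back, unclass), lapply(lib, unclass))
})

test_that("make_steps draws truncated-normal periods with the preset moments", {
  # degenerate variance: exact arithmetic spacing
  p0 <- turn_preset(mean_period = 1, sd_period = 0)
  st <- make_steps(p0, 3, seed = 1, t0 = 2)
  expect_equal(events_of(st, "touchdown"), c(2, 3, 4))
  expect_equal(events_of(st, "liftoff"), c(2, 3, 4) + p0$duty_fraction)

  # moment recovery at n = 2000 within 3 standard errors
  p <- get_preset("fl-inside")
  st <- make_steps(p, 2000, seed = 42)
  per <- diff(events_of(st, "touchdown"))
  n <- length(per)
  expect_lt(abs(mean(per) - 0.83), 3 * 0.21 / sqrt(n))
  expect_lt(abs(sd(per) - 0.21), 3 * 0.21 / sqrt(2 * n))
  # truncation floor respected
  expect_true(all(per >= 0.1 * 0.83))

  # determinism and errors
  expect_identical(make_steps(p, 50, seed = 7), make_steps(p, 50, seed = 7))
  expect_error(make_steps(p, 0), "positive count")
})

test_that("inside-mode nerve activity is phase-locked at the preset peaks", {
  p <- get_preset("fl-inside")
  st <- make_steps(p, 301, seed = 7)
  cy <- segment_steps(st)
  nv <- make_nerve_activity(st, "inside", p, seed = 8)
  ph_pro <- na.omit(phase_at(events_of(nv$protractor, "spike"), cy))
  ph_ret <- na.omit(phase_at(events_of(nv$retractor, "spike"), cy))
  mv_pro <- mean_vector(ph_pro)
  mv_ret <- mean_vector(ph_ret)
  dd <- function(a, b) min(abs(a - b), 360 - abs(a - b))
  expect_lt(dd(mv_pro$mean_deg, 270), 5)
  expect_lt(dd(mv_ret$mean_deg, 90), 5)
  # concentration near the von Mises Bessel ratio for kappa = 4
  expect_lt(abs(mv_pro$R - besselI(4, 1) / besselI(4, 0)), 0.05)
  expect_error(make_nerve_activity(st, "sideways", p), "arg")
})

test_that("outside-mode activity is tonic: uniform phases, retractor-biased", {
  p <- get_preset("fl-inside")
  st <- make_steps(p, 201, seed = 9)
  cy <- segment_steps(st)
  nv <- make_nerve_activity(st, "outside", p, seed = 10)
  ph <- na.omit(phase_at(events_of(nv$retractor, "spike"), cy))
  n <- length(ph)
  expect_gt(n, 1000)
  expect_lt(mean_vector(ph)$R, 0.1)  # uniform null: E[R] ~ sqrt(pi / (4 n))
  n_ret <- nrow(nv$retractor); n_pro <- nrow(nv$protractor)
  expect_gt(n_ret / n_pro, 2)  # 3:1 Poisson bias
})

test_that("pilocarpine rhythm frequencies follow the regime intervals", {
  r <- make_pilocarpine_rhythm(60, list(), "pilo-quiet", seed = 5)
  f <- rhythm_frequency(detect_bursts(r$protractor))
  expect_lt(abs(f - 0.27), 0.04)

  r2 <- make_pilocarpine_rhythm(90, list(c(30, 60)), "pilo-stepping", seed = 6)
  b2 <- detect_bursts(r2$protractor)
  expect_lt(abs(rhythm_frequency(b2, c(30, 60)) - 1.16), 0.12)
  expect_lt(abs(rhythm_frequency(b2, c(0, 30)) - 0.27), 0.06)

  # anti-phase construction: correlation dip at lag 0, peak near half cycle
  pro <- spikes_to_rate(r$protractor, 0, 60)
  ret <- spikes_to_rate(r$retractor, 0, 60)
  xc <- cross_correlate(pro, ret, max_lag = 2.5)
  r0 <- xc$r[which.min(abs(xc$lag))]
  expect_lt(r0, 0)
  half <- 0.5 / 0.27
  near_half <- abs(abs(xc$lag) - half) < 0.6
  expect_gt(max(xc$r[near_half]), r0 + 0.5)

  expect_error(make_pilocarpine_rhythm(60, list(c(10, 30), c(20, 40)),
                                       "pilo-quiet"), "overlap")
  expect_error(make_pilocarpine_rhythm(60, list(c(-1, 30)), "pilo-quiet"),
               "within")
})

test_that("load trials carry ground truth matching the preset probabilities", {
  fx <- small_load_trial(n_stimuli = 400, seed = 21)
  truth <- fx$trial$truth[!fx$trial$truth$is_control, ]
  p_none <- 0.188
  se <- sqrt(p_none * (1 - p_none) / nrow(truth))
  expect_lt(abs(mean(truth$klass == "NONE") - p_none), 3 * se)
  # no-response stimuli concentrate at the preset phase
  mv <- mean_vector(truth$phase[truth$klass == "NONE"])
  expect_lt(min(abs(mv$mean_cycle - 0.89), 1 - abs(mv$mean_cycle - 0.89)), 0.03)
  # all-retractor preset
  st <- make_steps("load-outside", 83, seed = 22)
  tr <- make_load_trial(st, "load-outside", n_stimuli = 40, seed = 23)
  expect_true(all(tr$truth$klass == "RET_ACT"))
  # determinism
  tr2 <- make_load_trial(st, "load-outside", n_stimuli = 40, seed = 23)
  expect_identical(tr, tr2)
  expect_error(make_load_trial(st, "load-outside", n_stimuli = 200, seed = 1),
               "at least")
})

test_that("EMG generator embeds the stated crosstalk and is seed-deterministic", {
  p <- get_preset("fl-inside", list(noise_sd = 0, crosstalk_coeff = 0))
  st <- make_steps(p, 30, seed = 31)
  emg <- make_emg(st, p, seed = 32)
  expect_equal(emg$protractor$values, emg$truth_protractor$values)

  p3 <- get_preset("fl-inside", list(noise_sd = 0, crosstalk_coeff = 0.3))
  emg3 <- make_emg(st, p3, seed = 32)
  # at the antagonist peak the own envelope vanishes, leaving 0.3x leakage
  cy <- segment_steps(st)
  tt <- trace_times(emg3$protractor)
  ph <- phase_at(tt, cy)
  at_ret_peak <- !is.na(ph) & abs(ph - 90 / 360) < 0.02
  leak <- mean(emg3$protractor$values[at_ret_peak]) /
    mean(emg3$truth_retractor$values[at_ret_peak])
  expect_lt(abs(leak - 0.3), 0.02)

  pd <- get_preset("fl-inside")
  expect_identical(make_emg(st, pd, seed = 1), make_emg(st, pd, seed = 1))
  expect_error(make_emg(st, get_preset("fl-inside", list(fs = 500))), "fs")
})

test_that("trace and event file round trips preserve data", {
  tr <- sampled_trace(rnorm(50), fs = 250, t0 = -1.5, label = "ret", units = "mV")
  path <- tempfile()
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$values, tr$values)
  expect_equal(back$fs, tr$fs)
  expect_equal(back$t0, tr$t0)
  expect_equal(back$label, tr$label)

  ev <- event_series(c(0.5, 1.2, 2.0), c("touchdown", "liftoff", "touchdown"), "FL")
  path2 <- tempfile()
  write_events(ev, path2)
  expect_equal(read_events(path2), ev)
})
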