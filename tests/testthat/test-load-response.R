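test_that("PSTH bins are aligned at lag zero and conserve counts", {
  # events 5 ms after each stimulus, 10 ms bins: single nonzero bin [0, 10) ms
  stims <- c(1, 2, 3)
  h <- psth(stims + 0.005, stims, pre = 0.05, post = 0.05, bin = 0.01)
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[h$lag_lo == 0], 3)
  expect_true(0 %in% h$lag_lo)
  # empty events: all-zero histogram
  h0 <- psth(numeric(), stims, 0.05, 0.05, 0.01)
  expect_equal(sum(h0$count), 0)
  # homogeneous Poisson: each bin ~ lambda * bin * n_stims
  set.seed(21)
  lambda <- 200
  ev <- cumsum(rexp(4000, lambda))
  stims2 <- seq(2, 18, by = 0.5)
  h2 <- psth(ev, stims2, pre = 0.1, post = 0.1, bin = 0.02)
  expected <- lambda * 0.02 * length(stims2)
  expect_true(all(abs(h2$count - expected) < 3 * sqrt(expected)))
  # conservation: total equals events falling in all windows
  n_in <- sum(vapply(stims2, function(s)
    sum(ev >= s - 0.1 & ev < s + 0.1), 0))
  expect_equal(sum(h2$count), n_in)
  expect_error(psth(ev, numeric()), "at least one")
})

test_that("response magnitude is the windowed maximum over the control mean", {
  fs <- 1000
  env <- sampled_trace(c(rep(1, 500), rep(2, 200), rep(1, 300)), fs, t0 = 0)
  # window max equals the control mean -> 1.0
  expect_equal(response_magnitude(env, 0.1, control_max_mean = 1), 1)
  # post-stim max of 2 against control 1 -> 2 (linearity of max)
  expect_equal(response_magnitude(env, 0.5, control_max_mean = 1), 2)
  # zero envelope after the stimulus -> 0
  env0 <- sampled_trace(rep(0, 1000), fs)
  expect_equal(response_magnitude(env0, 0.2, control_max_mean = 1), 0)
  expect_error(response_magnitude(env, 0.95, 1), "exceeds")
  expect_error(response_magnitude(env, 0.1, 0), "> 0")
  # control helper averages per-stimulus window maxima
  expect_equal(control_max_mean(env, c(0.1, 0.5)), mean(c(1, 2)))
})

test_that("Michelson contrast follows (post - pre)/(post + pre)", {
  fs <- 100
  mk <- function(pre_val, post_val)
    sampled_trace(c(rep(pre_val, 100), rep(post_val, 100)), fs, t0 = 0)
  ct <- function(a, b) michelson_contrast(mk(a, b), stim_time = 1, w = 0.1)
  expect_equal(ct(2, 2), 0)
  expect_equal(ct(0, 5), 1)
  expect_equal(ct(3, 1), -0.5)
  # hand-computed coarse windows: pre mean 3, post mean 1
  env3 <- sampled_trace(c(3, 3, 1, 1), fs = 1, t0 = 0)
  expect_equal(michelson_contrast(env3, 1.5, w = 1), (1 - 3) / (1 + 3))
  # 0/0 defined as 0 (silent trace)
  expect_equal(ct(0, 0), 0)
  # antisymmetry under swapping pre/post
  set.seed(5)
  for (i in 1:25) {
    a <- runif(1); b <- runif(1)
    expect_equal(ct(a, b), -ct(b, a), tolerance = 1e-12)
  }
  expect_error(ct(-1, 2), "rectify")
  expect_error(michelson_contrast(mk(1, 1), 0.05, w = 0.1), "exceed")
})

test_that("contrast is always bounded in [-1, 1] (fuzz)", {
  set.seed(77)
  for (i in 1:10000) {
    v <- abs(rnorm(9, sd = runif(1, 0.01, 10)))
    env <- sampled_trace(v, fs = 4, t0 = 0)
    cc <- michelson_contrast(env, 1, w = 1)
    expect_true(cc >= -1 && cc <= 1)
  }
})

test_that("response classification separates the three transient types", {
  fs <- 1000
  flat <- function() rep(0.5, 2000)
  step_up <- function(at) { v <- flat(); v[at:(at + 150)] <- 5; v }
  step_down <- function(at) { v <- flat(); v[at:(at + 150)] <- 0; v }
  s <- 1.0  # stimulus at sample 1000
  # strong retractor step-up, flat protractor -> RET_ACT
  cl <- classify_response(sampled_trace(flat(), fs), sampled_trace(step_up(1000), fs), s)
  expect_equal(cl$klass, "RET_ACT")
  # retractor step-down + protractor step-up -> PRO_ACT
  cl2 <- classify_response(sampled_trace(step_up(1000), fs),
                           sampled_trace(step_down(1000), fs), s)
  expect_equal(cl2$klass, "PRO_ACT")
  # no transient -> NONE
  cl3 <- classify_response(sampled_trace(flat(), fs), sampled_trace(flat(), fs), s)
  expect_equal(cl3$klass, "NONE")
})

test_that("classification recovers generator ground truth", {
  fx <- small_load_trial(n_stimuli = 80, seed = 41)
  truth <- fx$trial$truth[!fx$trial$truth$is_control, ]
  sc <- score_responses(fx$pro, fx$ret, truth$time, steps = fx$cycles,
                        control_times = fx$trial$truth$time[fx$trial$truth$is_control])
  expect_gte(mean(sc$klass == truth$klass), 0.95)
  # control-normalized magnitudes: activations near 1, non-responses well below
  expect_equal(median(sc$magnitude[sc$klass == "RET_ACT"]), 1, tolerance = 0.1)
  expect_lt(median(sc$magnitude[sc$klass == "NONE"]), 0.5)
})

test_that("phase analysis of a response class delegates to circular stats", {
  cy <- segment_steps(0:10, 0:9 + 0.6)
  resp <- data.frame(stim_time = (0:9) + 0.89,
                     klass = rep("NONE", 10))
  pv <- response_vs_phase(resp, cy, klass = "NONE")
  expect_false(pv$flagged)
  expect_equal(pv$summary$mean_cycle, 0.89, tolerance = 1e-9)
  expect_equal(pv$summary$R, 1, tolerance = 1e-12)
  # too few responses of the class: flagged, no test
  pv2 <- response_vs_phase(resp[1:3, ], cy, klass = "NONE")
  expect_true(pv2$flagged)
  expect_null(pv2$summary)
  # phase-independent magnitudes show no circular-linear association:
  # compare a rank correlation of (cos phase, magnitude) to a permutation null
  set.seed(8)
  ph <- runif(200)
  mag <- rlnorm(200)
  obs <- abs(cor(cos(2 * pi * ph), mag))
  null <- replicate(1000, abs(cor(cos(2 * pi * sample(ph)), mag)))
  expect_lt(obs, quantile(null, 0.99))
})
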