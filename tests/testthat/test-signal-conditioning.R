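test_that("rectification is elementwise absolute value and idempotent", {
  tr <- sampled_trace(c(-2, 0, 3), fs = 10)
  expect_equal(rectify(tr)$values, c(2, 0, 3))
  x <- rnorm(200)
  tr2 <- sampled_trace(x, fs = 100, label = "emg", units = "mV")
  r1 <- rectify(tr2)
  expect_equal(r1$values, abs(x))
  expect_equal(rectify(r1), r1)
  expect_equal(r1$label, "emg")  # metadata preserved
})

test_that("boxcar smoothing matches its window definition", {
  # constant is a fixed point everywhere, including edges
  cst <- sampled_trace(rep(3.7, 40), fs = 100)
  expect_equal(smooth_boxcar(cst, 0.05)$values, rep(3.7, 40))
  # T = 0 is the identity
  tr <- sampled_trace(rnorm(50), fs = 100)
  expect_equal(smooth_boxcar(tr, 0)$values, tr$values)
  # unit impulse at fs = 100, T = 0.05: plateau of 11 samples of 1/11
  imp <- impulse_trace(n = 101, at = 51, fs = 100)
  sm <- smooth_boxcar(imp, 0.05)$values
  expect_equal(sm[46:56], rep(1 / 11, 11))
  expect_equal(sm[c(45, 57)], c(0, 0))
  expect_error(smooth_boxcar(tr, -0.01), ">= 0")
})

test_that("smoothing matches a direct convolution oracle in the interior", {
  set.seed(1)
  x <- rnorm(300)
  tr <- sampled_trace(x, fs = 200)
  # boxcar T = 0.05 -> 21-point window
  k <- rep(1 / 21, 21)
  oracle <- as.numeric(stats::filter(x, k, sides = 2))
  got <- smooth_boxcar(tr, 0.05)$values
  interior <- 11:290
  expect_lt(max(abs(got[interior] - oracle[interior])) /
              max(abs(oracle[interior])), 1e-9)
  # gaussian width 0.1 -> support +/-0.05 s, sigma 0.025 s
  kg <- dnorm((-10:10) / 200, sd = 0.025); kg <- kg / sum(kg)
  og <- as.numeric(stats::filter(x, kg, sides = 2))
  gg <- smooth_gaussian(tr, 0.1)$values
  expect_lt(max(abs(gg[interior] - og[interior])) /
              max(abs(og[interior])), 1e-9)
  # linearity + shift equivariance away from edges
  y <- rnorm(300)
  s_sum <- smooth_boxcar(sampled_trace(x + 2 * y, fs = 200), 0.05)$values
  s_parts <- smooth_boxcar(tr, 0.05)$values +
    2 * smooth_boxcar(sampled_trace(y, fs = 200), 0.05)$values
  expect_equal(s_sum, s_parts, tolerance = 1e-12)
  shifted <- sampled_trace(c(rep(0, 5), x[1:295]), fs = 200)
  s_shift <- smooth_boxcar(shifted, 0.05)$values
  expect_equal(s_shift[16:290], smooth_boxcar(tr, 0.05)$values[11:285],
               tolerance = 1e-12)
})

test_that("gaussian kernel is renormalized and peaked at its centre", {
  cst <- sampled_trace(rep(-1.2, 60), fs = 100)
  expect_equal(smooth_gaussian(cst, 0.1)$values, rep(-1.2, 60))
  imp <- impulse_trace(n = 101, at = 51, fs = 100)
  sm <- smooth_gaussian(imp, 0.1)$values
  expect_equal(sum(sm), 1, tolerance = 1e-12)  # interior impulse: mass conserved
  k <- dnorm((-5:5) / 100, sd = 0.025); k <- k / sum(k)
  expect_equal(sm[51], k[6])  # peak equals the kernel centre weight
  expect_equal(which.max(sm), 51)
  expect_error(smooth_gaussian(imp, 0), "> 0")
})

test_that("crosstalk subtraction follows the capped-rescale rule", {
  fs <- 100
  ag <- sampled_trace(c(0, 1, 0.4), fs)
  # antagonist chosen so its [0, 0.5] rescale is exactly [0, 0.25, 0.5]
  an <- sampled_trace(c(2, 3, 4), fs)
  out <- remove_crosstalk(ag, an, cap = 0.5)
  expect_equal(out$values, c(0, 0.75, 0))
  # constant antagonist rescales to zero: agonist (normalized) unchanged
  an_c <- sampled_trace(rep(5, 3), fs)
  expect_equal(remove_crosstalk(ag, an_c)$values, c(0, 1, 0.4))
  # zero agonist stays zero
  ag0 <- sampled_trace(rep(0, 3), fs)
  expect_equal(remove_crosstalk(ag0, an)$values, rep(0, 3))
  expect_error(remove_crosstalk(ag, sampled_trace(1:4, fs)), "aligned")
})

test_that("per-step normalization maps segments onto [0, 1]", {
  tr <- sampled_trace(c(2, 4, 6), fs = 1, t0 = 0)
  step <- list(touchdown = 0, next_touchdown = 3)
  expect_equal(normalize_per_step(tr, step)$values, c(0, 0.5, 1))
  cst <- sampled_trace(rep(2, 5), fs = 1)
  expect_equal(normalize_per_step(cst, list(touchdown = 0, next_touchdown = 5))$values,
               rep(0, 5))
  # property: min 0, max 1 for any non-constant segment
  set.seed(4)
  for (i in 1:20) {
    v <- rnorm(30, sd = runif(1, 0.1, 10))
    out <- normalize_per_step(sampled_trace(v, fs = 10),
                              list(touchdown = 0, next_touchdown = 3))
    expect_equal(range(out$values), c(0, 1))
  }
  expect_error(normalize_per_step(tr, list(touchdown = 5, next_touchdown = 6)),
               "no samples")
})

test_that("contact events come from threshold crossing and steepest slope", {
  # trapezoidal pulse: known linear-ramp crossing
  fs <- 1000
  st <- make_steps(turn_preset(mean_period = 1, sd_period = 0.1), 20, seed = 2)
  ct <- make_contact_trace(st, fs = fs)
  ev <- detect_contact_events(ct, 0.5)
  td_true <- events_of(st, "touchdown"); td_det <- events_of(ev, "touchdown")
  lo_true <- events_of(st, "liftoff"); lo_det <- events_of(ev, "liftoff")
  expect_equal(length(td_det), length(td_true))
  expect_lt(max(abs(td_det - td_true)), 1 / fs)   # sub-sample interpolation
  expect_equal(length(lo_det), length(lo_true))
  expect_lt(max(abs(lo_det - lo_true)), 1.5 / fs) # steepest ascending slope
  # alternation: touchdown, liftoff, touchdown, ...
  expect_true(all(ev$kind == rep(c("touchdown", "liftoff"),
                                 length.out = nrow(ev))))
  # flat trace: empty series, not an error
  expect_equal(nrow(detect_contact_events(sampled_trace(rep(1, 100), fs), 0.5)), 0)
  # tie for steepest slope resolves to the earliest sample
  x <- c(1, 1, 0.2, 0, 0, 0.5, 1, 1)  # two equal ascending diffs of 0.5
  ev2 <- detect_contact_events(sampled_trace(x, fs = 1, t0 = 0), 0.5)
  expect_equal(events_of(ev2, "liftoff"), 4)
})

test_that("spike detection finds one event per excursion with a dead time", {
  fs <- 1000
  v <- numeric(300)
  v[100 + 0:4] <- c(0.5, 1.5, 2, 1.5, 0.5)
  v[200 + 0:4] <- c(0.5, 1.5, 2, 1.5, 0.5)
  tr <- sampled_trace(v, fs)
  ev <- detect_spikes(tr, 1)
  expect_equal(events_of(ev, "spike"), c(102, 202) / fs - 1 / fs + 0)
  # all sub-threshold: empty
  expect_equal(nrow(detect_spikes(sampled_trace(rep(0.1, 50), fs), 1)), 0)
  # double crossing within the dead time merges into one event
  v2 <- numeric(100)
  v2[50] <- 2; v2[51] <- 0.5; v2[52] <- 1.8  # dip below threshold for 1 ms
  ev2 <- detect_spikes(sampled_trace(v2, fs), 1, dead_time = 0.003)
  expect_equal(nrow(ev2), 1)
  ev3 <- detect_spikes(sampled_trace(v2, fs), 1, dead_time = 0.0005)
  expect_equal(nrow(ev3), 2)
})
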