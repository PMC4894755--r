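# Synthetic-data generator: step trains, phase-locked spike trains,
# load-stimulus trials, EMG envelopes with crosstalk, and slow alternating
# rhythms, all with known ground truth for parameter-recovery testing.

# run expr under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# normal draws truncated below at `lower` (rejection; exact for our use)
rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

# von Mises sampler (Best & Fisher rejection scheme); mu in radians
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3L] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

resolve_preset <- function(preset) {
  if (is.character(preset)) preset <- get_preset(preset)
  stopifnot(inherits(preset, "turn_preset"))
  preset
}

pick_seed <- function(seed, preset) {
  if (is.null(seed) || is.na(seed)) preset$seed else seed
}

#' Generate a synthetic step train
#'
#' Produces `n_steps` touchdowns with periods drawn from a Normal
#' distribution (mean `mean_period`, SD `sd_period`) truncated below at
#' 0.1 x `mean_period` so periods stay positive; each lift-off falls at
#' `touchdown + duty_fraction * period`.
#'
#' @param preset A [turn_preset()] or the name of a shipped preset.
#' @param n_steps Number of touchdowns to generate (>= 1). `n_steps`
#'   touchdowns delimit `n_steps - 1` complete cycles.
#' @param seed Integer seed; identical preset + seed gives identical output.
#' @param t0 Time of the first touchdown in seconds.
#' @return An [event_series()] containing `touchdown` and `liftoff` events
#'   labelled with the preset name.
#' @examples
#' st <- make_steps("fl-inside", n_steps = 10, seed = 1)
#' head(events_of(st, "touchdown"))
#' @export
make_steps <- function(preset, n_steps, seed = NULL, t0 = 0) {
  preset <- resolve_preset(preset)
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("`n_steps` must be a positive count")
  n_steps <- as.integer(n_steps)
  seed <- pick_seed(seed, preset)
  with_seed(seed, {
    periods <- rtrunc_norm(n_steps, preset$mean_period, preset$sd_period,
                           0.1 * preset$mean_period)
    td <- t0 + c(0, cumsum(periods))[seq_len(n_steps)]
    lo <- td + preset$duty_fraction * periods
    event_series(c(td, lo),
                 c(rep("touchdown", n_steps), rep("liftoff", n_steps)),
                 preset$name)
  })
}

#' Synthetic tarsal-contact trace for a step train
#'
#' Emulates the electrical tarsal-contact signal: high during swing, low
#' during stance. The contact onset is a linear fall centred on the
#' touchdown (so a mid-amplitude threshold crossing recovers the touchdown
#' exactly), and the release is a linear rise starting at lift-off, whose
#' steepest ascending slope marks the lift-off.
#'
#' @param steps An [event_series()] with touchdowns and lift-offs.
#' @param fs Sampling rate in Hz.
#' @param fall_time,rise_time Durations of the contact/release transitions (s).
#' @param high,low Signal levels during swing and stance.
#' @param noise_sd Gaussian noise SD added to the trace.
#' @param seed Seed for the noise.
#' @return A [sampled_trace()].
#' @export
make_contact_trace <- function(steps, fs = 1000, fall_time = 0.004,
                               rise_time = 0.01, high = 1, low = 0,
                               noise_sd = 0, seed = NULL) {
  td <- as_event_times(steps, "touchdown")
  lo <- as_event_times(steps, "liftoff")
  if (!length(td)) stop("`steps` contains no touchdowns")
  t_start <- min(td) - 0.25
  t_end <- max(c(td, lo)) + 0.25
  kx <- t_start; ky <- high
  for (k in seq_along(td)) {
    kx <- c(kx, td[k] - fall_time / 2, td[k] + fall_time / 2)
    ky <- c(ky, high, low)
    lk <- lo[lo > td[k]][1L]
    if (!is.na(lk)) {
      kx <- c(kx, lk, lk + rise_time)
      ky <- c(ky, low, high)
    }
  }
  kx <- c(kx, t_end); ky <- c(ky, ky[length(ky)])
  tt <- seq(t_start, t_end, by = 1 / fs)
  vals <- stats::approx(kx, ky, xout = tt, rule = 2, ties = "ordered")$y
  if (noise_sd > 0)
    vals <- with_seed(seed, vals + stats::rnorm(length(vals), 0, noise_sd))
  sampled_trace(vals, fs = fs, t0 = t_start, label = "tarsal_contact")
}

#' Generate phase-locked or tonic motoneuron spike trains
#'
#' In `inside` mode, protractor and retractor spike trains are inhomogeneous
#' Poisson processes whose rate is modulated over the step cycle by a von
#' Mises profile centred on the preset's peak phases (protractor near 270
#' degrees, retractor near 90 degrees), generated by Poisson thinning: the
#' rate at cycle phase theta is
#' `base_rate * exp(kappa * cos(theta - mu)) / I0(kappa)`, whose cycle
#' average is `base_rate`. In `outside` mode both pools fire tonically
#' (homogeneous Poisson) with the retractor biased over the protractor by
#' `outside_bias`.
#'
#' @inheritParams make_steps
#' @param steps Step train ([event_series()]) to lock to; non-empty.
#' @param mode `"inside"` (alternating, phase-locked) or `"outside"` (tonic).
#' @param outside_bias Retractor:protractor rate ratio in outside mode.
#' @return A list with spike [event_series()] elements `protractor` and
#'   `retractor`.
#' @export
make_nerve_activity <- function(steps, mode = c("inside", "outside"),
                                preset, seed = NULL, outside_bias = 3) {
  mode <- match.arg(mode)
  preset <- resolve_preset(preset)
  cycles <- segment_steps(steps)
  if (!nrow(cycles)) stop("`steps` yields no complete step cycles")
  t0 <- min(cycles$touchdown); t1 <- max(cycles$next_touchdown)
  seed <- pick_seed(seed, preset)
  with_seed(seed, {
    if (mode == "inside") {
      gen <- function(peak_deg) {
        lmax <- preset$base_rate * exp(preset$kappa) / besselI(preset$kappa, 0)
        n_cand <- stats::rpois(1L, lmax * (t1 - t0))
        cand <- sort(stats::runif(n_cand, t0, t1))
        ph <- phase_at(cand, cycles)
        lam <- ifelse(is.na(ph), 0,
                      preset$base_rate *
                        exp(preset$kappa * cos(2 * pi * (ph - peak_deg / 360))) /
                        besselI(preset$kappa, 0))
        cand[stats::runif(n_cand) < lam / lmax]
      }
      pro <- gen(preset$pro_peak_deg)
      ret <- gen(preset$ret_peak_deg)
    } else {
      gen_hom <- function(rate) {
        n <- stats::rpois(1L, rate * (t1 - t0))
        sort(stats::runif(n, t0, t1))
      }
      ret <- gen_hom(preset$base_rate)
      pro <- gen_hom(preset$base_rate / outside_bias)
    }
    list(protractor = event_series(pro, "spike", "protractor"),
         retractor = event_series(ret, "spike", "retractor"))
  })
}

#' Generate a slow alternating burst rhythm
#'
#' Emulates the pharmacologically induced slow rhythm of antagonist
#' motoneuron pools: alternating protractor/retractor bursts whose cycle
#' frequency is `rhythm_freq_quiet` outside the supplied stepping intervals
#' and `rhythm_freq_step` inside them. Cycle periods carry a small
#' multiplicative jitter (`period_cv`), and an ongoing cycle is truncated at
#' an interval boundary so each regime's frequency is expressed immediately.
#' Protractor bursts occupy the first `burst_fraction` of each cycle and
#' retractor bursts the same fraction starting at half cycle (anti-phase).
#'
#' @inheritParams make_steps
#' @param duration Total record duration in seconds (> 0).
#' @param stepping_intervals List of `c(start, end)` pairs (seconds) during
#'   which the fast regime applies; must not overlap.
#' @param intra_rate Within-burst firing rate in spikes/s.
#' @param burst_fraction Fraction of the cycle occupied by each burst.
#' @param period_cv Coefficient of variation of the cycle period.
#' @return A list with spike [event_series()] elements `protractor` and
#'   `retractor`.
#' @export
make_pilocarpine_rhythm <- function(duration, stepping_intervals = list(),
                                    preset, seed = NULL, intra_rate = 30,
                                    burst_fraction = 0.35, period_cv = 0.05) {
  preset <- resolve_preset(preset)
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  iv <- lapply(stepping_intervals, function(x) {
    x <- as.numeric(x)
    if (length(x) != 2L || x[1L] >= x[2L]) stop("intervals must be (start, end) with start < end")
    if (x[1L] < 0 || x[2L] > duration) stop("intervals must lie within [0, duration]")
    x
  })
  if (length(iv) > 1L) {
    o <- order(vapply(iv, `[`, 0, 1L)); iv <- iv[o]
    starts <- vapply(iv, `[`, 0, 1L); ends <- vapply(iv, `[`, 0, 2L)
    if (any(starts[-1L] < ends[-length(ends)])) stop("stepping intervals overlap")
  }
  in_stepping <- function(t)
    any(vapply(iv, function(x) t >= x[1L] && t < x[2L], TRUE))
  boundaries <- sort(unlist(iv))
  seed <- pick_seed(seed, preset)
  with_seed(seed, {
    pro <- numeric(); ret <- numeric()
    t <- 0
    while (t < duration - 1e-9) {
      f <- if (in_stepping(t)) preset$rhythm_freq_step else preset$rhythm_freq_quiet
      period <- rtrunc_norm(1L, 1 / f, period_cv / f, 0.5 / f)
      nb <- boundaries[boundaries > t + 1e-9]
      if (length(nb) && t + period > nb[1L]) period <- nb[1L] - t
      if (t + period > duration) period <- duration - t
      emit <- function(onset, len) {
        if (len <= 0) return(numeric())
        sp <- seq(onset, onset + len, by = 1 / intra_rate)
        sort(pmax(sp + stats::rnorm(length(sp), 0, 1e-3), 0))
      }
      blen <- burst_fraction * period
      if (blen * intra_rate >= 3) {
        pro <- c(pro, emit(t, blen))
        ret <- c(ret, emit(t + 0.5 * period, min(blen, 0.5 * period - 1e-3)))
      }
      t <- t + period
    }
    list(protractor = event_series(sort(pro), "spike", "protractor"),
         retractor = event_series(sort(ret), "spike", "retractor"))
  })
}

#' Generate a load-stimulus trial with ground truth
#'
#' Places load stimuli on a step train, assigns each stimulus a response
#' class by the preset probabilities (retractor activation, protractor
#' activation with retractor termination, or no response), and synthesizes
#' protractor/retractor activity envelopes containing the corresponding
#' 150 ms rate transients. No-response stimuli are placed preferentially at
#' step-cycle phase `none_phase_mu` (von Mises, concentration `none_kappa`);
#' the other classes are placed uniformly in phase. Stimuli occupy at most
#' one step cycle each, on alternating cycles, so the pre/post analysis
#' windows of neighbouring stimuli cannot overlap. A block of control
#' stimuli (stereotyped retractor activation, as in the quiescent animal)
#' is appended after the walking bout.
#'
#' @inheritParams make_steps
#' @param steps Step train; must supply at least `2 * n_stimuli` complete
#'   cycles.
#' @param n_stimuli Number of within-walking stimuli. Alternatively give
#'   `stim_rate` (stimuli per second of walking).
#' @param stim_rate Optional stimulus rate in Hz, used when `n_stimuli` is
#'   `NULL`.
#' @param n_control Number of control stimuli appended after the bout.
#' @param response_dur Duration of the response transient in seconds.
#' @param amp Amplitude of the activation transient (envelope units above
#'   the 0.5 baseline).
#' @return A list with elements `stimuli` ([event_series()]),
#'   `protractor`/`retractor` ([sampled_trace()] envelopes), and `truth`
#'   (data frame: `time`, `klass`, `phase`, `is_control`).
#' @export
make_load_trial <- function(steps, preset, n_stimuli = NULL, stim_rate = NULL,
                            n_control = 10, response_dur = 0.15, amp = 4.5,
                            seed = NULL) {
  preset <- resolve_preset(preset)
  cycles <- segment_steps(steps)
  if (!nrow(cycles)) stop("`steps` yields no complete step cycles")
  span <- max(cycles$next_touchdown) - min(cycles$touchdown)
  if (is.null(n_stimuli)) {
    if (is.null(stim_rate) || stim_rate <= 0)
      stop("give `n_stimuli`, or a positive `stim_rate`")
    n_stimuli <- max(1L, round(stim_rate * span))
  }
  n_stimuli <- as.integer(n_stimuli)
  eligible <- seq(2L, nrow(cycles), by = 2L)
  if (length(eligible) < n_stimuli)
    stop("need at least ", 2L * n_stimuli, " complete step cycles for ",
         n_stimuli, " stimuli; got ", nrow(cycles))
  seed <- pick_seed(seed, preset)
  with_seed(seed, {
    klass <- sample(c("RET_ACT", "PRO_ACT", "NONE"), n_stimuli, replace = TRUE,
                    prob = c(preset$p_ret_act, preset$p_pro_act, preset$p_none))
    cyc <- sort(sample(eligible, n_stimuli))
    phase <- stats::runif(n_stimuli)
    is_none <- klass == "NONE"
    if (any(is_none))
      phase[is_none] <- rvonmises(sum(is_none), 2 * pi * preset$none_phase_mu,
                                  preset$none_kappa) / (2 * pi)
    stim_t <- cycles$touchdown[cyc] + phase * cycles$period[cyc]
    ctrl_t <- if (n_control > 0)
      max(cycles$next_touchdown) + 2 + seq_len(n_control) - 1 else numeric()
    all_t <- c(stim_t, ctrl_t)
    all_k <- c(klass, rep("RET_ACT", length(ctrl_t)))
    fs <- preset$fs
    t_lo <- min(cycles$touchdown) - 0.5
    t_hi <- max(all_t) + 1
    n <- ceiling((t_hi - t_lo) * fs) + 1L
    base <- 0.5
    ret <- rep(base, n); pro <- rep(base, n)
    idx_of <- function(t) pmin(pmax(1L, 1L + round((t - t_lo) * fs)), n)
    for (k in seq_along(all_t)) {
      i0 <- idx_of(all_t[k]); i1 <- idx_of(all_t[k] + response_dur)
      if (all_k[k] == "RET_ACT") {
        ret[i0:i1] <- ret[i0:i1] + amp
      } else if (all_k[k] == "PRO_ACT") {
        ret[i0:i1] <- 0
        pro[i0:i1] <- pro[i0:i1] + amp
      }
    }
    if (preset$noise_sd > 0) {
      ret <- ret + stats::rnorm(n, 0, preset$noise_sd)
      pro <- pro + stats::rnorm(n, 0, preset$noise_sd)
    }
    truth <- data.frame(time = all_t, klass = all_k,
                        phase = c(phase, rep(NA_real_, length(ctrl_t))),
                        is_control = c(rep(FALSE, n_stimuli),
                                       rep(TRUE, length(ctrl_t))))
    truth <- truth[order(truth$time), ]
    rownames(truth) <- NULL
    list(stimuli = event_series(sort(all_t), "stim_onset", "CS"),
         protractor = sampled_trace(pro, fs = fs, t0 = t_lo, label = "protractor"),
         retractor = sampled_trace(ret, fs = fs, t0 = t_lo, label = "retractor"),
         truth = truth)
  })
}

#' Generate antagonist EMG envelopes with known crosstalk
#'
#' Each muscle's true activity envelope is a phase-locked von Mises bump
#' over the step cycle (protractor and retractor peaks from the preset).
#' The recorded trace is the muscle's own envelope plus
#' `crosstalk_coeff` times the antagonist's envelope plus Gaussian noise,
#' and the true envelopes are returned for recovery tests.
#'
#' @inheritParams make_steps
#' @param steps Step train to lock to.
#' @param env_kappa Concentration of the envelope bumps.
#' @return A list of [sampled_trace()]s: `protractor`, `retractor`
#'   (recorded) and `truth_protractor`, `truth_retractor`.
#' @export
make_emg <- function(steps, preset, seed = NULL, env_kappa = 4) {
  preset <- resolve_preset(preset)
  if (preset$fs < 1000) stop("EMG generation requires fs >= 1000 Hz")
  cycles <- segment_steps(steps)
  if (!nrow(cycles)) stop("`steps` yields no complete step cycles")
  fs <- preset$fs
  t_lo <- min(cycles$touchdown) - 0.2
  t_hi <- max(cycles$next_touchdown) + 0.2
  tt <- seq(t_lo, t_hi, by = 1 / fs)
  ph <- phase_at(tt, cycles)
  bump <- function(peak_deg) {
    out <- numeric(length(tt))
    ok <- !is.na(ph)
    out[ok] <- exp(env_kappa * (cos(2 * pi * (ph[ok] - peak_deg / 360)) - 1))
    out
  }
  env_pro <- bump(preset$pro_peak_deg)
  env_ret <- bump(preset$ret_peak_deg)
  seed <- pick_seed(seed, preset)
  with_seed(seed, {
    nz <- function() if (preset$noise_sd > 0)
      stats::rnorm(length(tt), 0, preset$noise_sd) else 0
    rec_pro <- env_pro + preset$crosstalk_coeff * env_ret + nz()
    rec_ret <- env_ret + preset$crosstalk_coeff * env_pro + nz()
    list(protractor = sampled_trace(rec_pro, fs, t_lo, "protractor"),
         retractor = sampled_trace(rec_ret, fs, t_lo, "retractor"),
         truth_protractor = sampled_trace(env_pro, fs, t_lo, "protractor_truth"),
         truth_retractor = sampled_trace(env_ret, fs, t_lo, "retractor_truth"))
  })
}
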