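# shared fixtures built in code

impulse_trace <- function(n = 101, at = 51, fs = 100) {
  v <- numeric(n); v[at] <- 1
  sampled_trace(v, fs = fs)
}

# a fully conditioned small load trial (shared by load-response tests)
small_load_trial <- function(preset = "load-inside", n_stimuli = 60, seed = 11) {
  st <- make_steps(preset, 2 * n_stimuli + 3, seed = seed)
  trial <- make_load_trial(st, preset, n_stimuli = n_stimuli, seed = seed + 1)
  list(steps = st,
       cycles = segment_steps(st),
       trial = trial,
       pro = smooth_gaussian(rectify(trial$protractor), 0.1),
       ret = smooth_gaussian(rectify(trial$retractor), 0.1))
}
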