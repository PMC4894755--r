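# turncycle

Analysis of body-side-specific motor output in a turning insect:
step-cycle statistics, EMG conditioning, load-stimulus response scoring
and classification, phase coupling via circular statistics, and central
pattern generator (CPG) rhythm analysis — with a seeded synthetic-data
generator so every stage is testable by parameter recovery.

## Who this is for

Motor-control electrophysiologists working with walking-insect
preparations (or any rhythmic motor system) who need to turn raw contact
signals, EMG/nerve traces and stimulus trains into the field's standard
quantities:

* **Step cycles** — stance-anchored segmentation from touchdown/lift-off
  events, periods, stance/swing durations, pause exclusion, and Welch
  comparisons of per-sequence mean periods between conditions.
* **Signal conditioning** — rectification, boxcar smoothing over
  `[t − T, t + T]` (T = 50 ms), a 100 ms running Gaussian average,
  per-step min-max normalization, antagonist crosstalk subtraction
  (antagonist rescaled to [0, 0.5] and subtracted), and event detection:
  touchdown by sub-sample threshold crossing, lift-off by the steepest
  ascending slope, spikes by threshold with a dead time.
* **Load responses** — peristimulus time histograms; response magnitude
  = max envelope in the 150 ms post-stimulus window normalized to
  control stimulations; Michelson contrast
  `(post − pre)/(post + pre) ∈ [−1, 1]` of 100 ms windows; three-way
  classification into retractor activation / protractor activation with
  retractor termination / no response.
* **Circular statistics** — weighted mean resultant vectors
  `R e^{iμ} = Σ w e^{iθ} / Σ w`, the Rayleigh uniformity test
  (`Z = nR²`, second-order series p-value, α = 0.005 for polar
  vectors), and phase histograms on half-open cycle-fraction bins.
* **CPG rhythms** — burst detection by maximal ISI runs, cycle frequency
  as the inverse mean inter-onset interval, paired quiescent-vs-stepping
  frequency tests, and lag-wise Pearson cross-correlation of antagonist
  envelopes (alternation dip at lag 0).

The generator (`make_steps()`, `make_nerve_activity()`,
`make_pilocarpine_rhythm()`, `make_load_trial()`, `make_emg()`,
`make_contact_trace()`) emulates the study conditions with known ground
truth: Gaussian step periods (e.g. 0.83 ± 0.21 s front-leg inside,
1.13 ± 0.28 s middle-leg outside), von Mises phase-locked spiking peaking
at 270°/90° of the step cycle, a slow rhythm at 0.27 Hz speeding to
1.16 Hz during stepping, and stochastic load responses with an 18.8 %
no-response class concentrated at phase 0.89.

## Worked example

```r
library(turncycle)
run <- run_experiment("inside-walk", seed = 7, n_steps = 120)
run
#> <turn_run> scenario inside-walk, seed 7
#>   n_cycles: 119
#>   period_mean: 0.80878
#>   period_sd: 0.22488
#>   pro_mean_deg: 269.71
#>   pro_R: 0.86378
#>   pro_p: 2.2251e-308
#>   ret_mean_deg: 90.25
#>   ret_R: 0.86593
#>   ret_p: 2.2251e-308
#>   ret_pro_spike_ratio: 1.0634
```

119 synthetic inside-turn step cycles average 0.809 s (sample SD 0.225,
consistent with the 0.83 ± 0.21 s preset at n = 119). Protractor spikes
phase-lock at 269.7° of the step cycle and retractor spikes at 90.3°,
each with mean resultant length R ≈ 0.86 (the von Mises Bessel ratio for
concentration 4) and Rayleigh p below machine precision — alternating,
phase-coupled antagonist drive. The near-1 spike-count ratio shows
neither pool dominates in inside mode.

```r
pilo <- run_experiment("pilocarpine", seed = 7, duration = 60)
c(quiet = pilo$summary$freq_quiet, stepping = pilo$summary$freq_stepping)
#>     quiet  stepping
#> 0.2666818 1.1506203
```

The slow rhythm runs at 0.267 Hz in quiescence and 1.151 Hz during the
stepping interval — recovery of the 0.27/1.16 Hz generator regimes by
burst detection and inter-onset averaging.

Individual stages compose directly, e.g.:

```r
steps  <- make_steps("fl-inside", 301, seed = 1)
cycles <- segment_steps(steps)
period_stats(cycles)
nerve  <- make_nerve_activity(steps, "inside", get_preset("fl-inside"), seed = 2)
mean_vector(na.omit(phase_at(events_of(nerve$protractor, "spike"), cycles)))
```

A thin command-line wrapper for shell-driven runs ships in
`inst/scripts/turncycle.R`
(`Rscript turncycle.R run --scenario load-inside --seed 3 --outdir out/`);
outputs are delimited text with provenance headers (seed, config,
version).

## Methods

See the methods vignette (`vignettes/turncycle-methods.Rmd`) for the
models, parameter conventions, numerical choices, what the generator
does and does not emulate, and known limitations.
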