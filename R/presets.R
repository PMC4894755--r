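#' Generator presets
#'
#' A preset bundles every parameter of the synthetic-data generator: step
#' timing (mean/SD of the step period, duty fraction), phase-locked nerve
#' activity (von Mises peak phases and concentration, base firing rate),
#' slow-rhythm frequencies in the quiescent and stepping states, load-response
#' class probabilities and the phase concentration of no-response stimuli,
#' and recording nuisance parameters (crosstalk coefficient, noise SD,
#' sampling rate).
#'
#' The shipped preset library ([preset_library()], [get_preset()]) encodes
#' the study conditions: front-leg inside/outside step periods 0.83 s (SD
#' 0.21) / 1.21 s (SD 0.37), middle-leg 0.76 s (SD 0.15) / 1.13 s (SD 0.28);
#' protractor/retractor phase peaks at 270 and 90 degrees of the step
#' cycle; pilocarpine rhythm 0.27 Hz quiescent speeding to 1.16 Hz during
#' stepping; and an 18.8 % no-response rate with phase preference at 0.89
#' of the cycle for inside-turn load stimuli.
#'
#' @param name Preset label.
#' @param mean_period,sd_period Mean and SD of the step period in seconds.
#' @param duty_fraction Stance fraction of the cycle, in (0, 1).
#' @param pro_peak_deg,ret_peak_deg Protractor/retractor activity peak phase
#'   in degrees of the step cycle, in \[0, 360).
#' @param kappa Von Mises concentration of phase-locked firing (>= 0).
#' @param base_rate Mean firing rate in spikes/s.
#' @param rhythm_freq_quiet,rhythm_freq_step Slow-rhythm cycle frequency
#'   (Hz) in the quiescent animal and during stepping.
#' @param p_ret_act,p_pro_act,p_none Load-response class probabilities
#'   (retractor activation, protractor activation with retractor
#'   termination, no response); must sum to 1.
#' @param none_phase_mu Preferred step-cycle phase (cycle fraction in
#'   \[0, 1)) of no-response stimuli.
#' @param none_kappa Von Mises concentration of the no-response phase.
#' @param crosstalk_coeff Fraction of the antagonist signal leaking into an
#'   EMG channel, in \[0, 1).
#' @param noise_sd Gaussian noise SD added to synthetic traces (signal units).
#' @param fs Sampling rate of synthetic traces in Hz.
#' @param seed Optional default seed used when an operation is not given one.
#'
#' @return An object of class `turn_preset` (a validated named list).
#' @examples
#' p <- get_preset("fl-inside")
#' p$mean_period
#' names(preset_library())
#' @export
turn_preset <- function(name = "custom",
                        mean_period = 0.83, sd_period = 0.21,
                        duty_fraction = 0.6,
                        pro_peak_deg = 270, ret_peak_deg = 90,
                        kappa = 4, base_rate = 25,
                        rhythm_freq_quiet = 0.27, rhythm_freq_step = 1.16,
                        p_ret_act = 0.712, p_pro_act = 0.10, p_none = 0.188,
                        none_phase_mu = 0.89, none_kappa = 4,
                        crosstalk_coeff = 0.3, noise_sd = 0.05,
                        fs = 1000, seed = NA_integer_) {
  p <- list(name = as.character(name)[1L],
            mean_period = mean_period, sd_period = sd_period,
            duty_fraction = duty_fraction,
            pro_peak_deg = pro_peak_deg %% 360, ret_peak_deg = ret_peak_deg %% 360,
            kappa = kappa, base_rate = base_rate,
            rhythm_freq_quiet = rhythm_freq_quiet,
            rhythm_freq_step = rhythm_freq_step,
            p_ret_act = p_ret_act, p_pro_act = p_pro_act, p_none = p_none,
            none_phase_mu = none_phase_mu, none_kappa = none_kappa,
            crosstalk_coeff = crosstalk_coeff, noise_sd = noise_sd,
            fs = fs,
            seed = if (is.null(seed) || is.na(seed)) NA_integer_
                   else as.integer(seed))
  validate_preset(p)
  structure(p, class = "turn_preset")
}

validate_preset <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("mean_period", "sd_period", "duty_fraction", "pro_peak_deg",
              "ret_peak_deg", "kappa", "base_rate", "rhythm_freq_quiet",
              "rhythm_freq_step", "p_ret_act", "p_pro_act", "p_none",
              "none_phase_mu", "none_kappa", "crosstalk_coeff", "noise_sd",
              "fs"))
    if (!num1(p[[f]])) stop("preset field `", f, "` must be a finite scalar")
  if (p$mean_period <= 0) stop("mean_period must be > 0")
  if (p$sd_period < 0) stop("sd_period must be >= 0")
  if (p$duty_fraction <= 0 || p$duty_fraction >= 1)
    stop("duty_fraction must lie strictly between 0 and 1")
  if (p$kappa < 0 || p$none_kappa < 0) stop("concentrations must be >= 0")
  if (p$base_rate <= 0) stop("base_rate must be > 0")
  if (p$rhythm_freq_quiet <= 0 || p$rhythm_freq_step <= 0)
    stop("rhythm frequencies must be > 0")
  probs <- c(p$p_ret_act, p$p_pro_act, p$p_none)
  if (any(probs < 0)) stop("class probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("p_ret_act + p_pro_act + p_none must equal 1 (got ",
         format(sum(probs), digits = 15), ")")
  if (p$none_phase_mu < 0 || p$none_phase_mu >= 1)
    stop("none_phase_mu must lie in [0, 1)")
  if (p$crosstalk_coeff < 0 || p$crosstalk_coeff >= 1)
    stop("crosstalk_coeff must lie in [0, 1)")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$fs <= 0) stop("fs must be > 0")
  invisible(p)
}

#' @export
print.turn_preset <- function(x, ...) {
  cat(sprintf("<turn_preset> %s: period %.3g s (SD %.3g), duty %.2f, peaks %g/%g deg (kappa %g)\n",
              x$name, x$mean_period, x$sd_period, x$duty_fraction,
              x$pro_peak_deg, x$ret_peak_deg, x$kappa))
  cat(sprintf("  rhythm %g -> %g Hz; classes RET %.3f / PRO %.3f / NONE %.3f (mu %.2f, kappa %g)\n",
              x$rhythm_freq_quiet, x$rhythm_freq_step,
              x$p_ret_act, x$p_pro_act, x$p_none, x$none_phase_mu, x$none_kappa))
  invisible(x)
}

#' @rdname turn_preset
#' @export
preset_library <- function() {
  list(
    "fl-inside"     = turn_preset("fl-inside",  mean_period = 0.83, sd_period = 0.21),
    "fl-outside"    = turn_preset("fl-outside", mean_period = 1.21, sd_period = 0.37),
    "ml-inside"     = turn_preset("ml-inside",  mean_period = 0.76, sd_period = 0.15),
    "ml-outside"    = turn_preset("ml-outside", mean_period = 1.13, sd_period = 0.28),
    "pilo-quiet"    = turn_preset("pilo-quiet",
                                  rhythm_freq_quiet = 0.27, rhythm_freq_step = 0.27),
    "pilo-stepping" = turn_preset("pilo-stepping",
                                  rhythm_freq_quiet = 0.27, rhythm_freq_step = 1.16),
    "load-inside"   = turn_preset("load-inside", mean_period = 0.83, sd_period = 0.21,
                                  p_ret_act = 0.712, p_pro_act = 0.10, p_none = 0.188,
                                  none_phase_mu = 0.89),
    "load-outside"  = turn_preset("load-outside", mean_period = 1.21, sd_period = 0.37,
                                  p_ret_act = 1, p_pro_act = 0, p_none = 0))
}

#' @rdname turn_preset
#' @param overrides Named list of preset fields to override.
#' @export
get_preset <- function(name, overrides = list()) {
  lib <- preset_library()
  if (!name %in% names(lib))
    stop("unknown preset '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  p <- unclass(lib[[name]])
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) stop("unknown preset fields: ", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  do.call(turn_preset, p[setdiff(names(p), character())])
}

#' Serialize presets to and from JSON
#'
#' @param presets A named list of [turn_preset()] objects.
#' @param path File path for the JSON preset library.
#' @return `read_presets()` returns a named list of validated presets.
#' @export
write_presets <- function(presets, path) {
  if (inherits(presets, "turn_preset")) presets <- stats::setNames(list(presets), presets$name)
  stopifnot(all(vapply(presets, inherits, TRUE, "turn_preset")))
  strip <- function(p) {
    p <- unclass(p)
    if (is.na(p$seed)) p$seed <- NULL  # JSON has no NA; default restores it
    p
  }
  jsonlite::write_json(lapply(presets, strip), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_presets
#' @export
read_presets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) do.call(turn_preset, p))
}
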