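#' Quality degradation specification
#'
#' Describes how a clean cECG signal is corrupted to emulate one of the three
#' signal-quality classes:
#' * `C1` — clear waveform: very light broadband noise and baseline wander;
#' * `C2` — blurry waveform with clear R peaks: moderate noise and wander,
#'   occasional artifact bursts, P and T waves attenuated while R is preserved;
#' * `N` — noise: movement-dominated signal in which the noise energy exceeds
#'   the remaining ECG energy (coupling largely lost, all waves attenuated).
#'
#' Defaults are generator configuration chosen so the classes are statistically
#' separable at segment level; they are stated as such, not as measured facts
#' about any particular hardware.
#'
#' @param quality_class one of `"C1"`, `"C2"`, `"N"`.
#' @param broadband_noise_sd standard deviation of additive Gaussian noise
#'   (signal units, >= 0).
#' @param baseline_wander `c(amplitude, frequency)`: sinusoidal wander amplitude
#'   (signal units) and frequency (Hz); a random-walk component of comparable
#'   terminal scale is added on top.
#' @param artifact_burst `c(rate, amplitude)`: Poisson rate of movement bursts
#'   (events/s) and their amplitude (signal units).
#' @param waveform_attenuation named per-wave multipliers (P,Q,R,S,T) applied to
#'   the clean waveform.
#' @return an object of class `quality_spec`.
#' @export
quality_spec <- function(quality_class,
                         broadband_noise_sd = NULL,
                         baseline_wander = NULL,
                         artifact_burst = NULL,
                         waveform_attenuation = NULL) {
  if (!is.character(quality_class) || length(quality_class) != 1 ||
      !quality_class %in% QUALITY_LEVELS)
    stop_cecg("`quality_class` must be one of 'C1', 'C2', 'N'",
              "cecg_invalid_label")
  defaults <- list(
    C1 = list(broadband_noise_sd = 0.008,
              baseline_wander = c(amplitude = 0.015, frequency = 0.30),
              artifact_burst = c(rate = 0, amplitude = 0),
              waveform_attenuation = c(P = 1, Q = 1, R = 1, S = 1, T = 1)),
    C2 = list(broadband_noise_sd = 0.06,
              baseline_wander = c(amplitude = 0.25, frequency = 0.33),
              artifact_burst = c(rate = 0.05, amplitude = 0.4),
              waveform_attenuation = c(P = 0.35, Q = 0.7, R = 1, S = 0.7, T = 0.35)),
    N = list(broadband_noise_sd = 0.45,
             baseline_wander = c(amplitude = 1.2, frequency = 0.40),
             artifact_burst = c(rate = 0.5, amplitude = 1.5),
             waveform_attenuation = c(P = 0.3, Q = 0.3, R = 0.3, S = 0.3, T = 0.3))
  )[[quality_class]]
  pick <- function(x, d, nm) {
    x <- if (is.null(x)) d else x
    if (!is.null(nm)) {
      x <- if (is.null(names(x))) stats::setNames(x, nm) else x[nm]
    }
    if (any(is.na(x)) || any(x < 0))
      stop_cecg("quality_spec noise parameters must be non-negative",
                "cecg_invalid_parameter")
    x
  }
  structure(list(
    quality_class = quality_class,
    broadband_noise_sd = pick(broadband_noise_sd, defaults$broadband_noise_sd, NULL),
    baseline_wander = pick(baseline_wander, defaults$baseline_wander,
                           c("amplitude", "frequency")),
    artifact_burst = pick(artifact_burst, defaults$artifact_burst,
                          c("rate", "amplitude")),
    waveform_attenuation = pick(waveform_attenuation,
                                defaults$waveform_attenuation, WAVE_NAMES)
  ), class = "quality_spec")
}

#' Default degradation specs for all three quality classes
#' @return named list of [quality_spec()] objects (C1, C2, N).
#' @export
default_quality_specs <- function() {
  stats::setNames(lapply(QUALITY_LEVELS, quality_spec), QUALITY_LEVELS)
}

#' Degrade a clean signal according to a quality spec
#'
#' Applies, in order: per-wave attenuation (exact when the per-wave component
#' matrix from [render_position()] is supplied, otherwise a uniform scaling by
#' the mean attenuation), additive Gaussian broadband noise, baseline wander
#' (sinusoid with random phase plus a random walk), and Poisson-timed artifact
#' bursts (damped 8 Hz oscillations of ~0.3 s). Reproducible from `seed`. A
#' spec with all noise terms zero and attenuation one returns the input
#' unchanged.
#'
#' @param clean numeric finite-valued clean signal.
#' @param spec a [quality_spec()].
#' @param fs sampling frequency (Hz, > 0).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param components optional n x 5 per-wave component matrix (attribute
#'   `"components"` of [render_position()] output).
#' @return degraded numeric signal, same length as `clean`.
#' @export
degrade <- function(clean, spec, fs, seed = NULL, components = NULL) {
  if (!is.numeric(clean) || any(!is.finite(clean)))
    stop_cecg("`clean` must be finite-valued", "cecg_invalid_signal")
  if (!inherits(spec, "quality_spec"))
    stop_cecg("`spec` must be a quality_spec()", "cecg_invalid_parameter")
  if (!is.numeric(fs) || fs <= 0)
    stop_cecg("`fs` must be > 0", "cecg_invalid_parameter")
  if (is.null(components)) components <- attr(clean, "components")

  n <- length(clean)
  att <- spec$waveform_attenuation
  x <- as.numeric(clean)
  if (any(att != 1)) {
    if (!is.null(components)) {
      stopifnot(nrow(components) == n, ncol(components) == 5)
      x <- as.numeric(components %*% att)
    } else {
      x <- x * mean(att)
    }
  }

  noiseless <- spec$broadband_noise_sd == 0 &&
    spec$baseline_wander[["amplitude"]] == 0 &&
    spec$artifact_burst[["rate"]] == 0
  if (noiseless && all(att == 1)) return(as.numeric(clean))

  with_seed(seed, {
    if (spec$broadband_noise_sd > 0)
      x <- x + rnorm(n, 0, spec$broadband_noise_sd)
    bw_amp <- spec$baseline_wander[["amplitude"]]
    if (bw_amp > 0) {
      t <- (seq_len(n) - 1) / fs
      phase <- runif(1, 0, 2 * pi)
      x <- x + bw_amp * sin(2 * pi * spec$baseline_wander[["frequency"]] * t + phase)
      # random walk with expected terminal sd of bw_amp / 2
      x <- x + cumsum(rnorm(n, 0, bw_amp / (2 * sqrt(n))))
    }
    rate <- spec$artifact_burst[["rate"]]
    if (rate > 0) {
      n_ev <- rpois(1, rate * n / fs)
      if (n_ev > 0) {
        centers <- runif(n_ev, 0, n / fs)
        amps <- spec$artifact_burst[["amplitude"]] * runif(n_ev, 0.5, 1.5)
        t <- (seq_len(n) - 1) / fs
        for (e in seq_len(n_ev)) {
          dt <- t - centers[e]
          x <- x + amps[e] * exp(-(dt / 0.08)^2) * sin(2 * pi * 8 * dt)
        }
      }
    }
    x
  })
}

#' Segment-level signal-to-noise ratio against ground truth
#'
#' SNR (dB) of a degraded segment given its clean counterpart:
#' `10 log10(var(clean) / var(degraded - clean))`. Used to verify that the
#' quality classes are separable (a single threshold splits C1 from N at the
#' generator defaults).
#'
#' @param clean,degraded numeric vectors of equal length.
#' @return SNR in dB (`Inf` when degraded equals clean).
#' @export
segment_snr <- function(clean, degraded) {
  stopifnot(length(clean) == length(degraded))
  noise_var <- var(degraded - clean)
  if (noise_var < .Machine$double.eps) return(Inf)
  10 * log10(var(clean) / noise_var)
}
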