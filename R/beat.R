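#' Gaussian-sum PQRST beat template
#'
#' A single heartbeat is modelled as the sum of five Gaussian bumps (P, Q, R,
#' S, T), each described by an amplitude (signal units), a phase center
#' (fraction of the beat in [0, 1)) and a width (fraction of the beat, > 0).
#' The defaults give an upright lead-II-like morphology with a dominant R wave.
#'
#' @param amplitude named numeric vector of wave amplitudes (names P,Q,R,S,T).
#' @param phase_center named numeric vector of wave centers, strictly
#'   increasing in P < Q < R < S < T, each in [0, 1).
#' @param width named numeric vector of wave widths (> 0).
#' @return an object of class `beat_template` (data frame, one row per wave).
#' @examples
#' tpl <- beat_template()
#' beat <- synth_beat(tpl, fs = 300, beat_duration = 1)
#' @export
beat_template <- function(
    amplitude = c(P = 0.15, Q = -0.12, R = 1.00, S = -0.25, T = 0.35),
    phase_center = c(P = 0.16, Q = 0.36, R = 0.40, S = 0.44, T = 0.62),
    width = c(P = 0.045, Q = 0.012, R = 0.018, S = 0.014, T = 0.060)) {
  amplitude <- amplitude[WAVE_NAMES]
  phase_center <- phase_center[WAVE_NAMES]
  width <- width[WAVE_NAMES]
  if (any(is.na(amplitude)) || any(is.na(phase_center)) || any(is.na(width)))
    stop_cecg("template must define all five waves P,Q,R,S,T",
              "cecg_invalid_template")
  if (abs(amplitude[["R"]]) < max(abs(amplitude)))
    stop_cecg("R amplitude must have the largest absolute value",
              "cecg_invalid_template")
  if (any(diff(phase_center) <= 0) || any(phase_center < 0) || any(phase_center >= 1))
    stop_cecg("phase centers must be strictly increasing within [0,1)",
              "cecg_invalid_template")
  if (any(width <= 0))
    stop_cecg("wave widths must be > 0", "cecg_invalid_template")
  structure(
    data.frame(wave = WAVE_NAMES, amplitude = unname(amplitude),
               phase_center = unname(phase_center), width = unname(width)),
    class = c("beat_template", "data.frame"))
}

validate_template <- function(template) {
  if (!inherits(template, "beat_template"))
    stop_cecg("`template` must be a beat_template()", "cecg_invalid_template")
  template
}

#' Per-wave components of one synthesized beat
#'
#' @return matrix n x 5, one column per wave; rowSums() is the beat.
#' @noRd
synth_beat_components <- function(template, fs, beat_duration) {
  validate_template(template)
  if (!is.numeric(beat_duration) || beat_duration <= 0)
    stop_cecg("`beat_duration` must be > 0", "cecg_invalid_parameter")
  n <- round(fs * beat_duration)
  if (n < 10)
    stop_cecg("fs * beat_duration must be at least 10 samples",
              "cecg_invalid_parameter")
  phase <- (seq_len(n) - 1) / n
  comp <- vapply(seq_len(5), function(w) {
    template$amplitude[w] *
      exp(-(phase - template$phase_center[w])^2 / (2 * template$width[w]^2))
  }, numeric(n))
  colnames(comp) <- WAVE_NAMES
  comp
}

#' Synthesize one heartbeat from a template
#'
#' Deterministic: the beat is the pointwise sum of the five Gaussian bumps of
#' the template, sampled at `round(fs * beat_duration)` points spanning one
#' beat.
#'
#' @param template a [beat_template()].
#' @param fs sampling frequency (Hz).
#' @param beat_duration beat length in seconds (> 0; at least 10 samples).
#' @return numeric vector of length `round(fs * beat_duration)`.
#' @export
synth_beat <- function(template, fs, beat_duration) {
  rowSums(synth_beat_components(template, fs, beat_duration))
}
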