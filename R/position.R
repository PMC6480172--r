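#' Sleep-position projection profile
#'
#' The heart's electrical dipole projects onto the electrode axis with a
#' magnitude and polarity that depend on body orientation. A profile scales a
#' beat by `polarity * gain` and modulates individual waves. In the left
#' lateral position the projection is smallest, so the default profiles keep
#' `gain(L) < gain(S)` and `gain(L) < gain(R)`; supine (S) is the reference,
#' and the right lateral (R) profile differs from S by a slightly lower gain
#' and damped P/T waves so the two remain distinguishable. These values are
#' generator configuration, not physiological constants.
#'
#' @param position one of `"S"`, `"L"`, `"R"`.
#' @param gain dimensionless projection magnitude (> 0).
#' @param polarity `+1` or `-1`.
#' @param wave_modulation named per-wave multipliers (names P,Q,R,S,T).
#' @return an object of class `position_profile`.
#' @export
position_profile <- function(position,
                             gain = NULL,
                             polarity = NULL,
                             wave_modulation = NULL) {
  if (!is.character(position) || length(position) != 1 ||
      !position %in% POSITION_LEVELS)
    stop_cecg("`position` must be one of 'S', 'L', 'R'", "cecg_invalid_label")
  defaults <- list(
    S = list(gain = 1.00, polarity = +1,
             wave_modulation = c(P = 1, Q = 1, R = 1, S = 1, T = 1)),
    R = list(gain = 0.90, polarity = +1,
             wave_modulation = c(P = 0.8, Q = 1, R = 1, S = 1, T = 0.8)),
    L = list(gain = 0.35, polarity = -1,
             wave_modulation = c(P = 1, Q = 1, R = 1, S = 1, T = 1)))[[position]]
  gain <- if (is.null(gain)) defaults$gain else gain
  polarity <- if (is.null(polarity)) defaults$polarity else polarity
  wave_modulation <- if (is.null(wave_modulation)) defaults$wave_modulation
                     else wave_modulation[WAVE_NAMES]
  if (!is.numeric(gain) || gain <= 0 || !is.finite(gain))
    stop_cecg("`gain` must be a finite number > 0", "cecg_invalid_parameter")
  if (!polarity %in% c(-1, 1))
    stop_cecg("`polarity` must be +1 or -1", "cecg_invalid_parameter")
  if (any(is.na(wave_modulation)) || any(wave_modulation < 0))
    stop_cecg("`wave_modulation` must be named non-negative multipliers for P,Q,R,S,T",
              "cecg_invalid_parameter")
  structure(list(position = position, gain = gain, polarity = polarity,
                 wave_modulation = wave_modulation),
            class = "position_profile")
}

#' Default profiles for the three sleep positions
#'
#' @return named list of [position_profile()] objects for S, L and R,
#'   validated to satisfy the ordering `gain(L) < gain(S)`, `gain(L) < gain(R)`
#'   and S != R.
#' @export
default_position_profiles <- function() {
  p <- list(S = position_profile("S"), L = position_profile("L"),
            R = position_profile("R"))
  validate_position_profiles(p)
}

validate_position_profiles <- function(profiles) {
  stopifnot(all(POSITION_LEVELS %in% names(profiles)))
  g <- vapply(profiles, `[[`, numeric(1), "gain")
  if (!(g[["L"]] < g[["S"]] && g[["L"]] < g[["R"]]))
    stop_cecg("profiles must satisfy gain(L) < gain(S) and gain(L) < gain(R)",
              "cecg_invalid_parameter")
  s <- profiles[["S"]]; r <- profiles[["R"]]
  if (s$polarity == r$polarity && s$gain == r$gain &&
      all(s$wave_modulation == r$wave_modulation))
    stop_cecg("S and R profiles must differ (polarity, gain or modulation)",
              "cecg_invalid_parameter")
  profiles
}

#' Render a clean position-dependent cECG signal
#'
#' Concatenates template beats with (optionally jittered) RR intervals; each
#' beat is scaled by `polarity * gain` and per-wave modulation of the profile.
#' With zero jitter and `heart_rate = 60` the R peaks are exactly 1 s apart.
#'
#' @param template a [beat_template()].
#' @param profile a [position_profile()].
#' @param fs sampling frequency (Hz).
#' @param duration record length (s, > 0).
#' @param heart_rate mean heart rate (bpm, in [30, 220]).
#' @param rr_jitter_sd standard deviation of Gaussian RR jitter (s, >= 0).
#' @param seed integer seed for the jitter; `NULL` uses the current RNG state.
#' @param return_components also attach the per-wave component matrix
#'   (attribute `"components"`, n x 5), used for per-wave degradation.
#' @return numeric signal of length `round(fs * duration)` with attributes
#'   `r_peaks` (R-peak times, s) and `rr` (per-beat RR intervals, s).
#' @export
render_position <- function(template, profile, fs, duration,
                            heart_rate = 70, rr_jitter_sd = 0,
                            seed = NULL, return_components = FALSE) {
  validate_template(template)
  if (!inherits(profile, "position_profile"))
    stop_cecg("`profile` must be a position_profile()", "cecg_invalid_label")
  if (!is.numeric(duration) || duration <= 0)
    stop_cecg("`duration` must be > 0", "cecg_invalid_parameter")
  if (heart_rate < 30 || heart_rate > 220)
    stop_cecg("`heart_rate` must lie in [30, 220] bpm", "cecg_invalid_parameter")
  if (rr_jitter_sd < 0)
    stop_cecg("`rr_jitter_sd` must be >= 0", "cecg_invalid_parameter")

  n <- round(fs * duration)
  base_rr <- 60 / heart_rate
  n_beats <- ceiling(duration / base_rr) + 3L
  rr <- with_seed(seed, {
    r <- rep(base_rr, n_beats) +
      if (rr_jitter_sd > 0) rnorm(n_beats, 0, rr_jitter_sd) else 0
    pmax(r, 0.3 * base_rr)
  })
  onsets <- c(0, cumsum(rr))[seq_len(n_beats)]

  x <- numeric(n)
  comp <- if (return_components) matrix(0, n, 5, dimnames = list(NULL, WAVE_NAMES))
  scale_w <- profile$polarity * profile$gain * profile$wave_modulation
  r_peaks <- numeric(0)
  for (b in seq_len(n_beats)) {
    i0 <- round(onsets[b] * fs) # 0-based sample offset of beat onset
    if (i0 >= n) break
    bc <- synth_beat_components(template, fs, rr[b])
    nb <- min(nrow(bc), n - i0)
    idx <- (i0 + 1):(i0 + nb)
    bc <- bc[seq_len(nb), , drop = FALSE]
    x[idx] <- x[idx] + bc %*% scale_w
    if (return_components)
      comp[idx, ] <- comp[idx, ] + sweep(bc, 2, scale_w, `*`)
    rp <- onsets[b] + template$phase_center[3] * rr[b]
    if (rp < duration) r_peaks <- c(r_peaks, rp)
  }
  attr(x, "r_peaks") <- r_peaks
  attr(x, "rr") <- rr
  if (return_components) attr(x, "components") <- comp
  x
}
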