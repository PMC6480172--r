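#' Capacitive coupling equivalent circuit
#'
#' The electrode couples to the body through cloth, which acts as a lossy
#' capacitor: a contact resistance in series with the parallel combination of
#' the cloth resistance and cloth capacitance. Defaults correspond to a
#' conductive-fabric electrode through typical bed cloth (150 MOhm, 70 pF).
#'
#' @param r_cont contact resistance between cloth and electrode (Ohm, >= 0).
#' @param r_cloth cloth resistance (Ohm, > 0).
#' @param c_cloth cloth capacitance (F, > 0).
#' @return an object of class `coupling_circuit`.
#' @examples
#' cc <- coupling_circuit()
#' coupling_magnitude(cc, freq = c(0, 1, 10, 100))
#' @export
coupling_circuit <- function(r_cont = 0, r_cloth = 1.5e8, c_cloth = 7e-11) {
  if (!is.numeric(r_cont) || length(r_cont) != 1 || !is.finite(r_cont) || r_cont < 0)
    stop_cecg("`r_cont` must be a single finite number >= 0", "cecg_invalid_parameter")
  if (!is.numeric(r_cloth) || length(r_cloth) != 1 || !is.finite(r_cloth) || r_cloth <= 0)
    stop_cecg("`r_cloth` must be a single finite number > 0", "cecg_invalid_parameter")
  if (!is.numeric(c_cloth) || length(c_cloth) != 1 || !is.finite(c_cloth) || c_cloth <= 0)
    stop_cecg("`c_cloth` must be a single finite number > 0", "cecg_invalid_parameter")
  structure(list(r_cont = r_cont, r_cloth = r_cloth, c_cloth = c_cloth),
            class = "coupling_circuit")
}

#' @export
print.coupling_circuit <- function(x, ...) {
  cat("Capacitive coupling circuit\n")
  cat(sprintf("  R_cont : %.4g Ohm\n", x$r_cont))
  cat(sprintf("  R_cloth: %.4g Ohm\n", x$r_cloth))
  cat(sprintf("  C_cloth: %.4g F\n", x$c_cloth))
  invisible(x)
}

#' Coupling impedance magnitude versus frequency
#'
#' Magnitude of the total coupling impedance
#' `|Zt| = R_cont + R_cloth / sqrt((2 pi f R_cloth C_cloth)^2 + 1)`:
#' the contact resistance in series with the cloth RC parallel branch. It is
#' strictly decreasing in frequency, tends to `R_cont + R_cloth` as f -> 0 and
#' to `R_cont` as f -> Inf.
#'
#' @param circuit a [coupling_circuit()].
#' @param freq frequency or vector of frequencies (Hz, >= 0).
#' @return impedance magnitude(s) in Ohm.
#' @export
coupling_magnitude <- function(circuit, freq) {
  stopifnot(inherits(circuit, "coupling_circuit"))
  if (!is.numeric(freq) || any(!is.finite(freq)) || any(freq < 0))
    stop_cecg("`freq` must be finite and >= 0", "cecg_invalid_parameter")
  circuit$r_cont +
    circuit$r_cloth / sqrt((2 * pi * freq * circuit$r_cloth * circuit$c_cloth)^2 + 1)
}

#' Apply the coupling response as a linear zero-phase filter
#'
#' Optional stage that shapes a clean signal by the normalized coupling
#' magnitude response (gain 1 at DC, decreasing with frequency). Applied in the
#' frequency domain with zero phase. The generator leaves this off by default;
#' the circuit model is primarily descriptive.
#'
#' @param x numeric signal.
#' @param fs sampling frequency (Hz).
#' @param circuit a [coupling_circuit()].
#' @return filtered signal, same length as `x`.
#' @export
coupling_filter <- function(x, fs, circuit = coupling_circuit()) {
  stopifnot(is.numeric(x), length(x) > 1, fs > 0)
  n <- length(x)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f) # two-sided FFT bin frequencies
  gain <- coupling_magnitude(circuit, f) / coupling_magnitude(circuit, 0)
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}
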