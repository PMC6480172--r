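#' Band-pass filter specification
#'
#' Butterworth band-pass used to strip baseline drift and out-of-band noise
#' while keeping the physiologically informative spectrum. Defaults: 2nd order,
#' 0.05-40 Hz.
#'
#' @param order filter order (per pass).
#' @param band `c(low_hz, high_hz)` pass band edges, `0 < low < high`.
#' @param family filter family; only `"butterworth"` is implemented.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 2, band = c(0.05, 40), family = "butterworth") {
  stopifnot(identical(family, "butterworth"), length(band) == 2)
  if (!(band[1] > 0 && band[1] < band[2]))
    stop_cecg("band must satisfy 0 < low_hz < high_hz", "cecg_invalid_band")
  structure(list(family = family, order = as.integer(order),
                 band = as.numeric(band)),
            class = "filter_spec")
}

#' Steady state of an IIR filter for a unit-step input
#'
#' Initial filter state such that a constant input produces the constant
#' steady-state output from the first sample on. Starting each pass of the
#' forward-backward filter from this state (scaled by the first sample)
#' suppresses the multi-second startup transient the 0.05 Hz corner would
#' otherwise leave.
#' @noRd
iir_steady_state <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  A <- rbind(-a[2:n], cbind(diag(n - 2), rep(0, n - 2))) # companion of a
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

#' Forward-backward IIR filtering with odd-reflection padding and
#' steady-state initial conditions (both passes).
#' @noRd
filtfilt_ss <- function(b, a, x) {
  n <- max(length(a), length(b))
  pad <- 3L * (n - 1L)
  ext <- c(2 * x[1] - x[(pad + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)])
  zi <- iir_steady_state(b, a)
  y <- cpp_iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- rev(cpp_iir_filter(b, a, y, zi * y[1]))
  y[(pad + 1):(pad + length(x))]
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the Butterworth band-pass forward and backward, so the magnitude
#' response is squared and the phase is zero — R-peak timing is not shifted.
#' Each pass starts from the filter's unit-step steady state (with short
#' odd-reflection padding), so a constant offset is removed exactly instead of
#' decaying over the many seconds the 0.05 Hz corner would need. Output length
#' equals input length.
#'
#' @param x numeric signal (finite values).
#' @param fs sampling frequency (Hz); must exceed twice the upper band edge.
#' @param spec a [filter_spec()].
#' @return filtered signal.
#' @examples
#' x <- sin(2 * pi * 10 * (0:2999) / 300) + 2   # 10 Hz riding on DC
#' y <- bandpass(x, fs = 300)
#' @export
bandpass <- function(x, fs, spec = filter_spec()) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_cecg("`x` must be numeric with finite values", "cecg_invalid_signal")
  if (fs <= 2 * spec$band[2])
    stop_cecg("upper band edge must lie below the Nyquist frequency fs/2",
              "cecg_invalid_band")
  bf <- signal::butter(spec$order, 2 * spec$band / fs, type = "pass")
  if (length(x) <= 3 * max(length(bf$b), length(bf$a)))
    stop_cecg("signal too short for the filter order", "cecg_invalid_signal")
  filtfilt_ss(bf$b, bf$a, x)
}

#' Split a signal into fixed-length overlapping segments
#'
#' Window length `L = round(fs * seg_len_s)`, step
#' `round(L * (1 - overlap_frac))`; start indices are 0-based multiples of the
#' step and trailing samples that do not fill a window are dropped, so a signal
#' of `N >= L` samples yields `floor((N - L) / step) + 1` segments.
#'
#' @param x numeric signal.
#' @param fs sampling frequency (Hz).
#' @param seg_len_s window length (s); 2 and 4 are the usual choices.
#' @param overlap_frac overlap fraction in `[0, 1)`; 0.5 doubles the number of
#'   windows and acts as data augmentation.
#' @return list with `samples` (matrix, one segment per row), `start_index`
#'   (0-based sample offsets), `fs`, `seg_len_s`; zero rows when `x` is shorter
#'   than one window.
#' @export
segment_record <- function(x, fs, seg_len_s, overlap_frac = 0.5) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop_cecg("`overlap_frac` must lie in [0, 1)", "cecg_invalid_overlap")
  L <- round(fs * seg_len_s)
  step <- round(L * (1 - overlap_frac))
  if (step < 1) stop_cecg("overlap too large: step is 0", "cecg_invalid_overlap")
  n <- length(x)
  if (n < L) {
    return(list(samples = matrix(numeric(0), 0, L), start_index = integer(0),
                fs = fs, seg_len_s = seg_len_s))
  }
  starts <- seq.int(0L, n - L, by = step)
  idx <- outer(starts, seq_len(L), `+`) # n_seg x L matrix of 1-based indices
  list(samples = matrix(x[idx], nrow = length(starts)),
       start_index = as.integer(starts), fs = fs, seg_len_s = seg_len_s)
}

#' z-score a segment with the population standard deviation
#'
#' @param x numeric vector, length >= 2.
#' @return `(x - mean(x)) / sd_pop(x)`; raises a zero-variance error (condition
#'   class `cecg_zero_variance`) when the population sd is below `1e-12` —
#'   callers decide whether to reject and log the segment.
#' @export
normalize_segment <- function(x) {
  if (length(x) < 2)
    stop_cecg("segment must have at least 2 samples", "cecg_invalid_signal")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12)
    stop_cecg("zero-variance segment cannot be normalized", "cecg_zero_variance")
  (x - m) / s
}

#' Build a labeled segment dataset from annotated records
#'
#' Pipeline order: band-pass filter each record, segment it, label each window,
#' z-score each window. A window inherits a (quality, position) label only when
#' it lies entirely inside one truth interval; windows straddling interval
#' boundaries are discarded and counted, as are zero-variance windows.
#'
#' @param records list of `cecg_record` objects (all at one sampling
#'   frequency). Records without truth intervals raise a missing-annotation
#'   error unless `allow_unlabeled = TRUE` (their segments then carry `NA`
#'   labels).
#' @param seg_len_s window length (s).
#' @param overlap_frac overlap fraction in `[0, 1)`.
#' @param filter a [filter_spec()], or `NULL` to skip filtering.
#' @param allow_unlabeled admit records without annotations.
#' @return an object of class `segment_dataset`: fields `x` (n x L matrix of
#'   normalized segments), `quality` and `position` (factors), `record_id`,
#'   `start_index`, `fs`, `seg_len_s`, `overlap_frac`, `class_counts`
#'   (quality x position table), `n_straddling`, `n_zero_variance`.
#' @export
assemble_dataset <- function(records, seg_len_s = 4, overlap_frac = 0.5,
                             filter = filter_spec(), allow_unlabeled = FALSE) {
  if (inherits(records, "cecg_record")) records <- list(records)
  stopifnot(length(records) > 0)
  fs <- records[[1]]$fs
  L <- round(fs * seg_len_s)
  xs <- list(); qual <- character(0); pos <- character(0)
  rid <- character(0); st <- integer(0)
  n_straddle <- 0L; n_zerovar <- 0L
  for (rec in records) {
    stopifnot(inherits(rec, "cecg_record"))
    if (rec$fs != fs)
      stop_cecg("all records must share one sampling frequency",
                "cecg_invalid_parameter")
    iv <- rec$truth_intervals
    if (is.null(iv) || nrow(iv) == 0) {
      if (!allow_unlabeled)
        stop_cecg(sprintf("record '%s' has no annotations", rec$record_id),
                  "cecg_missing_annotation")
      iv <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       quality = character(0), position = character(0))
    }
    sig <- if (is.null(filter)) rec$samples else bandpass(rec$samples, fs, filter)
    seg <- segment_record(sig, fs, seg_len_s, overlap_frac)
    for (i in seq_along(seg$start_index)) {
      s0 <- seg$start_index[i] / fs
      s1 <- (seg$start_index[i] + L) / fs
      hit <- which(iv$start_s <= s0 + 1e-9 & iv$end_s >= s1 - 1e-9)
      if (length(hit) == 0) {
        if (nrow(iv) > 0) { n_straddle <- n_straddle + 1L; next }
        q <- NA_character_; p <- NA_character_
      } else {
        q <- iv$quality[hit[1]]; p <- iv$position[hit[1]]
      }
      z <- tryCatch(normalize_segment(seg$samples[i, ]),
                    cecg_zero_variance = function(e) NULL)
      if (is.null(z)) { n_zerovar <- n_zerovar + 1L; next }
      xs[[length(xs) + 1L]] <- z
      qual <- c(qual, q); pos <- c(pos, p)
      rid <- c(rid, rec$record_id); st <- c(st, seg$start_index[i])
    }
  }
  x <- if (length(xs)) do.call(rbind, xs) else matrix(numeric(0), 0, L)
  quality <- factor(qual, levels = QUALITY_LEVELS)
  position <- factor(pos, levels = POSITION_LEVELS)
  structure(list(
    x = x, quality = quality, position = position,
    record_id = rid, start_index = st,
    fs = fs, seg_len_s = seg_len_s, overlap_frac = overlap_frac,
    class_counts = table(quality = quality, position = position),
    n_straddling = n_straddle, n_zero_variance = n_zerovar
  ), class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("Segment dataset: %d segments of %g s (%d samples) at %g Hz, overlap %.0f%%\n",
              nrow(x$x), x$seg_len_s, ncol(x$x), x$fs, 100 * x$overlap_frac))
  print(x$class_counts)
  if (x$n_straddling || x$n_zero_variance)
    cat(sprintf("  discarded: %d straddling, %d zero-variance\n",
                x$n_straddling, x$n_zero_variance))
  invisible(x)
}
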