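#' Default per-cell segment counts
#'
#' Class mix used by the shipped experiments: the strong (quality x position)
#' imbalance observed in an unconstrained 12-subject bed-recording campaign
#' with 4 s windows, rescaled to a requested total by largest-remainder
#' rounding. Rows are quality classes (C1, C2, N), columns sleep positions
#' (S, L, R).
#'
#' @param total total number of segments across all nine cells.
#' @return a 3 x 3 integer matrix (rows C1,C2,N; columns S,L,R) summing to
#'   `total`.
#' @export
default_cell_counts <- function(total = 600) {
  stopifnot(total >= 9)
  ref <- matrix(c(1903, 928, 1144,   # C1: S, L, R
                  170,  583,  335,   # C2
                  569,  845,   73),  # N
                nrow = 3, byrow = TRUE,
                dimnames = list(QUALITY_LEVELS, POSITION_LEVELS))
  raw <- ref / sum(ref) * total
  cnt <- floor(raw)
  rem <- total - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[ord] <- cnt[ord] + 1
  }
  storage.mode(cnt) <- "integer"
  cnt
}

#' Generate a labeled synthetic cECG dataset
#'
#' For every requested (quality, position) cell one record is generated whose
#' length is chosen so that downstream segmentation (window `seg_len_s`,
#' overlap `overlap_frac`) yields exactly the requested number of segments.
#' Each record carries a single truth interval covering its extent; N-class
#' intervals keep their position label for bookkeeping but are flagged
#' position-uninformative. One root seed drives the whole dataset; per-record
#' child seeds are derived by a counter scheme, so the same
#' `(seed, parameters)` always reproduces the identical sample stream.
#'
#' @param cells 3 x 3 integer matrix of requested segment counts (rows C1,C2,N;
#'   columns S,L,R), e.g. [default_cell_counts()].
#' @param fs sampling frequency (Hz).
#' @param seg_len_s segment length the counts refer to (s).
#' @param overlap_frac segmentation overlap fraction the counts refer to.
#' @param heart_rate mean heart rate (bpm).
#' @param rr_jitter_sd RR jitter standard deviation (s).
#' @param seed integer root seed.
#' @param template a [beat_template()].
#' @param profiles named list of [position_profile()]s (S, L, R).
#' @param quality_specs named list of [quality_spec()]s (C1, C2, N).
#' @param apply_coupling apply [coupling_filter()] to the clean signal before
#'   degradation (off by default; the coupling model is descriptive).
#' @param circuit [coupling_circuit()] used when `apply_coupling = TRUE`.
#' @param max_record_s cap on a single record's duration (s); a cell whose
#'   count would need a longer record raises a capacity error.
#' @return list of `cecg_record` objects; each has fields `samples`, `clean`,
#'   `fs`, `heart_rate_series`, `truth_intervals`, `seed`, `record_id`,
#'   `generator_version`.
#' @examples
#' recs <- generate_dataset(default_cell_counts(60), seed = 1)
#' length(recs)
#' @export
generate_dataset <- function(cells = default_cell_counts(),
                             fs = 300, seg_len_s = 4, overlap_frac = 0.5,
                             heart_rate = 70, rr_jitter_sd = 0.04,
                             seed = 1,
                             template = beat_template(),
                             profiles = default_position_profiles(),
                             quality_specs = default_quality_specs(),
                             apply_coupling = FALSE,
                             circuit = coupling_circuit(),
                             max_record_s = 3600) {
  stopifnot(is.matrix(cells), all(dim(cells) == c(3, 3)))
  if (is.null(dimnames(cells)))
    dimnames(cells) <- list(QUALITY_LEVELS, POSITION_LEVELS)
  if (any(cells < 0) || all(cells == 0))
    stop_cecg("cell counts must be >= 0 with at least one > 0",
              "cecg_invalid_parameter")
  validate_position_profiles(profiles)
  L <- round(fs * seg_len_s)
  step <- round(L * (1 - overlap_frac))
  if (step < 1) stop_cecg("overlap too large: step is 0", "cecg_invalid_overlap")

  records <- list()
  counter <- 0L
  for (q in QUALITY_LEVELS) {
    for (p in POSITION_LEVELS) {
      n_seg <- cells[q, p]
      if (n_seg == 0) next
      counter <- counter + 1L
      n_samples <- (n_seg - 1) * step + L
      duration <- n_samples / fs
      if (duration > max_record_s)
        stop_cecg(sprintf(
          "cell (%s,%s) needs a %.0f s record, above the %.0f s cap",
          q, p, duration, max_record_s), "cecg_capacity_error")
      seed_render <- child_seed(seed, 2L * counter)
      seed_degrade <- child_seed(seed, 2L * counter + 1L)
      clean <- render_position(template, profiles[[p]], fs, duration,
                               heart_rate = heart_rate,
                               rr_jitter_sd = rr_jitter_sd,
                               seed = seed_render, return_components = TRUE)
      if (apply_coupling) {
        comp <- attr(clean, "components")
        rp <- attr(clean, "r_peaks"); rr <- attr(clean, "rr")
        comp <- apply(comp, 2, coupling_filter, fs = fs, circuit = circuit)
        clean <- rowSums(comp)
        attr(clean, "components") <- comp
        attr(clean, "r_peaks") <- rp; attr(clean, "rr") <- rr
      }
      samples <- degrade(clean, quality_specs[[q]], fs, seed = seed_degrade)
      rr <- attr(clean, "rr")
      records[[counter]] <- structure(list(
        record_id = sprintf("rec%03d_%s_%s", counter, q, p),
        samples = as.numeric(samples),
        clean = as.numeric(clean),
        r_peaks = attr(clean, "r_peaks"),
        fs = fs,
        heart_rate_series = 60 / rr,
        truth_intervals = data.frame(
          start_s = 0, end_s = n_samples / fs, quality = q, position = p,
          position_informative = q != "N", stringsAsFactors = FALSE),
        seed = c(root = seed, render = seed_render, degrade = seed_degrade),
        generator_version = GENERATOR_VERSION
      ), class = "cecg_record")
    }
  }
  records
}

#' @export
print.cecg_record <- function(x, ...) {
  iv <- x$truth_intervals
  cat(sprintf("cECG record '%s': %.1f s at %g Hz (%d samples)\n",
              x$record_id, length(x$samples) / x$fs, x$fs, length(x$samples)))
  cat(sprintf("  truth intervals: %d (%s)\n", nrow(iv),
              paste(sprintf("%s/%s %.0f-%.0fs", iv$quality, iv$position,
                            iv$start_s, iv$end_s), collapse = ", ")))
  invisible(x)
}

#' Write a record as CSV samples plus a JSON sidecar
#'
#' The CSV holds one sample per row under a `value` header; the sidecar
#' `<record_id>.json` holds `fs`, seeds, generator version and the truth
#' intervals.
#'
#' @param record a `cecg_record`.
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "cecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(record$record_id, ".csv"))
  js <- file.path(dir, paste0(record$record_id, ".json"))
  write.csv(data.frame(value = record$samples), csv, row.names = FALSE)
  jsonlite::write_json(list(
    record_id = record$record_id, fs = record$fs,
    seed = as.list(record$seed),
    generator_version = record$generator_version,
    truth_intervals = record$truth_intervals
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' Read a record written by [write_record()]
#'
#' @param csv path to the sample CSV; the sidecar is looked up by swapping the
#'   extension for `.json` (annotations optional when `allow_unlabeled`).
#' @param allow_unlabeled permit a missing sidecar (record without truth).
#' @return a `cecg_record` (fields available from disk only).
#' @export
read_record <- function(csv, allow_unlabeled = FALSE) {
  samples <- read.csv(csv)$value
  js <- sub("\\.csv$", ".json", csv)
  if (!file.exists(js)) {
    if (!allow_unlabeled)
      stop_cecg(paste("missing annotation sidecar:", js),
                "cecg_missing_annotation")
    meta <- list(record_id = sub("\\.csv$", "", basename(csv)), fs = NA_real_,
                 truth_intervals = NULL)
  } else {
    meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  }
  structure(list(
    record_id = meta$record_id, samples = as.numeric(samples),
    clean = NULL, r_peaks = NULL,
    fs = meta$fs, heart_rate_series = NULL,
    truth_intervals = meta$truth_intervals,
    seed = unlist(meta$seed), generator_version = meta$generator_version
  ), class = "cecg_record")
}
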