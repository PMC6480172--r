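#' Hierarchical quality-gate / position annotation of a record
#'
#' The end-to-end inference workflow: the record is band-pass filtered,
#' segmented with overlap, z-scored, every segment is labeled C1/C2/N by the
#' quality model, and exactly the segments the quality model calls C1 are
#' passed to the position model for an S/L/R label. Non-C1 segments carry no
#' position. Zero-variance segments (flat lines carry no ECG information) are
#' labeled N by convention and counted in the `n_zero_variance` attribute.
#'
#' @param record a `cecg_record`, or a numeric signal (then `fs` is required).
#' @param qua_model fitted quality classifier (labels C1, C2, N).
#' @param pos_model fitted position classifier (labels S, L, R).
#' @param fs sampling frequency; taken from the record when omitted.
#' @param seg_len_s,overlap_frac segmentation parameters; both models must have
#'   `input_len = round(fs * seg_len_s)`.
#' @param filter a [filter_spec()], or `NULL` to skip filtering.
#' @return an `annotation_track`: a data frame with one row per segment —
#'   `start_s`, `end_s`, `quality`, `p_C1`, `p_C2`, `p_N`, `position` (NA
#'   unless quality is C1), `p_S`, `p_L`, `p_R` — ordered by `start_s`, with
#'   attributes `record_id`, `fs`, `n_zero_variance` and `model_ids`.
#' @export
hierarchical_annotate <- function(record, qua_model, pos_model,
                                  fs = NULL, seg_len_s = 4,
                                  overlap_frac = 0.5,
                                  filter = filter_spec()) {
  stopifnot(inherits(qua_model, "cecg_cnn"), inherits(pos_model, "cecg_cnn"))
  if (inherits(record, "cecg_record")) {
    x <- record$samples
    fs <- record$fs
    record_id <- record$record_id
  } else {
    if (is.null(fs))
      stop_cecg("`fs` is required for a raw signal", "cecg_config_error")
    x <- as.numeric(record)
    record_id <- "record"
  }
  L <- round(fs * seg_len_s)
  if (length(x) < L)
    stop_cecg("record shorter than one segment", "cecg_input_error")
  if (qua_model$spec$input_len != L || pos_model$spec$input_len != L)
    stop_cecg(sprintf(
      "models expect input_len %d / %d but round(fs * seg_len_s) is %d",
      qua_model$spec$input_len, pos_model$spec$input_len, L),
      "cecg_config_error")
  if (!identical(qua_model$label_map, QUALITY_LEVELS))
    stop_cecg("qua_model must be trained on labels C1, C2, N",
              "cecg_config_error")
  if (!identical(sort(pos_model$label_map), sort(POSITION_LEVELS)))
    stop_cecg("pos_model must be trained on labels S, L, R",
              "cecg_config_error")

  sig <- if (is.null(filter)) x else bandpass(x, fs, filter)
  seg <- segment_record(sig, fs, seg_len_s, overlap_frac)
  n_seg <- nrow(seg$samples)
  keep <- logical(n_seg)
  X <- seg$samples
  for (i in seq_len(n_seg)) {
    z <- tryCatch(normalize_segment(X[i, ]),
                  cecg_zero_variance = function(e) NULL)
    if (!is.null(z)) { X[i, ] <- z; keep[i] <- TRUE }
  }
  n_zerovar <- sum(!keep)

  qprob <- matrix(NA_real_, n_seg, 3, dimnames = list(NULL, QUALITY_LEVELS))
  quality <- rep("N", n_seg) # zero-variance convention
  if (any(keep)) {
    qp <- predict(qua_model, X[keep, , drop = FALSE], type = "prob")
    qprob[keep, ] <- qp[, QUALITY_LEVELS]
    quality[keep] <- QUALITY_LEVELS[max.col(qprob[keep, , drop = FALSE],
                                            ties.method = "first")]
  }
  if (any(!keep))
    qprob[!keep, ] <- matrix(c(0, 0, 1), sum(!keep), 3, byrow = TRUE)

  pprob <- matrix(NA_real_, n_seg, 3, dimnames = list(NULL, POSITION_LEVELS))
  position <- rep(NA_character_, n_seg)
  c1 <- which(keep & quality == "C1")
  if (length(c1) > 0) {
    pp <- predict(pos_model, X[c1, , drop = FALSE], type = "prob")
    pprob[c1, ] <- pp[, POSITION_LEVELS]
    position[c1] <- POSITION_LEVELS[max.col(pprob[c1, , drop = FALSE],
                                            ties.method = "first")]
  }

  track <- data.frame(
    start_s = seg$start_index / fs,
    end_s = (seg$start_index + L) / fs,
    quality = factor(quality, levels = QUALITY_LEVELS),
    p_C1 = qprob[, "C1"], p_C2 = qprob[, "C2"], p_N = qprob[, "N"],
    position = factor(position, levels = POSITION_LEVELS),
    p_S = pprob[, "S"], p_L = pprob[, "L"], p_R = pprob[, "R"])
  track <- track[order(track$start_s), ]
  rownames(track) <- NULL
  structure(track,
            record_id = record_id, fs = fs, seg_len_s = seg_len_s,
            overlap_frac = overlap_frac, n_zero_variance = n_zerovar,
            model_ids = c(qua = sprintf("qua_%dblocks", qua_model$spec$n_blocks),
                          pos = sprintf("pos_%dblocks", pos_model$spec$n_blocks)),
            class = c("annotation_track", "data.frame"))
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("Annotation track for '%s': %d segments of %g s (overlap %.0f%%)\n",
              attr(x, "record_id"), nrow(x), attr(x, "seg_len_s"),
              100 * attr(x, "overlap_frac")))
  cat("  quality: "); print(table(x$quality))
  c1 <- x$quality == "C1"
  if (any(c1)) { cat("  position (C1 only): "); print(table(x$position[c1])) }
  if (attr(x, "n_zero_variance") > 0)
    cat(sprintf("  %d zero-variance segments labeled N by convention\n",
                attr(x, "n_zero_variance")))
  invisible(x)
}

#' Write an annotation track as CSV (and optionally JSON)
#' @param track an `annotation_track`.
#' @param csv,json output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_annotation_track <- function(track, csv = NULL, json = NULL) {
  stopifnot(inherits(track, "annotation_track"))
  if (!is.null(csv)) write.csv(as.data.frame(track), csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(record_id = attr(track, "record_id"),
                              fs = attr(track, "fs"),
                              model_ids = as.list(attr(track, "model_ids")),
                              segments = as.data.frame(track)),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' Configuration for a full experiment run
#'
#' Bundles every knob of the study analog: data generation, preprocessing, the
#' depth sweep for both tasks, and final hierarchical annotation.
#'
#' @param total_segments total synthetic segments across the nine
#'   (quality, position) cells, split per [default_cell_counts()].
#' @param fs sampling frequency (Hz).
#' @param seg_lens_s segment lengths to sweep (s).
#' @param depths network depths to sweep.
#' @param overlap_frac segmentation overlap.
#' @param k CV folds.
#' @param train a [train_config()] (its seed is re-derived per fold).
#' @param heart_rate,rr_jitter_sd generator heart-rate parameters.
#' @param seed root seed for everything.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(total_segments = 600, fs = 300,
                              seg_lens_s = 4, depths = 3:8,
                              overlap_frac = 0.5, k = 10,
                              train = train_config(),
                              heart_rate = 70, rr_jitter_sd = 0.04,
                              seed = 1) {
  stopifnot(total_segments >= 9 * k, all(depths %in% 3:8), k >= 2)
  structure(list(total_segments = as.integer(total_segments), fs = fs,
                 seg_lens_s = seg_lens_s, depths = as.integer(depths),
                 overlap_frac = overlap_frac, k = as.integer(k),
                 train = train, heart_rate = heart_rate,
                 rr_jitter_sd = rr_jitter_sd, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full study analog
#'
#' One call reproduces the complete workflow on synthetic data: generate
#' labeled records, preprocess them into segment datasets (one per segment
#' length), sweep network depth for the quality and position tasks with k-fold
#' CV, pick the best depth per task, train final models on the full dataset,
#' and hierarchically annotate a freshly generated held-out record. All
#' artifacts are written under `out_dir` (config.json, data/, models/,
#' reports/, annotations/, log.txt), each referencing the generating seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir run directory (created; pass `NULL` to skip writing).
#' @param verbose print progress.
#' @return an object of class `cecg_experiment`: `reports` (per task),
#'   `best` (best depth per task), `qua_model`, `pos_model`, `track`,
#'   `datasets`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste(format(Sys.time(), "%H:%M:%S"), msg))
    if (verbose) message(msg)
  }

  cells <- default_cell_counts(config$total_segments)
  datasets <- list()
  for (sl in config$seg_lens_s) {
    say("generating %d-segment dataset for %g s windows (seed %d)",
        sum(cells), sl, config$seed)
    recs <- generate_dataset(cells, fs = config$fs, seg_len_s = sl,
                             overlap_frac = config$overlap_frac,
                             heart_rate = config$heart_rate,
                             rr_jitter_sd = config$rr_jitter_sd,
                             seed = config$seed)
    datasets[[as.character(sl)]] <- assemble_dataset(
      recs, seg_len_s = sl, overlap_frac = config$overlap_frac)
  }

  reports <- list()
  for (task in c("quality", "position")) {
    say("depth sweep for task '%s' (depths %s, k = %d)", task,
        paste(config$depths, collapse = ","), config$k)
    reports[[task]] <- cross_validate(datasets, depths = config$depths,
                                      task = task, config = config$train,
                                      k = config$k, seed = config$seed,
                                      verbose = verbose)
  }
  best <- list(quality = reports$quality$best, position = reports$position$best)
  say("best depths: qua_model m = %d, pos_model n = %d",
      best$quality$n_blocks, best$position$n_blocks)

  # final models at the best depth, trained on the full dataset of the best
  # segment length for each task
  fit_final <- function(task) {
    b <- best[[task]]
    ds <- datasets[[as.character(b$seg_len_s)]]
    admit <- if (task == "position")
      which(!is.na(ds$quality) & ds$quality == "C1") else seq_len(nrow(ds$x))
    y <- if (task == "quality") droplevels(ds$quality[admit])
         else droplevels(ds$position[admit])
    spec <- cnn_spec(b$n_blocks, input_len = ncol(ds$x), fs = ds$fs,
                     n_classes = nlevels(y))
    cfg <- config$train
    cfg$seed <- child_seed(config$seed, if (task == "quality") 901L else 902L)
    cnn_fit(spec, ds$x[admit, , drop = FALSE], y, config = cfg)
  }
  say("training final models on the full dataset")
  qua_model <- fit_final("quality")
  pos_model <- fit_final("position")

  # held-out record: one fresh (C1, S) stretch for end-to-end annotation
  sl <- best$quality$seg_len_s
  held_cells <- matrix(0L, 3, 3, dimnames = list(QUALITY_LEVELS, POSITION_LEVELS))
  held_cells["C1", "S"] <- 20L
  held <- generate_dataset(held_cells, fs = config$fs, seg_len_s = sl,
                           overlap_frac = config$overlap_frac,
                           heart_rate = config$heart_rate,
                           rr_jitter_sd = config$rr_jitter_sd,
                           seed = child_seed(config$seed, 903L))[[1]]
  track <- hierarchical_annotate(held, qua_model, pos_model,
                                 seg_len_s = sl,
                                 overlap_frac = config$overlap_frac)

  result <- structure(list(reports = reports, best = best,
                           qua_model = qua_model, pos_model = pos_model,
                           track = track, datasets = datasets,
                           config = config),
                      class = "cecg_experiment")

  if (!is.null(out_dir)) {
    for (d in c("", "data", "models", "reports", "annotations"))
      dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(config)[setdiff(names(unclass(config)), "train")],
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(datasets)) {
      ds <- datasets[[nm]]
      write.csv(data.frame(quality = ds$quality, position = ds$position,
                           record_id = ds$record_id,
                           start_index = ds$start_index),
                file.path(out_dir, "data",
                          sprintf("segments_%ss_manifest.csv", nm)),
                row.names = FALSE)
    }
    save_model(qua_model, file.path(out_dir, "models", "qua_model.rds"))
    save_model(pos_model, file.path(out_dir, "models", "pos_model.rds"))
    for (task in names(reports))
      write_cv_report(reports[[task]],
                      csv = file.path(out_dir, "reports",
                                      sprintf("%s_sweep.csv", task)),
                      json = file.path(out_dir, "reports",
                                       sprintf("%s_sweep.json", task)))
    write_annotation_track(track,
                           csv = file.path(out_dir, "annotations", "track.csv"),
                           json = file.path(out_dir, "annotations", "track.json"))
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  result
}

#' @export
print.cecg_experiment <- function(x, ...) {
  cat("cECG experiment run\n")
  for (task in names(x$reports)) {
    b <- x$best[[task]]
    cat(sprintf("  %s: best depth %d at %g s — weighted precision %.3f, recall %.3f\n",
                task, b$n_blocks, b$seg_len_s, b$weighted_precision,
                b$weighted_recall))
  }
  cat(sprintf("  held-out track: %d segments, %d labeled C1\n",
              nrow(x$track), sum(x$track$quality == "C1")))
  invisible(x)
}
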