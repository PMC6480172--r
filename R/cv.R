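#' Stratified k-fold cross-validation plan
#'
#' Assigns every segment to exactly one test fold. Folds are stratified (by
#' default on the joint quality x position label) so each fold's stratum count
#' is within one of `n_stratum / k`; assignment is deterministic given the
#' seed. Strata smaller than `k` trigger a warning and a best-effort
#' assignment.
#'
#' @param dataset a [assemble_dataset()] result, or a factor/character vector
#'   of stratification labels.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param stratify_on for a `segment_dataset`: label fields to stratify on,
#'   any of `"quality"`, `"position"`.
#' @param inner_val_fraction fraction of each training portion reserved for
#'   epoch-wise validation during training.
#' @return an object of class `cv_plan`: `fold` (integer fold id per segment),
#'   `k`, `seed`, `inner_val_fraction`, `stratified`.
#' @export
make_folds <- function(dataset, k = 10, seed = 1,
                       stratify_on = c("quality", "position"),
                       inner_val_fraction = 0.1) {
  if (inherits(dataset, "segment_dataset")) {
    parts <- lapply(stratify_on, function(f) as.character(dataset[[f]]))
    strata <- do.call(paste, c(parts, sep = ":"))
    n <- nrow(dataset$x)
  } else {
    strata <- as.character(dataset)
    n <- length(strata)
  }
  if (k < 2 || n < k)
    stop_cecg("need n >= k >= 2", "cecg_invalid_parameter")
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < k)
        warning(sprintf("stratum '%s' has %d < k segments; best-effort assignment",
                        s, length(idx)))
      idx <- idx[sample.int(length(idx))]
      ids <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      fold[idx] <- ids
      offset <- offset + length(idx)
    }
  })
  structure(list(fold = fold, k = as.integer(k), seed = as.integer(seed),
                 inner_val_fraction = inner_val_fraction,
                 stratified = TRUE, strata = strata),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("%d-fold CV plan for %d segments (stratified, seed %d)\n",
              x$k, length(x$fold), x$seed))
  print(table(fold = x$fold))
  invisible(x)
}

#' Inject label noise into a training vector
#'
#' Flips a fraction of labels, chosen uniformly at random, to a different class
#' drawn uniformly from the remaining levels. Used for the noise-robustness
#' sanity experiment.
#'
#' @param y factor of labels.
#' @param fraction fraction of labels to corrupt, in `[0, 1]`.
#' @param seed integer seed.
#' @return factor with the same levels.
#' @export
flip_labels <- function(y, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  y <- factor(y)
  if (fraction == 0) return(y)
  with_seed(seed, {
    n_flip <- round(length(y) * fraction)
    idx <- sample(seq_along(y), n_flip)
    lv <- levels(y)
    y[idx] <- vapply(as.character(y[idx]), function(cur)
      sample(setdiff(lv, cur), 1), character(1))
    y
  })
}

#' Cross-validated depth sweep for quality or position models
#'
#' For every network depth (and every supplied segment length) the classifier
#' is trained and tested across the k folds of a stratified CV plan; confusion
#' counts are pooled across folds (every segment is tested exactly once), then
#' summarized per class and as support-weighted averages. For the position
#' task only segments with ground-truth quality C1 are admitted: noise carries
#' no position information and blurred waveforms lose the P/T shape on which
#' position discrimination relies.
#'
#' @param datasets a single `segment_dataset` or a list of them (one per
#'   segment length).
#' @param depths integer vector of block counts to sweep (within 3..8).
#' @param task `"quality"` or `"position"`.
#' @param config a [train_config()]; each fold trains with a child seed derived
#'   from `seed` so folds are independently reproducible.
#' @param k number of folds.
#' @param seed root seed for fold assignment and per-fold training.
#' @param verbose print progress.
#' @return an object of class `cv_report`: `results` (per depth x seg_len x
#'   class data frame), `summary` (weighted metrics per cell), `best` (the
#'   cell maximizing the mean of weighted precision and recall), `task`,
#'   `config`.
#' @export
cross_validate <- function(datasets, depths = 3:8,
                           task = c("quality", "position"),
                           config = train_config(), k = 10, seed = 1,
                           verbose = FALSE) {
  task <- match.arg(task)
  if (inherits(datasets, "segment_dataset")) datasets <- list(datasets)
  results <- list(); summaries <- list()
  for (ds in datasets) {
    admit <- if (task == "position") {
      which(!is.na(ds$quality) & ds$quality == "C1" & !is.na(ds$position))
    } else {
      which(!is.na(ds$quality))
    }
    if (length(admit) == 0)
      stop_cecg(sprintf("no admissible segments for task '%s'", task),
                "cecg_empty_task")
    x <- ds$x[admit, , drop = FALSE]
    y <- if (task == "quality") droplevels(ds$quality[admit])
         else droplevels(ds$position[admit])
    strata <- paste(ds$quality[admit], ds$position[admit], sep = ":")
    plan <- suppressWarnings(make_folds(strata, k = k, seed = seed))
    for (depth in depths) {
      spec <- cnn_spec(depth, input_len = ncol(x), fs = ds$fs,
                       n_classes = nlevels(y))
      pooled_truth <- factor(character(0), levels = levels(y))
      pooled_pred <- factor(character(0), levels = levels(y))
      for (f in seq_len(k)) {
        te <- which(plan$fold == f)
        tr <- which(plan$fold != f)
        cfg <- config
        cfg$seed <- child_seed(seed, depth * 100L + f)
        cfg$val_fraction <- plan$inner_val_fraction
        model <- cnn_fit(spec, x[tr, , drop = FALSE], y[tr], config = cfg)
        pred <- predict(model, x[te, , drop = FALSE], type = "class")
        pooled_truth <- c(pooled_truth, y[te])
        pooled_pred <- c(pooled_pred, pred)
        if (verbose)
          message(sprintf("[%s] seg %gs depth %d fold %d/%d: acc %.3f",
                          task, ds$seg_len_s, depth, f, k,
                          mean(pred == y[te])))
      }
      m <- class_metrics(pooled_truth, pooled_pred, labels = levels(y))
      res <- m$table
      res$task <- task; res$seg_len_s <- ds$seg_len_s; res$n_blocks <- depth
      results[[length(results) + 1L]] <- res
      summaries[[length(summaries) + 1L]] <- data.frame(
        task = task, seg_len_s = ds$seg_len_s, n_blocks = depth,
        weighted_precision = m$weighted_precision,
        weighted_recall = m$weighted_recall,
        accuracy = m$accuracy, n = m$n)
    }
  }
  results <- do.call(rbind, results)
  summary <- do.call(rbind, summaries)
  summary$score <- (summary$weighted_precision + summary$weighted_recall) / 2
  best <- summary[which.max(summary$score), ]
  structure(list(results = results, summary = summary, best = best,
                 task = task, k = k, seed = seed, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("%d-fold CV depth sweep, task '%s'\n", x$k, x$task))
  s <- x$summary
  s$weighted_precision <- round(s$weighted_precision, digits)
  s$weighted_recall <- round(s$weighted_recall, digits)
  s$score <- round(s$score, digits)
  print(s, row.names = FALSE)
  cat(sprintf("best cell: %d blocks at %g s (score %.3f)\n",
              x$best$n_blocks, x$best$seg_len_s, x$best$score))
  invisible(x)
}

#' Bar chart of class-wise precision/recall across depths
#'
#' Mirrors the depth-sweep comparison figures: one group of bars per class,
#' one bar per depth.
#'
#' @param x a [cross_validate()] report.
#' @param metric `"precision"` or `"recall"`.
#' @param ... passed to [barplot()].
#' @export
plot.cv_report <- function(x, metric = c("precision", "recall"), ...) {
  metric <- match.arg(metric)
  r <- x$results
  for (sl in unique(r$seg_len_s)) {
    ri <- r[r$seg_len_s == sl, ]
    m <- tapply(ri[[metric]], list(ri$n_blocks, ri$class), mean)
    barplot(m, beside = TRUE, ylim = c(0, 1),
            legend.text = rownames(m),
            main = sprintf("%s, %g s segments (%s)", x$task, sl, metric),
            xlab = "class", ylab = metric,
            args.legend = list(title = "blocks", x = "bottomright"), ...)
  }
  invisible(x)
}

#' Write a CV report as CSV + JSON
#' @param report a `cv_report`.
#' @param csv,json output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_cv_report <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "cv_report"))
  if (!is.null(csv)) write.csv(report$results, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(summary = report$summary, best = report$best,
                              task = report$task, k = report$k,
                              seed = report$seed),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}
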