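test_that("stratified folds partition 6000 segments into 600-segment folds", {
  # class mix of the default experiment, scaled tenfold
  cells <- default_cell_counts(600) * 10L
  labels <- unlist(mapply(function(q, p, n) rep(paste(q, p), n),
                          rep(rownames(cells), 3),
                          rep(colnames(cells), each = 3),
                          as.vector(cells)))
  plan <- make_folds(labels, k = 10, seed = 1)
  expect_equal(as.integer(table(plan$fold)), rep(600L, 10))
  # partition: disjoint and exhaustive by construction of fold ids
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_length(plan$fold, 6000)
  # stratum balance within +-1
  for (s in unique(labels)) {
    per_fold <- table(plan$fold[labels == s])
    expect_lte(diff(range(per_fold)), 1)
  }
  # determinism
  expect_identical(make_folds(labels, k = 10, seed = 1)$fold, plan$fold)
  expect_false(identical(make_folds(labels, k = 10, seed = 2)$fold, plan$fold))
  expect_warning(make_folds(rep(c("a", "b"), c(30, 3)), k = 5, seed = 1),
                 "best-effort")
  expect_error(make_folds(rep("a", 3), k = 5), class = "cecg_invalid_parameter")
})

test_that("precision and recall follow their confusion-count definitions", {
  # class A: tp = 9, fp = 1, fn = 3
  truth <- c(rep("A", 12), rep("B", 8))
  pred <- c(rep("A", 9), rep("B", 3), "A", rep("B", 7))
  m <- class_metrics(truth, pred)
  a <- m$table[m$table$class == "A", ]
  expect_equal(a$tp, 9L); expect_equal(a$fp, 1L); expect_equal(a$fn, 3L)
  expect_equal(a$precision, 0.9)
  expect_equal(a$recall, 0.75)
  # perfect predictions
  mp <- class_metrics(truth, truth)
  expect_true(all(mp$table$precision == 1))
  expect_true(all(mp$table$recall == 1))
  # collapse onto one class
  mc <- class_metrics(truth, rep("A", 20))
  expect_equal(mc$table$recall[mc$table$class == "A"], 1)
  expect_equal(mc$table$recall[mc$table$class == "B"], 0)
  expect_true(mc$table$zero_predicted[mc$table$class == "B"])
  expect_equal(mc$table$precision[mc$table$class == "B"], 0)
})

test_that("metrics agree with an independent confusion implementation", {
  set.seed(14)
  lv <- c("x", "y", "z")
  for (rep_ in 1:20) {
    n <- 50
    truth <- sample(lv, n, replace = TRUE)
    pred <- sample(lv, n, replace = TRUE)
    m <- class_metrics(truth, pred, labels = lv)
    for (cl in lv) {
      tp <- sum(pred == cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      row <- m$table[m$table$class == cl, ]
      expect_equal(row$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(row$recall, tp / (tp + fn))
    }
    sup <- vapply(lv, function(cl) sum(truth == cl), numeric(1))
    expect_equal(m$weighted_precision,
                 sum(sup / n * m$table$precision))
  }
})

test_that("training separates C1 from N and is seed-deterministic", {
  cells <- matrix(0L, 3, 3, dimnames = list(c("C1", "C2", "N"),
                                            c("S", "L", "R")))
  cells["C1", "S"] <- 60L; cells["N", "S"] <- 60L
  recs <- generate_dataset(cells, seg_len_s = 2, seed = 15)
  ds <- assemble_dataset(recs, seg_len_s = 2)
  keep <- ds$quality %in% c("C1", "N")
  x <- ds$x[keep, ]; y <- droplevels(ds$quality[keep])
  spec <- cnn_spec(3, input_len = 600, fs = 300, n_classes = 2)
  cfg <- train_config(max_epochs = 30, early_stop_patience = 5, seed = 16)
  m <- cnn_fit(spec, x, y, config = cfg)
  expect_gte(max(m$history$train_acc), 0.95)
  # forward pass returns probabilities
  p <- predict(m, x[1:7, ], type = "prob")
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  # determinism: identical seed, identical history
  cfg2 <- train_config(max_epochs = 3, early_stop_patience = 5, seed = 16)
  h1 <- cnn_fit(spec, x, y, config = cfg2)$history
  h2 <- cnn_fit(spec, x, y, config = cfg2)$history
  expect_identical(h1, h2)
  # degenerate configurations are rejected
  expect_error(cnn_fit(spec, x, factor(rep("C1", nrow(x)))),
               class = "cecg_config_error")
  expect_error(cnn_fit(spec, x[, 1:100], y), class = "cecg_input_error")
  expect_error(predict(m, x[, 1:100]), class = "cecg_input_error")
})

test_that("cross-validation sweeps the full depth grid and pools every segment", {
  ds <- tiny_dataset_2s()
  cfg <- train_config(max_epochs = 1, early_stop_patience = 0, seed = 3,
                      val_fraction = 0.1)
  rep_ <- cross_validate(ds, depths = 3:8, task = "quality", config = cfg,
                         k = 2, seed = 3)
  expect_equal(nrow(rep_$summary), 6) # one row per depth
  expect_equal(sort(unique(rep_$results$n_blocks)), 3:8)
  # pooled confusion counts cover the dataset exactly once per depth
  expect_true(all(rep_$summary$n == nrow(ds$x)))
  sup <- tapply(rep_$results$support, rep_$results$n_blocks, sum)
  expect_true(all(sup == nrow(ds$x)))
  expect_s3_class(rep_, "cv_report")

  # position task admits only C1 segments
  repp <- cross_validate(ds, depths = 3, task = "position", config = cfg,
                         k = 2, seed = 3)
  expect_equal(unique(repp$summary$n), sum(ds$quality == "C1"))

  # no C1 segments -> empty-task error
  ds2 <- ds
  ds2$quality[ds2$quality == "C1"] <- "C2"
  expect_error(cross_validate(ds2, depths = 3, task = "position",
                              config = cfg, k = 2),
               class = "cecg_empty_task")
})

test_that("label flipping corrupts the requested fraction", {
  y <- factor(rep(c("S", "L", "R"), each = 50))
  y2 <- flip_labels(y, 0.2, seed = 4)
  expect_equal(sum(y2 != y), 30)
  expect_identical(levels(y2), levels(y))
  expect_identical(flip_labels(y, 0, seed = 4), y)
  expect_identical(flip_labels(y, 0.2, seed = 4), y2)
})
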