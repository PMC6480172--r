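# Shared fixtures, built once per test run and cached. Everything is generated
# in code from fixed seeds; 2 s segments keep the networks small and fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Balanced-ish 2 s dataset covering all nine cells (~180 segments).
tiny_dataset_2s <- function() {
  cached("tiny_ds2", function() {
    cells <- matrix(20L, 3, 3,
                    dimnames = list(c("C1", "C2", "N"), c("S", "L", "R")))
    recs <- generate_dataset(cells, fs = 300, seg_len_s = 2,
                             overlap_frac = 0.5, seed = 11)
    assemble_dataset(recs, seg_len_s = 2, overlap_frac = 0.5)
  })
}

# Well-trained quality and position models for the pipeline tests. 4 s
# segments and a deeper position net: after per-segment z-scoring the supine
# and right-lateral morphologies differ only in the relative P/T shape, which
# needs the longer window (the quality classes are easy at any length).
tiny_models <- function() {
  cached("tiny_models", function() {
    cells <- matrix(20L, 3, 3,
                    dimnames = list(c("C1", "C2", "N"), c("S", "L", "R")))
    cells["C1", ] <- 60L
    recs <- generate_dataset(cells, fs = 300, seg_len_s = 4,
                             overlap_frac = 0.5, seed = 12)
    ds <- assemble_dataset(recs, seg_len_s = 4, overlap_frac = 0.5)
    cfg <- train_config(learning_rate = 2e-3, max_epochs = 25,
                        early_stop_patience = 4, seed = 5)
    qua <- cnn_fit(cnn_spec(3, input_len = 1200, fs = 300, n_classes = 3),
                   ds$x, ds$quality, config = cfg)
    c1 <- which(ds$quality == "C1")
    pos <- cnn_fit(cnn_spec(6, input_len = 1200, fs = 300, n_classes = 3),
                   ds$x[c1, , drop = FALSE], droplevels(ds$position[c1]),
                   config = cfg)
    list(qua = qua, pos = pos)
  })
}

# Hand-built record wrapper for preprocess tests.
make_record <- function(samples, fs, intervals, id = "recX") {
  structure(list(record_id = id, samples = samples, clean = NULL,
                 r_peaks = NULL, fs = fs, heart_rate_series = NULL,
                 truth_intervals = intervals, seed = c(root = 0L),
                 generator_version = "test"),
            class = "cecg_record")
}

# Digital filter gain |B(z)/A(z)|^2 at frequency f, evaluated directly from
# the polynomial coefficients (independent of signal::filtfilt).
butter_gain_sq <- function(bf, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- sum(bf$b * z^(seq_along(bf$b) - 1))
  den <- sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(num / den)^2
}

# Crude local-maximum peak counter used as an oracle for R-peak spacing.
count_peaks <- function(x, min_height) {
  n <- length(x)
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  idx[x[idx] >= min_height]
}
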