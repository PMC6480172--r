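test_that("coupling magnitude matches the RC closed form and its limits", {
  cc <- coupling_circuit(r_cont = 0, r_cloth = 1.5e8, c_cloth = 7e-11)
  # zero-frequency limit: contact resistance + full cloth resistance
  expect_equal(coupling_magnitude(cc, 0), 1.5e8)
  # direct evaluation of the closed form at 10 Hz (computed independently:
  # 1.5e8 / sqrt((2*pi*10*1.5e8*7e-11)^2 + 1) = 1.2521e8)
  expect_equal(coupling_magnitude(cc, 10), 1.2521e8, tolerance = 1e-4)
  # high-frequency limit: only the contact resistance remains
  cc2 <- coupling_circuit(r_cont = 1e3, r_cloth = 1.5e8, c_cloth = 7e-11)
  expect_lt(abs(coupling_magnitude(cc2, 1e12) - 1e3) / 1e3, 1e-3)
})

test_that("coupling magnitude is monotone non-increasing in frequency", {
  cc <- coupling_circuit()
  z <- coupling_magnitude(cc, c(0, 10^seq(-2, 6, by = 0.25)))
  expect_true(all(diff(z) <= 0))
  expect_error(coupling_circuit(r_cloth = -1), class = "cecg_invalid_parameter")
  expect_error(coupling_circuit(c_cloth = 0), class = "cecg_invalid_parameter")
  expect_error(coupling_magnitude(cc, -1), class = "cecg_invalid_parameter")
})

test_that("beat synthesis is deterministic with the R wave at its phase center", {
  tpl <- beat_template()
  beat <- synth_beat(tpl, fs = 300, beat_duration = 1)
  expect_length(beat, 300)
  # R bump centered at phase 0.40 -> sample index 0.40*300 + 1 (1-based)
  expect_equal(which.max(beat), round(tpl$phase_center[3] * 300) + 1)
  expect_identical(beat, synth_beat(tpl, fs = 300, beat_duration = 1))
  # all-zero amplitudes give the zero beat
  zero <- beat_template(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_equal(synth_beat(zero, 300, 1), rep(0, 300))
  # template invariants enforced
  expect_error(beat_template(amplitude = c(P = 2, Q = 0, R = 1, S = 0, T = 0)),
               class = "cecg_invalid_template")
  expect_error(beat_template(phase_center = c(P = 0.5, Q = 0.4, R = 0.6,
                                              S = 0.7, T = 0.8)),
               class = "cecg_invalid_template")
  expect_error(synth_beat(tpl, fs = 4, beat_duration = 1),
               class = "cecg_invalid_parameter")
})

test_that("a 60 bpm render has exactly 10 equally spaced R peaks in 10 s", {
  tpl <- beat_template()
  x <- render_position(tpl, position_profile("S"), fs = 300, duration = 10,
                       heart_rate = 60, rr_jitter_sd = 0)
  pk <- count_peaks(x, 0.6 * max(x))
  expect_length(pk, 10)
  expect_equal(diff(pk), rep(300, 9))
})

test_that("position rendering obeys the projection geometry", {
  tpl <- beat_template()
  pr <- default_position_profiles()
  sig <- lapply(pr, function(p)
    render_position(tpl, p, fs = 300, duration = 8, heart_rate = 72,
                    rr_jitter_sd = 0))
  ptp <- vapply(sig, function(s) diff(range(s)), numeric(1))
  # left lateral has the smallest projection
  expect_lt(ptp[["L"]], ptp[["S"]])
  expect_lt(ptp[["L"]], ptp[["R"]])
  # polarity flips negate the signal exactly
  up <- render_position(tpl, position_profile("S", polarity = 1), 300, 5,
                        heart_rate = 60, rr_jitter_sd = 0)
  dn <- render_position(tpl, position_profile("S", polarity = -1), 300, 5,
                        heart_rate = 60, rr_jitter_sd = 0)
  expect_equal(as.numeric(up), -as.numeric(dn))
  expect_error(position_profile("X"), class = "cecg_invalid_label")
  expect_error(render_position(tpl, pr$S, 300, 5, heart_rate = 10),
               class = "cecg_invalid_parameter")
})

test_that("amplitude ordering L < S and L < R holds across 100 seeded draws", {
  tpl <- beat_template()
  pr <- default_position_profiles()
  for (seed in 1:100) {
    hr <- 50 + (seed %% 40)
    s <- vapply(pr, function(p) {
      x <- render_position(tpl, p, fs = 300, duration = 4, heart_rate = hr,
                           rr_jitter_sd = 0.05, seed = seed)
      diff(range(x))
    }, numeric(1))
    expect_lt(s[["L"]], min(s[["S"]], s[["R"]]))
  }
})

test_that("degradation respects the identity case and is seed-reproducible", {
  x <- sin(2 * pi * (1:900) / 300)
  none <- quality_spec("C1", broadband_noise_sd = 0,
                       baseline_wander = c(0, 0.3), artifact_burst = c(0, 0),
                       waveform_attenuation = c(P = 1, Q = 1, R = 1, S = 1, T = 1))
  expect_identical(degrade(x, none, fs = 300, seed = 3), x)
  spec <- quality_spec("C2")
  d1 <- degrade(x, spec, fs = 300, seed = 9)
  d2 <- degrade(x, spec, fs = 300, seed = 9)
  expect_identical(d1, d2)
  expect_false(identical(d1, degrade(x, spec, fs = 300, seed = 10)))
  expect_error(quality_spec("C1", broadband_noise_sd = -1),
               class = "cecg_invalid_parameter")
  expect_error(degrade(c(1, NA), quality_spec("C1"), 300),
               class = "cecg_invalid_signal")
})

test_that("C2 keeps the R wave but damps P/T; N buries the waveform", {
  tpl <- beat_template()
  clean <- render_position(tpl, position_profile("S"), fs = 300, duration = 20,
                           heart_rate = 66, rr_jitter_sd = 0.03, seed = 21,
                           return_components = TRUE)
  comp <- attr(clean, "components")
  rp <- attr(clean, "r_peaks")
  d2 <- degrade(clean, quality_spec("C2"), fs = 300, seed = 22)
  # cross-correlation with the clean signal around true R instants stays
  # above half the clean autocorrelation
  win <- -15:15
  idx <- unlist(lapply(round(rp * 300) + 1, function(i) i + win))
  idx <- idx[idx >= 1 & idx <= length(clean)]
  expect_gt(sum(d2[idx] * clean[idx]) / sum(clean[idx]^2), 0.5)
  # the per-wave attenuation itself, isolated from the additive noise terms:
  # P/T energy drops to the squared attenuation while R is untouched
  att_only <- quality_spec("C2", broadband_noise_sd = 0,
                           baseline_wander = c(0, 0.33),
                           artifact_burst = c(0, 0))
  da <- degrade(clean, att_only, fs = 300, seed = 22)
  pt <- comp[, "P"] + comp[, "T"]
  expect_equal(sum(da * pt) / sum(pt^2), 0.35, tolerance = 0.05)
  expect_equal(sum(da * comp[, "R"]) / sum(comp[, "R"]^2), 1, tolerance = 0.05)
  # N: less than half the variance is explained by the clean component
  dn <- degrade(clean, quality_spec("N"), fs = 300, seed = 23)
  expect_lt(cor(dn, as.numeric(clean))^2, 0.5)
  # C1: degradation adds less than 10% of the clean energy, even for the
  # weakest (left lateral) projection
  cl <- render_position(tpl, position_profile("L"), fs = 300, duration = 20,
                        heart_rate = 66, rr_jitter_sd = 0.03, seed = 24)
  d1 <- degrade(cl, quality_spec("C1"), fs = 300, seed = 25)
  expect_lt(mean((d1 - cl)^2) / mean(cl^2), 0.10)
})

test_that("generated datasets hit the requested cell counts exactly", {
  cells <- matrix(0L, 3, 3, dimnames = list(c("C1", "C2", "N"),
                                            c("S", "L", "R")))
  cells["C1", "S"] <- 10L
  recs <- generate_dataset(cells, seg_len_s = 2, seed = 4)
  expect_length(recs, 1)
  iv <- recs[[1]]$truth_intervals
  expect_equal(iv$quality, "C1")
  expect_equal(iv$position, "S")
  ds <- assemble_dataset(recs, seg_len_s = 2)
  expect_equal(unname(ds$class_counts["C1", "S"]), 10L)

  ds2 <- tiny_dataset_2s()
  expect_true(all(ds2$class_counts == 20L))
  expect_equal(ds2$n_straddling, 0L)

  expect_error(generate_dataset(matrix(0L, 3, 3)),
               class = "cecg_invalid_parameter")
  big <- matrix(0L, 3, 3); big[1, 1] <- 100000L
  expect_error(generate_dataset(big, max_record_s = 60),
               class = "cecg_capacity_error")
})

test_that("the generator is bitwise reproducible from (seed, config)", {
  cells <- default_cell_counts(45)
  a <- generate_dataset(cells, seg_len_s = 2, seed = 77)
  b <- generate_dataset(cells, seg_len_s = 2, seed = 77)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  c_ <- generate_dataset(cells, seg_len_s = 2, seed = 78)
  expect_false(identical(a[[1]]$samples, c_[[1]]$samples))
  # N intervals keep a position label but are flagged uninformative
  nrec <- Filter(function(r) r$truth_intervals$quality == "N", a)
  expect_true(all(vapply(nrec, function(r)
    !r$truth_intervals$position_informative, logical(1))))
  expect_true(all(vapply(nrec, function(r)
    r$truth_intervals$position %in% c("S", "L", "R"), logical(1))))
})

test_that("a ground-truth SNR threshold separates C1 from N completely", {
  cells <- default_cell_counts(90)
  recs <- generate_dataset(cells, seg_len_s = 2, seed = 31)
  snr <- list(C1 = numeric(0), C2 = numeric(0), N = numeric(0))
  for (r in recs) {
    q <- r$truth_intervals$quality
    sc <- segment_record(r$clean, r$fs, 2, 0.5)
    sd_ <- segment_record(r$samples, r$fs, 2, 0.5)
    vals <- vapply(seq_along(sc$start_index), function(i)
      segment_snr(sc$samples[i, ], sd_$samples[i, ]), numeric(1))
    snr[[q]] <- c(snr[[q]], vals)
  }
  expect_gt(min(snr$C1), max(snr$N)) # a threshold in between is 100% accurate
})

test_that("records round-trip through the CSV + JSON sidecar format", {
  dir <- withr::local_tempdir()
  rec <- generate_dataset(default_cell_counts(18), seg_len_s = 2,
                          seed = 13)[[1]]
  paths <- write_record(rec, dir)
  back <- read_record(paths[["csv"]])
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$truth_intervals$quality, rec$truth_intervals$quality)
  file.remove(paths[["json"]])
  expect_error(read_record(paths[["csv"]]), class = "cecg_missing_annotation")
  expect_silent(read_record(paths[["csv"]], allow_unlabeled = TRUE))
})
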