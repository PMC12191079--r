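test_that("feature generator bookkeeping matches the spec layout", {
  spec <- synthetic_spec(n_subjects = 5L, n_classes = 3L,
                         n_trials_per_class = 2L,
                         n_segments_per_trial = 10L)
  # 5 subjects x (3 classes x 2 trials) x 10 segments = 300 rows
  ft <- generate_features(spec)
  expect_identical(dim(ft$values), c(300L, 62L, 5L))
  expect_identical(sort(unique(ft$labels)), 1:3)
  expect_identical(sort(unique(ft$subject_id)), 1:5)
  expect_equal(as.vector(table(ft$labels)), rep(100L, 3L),
               ignore_attr = TRUE)
  # classes cycle through trials so early trials are class-balanced
  first3 <- unique(cbind(ft$trial_id, ft$labels))[1:3, ]
  expect_identical(sort(first3[, 2L]), 1:3)
  # deterministic under the seed
  expect_identical(generate_features(spec)$values, ft$values)
})

test_that("generator moments match the spec at Monte-Carlo scale", {
  spec <- synthetic_spec(n_subjects = 1L, n_trials_per_class = 10L,
                         n_segments_per_trial = 10L, E = 10L, F = 2L,
                         effect_channels = c(1L, 4L), effect_bands = 1L,
                         effect_size = 0, noise_sd = 2,
                         subject_gain_sd = 0, subject_offset_sd = 0,
                         seed = 123L)
  ft <- generate_features(spec)
  vals <- as.vector(ft$values)  # 300 x 10 x 2 = 6000 draws
  expect_lt(abs(mean(vals)), 4 * 2 / sqrt(length(vals)))
  expect_equal(stats::sd(vals), 2, tolerance = 0.1)
})

test_that("null effect is statistically invisible; strong effect separable", {
  # effect 0 -> two-sample t between classes stays small
  spec0 <- synthetic_spec(n_subjects = 2L, n_trials_per_class = 10L,
                          n_segments_per_trial = 25L, E = 8L, F = 2L,
                          effect_channels = c(2L, 5L), effect_bands = 2L,
                          effect_size = 0, subject_gain_sd = 0,
                          subject_offset_sd = 0, seed = 42L)
  ft0 <- generate_features(spec0)
  x <- ft0$values[, 2L, 2L]
  tt <- stats::t.test(x[ft0$labels == 1L], x[ft0$labels == 2L])
  expect_lt(abs(tt$statistic), 4)
  # effect 5 -> nearest-centroid oracle separates classes essentially
  # perfectly (Bayes accuracy ~ 100% at this SNR)
  spec5 <- synthetic_spec(n_subjects = 2L, n_trials_per_class = 5L,
                          n_segments_per_trial = 20L, E = 8L, F = 2L,
                          effect_channels = c(2L, 5L, 7L), effect_bands = 2L,
                          effect_size = 5, noise_sd = 1,
                          subject_gain_sd = 0, subject_offset_sd = 0,
                          seed = 42L)
  ft5 <- generate_features(spec5)
  flat <- matrix(ft5$values, dim(ft5$values)[1L])
  n_cl <- length(unique(ft5$labels))
  centro <- rowsum(flat, ft5$labels) / as.vector(table(ft5$labels))
  d <- as.matrix(stats::dist(rbind(centro, flat)))[-(seq_len(n_cl)),
                                                   seq_len(n_cl)]
  expect_gte(mean(max.col(-d) == ft5$labels), 0.99)
})

test_that("subject shift applies per-subject affine distortions", {
  spec <- synthetic_spec(n_subjects = 6L, n_trials_per_class = 2L,
                         n_segments_per_trial = 20L, E = 6L, F = 2L,
                         effect_channels = 1L, effect_bands = 1L,
                         effect_size = 0, noise_sd = 1,
                         subject_gain_sd = 0.5, subject_offset_sd = 2,
                         seed = 77L)
  ft <- generate_features(spec)
  means <- tapply(as.vector(ft$values[, 3L, 1L]),
                  ft$subject_id[seq_len(dim(ft$values)[1L])], mean)
  sds <- tapply(as.vector(ft$values[, 3L, 1L]),
                ft$subject_id[seq_len(dim(ft$values)[1L])], stats::sd)
  # offsets spread the subject means; gains spread the subject scales
  expect_gt(stats::sd(means), 0.5)
  expect_gt(max(sds) / min(sds), 1.3)
})

test_that("raw-signal generator recovers injected band structure", {
  spec <- synthetic_spec(n_subjects = 1L, n_trials_per_class = 1L,
                         n_segments_per_trial = 8L, E = 6L, F = 5L,
                         effect_channels = 2L, effect_bands = 3L,
                         effect_size = 0, noise_sd = 0.1,
                         band_amplitudes = c(1, 1, 10, 1, 1),
                         subject_gain_sd = 0,
                         seed = 55L, mode = "raw_signal")
  recs <- generate_raw(spec)
  expect_length(recs, 3L)  # 3 classes x 1 trial
  rec <- recs[[1L]]$recording
  expect_identical(dim(rec$signal), c(6L, 1600L))
  # alpha amplitude 10x others -> alpha is the max PSD column everywhere
  ps <- psd_feature(rec$signal, fs = spec$fs)
  expect_true(all(max.col(ps) == 3L))
  # DE/PSD extracted end-to-end keep the band ordering
  ft <- extract_features(rec, montage(paste0("C", 1:6)), kind = "psd",
                         do_preprocess = FALSE)
  expect_identical(dim(ft$values), c(8L, 6L, 5L))
  # zero-amplitude, zero-noise spec triggers the DE variance guard
  spec0 <- synthetic_spec(n_subjects = 1L, n_trials_per_class = 1L,
                          n_segments_per_trial = 2L, E = 3L,
                          effect_size = 0, noise_sd = 0,
                          band_amplitudes = rep(0, 5L),
                          effect_channels = 1L,
                          subject_gain_sd = 0, seed = 1L,
                          mode = "raw_signal")
  recs0 <- generate_raw(spec0)
  expect_error(de_feature(recs0[[1L]]$recording$signal, fs = 200),
               "zero-variance")
  # seed-fixed calls are identical
  expect_identical(generate_raw(spec)[[2L]]$recording$signal,
                   recs[[2L]]$recording$signal)
})
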