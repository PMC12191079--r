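make_toy_dataset <- function(n_subjects = 3L, n_classes = 3L,
                             effect = 5, seed = 7) {
  spec <- synthetic_spec(n_subjects = n_subjects, n_trials_per_class = 2L,
                         n_segments_per_trial = 4L, n_classes = n_classes,
                         E = 8L, F = 3L, effect_channels = c(2L, 5L, 7L),
                         effect_bands = c(2L, 3L), effect_size = effect,
                         subject_gain_sd = 0, subject_offset_sd = 0,
                         noise_sd = 1, seed = seed)
  generate_features(spec)
}

test_that("split plans respect both protocols and never leak", {
  subj <- rep(1:15, each = 12L)
  trial <- rep(rep(1:15, each = 4L), times = 3L)[seq_along(subj)]
  # LOSO: 15 folds, each test set one subject, train sets of 14 subjects
  plan <- make_splits(subj, trial, "loso")
  expect_length(plan$folds, 15L)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(unique(subj[f$test]), 1L)
    expect_length(unique(subj[f$train]), 14L)
  }
  expect_setequal(unlist(lapply(plan$folds, function(f) unique(subj[f$test]))),
                  1:15)
  # subject-dependent: first 9 trials train, remaining 6 test, per subject
  subj2 <- rep(1:2, each = 30L)
  trial2 <- rep(rep(1:15, each = 2L), times = 2L)
  plan2 <- make_splits(subj2, trial2, "subject_dependent")
  expect_length(plan2$folds, 2L)
  for (f in plan2$folds) {
    expect_length(intersect(unique(trial2[f$train]),
                            unique(trial2[f$test])), 0L)
    expect_identical(sort(unique(trial2[f$train])), 1:9)
    expect_identical(sort(unique(trial2[f$test])), 10:15)
  }
  # 2 subjects LOSO -> 2 symmetric folds; < 2 subjects errors
  plan3 <- make_splits(rep(1:2, each = 3L), rep(1:3, 2L), "loso")
  expect_length(plan3$folds, 2L)
  expect_identical(plan3$folds[[1L]]$train, plan3$folds[[2L]]$test)
  expect_error(make_splits(rep(1L, 6L), rep(1:6), "loso"), "2 subjects")
})

test_that("evaluation metrics match brute-force recounts", {
  ft <- make_toy_dataset()
  fit <- train_model(ft, train_cfg = train_config(epochs = 2L,
                                                  batch_size = 16L))
  ev <- evaluate_model(fit, ft)
  pred <- predict(fit, ft$values)
  expect_equal(ev$accuracy, 100 * mean(pred == ft$labels))
  expect_equal(rowSums(ev$confusion), rep(100, 3), tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(sum(ev$counts), length(ft$labels))
  expect_error(evaluate_model(fit, list(x = ft$values[0, , , drop = FALSE],
                                        y = integer(0))), "empty")
  # report aggregation: {80, 90} -> mean 85, population sd 5
  r1 <- list(accuracy = 80, counts = matrix(c(8, 2, 0, 10), 2))
  r2 <- list(accuracy = 90, counts = matrix(c(9, 1, 0, 10), 2))
  rep <- eval_report(list(r1, r2))
  expect_equal(rep$mean_accuracy, 85)
  expect_equal(rep$sd_accuracy, 5)
})

test_that("training is deterministic under a fixed seed", {
  ft <- make_toy_dataset()
  tc <- train_config(epochs = 3L, batch_size = 16L, seed = 100L)
  f1 <- train_model(ft, train_cfg = tc)
  f2 <- train_model(ft, train_cfg = tc)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  f3 <- train_model(ft, train_cfg = train_config(epochs = 3L,
                                                 batch_size = 16L,
                                                 seed = 101L))
  expect_false(identical(f1$params, f3$params))
})

test_that("separable features are learned; standardization stats are fold-local", {
  ft <- make_toy_dataset(effect = 5)
  fit <- train_model(ft, train_cfg = train_config(epochs = 30L,
                                                  batch_size = 16L))
  expect_gte(utils::tail(fit$history$train_acc, 1L), 99)
  # logistic-oracle sanity: the same data is linearly separable
  flat <- matrix(ft$values, dim(ft$values)[1L])
  centro <- rowsum(flat, ft$labels) / as.vector(table(ft$labels))
  d <- as.matrix(stats::dist(rbind(centro, flat)))[-(1:3), 1:3]
  expect_gte(mean(max.col(-d) == ft$labels), 0.99)
  # standardization statistics come from the training data only
  expect_equal(dim(fit$stand$mu), c(8L, 3L))
})

test_that("domain branch trains under both schemes", {
  ft <- make_toy_dataset(n_subjects = 3L)
  tgt <- generate_features(synthetic_spec(
    n_subjects = 1L, n_trials_per_class = 2L, n_segments_per_trial = 4L,
    E = 8L, F = 3L, effect_channels = c(2L, 5L, 7L),
    effect_bands = c(2L, 3L), effect_size = 5,
    subject_gain_sd = 0.5, subject_offset_sd = 1, seed = 9))
  tc <- train_config(epochs = 2L, batch_size = 16L)
  fit <- train_model(ft, train_cfg = tc,
                     adapt_cfg = grl_config(enabled = TRUE),
                     target_x = tgt$values)
  expect_true(all(fit$history$domain_loss > 0))
  expect_identical(ncol(fit$domain_params$W2), 2L)
  fit2 <- train_model(ft, train_cfg = tc,
                      adapt_cfg = grl_config(enabled = TRUE,
                                             scheme = "per_subject"))
  expect_identical(ncol(fit2$domain_params$W2), 3L)
  expect_error(train_model(ft, train_cfg = tc,
                           adapt_cfg = grl_config(enabled = TRUE)),
               "target_x")
})

test_that("ablation suite produces the four-variant table", {
  ft <- make_toy_dataset(n_subjects = 2L)
  ab <- run_ablation(ft, seeds = 100L, protocol = "loso",
                     train_cfg = train_config(epochs = 1L,
                                              batch_size = 16L))
  expect_setequal(unique(ab$table$variant),
                  c("full", "no_attention_conv", "no_global_attention",
                    "no_grl"))
  expect_identical(nrow(ab$table), 4L)
  expect_identical(nrow(ab$summary), 4L)
})

test_that("sum pooling equals the oracle node sum", {
  set.seed(13)
  cfg <- tiny_config(E = 4L, F_in = 3L, pooling = "sum")
  p <- init_model_params(cfg)
  X <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  fwd <- model_forward(p, X, cfg)
  for (b in 1:2) {
    expect_equal(fwd$flat[b, ], colSums(fwd$Z[b, , ]), tolerance = 1e-10)
  }
})

test_that("attention export produces one matrix per layer plus beta", {
  ft <- make_toy_dataset()
  fit <- train_model(ft, train_cfg = train_config(epochs = 1L,
                                                  batch_size = 16L))
  ex <- export_attention_weights(fit, ft$values,
                                 electrode_labels = letters[1:8])
  expect_length(ex$adjacency, 2L)
  expect_identical(dim(ex$adjacency[[1L]]), c(8L, 8L))
  expect_equal(sum(ex$beta), 1, tolerance = 1e-8)
  expect_identical(names(ex$beta), letters[1:8])
})
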