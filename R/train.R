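#' Training configuration
#'
#' Reference optimization settings: Adam, batch size 64, 40 epochs,
#' learning rate 0.01, cross-entropy loss, seed 100. Evaluation batches
#' use the same size as training batches.
#'
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed governing initialization and shuffling.
#' @param standardize z-score each (electrode, band) feature using
#'   training-fold statistics only (`"per_fold_zscore"` behavior);
#'   `FALSE` disables.
#' @param verbose print per-epoch progress lines.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, epochs = 40L, lr = 0.01,
                         seed = 100L, standardize = TRUE,
                         verbose = FALSE) {
  stopifnot(batch_size >= 1L, epochs >= 1L, lr > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed), standardize = standardize,
                 verbose = verbose),
            class = "train_config")
}

# pull (x, y, subject, trial) out of a feature_tensor or plain list
as_dataset <- function(data) {
  if (inherits(data, "feature_tensor")) {
    list(x = data$values, y = data$labels, subject = data$subject_id,
         trial = data$trial_id)
  } else {
    stopifnot(is.list(data), !is.null(data$x), !is.null(data$y))
    list(x = data$x, y = data$y,
         subject = data$subject %||% rep(1L, length(data$y)),
         trial = data$trial %||% rep(1L, length(data$y)))
  }
}

# per-(electrode, band) z-scoring statistics from training data
standardize_stats <- function(x) {
  d <- dim(x)
  mu <- apply(x, c(2L, 3L), mean)
  sd <- apply(x, c(2L, 3L), stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

apply_standardize <- function(x, stats) {
  d <- dim(x)
  sweep(sweep(x, c(2L, 3L), stats$mu, "-"), c(2L, 3L), stats$sd, "/")
}

#' Build cross-validation splits
#'
#' Leave-one-subject-out: one fold per subject, testing on that subject's
#' segments and training on everyone else's. Subject-dependent: one fold
#' per subject, training on each subject's first `n_train_trials` trials
#' (in trial order) and testing on the remainder.
#'
#' @param subject per-segment subject identifiers.
#' @param trial per-segment trial identifiers.
#' @param protocol `"loso"` or `"subject_dependent"`.
#' @param n_train_trials training trials per subject for the
#'   subject-dependent protocol (reference split: first 9 of 15).
#' @return object of class `split_plan`: list of folds, each with `train`
#'   and `test` segment indices and a `description`.
#' @export
make_splits <- function(subject, trial,
                        protocol = c("loso", "subject_dependent"),
                        n_train_trials = 9L) {
  protocol <- match.arg(protocol)
  stopifnot(length(subject) == length(trial))
  subjects <- sort(unique(subject))
  folds <- list()
  if (protocol == "loso") {
    if (length(subjects) < 2L) {
      stop("LOSO requires at least 2 subjects")
    }
    for (s in subjects) {
      folds[[length(folds) + 1L]] <- list(
        train = which(subject != s), test = which(subject == s),
        description = paste0("test subject ", s))
    }
  } else {
    for (s in subjects) {
      idx <- which(subject == s)
      trials <- unique(trial[idx])  # preserves first-appearance order
      if (length(trials) <= n_train_trials) {
        stop("subject ", s, " has ", length(trials),
             " trials; need more than ", n_train_trials)
      }
      tr <- trials[seq_len(n_train_trials)]
      folds[[length(folds) + 1L]] <- list(
        train = idx[trial[idx] %in% tr],
        test = idx[!trial[idx] %in% tr],
        description = paste0("subject ", s, ": first ", n_train_trials,
                             " trials train"))
    }
  }
  structure(list(protocol = protocol, folds = folds), class = "split_plan")
}

#' Train the model
#'
#' Mini-batch Adam optimization of the cross-entropy emotion loss, plus
#' (when adaptation is enabled) the adversarial domain loss routed
#' through the gradient reversal layer. Deterministic given the seed.
#'
#' @param data a [feature_tensor()] or list with `x` (N x E x F array),
#'   `y` (labels), and optional `subject`.
#' @param model_cfg a [model_config()]; `E`, `F_in` and `n_classes` are
#'   overridden from the data when they disagree.
#' @param train_cfg a [train_config()].
#' @param adapt_cfg a [grl_config()]; when enabled with the
#'   binary scheme, `target_x` supplies the unlabeled target-domain
#'   feature array.
#' @param target_x unlabeled N_t x E x F array from the target domain
#'   (e.g. the held-out subject), used only by the domain branch.
#' @return object of class `eegatt_fit` with elements `params`,
#'   `domain_params`, `history` (per-epoch data frame), the configs, the
#'   standardization statistics and the class level mapping.
#' @export
train_model <- function(data, model_cfg = NULL, train_cfg = train_config(),
                        adapt_cfg = grl_config(enabled = FALSE),
                        target_x = NULL) {
  ds <- as_dataset(data)
  x <- ds$x
  n <- dim(x)[1L]
  class_levels <- sort(unique(ds$y))
  y <- match(ds$y, class_levels)
  if (is.null(model_cfg)) model_cfg <- model_config()
  if (model_cfg$E != dim(x)[2L] || model_cfg$F_in != dim(x)[3L] ||
      model_cfg$n_classes != length(class_levels)) {
    model_cfg <- model_config(
      E = dim(x)[2L], F_in = dim(x)[3L],
      layer_dims = model_cfg$layer_dims,
      classifier_dims = model_cfg$classifier_dims,
      n_classes = length(class_levels),
      activation = model_cfg$activation, pooling = model_cfg$pooling,
      conv = model_cfg$conv, gcn_k = model_cfg$gcn_k)
  }
  set.seed(train_cfg$seed)
  stats <- if (train_cfg$standardize) standardize_stats(x) else NULL
  if (!is.null(stats)) {
    x <- apply_standardize(x, stats)
    if (!is.null(target_x)) target_x <- apply_standardize(target_x, stats)
  }
  params <- init_model_params(model_cfg)
  use_domain <- isTRUE(adapt_cfg$enabled)
  domain_params <- NULL
  dom_state <- NULL
  n_domains <- 0L
  subj_levels <- sort(unique(ds$subject))
  if (use_domain) {
    if (adapt_cfg$scheme == "binary_source_target") {
      if (is.null(target_x)) {
        stop("binary domain scheme needs target_x (unlabeled target data)")
      }
      n_domains <- 2L
    } else {
      n_domains <- length(subj_levels)
      if (n_domains < 2L) stop("per_subject scheme needs >= 2 subjects")
    }
    domain_params <- init_domain_params(model_cfg$head_in, n_domains)
    dom_state <- adam_init(domain_params)
  }
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        domain_loss = numeric(0), train_acc = numeric(0))
  tgt_perm <- if (use_domain && !is.null(target_x)) {
    sample(dim(target_x)[1L])
  } else NULL
  tgt_ptr <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    perm <- sample(n)
    starts <- seq.int(1L, n, by = train_cfg$batch_size)
    ep_loss <- 0; ep_dloss <- 0; ep_correct <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + train_cfg$batch_size - 1L, n)]
      xb <- x[idx, , , drop = FALSE]
      yb <- y[idx]
      fwd <- model_forward(params, xb, model_cfg, keep_cache = TRUE)
      ce <- ce_loss_grad(fwd$probs, yb)
      dflat_extra <- NULL
      grads_extra <- NULL
      dloss <- 0
      if (use_domain) {
        if (adapt_cfg$scheme == "binary_source_target") {
          nt <- min(length(idx), dim(target_x)[1L])
          ti <- integer(nt)
          for (k in seq_len(nt)) {
            tgt_ptr <- tgt_ptr %% length(tgt_perm) + 1L
            ti[k] <- tgt_perm[tgt_ptr]
          }
          xt <- target_x[ti, , , drop = FALSE]
          fwd_t <- model_forward(params, xt, model_cfg, keep_cache = TRUE)
          dom_in <- grl_forward(rbind(fwd$flat, fwd_t$flat), adapt_cfg)
          d_labels <- c(rep(1L, length(idx)), rep(2L, nt))
        } else {
          fwd_t <- NULL
          dom_in <- grl_forward(fwd$flat, adapt_cfg)
          d_labels <- match(ds$subject[idx], subj_levels)
        }
        dc <- domain_classify(dom_in, domain_params, train = TRUE)
        dn <- domain_nll(dc, d_labels)
        dloss <- dn$loss
        db <- domain_backward(domain_params, dc, dn$dlogits)
        dflat_all <- grl_backward(db$dX, adapt_cfg)
        dflat_extra <- dflat_all[seq_along(idx), , drop = FALSE]
        if (!is.null(fwd_t)) {
          dflat_t <- dflat_all[-seq_along(idx), , drop = FALSE]
          bt <- model_backward(params, model_cfg, fwd_t,
                               dlogits = NULL, dflat_extra = dflat_t)
          grads_extra <- bt$grads
        }
        upd_d <- adam_step(domain_params, db$grads, dom_state,
                           lr = train_cfg$lr)
        run <- attr(domain_params, "running")
        domain_params <- upd_d$params
        attr(domain_params, "running") <- run
        dom_state <- upd_d$state
      }
      bk <- model_backward(params, model_cfg, fwd, dlogits = ce$dlogits,
                           dflat_extra = dflat_extra)
      grads <- tree_add(bk$grads, grads_extra)
      if (!is.finite(ce$loss) || !is.finite(dloss)) {
        stop(sprintf("non-finite loss at epoch %d (emotion %g, domain %g)",
                     epoch, ce$loss, dloss))
      }
      upd <- adam_step(params, grads, state, lr = train_cfg$lr)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + ce$loss * length(idx)
      ep_dloss <- ep_dloss + dloss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs, ties.method = "first") == yb)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss / n, domain_loss = ep_dloss / n,
      train_acc = 100 * ep_correct / n))
    if (train_cfg$verbose) {
      message(sprintf("epoch %3d  loss %.4f  domain %.4f  acc %.1f%%",
                      epoch, ep_loss / n, ep_dloss / n,
                      100 * ep_correct / n))
    }
  }
  structure(list(params = params, domain_params = domain_params,
                 model_cfg = model_cfg, train_cfg = train_cfg,
                 adapt_cfg = adapt_cfg, stand = stats,
                 class_levels = class_levels, history = history),
            class = "eegatt_fit")
}

#' @export
print.eegatt_fit <- function(x, ...) {
  cat(sprintf(
    "<eegatt_fit> %d-class, %d electrodes, %d layers, %s pooling, %s conv; %d parameters\n",
    x$model_cfg$n_classes, x$model_cfg$E, length(x$model_cfg$layer_dims),
    x$model_cfg$pooling, x$model_cfg$conv, count_params(x$params)))
  cat(sprintf("  final train accuracy %.1f%% after %d epochs\n",
              utils::tail(x$history$train_acc, 1L), nrow(x$history)))
  invisible(x)
}

#' Predict emotion classes or probabilities
#'
#' @param object an `eegatt_fit`.
#' @param x N x E x F feature array (raw scale; standardization from the
#'   training fold is applied internally).
#' @param type `"class"` or `"prob"`.
#' @param batch_size evaluation batch size; defaults to the training
#'   batch size.
#' @param ... unused.
#' @export
predict.eegatt_fit <- function(object, x, type = c("class", "prob"),
                               batch_size = NULL, ...) {
  type <- match.arg(type)
  if (inherits(x, "feature_tensor")) x <- x$values
  if (!is.null(object$stand)) x <- apply_standardize(x, object$stand)
  n <- dim(x)[1L]
  bs <- batch_size %||% object$train_cfg$batch_size
  probs <- matrix(0, n, object$model_cfg$n_classes)
  for (s in seq.int(1L, n, by = bs)) {
    idx <- s:min(s + bs - 1L, n)
    fwd <- model_forward(object$params, x[idx, , , drop = FALSE],
                         object$model_cfg)
    probs[idx, ] <- fwd$probs
  }
  if (type == "prob") return(probs)
  object$class_levels[max.col(probs, ties.method = "first")]
}

#' Evaluate a fitted model on a test fold
#'
#' @param fit an `eegatt_fit`.
#' @param data test [feature_tensor()] or list with `x`, `y`.
#' @return list with `accuracy` (percent), `n`, `confusion`
#'   (row-normalized percent, rows = true class) and `counts` (raw
#'   confusion counts).
#' @export
evaluate_model <- function(fit, data) {
  ds <- as_dataset(data)
  if (length(ds$y) == 0L) stop("empty test fold")
  pred <- predict(fit, ds$x)
  classes <- fit$class_levels
  counts <- table(factor(ds$y, levels = classes),
                  factor(pred, levels = classes))
  counts <- matrix(as.integer(counts), length(classes), length(classes),
                   dimnames = list(true = classes, pred = classes))
  conf <- counts / pmax(rowSums(counts), 1L) * 100
  list(accuracy = 100 * sum(ds$y == pred) / length(ds$y),
       n = length(ds$y), confusion = conf, counts = counts)
}

#' Aggregate per-fold results into an evaluation report
#'
#' @param fold_results list of [evaluate_model()] results.
#' @param attention optional list of attention exports per fold.
#' @return object of class `eval_report`: per-fold accuracies, mean,
#'   population standard deviation, pooled row-normalized confusion
#'   matrix (percent).
#' @export
eval_report <- function(fold_results, attention = NULL) {
  acc <- vapply(fold_results, `[[`, numeric(1), "accuracy")
  counts <- Reduce(`+`, lapply(fold_results, `[[`, "counts"))
  conf <- counts / pmax(rowSums(counts), 1L) * 100
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = sqrt(mean((acc - mean(acc))^2)),
                 confusion = conf, counts = counts,
                 attention = attention),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d folds: %.2f +/- %.2f %%\n",
              length(x$fold_accuracy), x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Run a full cross-validation protocol
#'
#' Trains and evaluates one model per fold of the chosen protocol. Under
#' LOSO with binary-scheme adaptation enabled, the held-out subject's
#' unlabeled features form the target domain of the adversarial branch;
#' under the subject-dependent protocol the domain branch defaults to
#' off (switchable by passing an enabled `adapt_cfg` with the
#' `per_subject` scheme).
#'
#' @param data a [feature_tensor()] or list with `x`, `y`, `subject`,
#'   `trial`.
#' @param protocol `"loso"` or `"subject_dependent"`.
#' @param model_cfg,train_cfg,adapt_cfg configurations; `adapt_cfg`
#'   defaults to GRL enabled (alpha 0.1) for LOSO and disabled for the
#'   subject-dependent protocol.
#' @param export_attention also export mean attention adjacency and
#'   pooling weights per fold.
#' @return an [eval_report()].
#' @export
run_protocol <- function(data, protocol = c("loso", "subject_dependent"),
                         model_cfg = NULL, train_cfg = train_config(),
                         adapt_cfg = NULL, export_attention = FALSE) {
  protocol <- match.arg(protocol)
  ds <- as_dataset(data)
  if (is.null(adapt_cfg)) {
    adapt_cfg <- if (protocol == "loso") grl_config(enabled = TRUE)
                 else grl_config(enabled = FALSE)
  }
  plan <- make_splits(ds$subject, ds$trial, protocol)
  results <- list()
  attn <- if (export_attention) list() else NULL
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    train_ds <- list(x = ds$x[fold$train, , , drop = FALSE],
                     y = ds$y[fold$train],
                     subject = ds$subject[fold$train],
                     trial = ds$trial[fold$train])
    test_ds <- list(x = ds$x[fold$test, , , drop = FALSE],
                    y = ds$y[fold$test])
    tx <- NULL
    if (isTRUE(adapt_cfg$enabled) &&
        adapt_cfg$scheme == "binary_source_target") {
      tx <- test_ds$x  # unlabeled target features only
    }
    fit <- train_model(train_ds, model_cfg, train_cfg, adapt_cfg,
                       target_x = tx)
    results[[f]] <- evaluate_model(fit, test_ds)
    if (export_attention) {
      attn[[f]] <- export_attention_weights(fit, test_ds$x)
    }
  }
  eval_report(results, attention = attn)
}

#' Export attention weights for visualization
#'
#' Mean symmetrized attention adjacency per layer and mean global
#' attention pooling weights, averaged over the given segments. These
#' are the per-electrode importance profiles used to inspect which
#' channels the model relies on.
#'
#' @param fit an `eegatt_fit`.
#' @param x N x E x F feature array (raw scale).
#' @param electrode_labels optional labels for dimnames.
#' @return list with `adjacency` (list of E x E matrices, one per
#'   attention layer) and `beta` (length-E mean pooling weights, or
#'   `NULL` for sum pooling).
#' @export
export_attention_weights <- function(fit, x, electrode_labels = NULL) {
  if (inherits(x, "feature_tensor")) x <- x$values
  if (!is.null(fit$stand)) x <- apply_standardize(x, fit$stand)
  n <- dim(x)[1L]
  E <- fit$model_cfg$E
  L <- length(fit$model_cfg$layer_dims)
  adj <- replicate(L, matrix(0, E, E), simplify = FALSE)
  beta <- numeric(E)
  bs <- fit$train_cfg$batch_size
  for (s in seq.int(1L, n, by = bs)) {
    idx <- s:min(s + bs - 1L, n)
    fwd <- model_forward(fit$params, x[idx, , , drop = FALSE],
                         fit$model_cfg)
    for (l in seq_len(L)) {
      if (!is.null(fwd$attention[[l]])) {
        adj[[l]] <- adj[[l]] + apply(fwd$attention[[l]], c(2L, 3L), sum)
      }
    }
    if (!is.null(fwd$pool$beta)) beta <- beta + colSums(fwd$pool$beta)
  }
  adj <- lapply(adj, function(a) a / n)
  beta <- if (fit$model_cfg$pooling == "global_attention") beta / n else NULL
  if (!is.null(electrode_labels)) {
    adj <- lapply(adj, function(a) {
      dimnames(a) <- list(electrode_labels, electrode_labels); a })
    if (!is.null(beta)) names(beta) <- electrode_labels
  }
  list(adjacency = adj, beta = beta)
}

#' Run the ablation suite
#'
#' Four configurations: the full model, the fixed-graph plain-GCN variant
#' (no attention convolution), the direct-summation variant (no global
#' attention pooling) and the no-GRL variant (domain branch removed
#' entirely). Each is evaluated under the given protocol for every seed.
#'
#' @param data dataset as in [run_protocol()].
#' @param seeds integer vector of training seeds (>= 1 seed).
#' @param protocol evaluation protocol.
#' @param model_cfg,train_cfg,adapt_cfg base configurations; `adapt_cfg`
#'   (default GRL enabled, alpha 0.1) applies to all variants except
#'   "no_grl".
#' @return list with `table` (data.frame: variant, seed, mean accuracy,
#'   sd) and `summary` (data.frame of per-variant mean over seeds).
#' @export
run_ablation <- function(data, seeds = 100L, protocol = "loso",
                         model_cfg = NULL, train_cfg = train_config(),
                         adapt_cfg = grl_config(enabled = TRUE)) {
  if (is.null(model_cfg)) model_cfg <- model_config()
  variants <- list(
    full = list(cfg = model_cfg, adapt = adapt_cfg),
    no_attention_conv = list(
      cfg = modify_model_cfg(model_cfg, conv = "plain_gcn"),
      adapt = adapt_cfg),
    no_global_attention = list(
      cfg = modify_model_cfg(model_cfg, pooling = "sum"),
      adapt = adapt_cfg),
    no_grl = list(cfg = model_cfg, adapt = grl_config(enabled = FALSE)))
  rows <- list()
  for (v in names(variants)) {
    for (sd in seeds) {
      tc <- train_cfg
      tc$seed <- as.integer(sd)
      rep <- run_protocol(data, protocol, variants[[v]]$cfg, tc,
                          variants[[v]]$adapt)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = sd, mean_accuracy = rep$mean_accuracy,
        sd_accuracy = rep$sd_accuracy)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- stats::aggregate(mean_accuracy ~ variant, tab, mean)
  list(table = tab, summary = summ)
}

# rebuild a model_config with selected fields replaced
modify_model_cfg <- function(cfg, ...) {
  repl <- list(...)
  args <- list(E = cfg$E, F_in = cfg$F_in, layer_dims = cfg$layer_dims,
               classifier_dims = cfg$classifier_dims,
               n_classes = cfg$n_classes, activation = cfg$activation,
               pooling = cfg$pooling, conv = cfg$conv, gcn_k = cfg$gcn_k)
  args[names(repl)] <- repl
  do.call(model_config, args)
}
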