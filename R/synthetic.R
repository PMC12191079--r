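#' Synthetic EEG dataset specification
#'
#' Describes the world the generator emulates: a multi-subject,
#' multi-trial affective-EEG study with a segments x electrodes x bands
#' feature layout (62 electrodes x 5 bands by default), 3- or 4-class
#' label regimes, class-dependent effects concentrated on a small set of
#' electrodes, and subject-level affine distribution shift (per-subject
#' gain and offset) — the inter-subject variability that domain
#' adaptation must overcome.
#'
#' Defaults: 5 subjects with 15 trials each (5 per class x 3 classes, 10
#' one-second segments per trial) mirror the per-session structure of
#' public affective-EEG corpora at desk scale; effect channels default to
#' the temporal/parietal electrode indices reported as most
#' emotion-discriminative (15, 23, 25, 31, 32, 33, 50 on the 62-channel
#' cap); the class effect rides on the beta and gamma bands.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_class trials per class per subject.
#' @param n_segments_per_trial one-second segments per trial.
#' @param n_classes 3 or 4.
#' @param E electrodes; `F` bands.
#' @param effect_channels electrode indices carrying the class signal.
#' @param effect_bands band indices carrying the class signal.
#' @param effect_size mean shift per class in feature (z) units.
#' @param subject_gain_sd log-normal sd of the per-subject multiplicative
#'   gain.
#' @param subject_offset_sd sd of the per-subject additive offset.
#' @param noise_sd baseline feature noise sd.
#' @param band_amplitudes per-band oscillator amplitudes for raw-signal
#'   mode.
#' @param fs sampling rate of generated raw signals (Hz).
#' @param seed RNG seed; the generator is fully determined by it.
#' @param mode `"features"` or `"raw_signal"`.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 5L, n_trials_per_class = 5L,
                           n_segments_per_trial = 10L, n_classes = 3L,
                           E = 62L, F = 5L,
                           effect_channels = c(15L, 23L, 25L, 31L, 32L,
                                               33L, 50L),
                           effect_bands = c(4L, 5L),
                           effect_size = 1,
                           subject_gain_sd = 0.4,
                           subject_offset_sd = 1,
                           noise_sd = 1,
                           band_amplitudes = rep(1, 5L),
                           fs = 200,
                           seed = 100L,
                           mode = c("features", "raw_signal")) {
  mode <- match.arg(mode)
  stopifnot(n_classes %in% c(3L, 4L), effect_size >= 0,
            all(effect_channels >= 1L), all(effect_channels <= E),
            all(effect_bands >= 1L), all(effect_bands <= F))
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_class = as.integer(n_trials_per_class),
    n_segments_per_trial = as.integer(n_segments_per_trial),
    n_classes = as.integer(n_classes), E = as.integer(E),
    F = as.integer(F), effect_channels = as.integer(effect_channels),
    effect_bands = as.integer(effect_bands), effect_size = effect_size,
    subject_gain_sd = subject_gain_sd,
    subject_offset_sd = subject_offset_sd, noise_sd = noise_sd,
    band_amplitudes = band_amplitudes, fs = fs,
    seed = as.integer(seed), mode = mode), class = "synthetic_spec")
}

# deterministic orthonormal class patterns over the effect channels
# (QR of a fixed full-rank matrix), so every class pair is equally
# separated regardless of the 3- or 4-class regime; zero matrix when the
# effect is off (patterns are then unused)
class_patterns <- function(n_channels, n_classes, effect_size = 1) {
  if (effect_size == 0) return(matrix(0, n_channels, n_classes))
  if (n_channels < n_classes) {
    stop("need at least as many effect channels as classes for ",
         "orthogonal class patterns")
  }
  M <- outer(seq_len(n_channels), seq_len(n_classes),
             function(i, k) cos(0.9 * i * k + 0.2 * i + 0.1 * k))
  qd <- qr(M)
  if (qd$rank < n_classes) stop("degenerate class pattern basis")
  qr.Q(qd)[, seq_len(n_classes), drop = FALSE]
}

#' Generate a synthetic feature dataset
#'
#' Baseline iid Gaussian(0, noise_sd^2) features; class `c` adds
#' `effect_size` times an orthonormal class pattern on the effect
#' channels and bands; each subject then applies a sampled log-normal
#' gain and Gaussian offset to all its features. Trials cycle through the
#' classes so every contiguous block of trials is class-balanced.
#'
#' @param spec a [synthetic_spec()].
#' @return a [feature_tensor()] (kind `"de"`) with per-segment labels,
#'   subject and trial ids.
#' @export
generate_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    pat <- class_patterns(length(spec$effect_channels), spec$n_classes,
                          spec$effect_size)
    n_trials <- spec$n_classes * spec$n_trials_per_class
    n_per_subj <- n_trials * spec$n_segments_per_trial
    n <- spec$n_subjects * n_per_subj
    x <- array(stats::rnorm(n * spec$E * spec$F, 0, spec$noise_sd),
               c(n, spec$E, spec$F))
    labels <- integer(n)
    subject <- integer(n)
    trial <- integer(n)
    row <- 0L
    for (s in seq_len(spec$n_subjects)) {
      gain <- stats::rlnorm(1L, 0, spec$subject_gain_sd)
      offset <- stats::rnorm(1L, 0, spec$subject_offset_sd)
      for (t in seq_len(n_trials)) {
        cls <- (t - 1L) %% spec$n_classes + 1L
        for (g in seq_len(spec$n_segments_per_trial)) {
          row <- row + 1L
          for (bd in spec$effect_bands) {
            x[row, spec$effect_channels, bd] <-
              x[row, spec$effect_channels, bd] +
              spec$effect_size * pat[, cls]
          }
          x[row, , ] <- gain * x[row, , ] + offset
          labels[row] <- cls
          subject[row] <- s
          trial[row] <- t
        }
      }
    }
    feature_tensor(x, "de", labels = labels, subject_id = subject,
                   trial_id = trial)
  })
}

#' Generate synthetic raw recordings
#'
#' Each trial is a channels x samples recording at `spec$fs`: per channel
#' a sum of five band-limited oscillators (one per classical band, at the
#' band's center frequency with a random phase) plus white noise. Class
#' effects modulate the oscillator amplitudes on the effect channels and
#' bands, so features extracted downstream recover the injected band
#' structure. Duration is `n_segments_per_trial` seconds per trial.
#'
#' @param spec a [synthetic_spec()] (`mode = "raw_signal"`).
#' @param bands a [band_set()] giving the oscillator bands.
#' @return list of records, each a list with `recording`
#'   (a [raw_recording()]), `subject`, `trial`, `label`.
#' @export
generate_raw <- function(spec, bands = band_set()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$mode != "raw_signal") {
    stop("spec$mode must be 'raw_signal' for generate_raw()")
  }
  stopifnot(length(spec$band_amplitudes) == length(bands))
  centers <- vapply(bands, mean, numeric(1))
  with_seed(spec$seed, {
    pat <- class_patterns(length(spec$effect_channels), spec$n_classes,
                          spec$effect_size)
    n_trials <- spec$n_classes * spec$n_trials_per_class
    dur <- spec$n_segments_per_trial
    tgrid <- seq(0, dur - 1 / spec$fs, by = 1 / spec$fs)
    out <- list()
    for (s in seq_len(spec$n_subjects)) {
      gain <- stats::rlnorm(1L, 0, spec$subject_gain_sd)
      for (tr in seq_len(n_trials)) {
        cls <- (tr - 1L) %% spec$n_classes + 1L
        amp <- matrix(spec$band_amplitudes, spec$E, spec$F, byrow = TRUE)
        for (bd in spec$effect_bands) {
          amp[spec$effect_channels, bd] <- pmax(
            amp[spec$effect_channels, bd] *
              (1 + spec$effect_size * pat[, cls]), 0)
        }
        sig <- matrix(0, spec$E, length(tgrid))
        for (j in seq_along(centers)) {
          phase <- stats::runif(spec$E, 0, 2 * pi)
          osc <- sin(outer(rep(2 * pi * centers[j], spec$E), tgrid) + phase)
          sig <- sig + amp[, j] * osc
        }
        if (spec$noise_sd > 0) {
          sig <- sig + matrix(stats::rnorm(length(sig), 0, spec$noise_sd),
                              nrow(sig))
        }
        sig <- gain * sig
        out[[length(out) + 1L]] <- list(
          recording = raw_recording(sig, spec$fs, label = cls),
          subject = s, trial = tr, label = cls)
      }
    }
    out
  })
}
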