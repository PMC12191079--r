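#' Raw multi-channel EEG recording
#'
#' Thin container for a continuous recording: a channels x samples matrix
#' in microvolts plus its sampling rate and optional per-recording label.
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param label optional emotion class label of the trial.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs, label = NA) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(signal), fs > 0)
  if (anyNA(signal)) stop("recording contains NA samples")
  structure(list(signal = signal, fs = fs, label = label),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  invisible(x)
}

#' Frequency band definitions
#'
#' The five classical EEG rhythms. Band edges are a convention of the
#' affective-EEG literature, not a physical constant, so they are
#' user-overridable everywhere they are consumed.
#'
#' @param edges named list of `c(low, high)` pairs in Hz, ordered,
#'   non-overlapping.
#' @return object of class `band_set` (the validated list).
#' @export
band_set <- function(edges = default_bands()) {
  stopifnot(is.list(edges), length(edges) >= 1L, !is.null(names(edges)))
  lows <- vapply(edges, `[`, numeric(1), 1L)
  highs <- vapply(edges, `[`, numeric(1), 2L)
  if (any(lows <= 0) || any(highs <= lows)) {
    stop("band edges must satisfy 0 < low < high")
  }
  if (any(diff(as.vector(rbind(lows, highs))) < 0)) {
    stop("bands must be ordered and non-overlapping")
  }
  structure(edges, class = "band_set")
}

#' @rdname band_set
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 14),
       beta = c(14, 31), gamma = c(31, 50))
}

#' Preprocess a raw recording
#'
#' The standard conditioning chain for affective-EEG feature extraction:
#' zero-phase band-pass filtering (default 0.3-50 Hz, removing drift and
#' high-frequency noise) followed by resampling to the target rate
#' (default 200 Hz).
#'
#' @param rec a [raw_recording()].
#' @param target_fs output sampling rate in Hz.
#' @param passband `c(low, high)` filter edges in Hz.
#' @param order Butterworth order of each cascade section. The default 6
#'   puts the zero-phase stopband rejection 20% past the band edge above
#'   20 dB; the per-band feature filters use order 4 independently.
#' @return a [raw_recording()] at `target_fs`.
#' @export
preprocess <- function(rec, target_fs = 200, passband = c(0.3, 50),
                       order = 6L) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$fs < 2 * passband[2L]) {
    stop(sprintf(
      "sampling rate %g Hz is below twice the passband edge %g Hz (aliasing)",
      rec$fs, passband[2L]))
  }
  X <- t(rec$signal)  # samples x channels
  X <- bandpass_zp(X, passband[1L], passband[2L], rec$fs, order = order)
  n_out <- as.integer(round(nrow(X) * target_fs / rec$fs))
  if (n_out != nrow(X)) {
    X <- apply(X, 2L, fft_resample, n_out = n_out)
    X <- matrix(X, nrow = n_out)
  }
  raw_recording(t(X), target_fs, label = rec$label)
}

#' Cut a recording into fixed-length epochs
#'
#' @param rec a [raw_recording()].
#' @param window_s epoch length in seconds; `window_s * fs` must be an
#'   integer number of samples.
#' @param overlap_s overlap between consecutive epochs in seconds.
#' @return list of channels x samples matrices; a trailing remainder
#'   shorter than one window is dropped. Empty list (with a warning) when
#'   the recording is shorter than one window.
#' @export
segment_recording <- function(rec, window_s = 1, overlap_s = 0) {
  stopifnot(inherits(rec, "raw_recording"), overlap_s < window_s)
  win <- window_s * rec$fs
  if (abs(win - round(win)) > 1e-9) {
    stop("window_s * fs must be an integer number of samples")
  }
  win <- as.integer(round(win))
  step <- as.integer(round((window_s - overlap_s) * rec$fs))
  n <- ncol(rec$signal)
  if (n < win) {
    warning("recording shorter than one window; no epochs produced")
    return(list())
  }
  starts <- seq.int(1L, n - win + 1L, by = step)
  lapply(starts, function(s) rec$signal[, s:(s + win - 1L), drop = FALSE])
}

#' Differential entropy features per electrode and band
#'
#' Differential entropy of a band-limited Gaussian signal has the closed
#' form `0.5 * log(2 * pi * e * variance)`; the band variance is measured
#' on the zero-phase band-filtered epoch. This is the standard estimator
#' for affective-EEG work and captures signal "complexity" per rhythm.
#'
#' @param epoch channels x samples matrix (one segment).
#' @param bands a [band_set()].
#' @param fs sampling rate in Hz.
#' @param order Butterworth order for the per-band filters.
#' @param on_zero_variance `"error"` (default) to fail on a degenerate
#'   zero-variance band signal, `"neginf"` to emit `-Inf` instead.
#' @return electrodes x bands matrix of DE values (log microvolts-squared
#'   scale, dimensionless offset).
#' @export
de_feature <- function(epoch, bands = band_set(), fs, order = 4L,
                       on_zero_variance = c("error", "neginf")) {
  on_zero_variance <- match.arg(on_zero_variance)
  epoch <- as.matrix(epoch)
  stopifnot(ncol(epoch) >= 2L)
  X <- t(epoch)
  out <- matrix(NA_real_, nrow(epoch), length(bands),
                dimnames = list(rownames(epoch), names(bands)))
  for (j in seq_along(bands)) {
    bf <- bandpass_zp(X, bands[[j]][1L], bands[[j]][2L], fs, order = order)
    bf <- matrix(bf, nrow = nrow(X))
    v <- colMeans(bf^2) - colMeans(bf)^2  # population variance
    if (any(v <= 0)) {
      if (on_zero_variance == "error") {
        stop("zero-variance band signal in band '", names(bands)[j],
             "'; differential entropy undefined")
      }
      v[v <= 0] <- 0
    }
    out[, j] <- 0.5 * log(2 * pi * exp(1) * v)
  }
  out
}

#' Band power features from the power spectral density
#'
#' Estimates the PSD of each channel with a Hann-windowed periodogram on
#' the epoch and integrates it (rectangle rule) over each band's frequency
#' range, yielding band power in microvolts-squared.
#'
#' @inheritParams de_feature
#' @return electrodes x bands matrix of band powers.
#' @export
psd_feature <- function(epoch, bands = band_set(), fs) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  stopifnot(n >= 4L)
  highs <- vapply(bands, `[`, numeric(1), 2L)
  if (any(highs > fs / 2)) {
    stop("band edge above the Nyquist frequency ", fs / 2, " Hz")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  U <- sum(w^2)
  nf <- n %/% 2L + 1L
  freqs <- (seq_len(nf) - 1L) * fs / n
  df <- fs / n
  out <- matrix(NA_real_, nrow(epoch), length(bands),
                dimnames = list(rownames(epoch), names(bands)))
  spec <- t(apply(epoch, 1L, function(x) {
    F <- stats::fft(x * w)[seq_len(nf)]
    p <- (Mod(F)^2) / (fs * U)
    p[2:nf] <- 2 * p[2:nf]
    if (n %% 2L == 0L) p[nf] <- p[nf] / 2  # Nyquist bin is not doubled
    p
  }))
  for (j in seq_along(bands)) {
    sel <- freqs >= bands[[j]][1L] & freqs < bands[[j]][2L]
    out[, j] <- rowSums(spec[, sel, drop = FALSE]) * df
  }
  out
}

#' Hemispheric asymmetry features (DASM / RASM)
#'
#' Differential (left minus right) or rational (left over right) asymmetry
#' of a per-electrode feature map across the montage's homologous mirror
#' pairs; on the 62-channel default montage this produces 27 rows.
#'
#' @param feat electrodes x bands matrix computed on the montage's full
#'   electrode set (by convention differential entropy; any per-electrode
#'   feature works).
#' @param montage a [montage()].
#' @param kind `"dasm"` (difference) or `"rasm"` (ratio).
#' @param ratio_guard magnitude below which a RASM denominator is
#'   considered degenerate.
#' @param on_small_denominator `"error"` (default) or `"clip"` (clamp the
#'   denominator to `ratio_guard` with its sign).
#' @return pairs x bands matrix, rows ordered as `montage$mirror_pairs`.
#' @export
asymmetry_features <- function(feat, montage, kind = c("dasm", "rasm"),
                               ratio_guard = 1e-8,
                               on_small_denominator = c("error", "clip")) {
  kind <- match.arg(kind)
  on_small_denominator <- match.arg(on_small_denominator)
  stopifnot(inherits(montage, "montage"))
  feat <- as.matrix(feat)
  if (nrow(feat) != length(montage$labels)) {
    stop("feature matrix rows must match the montage electrode count")
  }
  l <- montage$mirror_pairs[, "left"]
  r <- montage$mirror_pairs[, "right"]
  left <- feat[l, , drop = FALSE]
  right <- feat[r, , drop = FALSE]
  rownames(left) <- paste0(montage$labels[l], "-", montage$labels[r])
  if (kind == "dasm") return(left - right)
  small <- abs(right) < ratio_guard
  if (any(small)) {
    if (on_small_denominator == "error") {
      stop("RASM denominator below guard threshold ", ratio_guard)
    }
    right[small] <- sign(right[small] + (right[small] == 0)) * ratio_guard
  }
  left / right
}

#' Frontal-posterior caudality features (DCAU)
#'
#' Feature difference between paired frontal and posterior electrodes
#' (frontal minus posterior), following the differential-caudality
#' convention of the affective-EEG literature. Note the name's "causality"
#' heritage: no causal estimator is involved, only paired differences of a
#' per-electrode feature along the frontal-caudal axis.
#'
#' @inheritParams asymmetry_features
#' @return pairs x bands matrix, rows ordered as `montage$caudal_pairs`
#'   (23 on the default montage).
#' @export
dcau_feature <- function(feat, montage) {
  stopifnot(inherits(montage, "montage"))
  if (is.null(montage$caudal_pairs)) {
    stop("montage has no caudal pairs defined")
  }
  feat <- as.matrix(feat)
  if (nrow(feat) != length(montage$labels)) {
    stop("feature matrix rows must match the montage electrode count")
  }
  f <- montage$caudal_pairs[, "frontal"]
  p <- montage$caudal_pairs[, "posterior"]
  out <- feat[f, , drop = FALSE] - feat[p, , drop = FALSE]
  rownames(out) <- paste0(montage$labels[f], "-", montage$labels[p])
  out
}

#' Segments x electrodes x bands feature tensor
#'
#' The model's input container: a 3-D array of per-segment features plus
#' per-segment labels and subject/trial bookkeeping.
#'
#' @param values numeric array, segments x electrodes x bands.
#' @param feature_kind one of `"de"`, `"psd"`, `"dasm"`, `"rasm"`, `"dcau"`.
#' @param labels per-segment class labels (integer-like).
#' @param subject_id,trial_id per-segment identifiers (recycled if scalar).
#' @param band_names optional names for the band axis.
#' @param montage optional [montage()]; when given, the electrode-axis
#'   length is validated against the feature kind (62 for de/psd, mirror
#'   pair count for dasm/rasm, caudal pair count for dcau).
#' @return object of class `feature_tensor`.
#' @export
feature_tensor <- function(values, feature_kind, labels,
                           subject_id = 1L, trial_id = 1L,
                           band_names = NULL, montage = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  feature_kind <- match.arg(tolower(feature_kind),
                            c("de", "psd", "dasm", "rasm", "dcau"))
  n <- dim(values)[1L]
  stopifnot(length(labels) == n)
  if (length(subject_id) == 1L) subject_id <- rep(subject_id, n)
  if (length(trial_id) == 1L) trial_id <- rep(trial_id, n)
  stopifnot(length(subject_id) == n, length(trial_id) == n)
  if (!is.null(montage)) {
    expected <- switch(feature_kind,
      de = , psd = length(montage$labels),
      dasm = , rasm = nrow(montage$mirror_pairs),
      dcau = nrow(montage$caudal_pairs))
    if (dim(values)[2L] != expected) {
      stop(sprintf("electrode axis has length %d; %s on this montage needs %d",
                   dim(values)[2L], toupper(feature_kind), expected))
    }
  }
  structure(
    list(values = values, feature_kind = feature_kind,
         labels = as.integer(labels), subject_id = subject_id,
         trial_id = trial_id, band_names = band_names),
    class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<feature_tensor> %s: %d segments x %d electrodes x %d bands, %d class(es), %d subject(s)\n",
    toupper(x$feature_kind), d[1L], d[2L], d[3L],
    length(unique(x$labels)), length(unique(x$subject_id))))
  invisible(x)
}

#' Extract a feature tensor from a raw recording
#'
#' Convenience pipeline: [preprocess()] (optional), [segment_recording()],
#' per-epoch [de_feature()] or [psd_feature()], and for the asymmetry
#' families the derived pair features. DASM/RASM/DCAU are computed from
#' differential entropy by convention (`base_feature` switches to band
#' power).
#'
#' @param rec a [raw_recording()]; `rec$label` is used for all segments.
#' @param montage a [montage()].
#' @param kind feature family to extract.
#' @param bands a [band_set()].
#' @param window_s epoch length in seconds.
#' @param base_feature `"de"` or `"psd"`: the per-electrode feature from
#'   which dasm/rasm/dcau are derived.
#' @param do_preprocess apply the filtering/resampling chain first.
#' @param subject_id,trial_id bookkeeping identifiers for the output.
#' @param ... passed on to [preprocess()].
#' @return a [feature_tensor()].
#' @export
extract_features <- function(rec, montage, kind = c("de", "psd", "dasm",
                                                    "rasm", "dcau"),
                             bands = band_set(), window_s = 1,
                             base_feature = c("de", "psd"),
                             do_preprocess = TRUE,
                             subject_id = 1L, trial_id = 1L, ...) {
  kind <- match.arg(kind)
  base_feature <- match.arg(base_feature)
  stopifnot(inherits(montage, "montage"))
  if (nrow(rec$signal) != length(montage$labels)) {
    stop("recording channel count does not match the montage")
  }
  if (do_preprocess) rec <- preprocess(rec, ...)
  epochs <- segment_recording(rec, window_s = window_s)
  base_fun <- if (kind == "psd" ||
                  (kind %in% c("dasm", "rasm", "dcau") &&
                   base_feature == "psd")) {
    function(ep) psd_feature(ep, bands, rec$fs)
  } else {
    function(ep) de_feature(ep, bands, rec$fs)
  }
  feats <- lapply(epochs, function(ep) {
    base <- base_fun(ep)
    switch(kind,
      de = , psd = base,
      dasm = asymmetry_features(base, montage, "dasm"),
      rasm = asymmetry_features(base, montage, "rasm"),
      dcau = dcau_feature(base, montage))
  })
  vals <- array(NA_real_,
                c(length(feats), nrow(feats[[1L]]), ncol(feats[[1L]])))
  for (i in seq_along(feats)) vals[i, , ] <- feats[[i]]
  feature_tensor(vals, kind,
                 labels = rep(if (is.na(rec$label)) 0L else rec$label,
                              length(feats)),
                 subject_id = subject_id, trial_id = trial_id,
                 band_names = names(bands), montage = montage)
}
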