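# IIR filter design and zero-phase filtering.
#
# No DSP package ships with the target environment, so the classical
# pieces are implemented here: Butterworth low/high-pass design by analog
# prototype + bilinear transform, direct-form-II-transposed filtering
# vectorized across channels, forward-backward (zero-phase) application
# with odd-symmetric edge padding and steady-state initial conditions,
# and Fourier-domain resampling.

# polynomial coefficients (descending powers, monic) from complex roots
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) {
    coef <- c(coef, 0 + 0i) - c(0 + 0i, coef * ri)
  }
  coef
}

#' Butterworth filter coefficients
#'
#' Digital Butterworth low- or high-pass design (analog prototype, frequency
#' pre-warping, bilinear transform). Band-pass responses are applied as a
#' high-pass/low-pass cascade, which is numerically far better conditioned
#' than a single transfer function when band edges sit near DC.
#'
#' @param n filter order (poles).
#' @param fc cutoff frequency in Hz, in (0, fs/2).
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_coeffs <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, fc > 0, fc < fs / 2)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit-cutoff prototype poles
  warped <- 2 * fs * tan(pi * fc / fs)
  if (type == "low") {
    z <- complex(0)
    p <- warped * p
    gain <- warped^n
  } else {
    z <- rep(0 + 0i, n)
    p <- warped / p
    gain <- 1
  }
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

# steady-state state vector for a unit-step input (scipy lfilter_zi analog);
# scaling by the first input sample suppresses start-up transients
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[2:n] / a[1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[2:n] - a[2:n] * b[1L]
  # poles clustered at z = 1 (deep high-pass designs) make this system
  # numerically singular; zero state plus edge padding is then adequate
  tryCatch(solve(diag(n - 1L) - t(comp), B),
           error = function(e) numeric(n - 1L))
}

# direct-form-II-transposed IIR filter on a samples x channels matrix;
# zi is the per-unit state (scaled by the first row), or NULL for zero state
iir_filter_mat <- function(b, a, X, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  nt <- nrow(X)
  nc <- ncol(X)
  Y <- matrix(0, nt, nc)
  z <- matrix(0, n - 1L, nc)
  if (!is.null(zi)) z <- zi %o% rep(1, nc) * rep(X[1L, ], each = n - 1L)
  for (t in seq_len(nt)) {
    xt <- X[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (n > 2L) {
      for (k in 1:(n - 2L)) {
        z[k, ] <- b[k + 1L] * xt + z[k + 1L, ] - a[k + 1L] * yt
      }
    }
    z[n - 1L, ] <- b[n] * xt - a[n] * yt
    Y[t, ] <- yt
  }
  Y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward with odd-symmetric extension at
#' both ends and steady-state initial conditions, so the output has zero
#' phase distortion and the squared magnitude response of the design.
#'
#' @param b,a filter coefficients as from [butter_coeffs()].
#' @param x numeric vector or samples x channels matrix.
#' @return filtered data, same shape as `x`.
#' @export
filtfilt_zp <- function(b, a, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  nt <- nrow(X)
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (nt <= npad) {
    stop("signal too short for zero-phase filtering (need > ", npad,
         " samples)")
  }
  top <- 2 * rep(1, npad) %o% X[1L, ] - X[(npad + 1L):2L, , drop = FALSE]
  bot <- 2 * rep(1, npad) %o% X[nt, ] - X[(nt - 1L):(nt - npad), , drop = FALSE]
  ext <- rbind(top, X, bot)
  zi <- filter_zi(b, a)
  Y <- iir_filter_mat(b, a, ext, zi = zi)
  Y <- iir_filter_mat(b, a, Y[nrow(Y):1L, , drop = FALSE], zi = zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  out <- Y[(npad + 1L):(npad + nt), , drop = FALSE]
  if (vec) drop(out) else out
}

# band-pass as zero-phase high-pass then low-pass cascade
bandpass_zp <- function(x, low, high, fs, order = 4L) {
  stopifnot(low < high)
  hp <- butter_coeffs(order, low, fs, "high")
  lp <- butter_coeffs(order, high, fs, "low")
  filtfilt_zp(lp$b, lp$a, filtfilt_zp(hp$b, hp$a, x))
}

#' Fourier-domain resampling
#'
#' Resamples a signal to `n_out` samples by truncating or zero-padding its
#' discrete spectrum (the classical FFT resampler). Assumes the signal is
#' band-limited below the output Nyquist rate; [preprocess()] guarantees
#' this by filtering before resampling.
#'
#' @param x numeric vector.
#' @param n_out desired output length.
#' @return numeric vector of length `n_out`.
#' @export
fft_resample <- function(x, n_out) {
  n <- length(x)
  n_out <- as.integer(n_out)
  if (n_out == n) return(x)
  W <- stats::fft(x)
  Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  h <- min(n, n_out)
  kmax <- (h - 1L) %/% 2L
  Y[1L] <- W[1L]
  if (kmax >= 1L) {
    Y[2L:(kmax + 1L)] <- W[2L:(kmax + 1L)]
    Y[(n_out - kmax + 1L):n_out] <- W[(n - kmax + 1L):n]
  }
  if (h %% 2L == 0L) {
    ny <- h %/% 2L
    if (n_out < n) {
      Y[ny + 1L] <- W[ny + 1L] + W[n - ny + 1L]  # fold aliased pair (real)
    } else {
      Y[ny + 1L] <- W[ny + 1L] / 2
      Y[n_out - ny + 1L] <- Conj(W[ny + 1L]) / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
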