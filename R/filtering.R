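# Frequency-domain helpers shared by the generator and the detector.

# FFT length with small prime factors; R's mixed-radix FFT degrades badly on
# lengths with large prime factors.
good_fft_length <- function(n) {
  if (n <= 1) return(max(n, 1))
  stats::nextn(n, factors = c(2, 3, 5))
}

# Raised-cosine band mask on FFT bin frequencies. Unity inside
# [low, high], cosine rolloff over the transition widths, zero outside.
band_mask <- function(freqs, low, high, trans_low = 0.5, trans_high = 2) {
  m <- numeric(length(freqs))
  f <- abs(freqs)
  inside <- f >= low & f <= high
  m[inside] <- 1
  lo0 <- max(low - trans_low, 0)
  ramp_lo <- f >= lo0 & f < low
  m[ramp_lo] <- 0.5 * (1 - cos(pi * (f[ramp_lo] - lo0) / (low - lo0)))
  ramp_hi <- f > high & f <= high + trans_high
  m[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - high) / trans_high))
  m
}

# Zero-phase band filter of a numeric vector via an FFT mask. `shape` is an
# optional extra amplitude-shaping function of frequency (used for coloured
# noise). Returns a vector of the original length.
fft_band_filter <- function(x, fs, low, high, shape = NULL,
                            trans_low = 0.5, trans_high = 2) {
  n <- length(x)
  if (n == 0) return(x)
  nfft <- good_fft_length(n)
  xp <- c(x, numeric(nfft - n))
  X <- stats::fft(xp)
  freqs <- c(0:(nfft %/% 2), -((nfft - nfft %/% 2 - 1):1)) * fs / nfft
  m <- band_mask(freqs, low, high, trans_low, trans_high)
  if (!is.null(shape)) {
    s <- shape(abs(freqs))
    s[!is.finite(s)] <- 0
    m <- m * s
  }
  Re(stats::fft(X * m, inverse = TRUE))[seq_len(n)] / nfft
}

#' Zero-phase band-pass filter
#'
#' Filters both channels of a record (or a plain numeric vector) with a
#' zero-phase frequency-domain mask: unit gain inside `[low_hz, high_hz]`,
#' raised-cosine transitions just outside, full stop elsewhere. Zero phase
#' means event boundaries are not shifted by group delay. Defaults match the
#' 1--40 Hz acquisition band conventionally used for rodent cortical EEG.
#'
#' @param x An [eeg_record()] or numeric vector.
#' @param low_hz,high_hz Pass-band corner frequencies in Hz.
#' @param sampling_rate Required when `x` is a bare vector.
#' @return Object of the same type as `x`, filtered.
#' @export
#' @examples
#' fs <- 200
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 10 * t)
#' y <- bandpass(x, 1, 40, sampling_rate = fs)
#' max(abs(y - x)) < 0.05
bandpass <- function(x, low_hz = 1, high_hz = 40, sampling_rate = NULL) {
  if (inherits(x, "eeg_record")) {
    fs <- x$sampling_rate
    check_corners(low_hz, high_hz, fs)
    x$left_uv <- fft_band_filter(x$left_uv, fs, low_hz, high_hz)
    x$right_uv <- fft_band_filter(x$right_uv, fs, low_hz, high_hz)
    return(x)
  }
  if (is.null(sampling_rate)) {
    stop("sampling_rate must be given when filtering a bare vector")
  }
  check_corners(low_hz, high_hz, sampling_rate)
  fft_band_filter(x, sampling_rate, low_hz, high_hz)
}

check_corners <- function(low, high, fs) {
  if (!(low > 0 && low < high)) {
    stop("need 0 < low_hz < high_hz")
  }
  if (high > fs / 2) {
    stop(sprintf("high corner %g Hz exceeds Nyquist (%g Hz)", high, fs / 2))
  }
  invisible(TRUE)
}

# Inverse-CDF truncated normal draw; deterministic given the RNG stream.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Mean and variance of a normal truncated to [lo, hi].
tnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  t1 <- if (is.finite(a)) a * da else 0
  t2 <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (t1 - t2) / Z - ((da - db) / Z)^2)
  list(mean = m, var = v)
}

# Untruncated mean mu such that the [lo, hi]-truncated normal with the given
# sd has expectation `target`; keeps sampled means on target despite the
# physiological range truncation.
tnorm_mean_adjust <- function(target, sd, lo, hi) {
  if (target <= lo || target >= hi) return(target)
  stats::uniroot(function(mu) tnorm_moments(mu, sd, lo, hi)$mean - target,
                 interval = c(lo - 3 * sd, hi + 3 * sd), tol = 1e-8)$root
}
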