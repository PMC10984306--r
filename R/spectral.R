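# Multitaper spectral estimation on a 1-40 Hz, 1-Hz grid; interhemispheric
# coherence; spectral peaks; per-frequency nonparametric group comparison
# with FDR control; peak-voltage variance test.

# Cache of DPSS taper matrices, keyed by (n, nw, k).
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth
#' product `nw` via the classical symmetric tridiagonal formulation; each
#' taper has unit energy. Results are cached per `(n, nw, k)`.
#'
#' @param n Taper length, samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (at most `2 * nw - 1` for well-concentrated
#'   tapers).
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  w <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- diag(d)
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  v <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    # standard sign convention: symmetric tapers have positive mean,
    # antisymmetric tapers a positive initial slope
    if ((abs(s) > 1e-8 && s < 0) ||
        (abs(s) <= 1e-8 && v[2, j] - v[1, j] < 0)) {
      v[, j] <- -v[, j]
    }
  }
  .taper_cache[[key]] <- v
  v
}

mt_params <- function(n, fs, bandwidth_hz, bandwidth_convention) {
  half_w <- switch(bandwidth_convention,
                   full = bandwidth_hz / 2,
                   half = bandwidth_hz)
  nw <- (n / fs) * half_w
  k <- max(1L, floor(2 * nw - 1))
  list(nw = nw, k = k)
}

# Tapered FFT coefficients of one epoch at the integer frequency grid.
# Returns a k x length(freqs) complex matrix.
taper_fft <- function(x, fs, freqs, bandwidth_hz, bandwidth_convention) {
  n <- length(x)
  p <- mt_params(n, fs, bandwidth_hz, bandwidth_convention)
  tp <- dpss_tapers(n, p$nw, p$k)
  X <- stats::mvfft(tp * (x - mean(x)))
  bins <- round(freqs * n / fs) + 1L
  if (any(abs(freqs * n / fs - (bins - 1)) > 1e-6)) {
    stop("epoch length incompatible with the 1-Hz frequency grid")
  }
  t(X[bins, , drop = FALSE])
}

#' Multitaper power spectral density (amplitude convention)
#'
#' DPSS multitaper spectrum of a 5-s epoch on the 1, 2, ..., 40 Hz grid.
#' The value at each frequency is the root-mean-square across tapers of the
#' tapered Fourier amplitude, so it scales linearly with the signal
#' (amplitude convention rather than squared power). The default reads the
#' taper bandwidth as a total width of 2 Hz (half-bandwidth 1 Hz,
#' time-bandwidth 5, 9 tapers), which resolves spectral peaks on the 1-Hz
#' grid; `bandwidth_convention = "half"` selects the wider reading
#' (half-bandwidth 2 Hz, 19 tapers).
#'
#' @param x Numeric vector, one channel of a 5-s epoch.
#' @param sampling_rate Hz.
#' @param freqs Frequency grid, Hz (default 1:40); each must be an integer
#'   multiple of the epoch's Rayleigh resolution.
#' @param bandwidth_hz Multitaper bandwidth parameter, Hz (default 2).
#' @param bandwidth_convention `"full"` (default) or `"half"`; see above.
#' @param epoch_s Required epoch length, seconds (`NULL` skips the check).
#' @param meta Optional list of epoch metadata carried in the result.
#' @return Object of class `psd_result`: list with `freqs_hz`, `power`
#'   (amplitude per frequency), `n_tapers`, `meta`.
#' @export
#' @examples
#' fs <- 200
#' x <- sin(2 * pi * 10 * seq(0, 5 - 1 / fs, by = 1 / fs))
#' psd <- multitaper_psd(x, fs)
#' psd$freqs_hz[which.max(psd$power)]  # 10
multitaper_psd <- function(x, sampling_rate, freqs = 1:40,
                           bandwidth_hz = 2,
                           bandwidth_convention = c("full", "half"),
                           epoch_s = 5, meta = NULL) {
  bandwidth_convention <- match.arg(bandwidth_convention)
  if (!is.null(epoch_s) &&
      abs(length(x) - epoch_s * sampling_rate) > 0.5) {
    stop(sprintf("epoch must be %g s (%d samples), got %d samples",
                 epoch_s, round(epoch_s * sampling_rate), length(x)))
  }
  X <- taper_fft(x, sampling_rate, freqs, bandwidth_hz,
                 bandwidth_convention)
  structure(
    list(freqs_hz = freqs,
         power = sqrt(colMeans(Mod(X)^2)),
         n_tapers = nrow(X),
         meta = meta),
    class = "psd_result"
  )
}

#' Interhemispheric magnitude coherence
#'
#' Amplitude-weighted phase coherence between two synchronized epochs:
#' `C(f) = |<A_l A_r e^(i dtheta)>| / sqrt(<A_l^2><A_r^2>)` with the
#' average taken across DPSS tapers. Bounded in \[0, 1\]; identically 1
#' for identical channels.
#'
#' @param left,right Equal-length epoch channels.
#' @param sampling_rate Hz.
#' @inheritParams multitaper_psd
#' @return Object of class `coherence_result`: list with `freqs_hz`,
#'   `coherence`.
#' @export
mt_coherence <- function(left, right, sampling_rate, freqs = 1:40,
                         bandwidth_hz = 2,
                         bandwidth_convention = c("full", "half"),
                         epoch_s = 5) {
  bandwidth_convention <- match.arg(bandwidth_convention)
  if (length(left) != length(right)) {
    stop("channels must have equal length")
  }
  if (!is.null(epoch_s) &&
      abs(length(left) - epoch_s * sampling_rate) > 0.5) {
    stop("epoch length mismatch")
  }
  Xl <- taper_fft(left, sampling_rate, freqs, bandwidth_hz,
                  bandwidth_convention)
  Xr <- taper_fft(right, sampling_rate, freqs, bandwidth_hz,
                  bandwidth_convention)
  cross <- Mod(colMeans(Xl * Conj(Xr)))
  denom <- sqrt(colMeans(Mod(Xl)^2) * colMeans(Mod(Xr)^2))
  coh <- ifelse(denom > 0, cross / denom, 0)
  structure(
    list(freqs_hz = freqs, coherence = pmin(coh, 1)),
    class = "coherence_result"
  )
}

#' Extract a 5-s epoch from an event
#'
#' `first5` is the first five seconds of the event, `last5` the last five,
#' `mid5` five seconds centred on the event midpoint. Events shorter than
#' `min_event_s` (default 20 s, the conventional threshold for "long"
#' seizures) are refused.
#'
#' @param event One-row data.frame (or list) with `start_s` and `end_s`.
#' @param record An [eeg_record()].
#' @param position One of `"first5"`, `"mid5"`, `"last5"`.
#' @param epoch_s Epoch length, seconds.
#' @param min_event_s Minimum admissible event duration, seconds.
#' @return List with `left`, `right` (sample vectors), `sampling_rate`,
#'   `start_s`, `position`.
#' @export
select_epochs <- function(event, record,
                          position = c("first5", "mid5", "last5"),
                          epoch_s = 5, min_event_s = 20) {
  position <- match.arg(position)
  dur <- event$end_s - event$start_s
  if (dur < min_event_s) {
    stop(sprintf(
      "insufficient data: event lasts %.1f s, minimum is %g s",
      dur, min_event_s))
  }
  t0 <- switch(position,
               first5 = event$start_s,
               last5 = event$end_s - epoch_s,
               mid5 = (event$start_s + event$end_s) / 2 - epoch_s / 2)
  fs <- record$sampling_rate
  i0 <- round(t0 * fs) + 1L
  idx <- i0:(i0 + round(epoch_s * fs) - 1L)
  if (idx[1] < 1 || idx[length(idx)] > record$n_samples) {
    stop("epoch extends beyond the record")
  }
  list(left = record$left_uv[idx], right = record$right_uv[idx],
       sampling_rate = fs, start_s = t0, position = position)
}

#' Local maxima of a spectrum
#'
#' Grid frequencies whose power is strictly greater than both neighbours
#' and whose topographic prominence (height above the higher of the two
#' saddle minima separating the peak from higher terrain) is at least
#' `floor_frac` of the spectrum maximum, in ascending frequency order.
#' The prominence floor suppresses ripples riding on the coloured
#' background; the "first peak" of a spectrum is the first element.
#' Monotone spectra yield an empty vector.
#'
#' @param psd A `psd_result` (or list with `freqs_hz` and `power`).
#' @param floor_frac Relative prominence floor in (0, 1\].
#' @return Numeric vector of peak frequencies, possibly empty.
#' @export
find_spectral_peaks <- function(psd, floor_frac = 0.1) {
  p <- psd$power
  f <- psd$freqs_hz
  n <- length(p)
  if (n < 3) return(numeric(0))
  i <- 2:(n - 1)
  peaks <- i[p[i] > p[i - 1] & p[i] > p[i + 1]]
  prom <- vapply(peaks, function(k) {
    higher_l <- which(p[seq_len(k - 1)] > p[k])
    lo_l <- min(p[(if (length(higher_l)) max(higher_l) else 1):k])
    higher_r <- which(p[(k + 1):n] > p[k])
    rb <- if (length(higher_r)) k + min(higher_r) else n
    lo_r <- min(p[k:rb])
    p[k] - max(lo_l, lo_r)
  }, numeric(1))
  as.numeric(f[peaks[prom >= floor_frac * max(p)]])
}

#' Per-frequency Mann-Whitney comparison with FDR control
#'
#' Two-sided Mann-Whitney U test between two groups of spectra at each
#' grid frequency, followed by Benjamini-Hochberg correction across
#' frequencies at FDR level `q` (default 0.01).
#'
#' @param group_a,group_b Matrices (observations x frequencies) or lists of
#'   `psd_result` objects on a common grid. At least 2 observations per
#'   group (3 or more recommended).
#' @param freqs Frequency grid (taken from the inputs when they are
#'   `psd_result` lists).
#' @param q FDR level.
#' @return data.frame of class `psd_comparison` with `freq_hz`,
#'   `u_statistic`, `p_value`, `p_adjusted`, `significant`.
#' @export
compare_psd_groups <- function(group_a, group_b, freqs = NULL, q = 0.01) {
  to_matrix <- function(g) {
    if (is.matrix(g)) return(g)
    if (is.list(g) && all(vapply(g, inherits, TRUE, "psd_result"))) {
      return(do.call(rbind, lapply(g, `[[`, "power")))
    }
    stop("groups must be matrices or lists of psd_result objects")
  }
  if (is.null(freqs) && is.list(group_a) && !is.matrix(group_a)) {
    freqs <- group_a[[1]]$freqs_hz
  }
  a <- to_matrix(group_a)
  b <- to_matrix(group_b)
  if (is.null(freqs)) freqs <- seq_len(ncol(a))
  if (ncol(a) != ncol(b)) stop("groups must share the frequency grid")
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("insufficient data: need at least 2 observations per group")
  }
  res <- vapply(seq_len(ncol(a)), function(j) {
    wt <- suppressWarnings(
      stats::wilcox.test(a[, j], b[, j], exact = NULL))
    c(wt$statistic, wt$p.value)
  }, numeric(2))
  p_adj <- stats::p.adjust(res[2, ], method = "BH")
  out <- data.frame(
    freq_hz = freqs,
    u_statistic = res[1, ],
    p_value = res[2, ],
    p_adjusted = p_adj,
    significant = p_adj <= q
  )
  class(out) <- c("psd_comparison", "data.frame")
  out
}

#' Homogeneity-of-variance test on per-cycle peak voltages
#'
#' Tests whether the variance of spike peak voltages differs between event
#' types (e.g. pre-injection discharges vs. initial status vs. second
#' period). Default is Bartlett's test, whose statistic is chi-square
#' distributed with `k - 1` degrees of freedom (df = 2 for three groups);
#' the Brown-Forsythe (median-centred Levene) test is available for
#' heavy-tailed data.
#'
#' @param groups List of at least three numeric vectors of per-cycle peak
#'   voltages, each with 5 or more values.
#' @param method `"bartlett"` (default) or `"levene"`.
#' @return List with `statistic`, `df` (two values for `"levene"`),
#'   `p_value`, `method`.
#' @export
peak_voltage_variance_test <- function(groups,
                                       method = c("bartlett", "levene")) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 3) {
    stop("need at least three groups of cycle peak voltages")
  }
  if (any(vapply(groups, length, 1L) < 5)) {
    stop("each group needs at least 5 cycle peaks")
  }
  if (method == "bartlett") {
    bt <- stats::bartlett.test(groups)
    return(list(statistic = unname(bt$statistic),
                df = unname(bt$parameter),
                p_value = bt$p.value, method = "bartlett"))
  }
  # Brown-Forsythe: one-way ANOVA on absolute deviations from group medians
  z <- unlist(lapply(groups, function(g) abs(g - stats::median(g))))
  grp <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::anova(stats::lm(z ~ grp))
  list(statistic = fit$`F value`[1],
       df = c(fit$Df[1], fit$Df[2]),
       p_value = fit$`Pr(>F)`[1], method = "levene")
}

#' FDR correction across animals
#'
#' Benjamini-Hochberg adjustment of a vector of per-animal p-values, with
#' the significance mask at level `q`.
#'
#' @param p Numeric vector of p-values.
#' @param q FDR level.
#' @return data.frame with `p`, `p_adjusted`, `significant`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p_adjusted = p_adj, significant = p_adj <= q)
}
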