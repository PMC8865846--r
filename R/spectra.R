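#' LFP estimation configuration
#'
#' The local field potential is approximated as the volume-conductor
#' point-source sum of the total synaptic currents of a random subset of
#' pyramidal cells, `V(x_e, t) = 1/(4 pi sigma_e) sum_n I_n(t) / |x_e -
#' x_n|`, with a uniform source distance (so the geometry only contributes a
#' constant scale), followed by a zero-phase low-pass filter.
#'
#' @param n_sample_cells Number of sampled cells (400).
#' @param sigma_e Extracellular conductivity, S/m (1/3.54).
#' @param distance Source-to-electrode distance, m (1 micron).
#' @param fs Sampling rate, Hz.
#' @param cutoff Low-pass cutoff, Hz.
#' @param order Butterworth filter order.
#' @return An object of class `lfp_config`.
#' @export
lfp_config <- function(n_sample_cells = 400, sigma_e = 1 / 3.54,
                       distance = 1e-6, fs = 1e4, cutoff = 500, order = 3) {
  stopifnot(n_sample_cells > 0, sigma_e > 0, distance > 0, fs > 0,
            cutoff > 0, order >= 1)
  structure(list(n_sample_cells = n_sample_cells, sigma_e = sigma_e,
                 distance = distance, fs = fs, cutoff = cutoff,
                 order = order), class = "lfp_config")
}

#' Estimate the LFP from recorded synaptic currents
#'
#' Sums the total synaptic (excitatory + inhibitory) currents of the
#' sampled cells, scales by `1 / (4 pi sigma_e * distance)` and low-pass
#' filters (forward-backward Butterworth, zero phase). Currents in pA give
#' an output in microvolts.
#'
#' @param currents Either a matrix (cells x time) of total synaptic
#'   currents in pA, a numeric vector of the already-summed current, or the
#'   `lfp` element of a [simulate_network()] result (list with `exc`,
#'   `inh`, `fs`).
#' @param config An [lfp_config()].
#' @param filter Apply the low-pass filter (set `FALSE` for the raw scaled
#'   sum).
#' @return list with `lfp` (uV), `fs` (Hz).
#' @export
estimate_lfp <- function(currents, config = lfp_config(), filter = TRUE) {
  if (is.list(currents) && !is.null(currents$exc)) {
    if (!is.null(currents$fs)) config$fs <- currents$fs
    total <- currents$exc + currents$inh
  } else if (is.matrix(currents)) {
    total <- colSums(currents)
  } else {
    total <- as.numeric(currents)
  }
  # pA -> A, V -> uV: 1e-12 / (4 pi sigma d) * 1e6
  scale <- 1e-12 / (4 * pi * config$sigma_e * config$distance) * 1e6
  v <- total * scale
  if (filter && length(v) > 3 * (config$order + 1)) {
    bf <- signal::butter(config$order, config$cutoff / (config$fs / 2),
                         type = "low")
    v <- as.numeric(signal::filtfilt(bf, v))
  }
  list(lfp = v, fs = config$fs)
}

#' Welch power spectral density
#'
#' Hann-windowed, half-overlapping segment-averaged periodogram with
#' constant (mean) detrending per segment, one-sided density scaling: the
#' integral of the PSD over frequency approximates the signal variance.
#'
#' @param x Signal.
#' @param fs Sampling rate, Hz.
#' @param segment_length Segment length in samples (512 for 1 kHz
#'   population rates, 4096 for 10 kHz LFP; halved when analysing
#'   concatenated event windows). Signals shorter than one segment are an
#'   error; use [band_analysis()] for zero-padded per-event spectra.
#' @param overlap Fractional overlap between segments.
#' @return list with `freq` (Hz), `psd` (power / Hz), `segment_length`,
#'   `n_segments`.
#' @export
welch_psd <- function(x, fs, segment_length = 512, overlap = 0.5) {
  n <- length(x)
  L <- as.integer(segment_length)
  if (n < L) stop("signal shorter than one Welch segment")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  win <- hann_window(L)
  U <- sum(win^2)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + L - 1L)]
    (seg - mean(seg)) * win
  }, numeric(L))
  X <- mvfft(segs)
  n_freq <- L %/% 2 + 1L
  P <- rowMeans(Mod(X[seq_len(n_freq), , drop = FALSE])^2) / (fs * U)
  # one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, n_freq)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[n_freq] <- 1
  list(freq = (seq_len(n_freq) - 1) * fs / L, psd = P * dbl,
       segment_length = L, n_segments = length(starts))
}

hann_window <- function(L) {
  0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

#' Fisher g-test for a periodic component
#'
#' Tests the null hypothesis of Gaussian white noise against a single
#' periodic component using Fisher's g-statistic, the ratio of the maximal
#' periodogram ordinate to the total power over the `N` supplied ordinates:
#' `g = max_k P(w_k) / sum_k P(w_k)`. The exact null p-value is
#' `p = sum_{k=1}^{b} (-1)^(k-1) choose(N, k) (1 - k g)^(N-1)` with `b` the
#' largest integer below `1/g`; terms are evaluated in log space and
#' truncated when `1 - k g <= 0`.
#'
#' When `band` is supplied (with `freq`), the candidate peak is the maximal
#' ordinate *inside* the band while the denominator and `N` still refer to
#' the full supplied spectrum; under the white-noise null this is
#' conservative (the in-band maximum can only be smaller than the global
#' one), and it prevents a strong out-of-band component from being
#' mistaken for an in-band rhythm.
#'
#' @param p_values Periodogram ordinates, length >= 2.
#' @param freq Optional frequencies matching `p_values` (for the peak
#'   frequency; required with `band`).
#' @param alpha Significance level.
#' @param band Optional frequency interval `c(lo, hi)` restricting where
#'   the candidate peak may lie.
#' @return An object of class `spectrum_peak_test`: list with `g`, `p`,
#'   `significant`, `peak_freq`, `n`, `alpha`.
#' @export
fisher_g_test <- function(p_values, freq = NULL, alpha = 0.05, band = NULL) {
  P <- as.numeric(p_values)
  if (length(P) < 2) stop("need at least 2 periodogram values")
  if (all(P == 0)) stop("all-zero periodogram")
  if (any(P < 0)) stop("periodogram values must be nonnegative")
  N <- length(P)
  if (is.null(band)) {
    peak_idx <- which.max(P)
  } else {
    stopifnot(!is.null(freq))
    in_band <- which(freq >= band[1] & freq <= band[2])
    if (!length(in_band)) stop("no ordinates inside band")
    peak_idx <- in_band[which.max(P[in_band])]
  }
  g <- P[peak_idx] / sum(P)
  if (g >= 1) {
    p <- 0
  } else if (g <= 1 / N) {
    # the classic statistic is always >= 1/N, so Pr(g* > g) = 1; reachable
    # only for a band-restricted peak far below the out-of-band power
    p <- 1
  } else {
    b <- min(ceiling(1 / g) - 1, N)   # largest integer < 1/g, at most N
    k <- seq_len(b)
    k <- k[1 - k * g > 0]
    terms <- exp(lchoose(N, k) + (N - 1) * log1p(-k * g))
    p <- sum(terms * (-1)^(k - 1))
    p <- min(max(p, 0), 1)
  }
  structure(list(g = g, p = p, significant = p < alpha,
                 peak_freq = if (!is.null(freq)) freq[peak_idx] else NA_real_,
                 n = N, alpha = alpha),
            class = "spectrum_peak_test")
}

#' @export
print.spectrum_peak_test <- function(x, ...) {
  cat(sprintf("Fisher g-test: g = %.4f over %d ordinates, p = %.4g (%s)%s\n",
              x$g, x$n, x$p,
              if (x$significant) "significant" else "not significant",
              if (is.finite(x$peak_freq))
                sprintf(", peak at %.1f Hz", x$peak_freq) else ""))
  invisible(x)
}

#' Per-event averaged Welch spectrum
#'
#' Computes one Welch PSD per event window (windows shorter than the
#' segment length are zero-padded to it, keeping the frequency grid fixed)
#' and averages across events. Used so that the low-frequency power at the
#' event-recurrence rate does not dominate the spectrum.
#'
#' @param x Signal.
#' @param fs Sampling rate, Hz.
#' @param events data.frame with `start`, `end` times (s) as returned by
#'   [detect_high_activity()].
#' @param segment_length Welch segment length (already the halved,
#'   event-window value).
#' @return As [welch_psd()], averaged over events.
#' @export
event_psd <- function(x, fs, events, segment_length = 256) {
  stopifnot(nrow(events) >= 1)
  psds <- lapply(seq_len(nrow(events)), function(i) {
    i0 <- max(1L, floor(events$start[i] * fs) + 1L)
    i1 <- min(length(x), ceiling(events$end[i] * fs))
    seg <- x[i0:i1]
    if (length(seg) < segment_length)
      seg <- c(seg, rep(0, segment_length - length(seg)))
    welch_psd(seg, fs, segment_length)
  })
  out <- psds[[1]]
  out$psd <- rowMeans(vapply(psds, `[[`, numeric(length(out$psd)), "psd"))
  out$n_segments <- sum(vapply(psds, `[[`, numeric(1), "n_segments"))
  out
}

#' Band-restricted peak significance and power fractions
#'
#' Applies the Fisher g-test to the periodogram ordinates inside the gamma
#' (30-100 Hz) and ripple (150-220 Hz) bands and computes each band's power
#' fraction (band sum divided by the total power in 0-500 Hz). When
#' `events` is supplied, the per-event averaged spectrum of
#' [event_psd()] is analysed instead of the full-signal Welch PSD.
#'
#' @param x Signal (population rate or LFP).
#' @param fs Sampling rate, Hz.
#' @param events Optional event windows (data.frame with `start`, `end`).
#' @param segment_length Welch segment length; default 512 without events,
#'   halved to 256 with events (scaled by `fs/1000` for other rates).
#' @param bands Named list of frequency intervals, Hz.
#' @param alpha Significance level.
#' @return list with one `spectrum_peak_test` per band (each with a
#'   `power_fraction` element appended) plus the `psd`.
#' @export
band_analysis <- function(x, fs, events = NULL, segment_length = NULL,
                          bands = list(gamma = c(30, 100),
                                       ripple = c(150, 220)),
                          alpha = 0.05) {
  base_seg <- as.integer(512 * fs / 1000)
  if (is.null(segment_length))
    segment_length <- if (is.null(events)) base_seg else base_seg %/% 2L
  psd <- if (is.null(events)) welch_psd(x, fs, segment_length)
         else event_psd(x, fs, events, segment_length)
  total_idx <- psd$freq > 0 & psd$freq <= 500
  total_power <- sum(psd$psd[total_idx])
  out <- lapply(bands, function(b) {
    idx <- psd$freq >= b[1] & psd$freq <= b[2]
    tst <- fisher_g_test(psd$psd[total_idx], psd$freq[total_idx], alpha,
                         band = b)
    tst$band <- b
    tst$power_fraction <- sum(psd$psd[idx]) / total_power
    tst
  })
  out$psd <- psd
  out
}

#' Morlet wavelet time-frequency map
#'
#' Continuous wavelet transform with the real Morlet wavelet
#' `psi(t) = exp(-t^2/2) cos(5 t)`, with scales mapped to the requested
#' centre frequencies through the Morlet centre-frequency relation
#' `f = 5 / (2 pi) * fs / scale`.
#'
#' @param x Signal.
#' @param fs Sampling rate, Hz.
#' @param freqs Centre frequencies, Hz (default 25-325 Hz in 2 Hz steps).
#' @return list with `t` (s), `freq` (Hz), `power` (magnitude matrix,
#'   frequencies x time).
#' @export
wavelet_tfr <- function(x, fs, freqs = seq(25, 325, by = 2)) {
  n <- length(x)
  fc <- 5 / (2 * pi)
  scales <- fc * fs / freqs
  nfft <- stats::nextn(2L * n, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  power <- matrix(0, length(freqs), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    half <- ceiling(6 * s)
    tt <- (-half):half
    psi <- exp(-(tt / s)^2 / 2) * cos(5 * tt / s) / sqrt(s)
    kern <- c(psi[(half + 1):(2 * half + 1)], rep(0, nfft - (2 * half + 1)),
              psi[1:half])
    conv <- Re(fft(X * fft(kern), inverse = TRUE)) / nfft
    power[j, ] <- abs(conv[seq_len(n)])
  }
  list(t = (seq_len(n) - 1) / fs, freq = freqs, power = power)
}
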