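#' Detect bursts in a spike train
#'
#' A spike belongs to a burst when interspike intervals are <= `isi_max`
#' and the first spike of the burst is preceded by a pause >= `pause_min`
#' (the first spike of a recording counts as preceded by silence).
#'
#' @param spike_times sorted spike times (ms).
#' @param isi_max intra-burst ISI bound (default 15 ms).
#' @param pause_min pre-burst silence (default 50 ms).
#' @return integer labels per spike: 0 = not in a burst, k > 0 = burst
#'   index.
#' @export
detect_bursts <- function(spike_times, isi_max = 15, pause_min = 50) {
  n <- length(spike_times)
  if (n == 0) return(integer(0))
  labels <- integer(n)
  bid <- 0L
  i <- 1
  while (i <= n) {
    pre_pause <- if (i == 1) Inf else spike_times[i] - spike_times[i - 1]
    j <- i
    while (j < n && spike_times[j + 1] - spike_times[j] <= isi_max) j <- j + 1
    if (j > i && pre_pause >= pause_min) {
      bid <- bid + 1L
      labels[i:j] <- bid
    }
    i <- j + 1
  }
  labels
}

#' Burst probability per cell
#'
#' Ratio of spikes belonging to a burst to all spikes, computed only for
#' cells whose baseline rate lies in `rate_range` (others are excluded
#' and returned as NA).
#'
#' @param trains named list of spike-time vectors (one per cell).
#' @param duration recording length (ms) for the baseline-rate filter.
#' @param rate_range admissible baseline rates in Hz (default c(1, 20)).
#' @return named numeric vector of burst probabilities (NA = excluded).
#' @export
burst_probability <- function(trains, duration, rate_range = c(1, 20)) {
  vapply(trains, function(st) {
    r <- length(st) / (duration / 1000)
    if (r < rate_range[1] || r > rate_range[2]) return(NA_real_)
    if (!length(st)) return(NA_real_)
    sum(detect_bursts(st) > 0) / length(st)
  }, numeric(1))
}

#' Population firing-rate histogram
#' @param spike_times pooled spike times (ms).
#' @param duration total time (ms).
#' @param bin_ms histogram bin (default 5 ms).
#' @param n_cells population size (rates in Hz per cell when given).
#' @return list(time = bin centers, rate).
#' @export
rate_histogram <- function(spike_times, duration, bin_ms = 5, n_cells = 1) {
  breaks <- seq(0, duration + bin_ms, by = bin_ms)
  h <- graphics::hist(spike_times[spike_times >= 0 & spike_times <= duration],
                      breaks = breaks, plot = FALSE)
  list(time = h$mids, rate = h$counts / n_cells / (bin_ms / 1000))
}

#' Oscillation frequency from the rate-histogram autocorrelation
#'
#' Computes the normalized autocorrelation of the firing-rate histogram
#' and returns the inverse of the lag of the first non-zero-lag peak.
#' Returns NA (flagged undefined) when no peak exists (e.g. constant
#' rate).
#'
#' @param hist rate histogram from [rate_histogram()].
#' @param max_lag_ms autocorrelation range (default 500 ms).
#' @param min_freq_hz ignore peaks slower than this (default 2 Hz).
#' @return frequency in Hz, or NA.
#' @export
oscillation_frequency <- function(hist, max_lag_ms = 500, min_freq_hz = 2) {
  r <- hist$rate
  if (length(r) < 4 || stats::sd(r) == 0) return(NA_real_)
  bin <- diff(hist$time[1:2])
  nlag <- min(length(r) - 2, ceiling(max_lag_ms / bin))
  ac <- stats::acf(r, lag.max = nlag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # light smoothing so shot noise does not masquerade as a peak
  if (length(ac) >= 5) {
    sm <- stats::filter(ac, rep(1 / 3, 3), sides = 2)
    ac <- ifelse(is.na(sm), ac, as.numeric(sm))
  }
  # descend from the zero-lag peak to the first trough, then take the
  # maximum after it (the first non-zero-lag oscillation peak)
  lag_max <- min(length(ac) - 1, floor(1000 / min_freq_hz / bin) + 1)
  trough <- which(diff(ac) > 0)[1]
  if (is.na(trough) || trough >= lag_max) return(NA_real_)
  # first local maximum after the trough (harmonics at longer lags can
  # be as tall, so a global maximum would be ambiguous)
  pk <- NA
  for (i in (trough + 1):lag_max) {
    if (ac[i] > 0.03 && ac[i] >= ac[i - 1] && ac[i] >= ac[i + 1]) {
      pk <- i
      break
    }
  }
  if (is.na(pk)) return(NA_real_)
  period_ms <- (pk - 1) * bin
  1000 / period_ms
}

#' Oscillation duration from rate-histogram peaks
#'
#' Peaks are counted when significantly higher than the baseline rate
#' (operationalized as exceeding `prominence` times the baseline mean
#' rate); duration is the time between the last and first peak (0 when
#' fewer than 2 peaks).
#'
#' @param hist rate histogram.
#' @param baseline_window ms window defining baseline (default the first
#'   20% of the histogram); alternatively a numeric baseline rate via
#'   `baseline_rate`.
#' @param baseline_rate optional explicit baseline rate (Hz).
#' @param prominence multiple of baseline required (default 2).
#' @param min_rate_hz absolute floor for a peak (default 1 Hz), used when
#'   the baseline is silent.
#' @return list(duration_ms, peak_times).
#' @export
oscillation_duration <- function(hist, baseline_window = NULL,
                                 baseline_rate = NULL, prominence = 2,
                                 min_rate_hz = 1) {
  r <- hist$rate; tt <- hist$time
  if (is.null(baseline_rate)) {
    if (is.null(baseline_window))
      baseline_window <- c(0, tt[max(1, floor(length(tt) * 0.2))])
    baseline_rate <- mean(r[tt >= baseline_window[1] &
                            tt <= baseline_window[2]])
  }
  thr <- max(prominence * baseline_rate, min_rate_hz)
  loc <- which(diff(sign(diff(r))) == -2) + 1
  loc <- loc[r[loc] >= thr]
  # merge peaks closer than 2 bins
  if (length(loc) > 1) {
    keep <- c(TRUE, diff(loc) > 2)
    loc <- loc[keep]
  }
  if (length(loc) < 2)
    return(list(duration_ms = 0, peak_times = tt[loc]))
  list(duration_ms = tt[loc[length(loc)]] - tt[loc[1]],
       peak_times = tt[loc])
}

#' Oscillation strength (maximum of the power spectral density)
#'
#' Periodogram of the mean-subtracted rate histogram; strength is the
#' maximal PSD value over frequencies above `min_freq_hz`.
#'
#' @param hist rate histogram.
#' @param min_freq_hz exclude the DC region (default 2 Hz).
#' @return list(strength, peak_freq_hz).
#' @export
oscillation_strength <- function(hist, min_freq_hz = 2) {
  r <- hist$rate - mean(hist$rate)
  if (length(r) < 8 || stats::sd(r) == 0)
    return(list(strength = 0, peak_freq_hz = NA_real_))
  bin_s <- diff(hist$time[1:2]) / 1000
  sp <- stats::spec.pgram(stats::ts(r, deltat = bin_s), taper = 0,
                          plot = FALSE, detrend = FALSE)
  sel <- sp$freq >= min_freq_hz
  if (!any(sel)) return(list(strength = 0, peak_freq_hz = NA_real_))
  k <- which.max(sp$spec[sel])
  list(strength = max(sp$spec[sel]), peak_freq_hz = sp$freq[sel][k])
}

#' Spectrogram of a voltage trace
#'
#' Short-time periodogram with a sliding Hann window (defaults: 10 kHz
#' sampling, 5000-sample window, 99% overlap, matching the reference
#' analysis settings).
#'
#' @param v voltage samples.
#' @param fs sampling frequency (Hz, default 10000).
#' @param window window length in samples (default 5000).
#' @param overlap fractional overlap (default 0.99).
#' @return list(time s, freq Hz, power [freq x time]).
#' @export
spectrogram <- function(v, fs = 10000, window = 5000, overlap = 0.99) {
  step <- max(1, round(window * (1 - overlap)))
  if (length(v) < window)
    stop("trace shorter than one spectrogram window")
  starts <- seq(1, length(v) - window + 1, by = step)
  han <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))
  nf <- window %/% 2
  pw <- matrix(0, nf, length(starts))
  for (k in seq_along(starts)) {
    seg <- v[starts[k]:(starts[k] + window - 1)]
    seg <- (seg - mean(seg)) * han
    ft <- stats::fft(seg)
    pw[, k] <- (Mod(ft[2:(nf + 1)])^2) / (fs * sum(han^2))
  }
  list(time = (starts + window / 2) / fs,
       freq = seq_len(nf) * fs / window,
       power = pw)
}

#' Per-cycle recruitment fractions
#'
#' Fraction of cells of each m-type firing within `window_ms` of each
#' oscillation peak. A peak at the stimulus time is prepended as cycle 0.
#'
#' @param spikes data.frame with gid, time, mtype.
#' @param peak_times oscillation peak times (ms).
#' @param stim_time stimulus time prepended as cycle 0 (NULL to skip).
#' @param window_ms half-window around each peak (default 30).
#' @param mtype_counts named list of population sizes.
#' @return data.frame cycle x mtype with recruitment fractions.
#' @export
cycle_recruitment <- function(spikes, peak_times, stim_time = NULL,
                              window_ms = 30, mtype_counts) {
  cycles <- c(if (!is.null(stim_time)) stim_time, peak_times)
  out <- list()
  for (ci in seq_along(cycles)) {
    pt <- cycles[ci]
    sel <- spikes[abs(spikes$time - pt) <= window_ms, ]
    for (mt in names(mtype_counts)) {
      frac <- length(unique(sel$gid[sel$mtype == mt])) /
        max(1, mtype_counts[[mt]])
      out[[length(out) + 1]] <- data.frame(
        cycle = ci - ifelse(is.null(stim_time), 0, 1), mtype = mt,
        fraction = frac, peak_time = pt)
    }
  }
  do.call(rbind, out)
}

#' Per-pulse response probability
#'
#' Fraction of (cell, pulse) pairs with at least one spike within
#' `resp_window` after each pulse.
#'
#' @param spikes data.frame with gid, time.
#' @param pulse_times stimulus times (ms).
#' @param cells gids of the responding population.
#' @param resp_window response window (ms, default 30).
#' @return numeric vector, one probability per pulse.
#' @export
response_probability <- function(spikes, pulse_times, cells,
                                 resp_window = 30) {
  vapply(pulse_times, function(pt) {
    resp <- unique(spikes$gid[spikes$time > pt &
                              spikes$time <= pt + resp_window])
    length(intersect(resp, cells)) / length(cells)
  }, numeric(1))
}
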