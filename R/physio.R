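#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero net phase shift) Butterworth filtering.  Pass
#' \code{low_hz = 0} for a pure low-pass or \code{high_hz = NULL} for a
#' pure high-pass.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param low_hz,high_hz band edges, Hz; \code{high_hz} must be below the
#'   Nyquist frequency.
#' @param order filter order.
#' @return filtered signal.
#' @export
bandpass_zero_phase <- function(x, fs, low_hz, high_hz, order = 4) {
  nyq <- fs / 2
  if (!is.null(high_hz) && high_hz >= nyq) stop("high cutoff must be below Nyquist")
  if (!is.null(high_hz) && low_hz > 0) {
    bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  } else if (low_hz > 0) {
    bf <- signal::butter(order, low_hz / nyq, type = "high")
  } else {
    bf <- signal::butter(order, high_hz / nyq, type = "low")
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' R-peak detection by calibrated amplitude threshold
#'
#' Local maxima of the filtered ECG above a per-recording threshold
#' (60% of the 99th percentile of positive amplitudes -- quantile-based,
#' hence scale invariant), with a 250 ms refractory period keeping the
#' larger of two competing peaks.
#'
#' @param ecg filtered ECG samples.
#' @param fs sampling rate, Hz.
#' @param threshold_frac fraction of the 99th-percentile amplitude.
#' @param refractory_s refractory period, seconds.
#' @return beat times in seconds (sorted, unique).
#' @export
detect_r_peaks <- function(ecg, fs, threshold_frac = 0.6,
                           refractory_s = 0.25) {
  pos <- ecg[ecg > 0]
  if (!length(pos)) stop("ECG quality error: no positive amplitudes")
  thr <- threshold_frac * quantile(pos, 0.99, names = FALSE)
  ## local maxima above threshold
  n <- length(ecg)
  is_peak <- c(FALSE, diff(sign(diff(ecg))) == -2, FALSE) & ecg > thr
  cand <- which(is_peak)
  if (length(cand)) {
    ## refractory: sweep left to right, keep the larger competing peak
    keep <- integer(0)
    ref_n <- round(refractory_s * fs)
    last <- -Inf
    for (i in cand) {
      if (i - last >= ref_n) {
        keep <- c(keep, i)
        last <- i
      } else if (ecg[i] > ecg[keep[length(keep)]]) {
        keep[length(keep)] <- i
        last <- i
      }
    }
    cand <- keep
  }
  dur_min <- n / fs / 60
  if (length(cand) < 10 * dur_min)
    stop(sprintf("ECG quality error: %d beats in %.1f min of signal",
                 length(cand), dur_min))
  cand / fs
}

#' Inter-beat intervals from beat times
#'
#' @param beat_times R-peak times, seconds.
#' @return object of class \code{ibi_series}: beat_times, ibis (ms,
#'   ibis[i] spans beat i to beat i+1), artifact_flags.
#' @export
compute_ibis <- function(beat_times) {
  stopifnot(!is.unsorted(beat_times))
  ibis <- 1000 * diff(beat_times)
  structure(list(beat_times = beat_times, ibis = ibis,
                 artifact_flags = rep(FALSE, length(ibis))),
            class = "ibi_series")
}

#' Correct IBI artifacts by the 30% rule
#'
#' Sweeping left to right, an IBI differing by more than 30% from the
#' previous accepted value is flagged as an artifact and replaced by
#' cubic-spline interpolation over the neighbouring unflagged IBIs.
#'
#' @param ibi an \code{ibi_series} (or numeric IBIs in ms).
#' @param max_change flagging threshold as a fraction (0.30).
#' @return corrected \code{ibi_series} with updated
#'   \code{artifact_flags}.
#' @export
correct_ibis <- function(ibi, max_change = 0.30) {
  if (is.numeric(ibi)) ibi <- structure(
    list(beat_times = c(0, cumsum(ibi) / 1000), ibis = ibi,
         artifact_flags = rep(FALSE, length(ibi))), class = "ibi_series")
  x <- ibi$ibis
  n <- length(x)
  if (n < 4) stop("need at least 4 IBIs")
  flag <- rep(FALSE, n)
  ref <- x[1]
  for (i in 2:n) {
    if (abs(x[i] - ref) / ref > max_change) {
      flag[i] <- TRUE
    } else {
      ref <- x[i]
    }
  }
  if (mean(flag) > 0.20)
    warning(sprintf("%.0f%% of IBIs flagged as artifacts", 100 * mean(flag)))
  if (any(flag)) {
    good <- which(!flag)
    x[flag] <- spline(good, x[good], xout = which(flag), method = "natural")$y
  }
  ibi$ibis <- x
  ibi$artifact_flags <- flag
  ibi
}

#' Convert IBIs to instantaneous heart rate
#'
#' iHR (bpm) = 60000 / IBI (ms).
#'
#' @param ibis numeric IBIs in ms, or an \code{ibi_series}.
#' @export
ibi_to_ihr <- function(ibis) {
  if (inherits(ibis, "ibi_series")) ibis <- ibis$ibis
  if (any(ibis <= 0)) stop("nonpositive IBI")
  60000 / ibis
}

#' Stimulus-locked iHR epochs
#'
#' Builds the continuous 10 Hz iHR series by linear interpolation of the
#' beat-wise values (each IBI's iHR assigned at the interval's closing
#' R-peak), band-pass filters it between 0.01 and 2 Hz (second-order
#' zero-phase Butterworth), epochs it from -4 to +10 s around each
#' stimulus onset, and subtracts the per-trial mean of the -2..-1 s
#' baseline window.
#'
#' @param ibi a corrected \code{ibi_series}.
#' @param events data.frame with \code{trial_index} and
#'   \code{onset_time_s}; trials whose epoch exceeds the recording are
#'   dropped and reported.
#' @param fs_epoch interpolation rate, Hz (10).
#' @param epoch_window seconds relative to onset, default c(-4, 10).
#' @param baseline_window default c(-2, -1).
#' @param filter_band band edges for the drift filter, Hz.
#' @return object of class \code{epoch_matrix}: \code{values}
#'   (trials x time, bpm change from baseline), \code{time} axis,
#'   \code{trial_index}, \code{fs_epoch}, \code{lock},
#'   \code{baseline_window}, \code{dropped} trial indices, and
#'   \code{values_prefilter} (epochs cut from the unfiltered series,
#'   for diagnostics).
#' @export
epoch_ihr <- function(ibi, events, fs_epoch = 10,
                      epoch_window = c(-4, 10),
                      baseline_window = c(-2, -1),
                      filter_band = c(0.01, 2)) {
  ihr <- ibi_to_ihr(ibi)
  t_beat <- ibi$beat_times[-1]          # iHR assigned at closing R-peak
  grid <- seq(ibi$beat_times[1], max(ibi$beat_times), by = 1 / fs_epoch)
  series <- approx(t_beat, ihr, xout = grid, rule = 2)$y
  ## centre and reflection-pad before filtering: the 0.01 Hz high-pass has
  ## a ~16 s time constant, so an unpadded DC step at the edges would leak
  ## far into the recording
  mu <- mean(series)
  pad <- min(length(series) - 1, 60 * fs_epoch)
  padded <- c(rev((series - mu)[2:(pad + 1)]), series - mu,
              rev((series - mu)[(length(series) - pad):(length(series) - 1)]))
  filt <- bandpass_zero_phase(padded, fs_epoch, filter_band[1],
                              filter_band[2], order = 2)
  filt <- filt[(pad + 1):(pad + length(series))]
  rel <- seq(epoch_window[1], epoch_window[2], by = 1 / fs_epoch)
  ok <- events$onset_time_s + epoch_window[1] >= grid[1] &
    events$onset_time_s + epoch_window[2] <= grid[length(grid)]
  dropped <- events$trial_index[!ok]
  ev <- events[ok, , drop = FALSE]
  cut_epochs <- function(src) {
    m <- matrix(NA_real_, nrow(ev), length(rel))
    for (i in seq_len(nrow(ev))) {
      m[i, ] <- approx(grid, src, xout = ev$onset_time_s[i] + rel)$y
    }
    bsel <- rel >= baseline_window[1] & rel <= baseline_window[2]
    m - rowMeans(m[, bsel, drop = FALSE])
  }
  structure(list(values = cut_epochs(filt),
                 values_prefilter = cut_epochs(series),
                 time = rel, trial_index = ev$trial_index,
                 fs_epoch = fs_epoch, lock = "stimulus_onset",
                 baseline_window = baseline_window,
                 dropped = dropped),
            class = "epoch_matrix")
}

#' Remove power-line noise by spectral interpolation
#'
#' Replaces the magnitude of FFT bins within +/- 0.5 Hz of the line
#' frequency and its harmonics (up to \code{max_harmonic_hz}) by linear
#' interpolation between the band edges, keeping each bin's original
#' phase.
#'
#' @param x signal.
#' @param fs sampling rate (>= 1000 Hz expected for EMG).
#' @param line_hz line frequency (50).
#' @param half_width_hz half width of the replaced band (0.5).
#' @param max_harmonic_hz highest harmonic treated (250).
#' @export
remove_line_noise <- function(x, fs, line_hz = 50, half_width_hz = 0.5,
                              max_harmonic_hz = 250) {
  n <- length(x)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- floor(n / 2)
  for (f0 in seq(line_hz, max_harmonic_hz, by = line_hz)) {
    band <- which(freqs[1:(half + 1)] >= f0 - half_width_hz &
                    freqs[1:(half + 1)] <= f0 + half_width_hz)
    if (length(band) < 1) next
    lo <- min(band) - 1; hi <- max(band) + 1
    if (lo < 1 || hi > half + 1) next
    mag <- Mod(X[band]); ph <- Arg(X[band])
    interp <- approx(c(lo, hi), Mod(X[c(lo, hi)]), xout = band)$y
    X[band] <- complex(modulus = interp, argument = ph)
    ## mirror for conjugate symmetry
    mirror <- n - band + 2
    mirror <- mirror[mirror <= n & mirror > half + 1]
    X[mirror] <- Conj(X[n - mirror + 2])
  }
  Re(fft(X, inverse = TRUE)) / n
}

#' EMG envelope
#'
#' Full-wave rectification followed by a zero-phase 4th-order low-pass at
#' 10 Hz.
#'
#' @param x band-passed EMG signal.
#' @param fs sampling rate.
#' @param lowpass_hz envelope cutoff (10).
#' @export
emg_envelope <- function(x, fs, lowpass_hz = 10) {
  bandpass_zero_phase(abs(x), fs, 0, lowpass_hz, order = 4)
}

#' Single-threshold EMG burst detection
#'
#' Baseline = the 500 ms moving-average window with the lowest mean in
#' the span from 1 s before stimulus onset to the response time.  Bursts
#' are runs of contiguous samples more than 3 baseline SDs above the
#' baseline mean; runs separated by less than 20 ms are merged, and
#' isolated runs shorter than 25 ms are discarded.  The RT-generating
#' burst is the one whose onset-offset window contains
#' \code{stim_onset + rt}.
#'
#' @param envelope EMG envelope samples.
#' @param fs sampling rate.
#' @param stim_onset stimulus onset, seconds (in recording time).
#' @param rt response time, seconds (relative to onset); required.
#' @param search_pad seconds past the response time to keep searching
#'   (bursts may extend beyond the button press).
#' @param baseline_win_s baseline window length (0.5).
#' @param n_sd threshold in baseline SDs (3).
#' @param merge_gap_s merge gap (0.020).
#' @param min_dur_s minimum isolated burst duration (0.025).
#' @return list: \code{bursts} data.frame (onset, offset, peak_time,
#'   peak_amplitude, contains_rt), \code{rt_burst} row index or NA,
#'   \code{baseline_mean}, \code{baseline_sd}, \code{threshold}.
#' @export
detect_bursts <- function(envelope, fs, stim_onset, rt,
                          search_pad = 0.3, baseline_win_s = 0.5,
                          n_sd = 3, merge_gap_s = 0.020,
                          min_dur_s = 0.025) {
  if (is.na(rt)) stop("rt missing: burst detection requires a response time")
  i0 <- round((stim_onset - 1) * fs) + 1
  i_rt <- round((stim_onset + rt) * fs)
  i1 <- min(round((stim_onset + rt + search_pad) * fs), length(envelope))
  if (i0 < 1 || i_rt > length(envelope))
    stop("baseline window unavailable: envelope does not cover the search span")
  win_n <- round(baseline_win_s * fs)
  seg <- envelope[i0:i_rt]
  if (length(seg) <= win_n)
    stop("search span shorter than the baseline window")
  ## moving average via cumsum; window with lowest mean
  cs <- cumsum(c(0, seg))
  mv <- (cs[(win_n + 1):length(cs)] - cs[1:(length(cs) - win_n)]) / win_n
  b0 <- which.min(mv)
  base_seg <- seg[b0:(b0 + win_n - 1)]
  bmean <- mean(base_seg); bsd <- sd(base_seg)
  thr <- bmean + n_sd * bsd

  span <- envelope[i0:i1]
  above <- span > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs)) {
    ## merge runs separated by < 20 ms
    gap_n <- merge_gap_s * fs
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1 < gap_n) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    ## drop isolated short bursts
    keep <- (merged$end - merged$start + 1) / fs >= min_dur_s
    merged <- merged[keep, , drop = FALSE]
    runs <- merged
  }
  if (!nrow(runs)) {
    return(list(bursts = data.frame(onset = numeric(0), offset = numeric(0),
                                    peak_time = numeric(0),
                                    peak_amplitude = numeric(0),
                                    contains_rt = logical(0)),
                rt_burst = NA_integer_, baseline_mean = bmean,
                baseline_sd = bsd, threshold = thr))
  }
  t_of <- function(i) (i0 - 1 + i) / fs
  bursts <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    sel <- runs$start[i]:runs$end[i]
    pk <- sel[which.max(span[sel])]
    data.frame(onset = t_of(runs$start[i]), offset = t_of(runs$end[i]),
               peak_time = t_of(pk), peak_amplitude = span[pk])
  }))
  rt_time <- stim_onset + rt
  bursts$contains_rt <- bursts$onset <= rt_time & rt_time <= bursts$offset
  rt_b <- which(bursts$contains_rt)
  list(bursts = bursts,
       rt_burst = if (length(rt_b)) rt_b[1] else NA_integer_,
       baseline_mean = bmean, baseline_sd = bsd, threshold = thr)
}

#' Tukey-fence rejection of EMG peak amplitudes
#'
#' Per participant, amplitudes outside 1.5 interquartile ranges below the
#' first or above the third quartile are artifacts.
#'
#' @param amplitudes numeric vector for one participant.
#' @param k fence multiplier (1.5).
#' @return logical keep-mask.
#' @export
reject_outlier_peaks <- function(amplitudes, k = 1.5) {
  q <- quantile(amplitudes, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  amplitudes >= q[1] - k * iqr & amplitudes <= q[2] + k * iqr
}

#' Z-score epochs within participant
#'
#' One mean and SD per participant from all concatenated epoch samples,
#' applied to every sample.
#'
#' @param epochs an \code{epoch_matrix} or plain matrix (trials x time).
#' @return same structure with z-scored values.
#' @export
zscore_within_participant <- function(epochs) {
  vals <- if (inherits(epochs, "epoch_matrix")) epochs$values else epochs
  if (nrow(vals) < 2) stop("need at least 2 trials")
  m <- mean(vals); s <- sd(as.numeric(vals))
  if (s == 0) stop("zero SD: cannot z-score")
  z <- (vals - m) / s
  if (inherits(epochs, "epoch_matrix")) {
    epochs$values <- z
    epochs$z_scored <- TRUE
    epochs
  } else z
}

#' Peak-centred EMG epochs
#'
#' Cuts +/- 500 ms epochs around the RT-generating burst peak of each
#' responded trial, optionally decimating the 2 kHz envelope to 1 kHz.
#'
#' @param envelope EMG envelope.
#' @param fs envelope sampling rate.
#' @param events data.frame trial_index, onset_time_s, rt_s.
#' @param fs_out output rate (1000).
#' @param half_window_s epoch half width (0.5).
#' @param ... passed to \code{\link{detect_bursts}}.
#' @return \code{epoch_matrix} plus \code{peak_amplitude} per trial and
#'   \code{no_burst} trial indices.
#' @export
epoch_emg_peaks <- function(envelope, fs, events, fs_out = 1000,
                            half_window_s = 0.5, ...) {
  rel <- seq(-half_window_s, half_window_s, by = 1 / fs_out)
  keep <- !is.na(events$rt_s)
  ev <- events[keep, , drop = FALSE]
  rows <- list(); amps <- c(); idx <- c(); no_burst <- c()
  tvec_all <- seq_along(envelope) / fs
  for (i in seq_len(nrow(ev))) {
    det <- tryCatch(
      detect_bursts(envelope, fs, ev$onset_time_s[i], ev$rt_s[i], ...),
      error = function(e) NULL)
    if (is.null(det) || is.na(det$rt_burst)) {
      no_burst <- c(no_burst, ev$trial_index[i]); next
    }
    pk <- det$bursts$peak_time[det$rt_burst]
    if (pk - half_window_s < 0 || pk + half_window_s > tvec_all[length(tvec_all)]) {
      no_burst <- c(no_burst, ev$trial_index[i]); next
    }
    sel_t <- pk + rel
    rows[[length(rows) + 1]] <- approx(tvec_all, envelope, xout = sel_t)$y
    amps <- c(amps, det$bursts$peak_amplitude[det$rt_burst])
    idx <- c(idx, ev$trial_index[i])
  }
  if (!length(rows)) stop("no RT-generating bursts found")
  structure(list(values = do.call(rbind, rows), time = rel,
                 trial_index = idx, fs_epoch = fs_out,
                 lock = "emg_peak", baseline_window = NULL,
                 peak_amplitude = amps, no_burst = no_burst),
            class = "epoch_matrix")
}
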