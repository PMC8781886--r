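#' Sampled pulse trace
#'
#' Container for a 1-D sampled signal: either a contact PPG reference
#' (e.g. a 60 Hz finger-oximeter trace) or a predicted rPPG trace at the
#' video frame rate.
#'
#' @param samples numeric vector of samples.
#' @param rate sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return object of class `pulse_trace`.
#' @export
pulse_trace <- function(samples, rate, t0 = 0) {
  stopifnot(is.numeric(samples), rate > 0, is.finite(t0))
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0),
            class = "pulse_trace")
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf("pulse_trace: %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

#' Align a reference pulse to video frame times
#'
#' Normalises the reference trace to zero mean and unit variance, then
#' linearly interpolates it at the frame timestamps, yielding a label trace
#' on the video's time base. A constant reference has no variance; it is
#' mapped to all-zeros with a warning.
#'
#' @param ppg a [pulse_trace()] (e.g. 60 Hz oximeter samples).
#' @param frame_times numeric vector of frame timestamps in seconds; must
#'   lie within the reference's time span.
#' @return a [pulse_trace()] at the (median) frame rate.
#' @export
resample_reference <- function(ppg, frame_times) {
  tt <- trace_times(ppg)
  bad <- frame_times < tt[1] - 1e-9 | frame_times > tt[length(tt)] + 1e-9
  if (any(bad))
    stop("frame time ", format(frame_times[which(bad)[1]]),
         " s outside the reference span [", format(tt[1]), ", ",
         format(tt[length(tt)]), "] s")
  s <- ppg$samples
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0) {
    warning("constant reference trace; normalised to all-zeros")
    z <- numeric(length(s))
  } else {
    z <- (s - mean(s)) / sdv
  }
  out <- stats::approx(tt, z, xout = frame_times)$y
  rate <- 1 / stats::median(diff(frame_times))
  pulse_trace(out, rate = rate, t0 = frame_times[1])
}

#' Band-pass filter a pulse trace
#'
#' Zero-phase (forward-backward) Butterworth band-pass restricted to the
#' physiological pulse band. `order` is the order of the band-pass transfer
#' function (6 poles by default, i.e. a 3rd-order low/high prototype pair).
#'
#' @param trace a [pulse_trace()].
#' @param band passband `(low, high)` in Hz; default 0.7-2.5 Hz
#'   (42-150 bpm).
#' @param order band-pass filter order; must be even.
#' @return filtered [pulse_trace()] of the same length and rate.
#' @export
bandpass <- function(trace, band = c(0.7, 2.5), order = 6L) {
  stopifnot(inherits(trace, "pulse_trace"), length(band) == 2L,
            band[1] > 0, band[2] > band[1])
  if (order %% 2L != 0L) stop("band-pass order must be even")
  if (trace$rate <= 2 * band[2])
    stop("sampling rate ", trace$rate, " Hz too low for a ", band[2],
         " Hz passband edge")
  x <- trace$samples
  n <- length(x)
  # pad by ~3 cycles of the low band edge so start-up transients of the
  # forward-backward pass stay outside the returned samples
  padlen <- min(n - 1L, ceiling(3 * trace$rate / band[1]))
  if (n < 3L * (order + 1L))
    stop("trace too short (", n, " samples) for the filter warm-up")
  x <- x - mean(x)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  bf <- signal::butter(order %/% 2L, band / (trace$rate / 2), type = "pass")
  y <- signal::filtfilt(bf, ext)[padlen + seq_len(n)]
  pulse_trace(y, rate = trace$rate, t0 = trace$t0)
}

#' Spectral heart-rate estimate for one window
#'
#' Power spectral density of the mean-removed, Hann-windowed, zero-padded
#' window; the heart rate is 60 times the frequency of the largest peak
#' inside the pulse band. Zero-padding refines the frequency grid to at
#' most 0.01 Hz (0.6 bpm) per bin.
#'
#' @param window a [pulse_trace()] covering one analysis window.
#' @param band search band in Hz.
#' @return heart rate in beats per minute.
#' @export
estimate_hr_window <- function(window, band = c(0.7, 2.5)) {
  x <- window$samples
  if (all(x == 0)) stop("all-zero window: heart rate undefined")
  n <- length(x)
  x <- x - mean(x)
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  x <- x * h
  nfft <- 2^ceiling(log2(max(n, window$rate / 0.01)))
  sp <- stats::fft(c(x, numeric(nfft - n)))
  psd <- Mod(sp[seq_len(nfft %/% 2 + 1)])^2
  freq <- (seq_len(nfft %/% 2 + 1) - 1) * window$rate / nfft
  inband <- which(freq >= band[1] & freq <= band[2])
  if (!length(inband)) stop("no frequency bin inside the search band")
  60 * freq[inband[which.max(psd[inband])]]
}

#' Windowed heart-rate series
#'
#' Slides a 10 s window in 2 s steps over the trace and estimates the heart
#' rate of each window spectrally. A trace of duration `dur` yields
#' `floor((dur - window) / step) + 1` windows.
#'
#' @param trace a (band-passed) [pulse_trace()].
#' @param window,step window length and hop in seconds.
#' @param band spectral search band in Hz.
#' @return object of class `hr_series`: a data frame with columns
#'   `start_s`, `end_s`, `bpm`.
#' @export
windowed_hr <- function(trace, window = 10, step = 2, band = c(0.7, 2.5)) {
  n <- length(trace$samples)
  wlen <- round(window * trace$rate)
  slen <- step * trace$rate
  if (n < wlen) {
    warning("trace shorter than one ", window, " s window; empty series")
    return(hr_series(data.frame(start_s = numeric(0), end_s = numeric(0),
                                bpm = numeric(0))))
  }
  nwin <- floor((n - wlen) / slen) + 1
  rows <- lapply(seq_len(nwin) - 1, function(k) {
    i0 <- round(k * slen) + 1
    seg <- pulse_trace(trace$samples[i0:(i0 + wlen - 1)], trace$rate,
                       t0 = trace$t0 + k * step)
    data.frame(start_s = trace$t0 + k * step,
               end_s = trace$t0 + k * step + window,
               bpm = estimate_hr_window(seg, band))
  })
  hr_series(do.call(rbind, rows))
}

hr_series <- function(df) {
  stopifnot(all(c("start_s", "end_s", "bpm") %in% names(df)))
  structure(df, class = c("hr_series", "data.frame"))
}

check_aligned <- function(pred, ref) {
  if (nrow(pred) != nrow(ref))
    stop("window counts differ: ", nrow(pred), " vs ", nrow(ref))
  if (nrow(pred) && max(abs(pred$start_s - ref$start_s)) > 1e-6)
    stop("window starts are not aligned")
}

#' Heart-rate agreement metrics
#'
#' Mean absolute error, root-mean-square error and the Pearson correlation
#' between per-window heart-rate estimates and the ground truth, pooled
#' over all supplied windows.
#'
#' @param pred,ref aligned `hr_series` objects.
#' @return object of class `metrics_report` with fields `mae_bpm`,
#'   `rmse_bpm`, `pearson_r`, `n_windows`. With a single window (or a
#'   constant series) the correlation is undefined and reported as `NA`
#'   with a warning.
#' @export
compute_metrics <- function(pred, ref) {
  check_aligned(pred, ref)
  d <- pred$bpm - ref$bpm
  r <- NA_real_
  if (length(d) >= 2L && stats::sd(pred$bpm) > 0 && stats::sd(ref$bpm) > 0) {
    r <- stats::cor(pred$bpm, ref$bpm)
  } else {
    warning("Pearson correlation undefined (constant or single-window series)")
  }
  structure(list(mae_bpm = mean(abs(d)), rmse_bpm = sqrt(mean(d^2)),
                 pearson_r = r, n_windows = length(d)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("HR agreement over %d windows: MAE %.3f bpm, RMSE %.3f bpm, R %s\n",
              x$n_windows, x$mae_bpm, x$rmse_bpm,
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' Bland-Altman agreement table
#'
#' Per-window `(mean, difference)` pairs between two heart-rate series plus
#' the bias and the 1.96-standard-deviation limits of agreement, ready for
#' plotting or CSV export.
#'
#' @param pred,ref aligned `hr_series` objects.
#' @return list with a `table` data frame (`start_s`, `mean_bpm`,
#'   `diff_bpm`) and summary fields `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`.
#' @export
bland_altman_table <- function(pred, ref) {
  check_aligned(pred, ref)
  d <- pred$bpm - ref$bpm
  m <- (pred$bpm + ref$bpm) / 2
  sdd <- if (length(d) >= 2L) stats::sd(d) else 0
  bias <- mean(d)
  list(table = data.frame(start_s = pred$start_s, mean_bpm = m, diff_bpm = d),
       bias = bias, sd_diff = sdd,
       loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd)
}
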