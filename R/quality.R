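# Per-unit quality metrics: bandpass-filtered SNR, firing rate, ISI-violation
# ratio.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Bandpass filter specification
#'
#' Frequency-domain filter with error-function roll-offs, used only for SNR
#' computation (sorters apply their own internal filters). The gain at
#' frequency magnitude `f` (Hz) is
#' `A(f) = 1/2 * sqrt(1 + erf((f - fmin)/low_width)) *
#'         sqrt(1 - erf((f - fmax)/high_width))`,
#' which is 1 in the passband, 1/sqrt(2) at the band edges, and essentially 0
#' at DC.
#'
#' @param fmin,fmax Band edges in Hz (defaults 300 and 6000).
#' @param low_width,high_width Roll-off widths in Hz at the low and high
#'   edges (defaults 100 and 1000).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(fmin = 300, fmax = 6000, low_width = 100,
                        high_width = 1000) {
  stopifnot(fmin > 0, fmax > fmin, low_width > 0, high_width > 0)
  structure(list(fmin = fmin, fmax = fmax, low_width = low_width,
                 high_width = high_width),
            class = "filter_spec")
}

#' Filter gain at given frequencies
#'
#' @param f Frequencies in Hz (magnitudes; negative frequencies use `|f|`).
#' @param spec A [filter_spec()].
#' @return Gain values in `[0, 1]`.
#' @export
filter_gain <- function(f, spec = filter_spec()) {
  f <- abs(f)
  0.5 * sqrt(1 + erf((f - spec$fmin) / spec$low_width)) *
    sqrt(pmax(0, 1 - erf((f - spec$fmax) / spec$high_width)))
}

#' Bandpass-filter a recording
#'
#' Applies the filter per channel by a single full-length FFT, multiplication
#' by the real gain `A(|f|)`, and inverse FFT; output is real with the same
#' shape.
#'
#' @param rec A [recording()] with at least 2 samples.
#' @param spec A [filter_spec()].
#' @return The filtered [recording()].
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "recording"), ncol(rec$traces) >= 2)
  n <- ncol(rec$traces)
  freqs <- (seq_len(n) - 1L) / n * rec$sample_rate
  freqs <- pmin(freqs, rec$sample_rate - freqs)  # fold to magnitudes
  gain <- filter_gain(freqs, spec)
  out <- rec
  for (c in seq_len(nrow(rec$traces))) {
    out$traces[c, ] <- Re(stats::fft(stats::fft(rec$traces[c, ]) * gain,
                                     inverse = TRUE)) / n
  }
  out
}

#' Robust noise estimate of a filtered channel
#'
#' The median absolute deviation divided by 0.6745, a robust estimate of the
#' noise standard deviation that is insensitive to the spikes themselves.
#'
#' @param x Numeric vector of filtered samples (length >= 2).
#' @return Estimated noise standard deviation.
#' @export
estimate_noise <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  stats::mad(x, constant = 1 / 0.6745)
}

#' Average spike waveform around event times
#'
#' Extracts clips `[t - w_pre, t + w_post)` around each (floored) event time
#' and averages them. Events whose clip crosses a recording boundary are
#' dropped and counted.
#'
#' @param rec A [recording()].
#' @param event_times Event times in samples (1-based; fractional floored).
#' @param w_pre,w_post Samples before / after the event. Defaults cover 1 ms
#'   before to 2 ms after at the recording's sample rate.
#' @return Channels x (w_pre + w_post) matrix with attribute `n_used` (events
#'   averaged) and `n_dropped` (boundary-clipped events).
#' @export
average_waveform <- function(rec, event_times,
                             w_pre = round(0.001 * rec$sample_rate),
                             w_post = round(0.002 * rec$sample_rate)) {
  stopifnot(inherits(rec, "recording"), length(event_times) >= 1)
  t <- floor(event_times)
  ok <- t - w_pre >= 1 & t + w_post - 1 <= ncol(rec$traces)
  if (!any(ok)) stop("no events fully inside the recording", call. = FALSE)
  t <- t[ok]
  acc <- matrix(0, nrow(rec$traces), w_pre + w_post)
  for (ti in t) {
    acc <- acc + rec$traces[, (ti - w_pre):(ti + w_post - 1L), drop = FALSE]
  }
  w <- acc / length(t)
  attr(w, "n_used") <- length(t)
  attr(w, "n_dropped") <- sum(!ok)
  w
}

#' Per-unit signal-to-noise ratio
#'
#' Bandpass-filters the recording, averages the spike waveform over the
#' unit's events, takes its peak absolute amplitude across channels and time,
#' and divides by the robust noise estimate on the channel where that peak
#' occurs. Invariant under rescaling of the whole recording.
#'
#' @param rec A [recording()]; pass `filtered = TRUE` if already filtered.
#' @param event_times The unit's event times in samples.
#' @param spec A [filter_spec()].
#' @param filtered Set `TRUE` to skip filtering (e.g. when computing SNR for
#'   many units of one recording; filter once, then reuse).
#' @return List with `snr` (Inf flagged when the noise estimate is zero) and
#'   `peak_channel`.
#' @export
compute_snr <- function(rec, event_times, spec = filter_spec(),
                        filtered = FALSE) {
  frec <- if (filtered) rec else bandpass_filter(rec, spec)
  w <- average_waveform(frec, event_times)
  peak_idx <- which(abs(w) == max(abs(w)), arr.ind = TRUE)[1L, ]
  peak_channel <- as.integer(peak_idx[1L])
  peak_amp <- abs(w[peak_idx[1L], peak_idx[2L]])
  noise <- estimate_noise(frec$traces[peak_channel, ])
  snr <- if (noise == 0) Inf else peak_amp / noise
  list(snr = snr, peak_channel = peak_channel)
}

#' Inter-spike-interval violation ratio
#'
#' The number of inter-spike intervals shorter than the refractory threshold,
#' divided by the count expected under homogeneous Poisson firing at the
#' unit's mean rate: each of the `N - 1` intervals falls below `t_ref` with
#' probability `1 - exp(-lambda * t_ref)` where `lambda = N / duration`.
#' A well-isolated unit gives a ratio near 0; a Poisson train gives ~1.
#'
#' @param event_times_s Event times in seconds, nondecreasing.
#' @param duration_s Recording duration in seconds.
#' @param refractory_ms Refractory threshold in milliseconds (default 2.5).
#' @return The ratio; `NA` (with a warning) for fewer than 2 events.
#' @export
isi_violation_ratio <- function(event_times_s, duration_s,
                                refractory_ms = 2.5) {
  n <- length(event_times_s)
  if (n < 2L) {
    warning("ISI-violation ratio undefined for < 2 events", call. = FALSE)
    return(NA_real_)
  }
  if (is.unsorted(event_times_s)) {
    stop("event times must be nondecreasing", call. = FALSE)
  }
  t_ref <- refractory_ms / 1000
  v <- sum(diff(event_times_s) < t_ref)
  lambda <- n / duration_s
  e <- (n - 1) * (1 - exp(-lambda * t_ref))
  v / e
}

#' Quality metrics for units of a recording
#'
#' Bundles SNR, peak channel, firing rate, event count and ISI-violation
#' ratio for each requested unit. The recording is filtered once and reused.
#'
#' @param rec A [recording()].
#' @param f A [firings()] object with ground-truth or sorted events.
#' @param labels Unit labels to evaluate (default: all units in `f`).
#' @param spec A [filter_spec()].
#' @return Data frame with one row per unit: `label`, `snr`, `peak_channel`,
#'   `firing_rate` (Hz), `num_events`, `isi_violation_ratio`.
#' @export
compute_unit_quality <- function(rec, f, labels = firings_labels(f),
                                 spec = filter_spec()) {
  stopifnot(inherits(rec, "recording"), inherits(f, "firings"))
  missing_labels <- setdiff(labels, firings_labels(f))
  if (length(missing_labels)) {
    stop("unit(s) not present in firings: ",
         paste(missing_labels, collapse = ", "), call. = FALSE)
  }
  frec <- bandpass_filter(rec, spec)
  dur <- duration_s(rec)
  rows <- lapply(labels, function(l) {
    t <- unit_times(f, l)
    s <- compute_snr(frec, t, spec, filtered = TRUE)
    ivr <- if (length(t) >= 2) {
      isi_violation_ratio(t / rec$sample_rate, dur)
    } else NA_real_
    data.frame(label = l, snr = s$snr, peak_channel = s$peak_channel,
               firing_rate = length(t) / dur, num_events = length(t),
               isi_violation_ratio = ivr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
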