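#' Detect R peaks on an ECG channel
#'
#' Standard derivative-energy QRS detector: the ECG is band-passed 5-40 Hz
#' (zero phase), differenced and squared; an adaptive threshold at
#' `thresh_frac` times the local 2-second maximum of the detection function
#' selects candidate beats, a refractory period suppresses double firing, and
#' each detection is refined to the raw-ECG local extremum within
#' `refine_ms`. Neonatal rhythms (roughly 1.5-4 Hz) are the design target.
#'
#' @param ecg numeric vector, at least 3 s of data.
#' @param fs sampling rate in Hz.
#' @param refractory_ms minimum R-R spacing enforced, in ms.
#' @param thresh_frac adaptive threshold as a fraction of the rolling 2-s
#'   maximum of the detection function.
#' @param refine_ms half-width of the raw-ECG refinement window, in ms.
#' @param min_peak_to_peak floor on the ECG peak-to-peak amplitude below
#'   which the signal is declared to contain no QRS activity.
#' @return An object of class `"rpeaks"`: `indices` (strictly increasing
#'   sample indices), `fs`, `hr_freq` (Hz, from the median R-R interval) and
#'   `warnings` (character, e.g. implausible rate).
#' @examples
#' ecg <- synthetic_ecg_wave(sort(seq(128, 5000, by = 107)), 5120)
#' detect_r_peaks(ecg, 256)
#' @export
detect_r_peaks <- function(ecg, fs, refractory_ms = 200, thresh_frac = 0.4,
                           refine_ms = 40, min_peak_to_peak = 1e-6) {
  n <- length(ecg)
  if (n < 3 * fs) stop("need at least 3 s of ECG data")
  if (diff(range(ecg)) <= min_peak_to_peak)
    stop("no QRS activity: ECG peak-to-peak amplitude below floor")
  h <- design_fir_bandpass(5, min(40, fs / 2 - 1), fs)
  bp <- apply_fir_zerophase(ecg, h)
  det <- c(0, diff(bp))^2
  # rolling 2-s max, approximated blockwise (1-s blocks, max over 3 blocks)
  blk <- ceiling(seq_len(n) / fs)
  bmax <- tapply(det, blk, max)
  nb <- length(bmax)
  roll <- vapply(seq_len(nb),
                 function(b) max(bmax[max(1, b - 1):min(nb, b + 1)]), 0)
  thr <- thresh_frac * roll[blk]
  above <- det > thr & det > 1e-12 * max(det)
  if (!any(above)) stop("no QRS activity: detection function never crosses threshold")
  # group contiguous supra-threshold runs, take the detection-function argmax
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- mapply(function(s, e) s - 1L + which.max(det[s:e]),
                 starts[runs$values], ends[runs$values])
  cand <- sort(cand)
  refr <- round(refractory_ms / 1000 * fs)
  keep <- integer(0)
  last <- -Inf
  for (p in cand) {
    if (p - last >= refr) { keep <- c(keep, p); last <- p }
    else if (det[p] > det[keep[length(keep)]]) { keep[length(keep)] <- p; last <- p }
  }
  # refine to the raw-ECG extremum (sign chosen from the dominant deflection)
  w <- round(refine_ms / 1000 * fs)
  pol <- if (abs(max(ecg)) >= abs(min(ecg))) 1 else -1
  idx <- vapply(keep, function(p) {
    a <- max(1L, p - w); b <- min(n, p + w)
    a - 1L + which.max(pol * ecg[a:b])
  }, 0)
  idx <- sort(unique(idx))
  # a refinement can merge neighbours; re-apply the refractory rule
  if (length(idx) > 1L) {
    d <- diff(idx)
    while (any(d < refr)) {
      i <- which(d < refr)[1]
      drop <- if (pol * ecg[idx[i]] >= pol * ecg[idx[i + 1]]) i + 1L else i
      idx <- idx[-drop]
      d <- diff(idx)
      if (length(idx) < 2L) break
    }
  }
  if (length(idx) < 2L) stop("no QRS activity: fewer than 2 beats detected")
  res <- rpeaks(idx, fs)
  if (res$hr_freq < 0.5 || res$hr_freq > 5)
    res$warnings <- c(res$warnings, sprintf(
      "detected rate %.2f Hz outside the plausible [0.5, 5] Hz range",
      res$hr_freq))
  res
}

#' R-peak series constructor
#'
#' @param indices strictly increasing sample indices of R peaks.
#' @param fs sampling rate in Hz.
#' @return An object of class `"rpeaks"` with the heart-rate frequency
#'   derived from the median R-R interval.
#' @export
rpeaks <- function(indices, fs) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop("R-peak indices must be strictly increasing")
  structure(list(indices = indices, fs = fs,
                 hr_freq = if (length(indices) >= 2L)
                   fs / stats::median(diff(indices)) else NA_real_,
                 warnings = character(0)),
            class = "rpeaks")
}

#' @export
print.rpeaks <- function(x, ...) {
  cat(sprintf("<rpeaks> %d beats @ %g Hz, heart rate %.3f Hz\n",
              length(x$indices), x$fs, x$hr_freq))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Heart-rate frequency from an R-peak series
#'
#' Returns `fs / median(diff(indices))`, the beat frequency in Hz implied by
#' the median R-R interval (robust to occasional missed or ectopic beats).
#' Neonatal rates are typically near 2.4 Hz.
#'
#' @param rp an [rpeaks()] series with at least two peaks.
#' @return heart-rate frequency in Hz.
#' @export
heart_rate_frequency <- function(rp) {
  stopifnot(inherits(rp, "rpeaks"))
  if (length(rp$indices) < 2L)
    stop("need at least 2 R peaks to estimate a rate")
  rp$fs / stats::median(diff(rp$indices))
}

#' Pulse-waveform template
#'
#' The per-beat waveform used to synthesize the Artificial Pulse Signal: a
#' linear saw-tooth ramp from 0 to 1 over `rise_fraction` of the beat,
#' followed by a raised-cosine decay back to 0. The shape mimics the high
#' amplitude and slow temporal progression of the vascular pulse, in contrast
#' to the rapid QRS deflection of the ECG. The template has a single global
#' maximum (value 1) and starts/ends at 0.
#'
#' @param duration nominal template duration in seconds (each beat instance
#'   is rescaled to the local R-R interval at synthesis time).
#' @param rise_fraction fraction of the duration spent on the rising ramp,
#'   in (0, 1).
#' @param fs sampling rate used to sample `samples`.
#' @return An object of class `"pulse_template"` with fields `duration`,
#'   `rise_fraction` and `samples` (unit-normalized waveform).
#' @export
pulse_template <- function(duration = 0.4, rise_fraction = 0.35, fs = 256) {
  stopifnot(duration > 0, rise_fraction > 0, rise_fraction < 1)
  n <- max(3L, round(duration * fs))
  u <- seq(0, 1, length.out = n)
  u[which.min(abs(u - rise_fraction))] <- rise_fraction  # sampled max = 1
  structure(list(duration = duration, rise_fraction = rise_fraction,
                 samples = pulse_shape(u, rise_fraction)),
            class = "pulse_template")
}

# saw-tooth rise + raised-cosine fall on normalized phase u in [0, 1]
pulse_shape <- function(u, rise_fraction) {
  ifelse(u <= rise_fraction,
         u / rise_fraction,
         0.5 * (1 + cos(pi * (u - rise_fraction) / (1 - rise_fraction))))
}

#' Synthesize the Artificial Pulse Signal (APS)
#'
#' Emits one pulse-template instance per detected heartbeat, with the
#' per-beat maximum aligned `delay` ms after each R peak (250 ms by default,
#' the typical lag of the vascular pulse behind ventricular depolarization).
#' Each instance spans the local R-R interval so consecutive instances never
#' overlap; the final beat reuses the median R-R interval and is truncated at
#' the end of the signal.
#'
#' @param rp an [rpeaks()] series (non-empty).
#' @param n_samples length of the output vector.
#' @param fs sampling rate in Hz.
#' @param delay delay of the per-beat maximum after the R peak, in ms.
#' @param template a [pulse_template()] supplying the rise fraction/shape.
#' @return numeric vector of length `n_samples`, zero baseline, one template
#'   instance per beat with unit maximum.
#' @examples
#' rp <- rpeaks(c(256, 512), 256)
#' aps <- synthesize_aps(rp, 700, 256)
#' which.max(aps[257:512]) + 256  # 320 = 256 + 0.250 * 256
#' @export
synthesize_aps <- function(rp, n_samples, fs, delay = 250,
                           template = pulse_template(fs = fs)) {
  stopifnot(inherits(rp, "rpeaks"), delay >= 0)
  r <- rp$indices
  if (length(r) == 0L) stop("empty R-peak series")
  d <- round(delay / 1000 * fs)
  if (n_samples < r[length(r)] + d)
    stop("n_samples too small to place the last beat's delayed pulse")
  rr <- diff(r)
  med_rr <- if (length(rr)) stats::median(rr) else round(fs / 2.4)
  rr <- c(rr, med_rr)
  rf <- template$rise_fraction
  out <- numeric(n_samples)
  for (i in seq_along(r)) {
    ti <- rr[i]                       # beat-local template length (samples)
    peak_at <- r[i] + d
    # phase anchored at the peak sample so the sampled maximum is exactly 1
    a <- ceiling(peak_at - rf * ti)
    b <- floor(peak_at + (1 - rf) * ti)
    ks <- max(1L, a):min(n_samples, b)
    u <- (ks - peak_at) / ti + rf
    out[ks] <- pmax(out[ks], pulse_shape(pmin(1, pmax(0, u)), rf))
  }
  out
}

#' Normalize a signal to the mean peak-to-peak EEG amplitude
#'
#' Rescales `signal` by `MAmpEEG / AmpSignal`, where `MAmpEEG` is the mean
#' over EEG channels of the per-channel peak-to-peak amplitude (max - min
#' over the whole segment) and `AmpSignal` is the signal's own peak-to-peak
#' amplitude. This puts the millivolt-scale ECG and the unit-scale APS on the
#' microvolt scale of the EEG before they are appended to the SOBI input, so
#' that all input signals share an amplitude order of magnitude. The
#' operation is idempotent.
#'
#' @param signal numeric vector with nonzero peak-to-peak amplitude.
#' @param eeg EEG matrix (channels x samples).
#' @param robust if `TRUE`, peak-to-peak amplitudes use the 0.5th-99.5th
#'   percentile spread instead of the literal max - min, guarding against
#'   single-sample spikes.
#' @return the rescaled signal; its peak-to-peak amplitude equals `MAmpEEG`.
#' @export
normalize_amplitude <- function(signal, eeg, robust = FALSE) {
  if (anyNA(signal) || anyNA(eeg)) stop("NaN/NA in inputs")
  if (length(eeg) == 0L) stop("empty EEG matrix")
  ptp <- function(x) {
    if (robust) diff(stats::quantile(x, c(0.005, 0.995), names = FALSE))
    else diff(range(x))
  }
  amp_sig <- ptp(signal)
  if (amp_sig <= 0) stop("signal peak-to-peak amplitude is zero")
  m_amp_eeg <- mean(apply(as.matrix(eeg), 1L, ptp))
  signal * (m_amp_eeg / amp_sig)
}
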