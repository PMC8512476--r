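#' Standard 19-channel neonatal montage labels
#'
#' The 10-20 positions used by the synthetic generator, in recording order.
#' @return character vector of 19 labels.
#' @export
neonatal_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

# Default per-channel leakage gains (uV, multiply unit-max source waveforms).
# The electrical cardiac leak spreads over every channel, strongest
# temporally/frontally, with clearly visible R spikes (tens of uV) as in
# contaminated clinical recordings. The pulse artifact reaches all channels
# through volume conduction but is concentrated (2-3x) on the fronto-central
# channels near the anterior fontanelle (around Fz/Cz).
default_ecc_weights <- function() {
  w <- c(Fp1 = 40, Fp2 = 44, F7 = 30, F3 = 16, Fz = 12, F4 = 16, F8 = 30,
         T7 = 50, C3 = 20, Cz = 12, C4 = 20, T8 = 50,
         P7 = 24, P3 = 10, Pz = 8, P4 = 10, P8 = 24, O1 = 6, O2 = 6)
  w[neonatal_montage()]
}

default_pcc_weights <- function() {
  w <- c(Fp1 = 14, Fp2 = 14, F7 = 10, F3 = 18, Fz = 24, F4 = 18, F8 = 10,
         T7 = 10, C3 = 16, Cz = 24, C4 = 16, T8 = 10,
         P7 = 8, P3 = 9, Pz = 10, P4 = 9, P8 = 8, O1 = 8, O2 = 8)
  w[neonatal_montage()]
}

#' Simulation configuration
#'
#' Parameters of the synthetic contaminated neonatal recording. Defaults
#' emulate a 5-minute, 19-channel, 256 Hz neonatal segment with a 2.4 Hz
#' heart rate, mild R-R jitter, an electrical cardiac leak spread over many
#' channels and a pulse artifact delayed 250 +/- 20 ms after the R peaks and
#' concentrated fronto-centrally.
#'
#' @param n_channels number of EEG channels.
#' @param fs sampling rate, Hz.
#' @param duration segment length, s.
#' @param hr_freq mean heart rate, Hz.
#' @param rr_jitter fractional standard deviation of the R-R intervals.
#' @param pulse_delay_ms mean pulse delay after the R peak, ms.
#' @param pulse_delay_jitter_ms half-range of the per-beat uniform delay
#'   jitter, ms.
#' @param ecc_channel_weights,pcc_channel_weights per-channel leakage gains
#'   in uV (multiply unit-maximum artifact waveforms); `NULL` uses the
#'   defaults described above. Set to zero vectors for artifact-free data.
#' @param brain_band low/high corner of the brain background, Hz (1/f-shaped
#'   within the band).
#' @param brain_rms per-channel RMS of the brain mixture, uV.
#' @param seizure add a seizure-like rhythmic burst source.
#' @param seizure_freq_range burst carrier frequency range, Hz.
#' @param seizure_duty fraction of time the burst is on.
#' @param snr_db sensor-noise SNR relative to the brain mixture, dB.
#' @param seed integer RNG seed; all randomness flows from it.
#' @return a `"simulation_config"` list.
#' @export
simulation_config <- function(n_channels = 19, fs = 256, duration = 300,
                              hr_freq = 2.4, rr_jitter = 0.03,
                              pulse_delay_ms = 250,
                              pulse_delay_jitter_ms = 20,
                              ecc_channel_weights = NULL,
                              pcc_channel_weights = NULL,
                              brain_band = c(0.5, 8), brain_rms = 20,
                              seizure = FALSE,
                              seizure_freq_range = c(1, 3),
                              seizure_duty = 0.5,
                              snr_db = 20, seed = 1) {
  if (is.null(ecc_channel_weights))
    ecc_channel_weights <- if (n_channels == 19) unname(default_ecc_weights())
                           else rep(10, n_channels)
  if (is.null(pcc_channel_weights))
    pcc_channel_weights <- if (n_channels == 19) unname(default_pcc_weights())
                           else c(rep(15, ceiling(n_channels / 3)),
                                  rep(0, n_channels - ceiling(n_channels / 3)))
  stopifnot(fs > 0, duration > 0, hr_freq > 0, rr_jitter >= 0,
            length(ecc_channel_weights) == n_channels,
            length(pcc_channel_weights) == n_channels)
  structure(list(n_channels = n_channels, fs = fs, duration = duration,
                 hr_freq = hr_freq, rr_jitter = rr_jitter,
                 pulse_delay_ms = pulse_delay_ms,
                 pulse_delay_jitter_ms = pulse_delay_jitter_ms,
                 ecc_channel_weights = ecc_channel_weights,
                 pcc_channel_weights = pcc_channel_weights,
                 brain_band = brain_band, brain_rms = brain_rms,
                 seizure = seizure, seizure_freq_range = seizure_freq_range,
                 seizure_duty = seizure_duty, snr_db = snr_db, seed = seed),
            class = "simulation_config")
}

#' Synthetic ECG waveform from R-peak positions
#'
#' Unit-amplitude ECG-like waveform: a Gaussian second-derivative (Ricker)
#' QRS spike of about 80 ms support centered at each R index (so the
#' waveform's per-beat maximum coincides exactly with the R peak), plus a low
#' cosine T-wave bump 200 ms later.
#'
#' @param r_indices R-peak sample indices.
#' @param n output length in samples.
#' @param fs sampling rate, Hz.
#' @param t_wave_amp relative T-wave amplitude.
#' @return numeric vector of length `n`, QRS peak value 1.
#' @export
synthetic_ecg_wave <- function(r_indices, n, fs = 256, t_wave_amp = 0.2) {
  out <- numeric(n)
  sigma <- 0.02 * fs                      # zero crossings at +/- sigma
  half <- round(4 * sigma)
  k <- -half:half
  qrs <- (1 - (k / sigma)^2) * exp(-0.5 * (k / sigma)^2)
  t_off <- round(0.2 * fs)
  t_half <- round(0.06 * fs)
  tk <- -t_half:t_half
  twave <- t_wave_amp * 0.5 * (1 + cos(pi * tk / t_half))
  add_at <- function(sig, center, shape, offs) {
    ks <- center + offs
    ok <- ks >= 1L & ks <= n
    sig[ks[ok]] <- sig[ks[ok]] + shape[ok]
    sig
  }
  for (r in r_indices) {
    out <- add_at(out, r, qrs, k)
    out <- add_at(out, r + t_off, twave, tk)
  }
  out
}

# 1/f-shaped Gaussian noise, band-limited; unit standard deviation
shaped_brain_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                    # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, band[1]))
  g[f > band[2]] <- 0
  g[f < 0.1] <- 0
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

# amplitude-modulated rhythmic burst source (seizure-like), unit sd
seizure_source <- function(n, fs, freq_range, duty) {
  f <- stats::runif(1, freq_range[1], freq_range[2])
  t <- (0:(n - 1)) / fs
  period <- 10 * fs                       # 10-s on/off cycle
  on_len <- round(duty * period)
  env <- rep(c(rep(1, on_len), rep(0, period - on_len)),
             length.out = n)
  ramp <- round(0.5 * fs)
  h <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  env <- stats::filter(env, rep(1 / ramp, ramp), sides = 2)
  env[is.na(env)] <- 0
  y <- sin(2 * pi * f * t) * as.numeric(env)
  if (stats::sd(y) == 0) y[1] <- 1e-9
  y / stats::sd(y)
}

#' Generate a contaminated synthetic neonatal recording
#'
#' Produces a [recording()] together with its complete ground truth. The EEG
#' is the sum of (i) `n_channels - 2` independent 1/f-shaped band-limited
#' brain sources mixed by a random full-rank matrix, (ii) an electrical
#' cardiac leak (the ECG waveform scaled per channel by
#' `ecc_channel_weights`), (iii) a pulse artifact (saw-tooth/cosine template
#' train, per-beat maximum `pulse_delay_ms` +/- jitter after each R peak,
#' scaled by `pcc_channel_weights`) and (iv) white sensor noise at `snr_db`.
#' The ECG channel is a clean synthetic ECG at millivolt scale. Deterministic
#' given `cfg$seed`; the global RNG state is left untouched.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `recording` (a [recording()]) and `truth`
#'   (class `"ground_truth"`): brain sources and mixing, artifact sources,
#'   weights, noise, R-peak indices and realized heart rate.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old_seed, envir = .GlobalEnv)
  })
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  mean_rr <- fs / cfg$hr_freq
  if (n < 2 * mean_rr) stop("duration too short for one beat")
  # R-peak train with jittered R-R intervals
  r <- round(0.4 * fs)
  repeat {
    rr <- mean_rr * (1 + stats::rnorm(1, sd = cfg$rr_jitter))
    rr <- max(rr, 0.2 * fs)
    nxt <- r[length(r)] + round(rr)
    if (nxt > n - fs) break                # 1-s tail margin
    r <- c(r, nxt)
  }
  if (length(r) < 2L) stop("duration too short for one beat")
  ecg_wave <- synthetic_ecg_wave(r, n, fs)
  ecg <- 1.2 * ecg_wave                    # mV scale
  ecg <- ecg + stats::rnorm(n, sd = sqrt(mean(ecg^2)) * 10^(-30 / 20))
  # pulse source: per-beat delayed template, unit maximum
  rr_loc <- c(diff(r), round(stats::median(diff(r))))
  d <- round((cfg$pulse_delay_ms +
              stats::runif(length(r), -cfg$pulse_delay_jitter_ms,
                           cfg$pulse_delay_jitter_ms)) / 1000 * fs)
  rf <- 0.35
  pcc_source <- numeric(n)
  for (i in seq_along(r)) {
    ti <- rr_loc[i]
    peak_at <- r[i] + d[i]
    ks <- max(1L, ceiling(peak_at - rf * ti)):
      min(n, floor(peak_at + (1 - rf) * ti))
    u <- (ks - peak_at) / ti + rf
    pcc_source[ks] <- pmax(pcc_source[ks],
                           pulse_shape(pmin(1, pmax(0, u)), rf))
  }
  ecc_source <- ecg_wave / max(abs(ecg_wave))
  # brain sources and mixing
  nb <- cfg$n_channels - 2L
  brain <- matrix(0, nb, n)
  for (i in seq_len(nb))
    brain[i, ] <- shaped_brain_noise(n, fs, cfg$brain_band)
  if (cfg$seizure)
    brain[nb, ] <- seizure_source(n, fs, cfg$seizure_freq_range,
                                  cfg$seizure_duty)
  mixing <- matrix(stats::rnorm(cfg$n_channels * nb), cfg$n_channels, nb) /
    sqrt(nb) * cfg$brain_rms
  brain_mix <- mixing %*% brain
  ecc_contrib <- outer(cfg$ecc_channel_weights, ecc_source)
  pcc_contrib <- outer(cfg$pcc_channel_weights, pcc_source)
  noise_sd <- sqrt(rowMeans(brain_mix^2)) * 10^(-cfg$snr_db / 20)
  noise <- matrix(stats::rnorm(cfg$n_channels * n), cfg$n_channels, n) *
    noise_sd
  eeg <- brain_mix + ecc_contrib + pcc_contrib + noise
  labels <- if (cfg$n_channels == 19) neonatal_montage()
            else paste0("EEG", seq_len(cfg$n_channels))
  rec <- recording(eeg, ecg, fs, labels,
                   meta = list(synthetic = TRUE, seed = cfg$seed))
  truth <- structure(list(
    brain_sources = brain, brain_mixing = mixing,
    ecc_source = ecc_source, ecc_weights = cfg$ecc_channel_weights,
    pcc_source = pcc_source, pcc_weights = cfg$pcc_channel_weights,
    noise = noise, r_peak_indices = r,
    hr_freq = fs / stats::median(diff(r)), config = cfg),
    class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' Score a decomposition against simulation ground truth
#'
#' For each planted artifact source (electrical cardiac, pulse), reports the
#' best absolute Pearson correlation over all ICs, the matching IC index, the
#' label that IC received and whether it is the correct one (ECC for the
#' electrical leak, PCC for the pulse). Also counts false alarms on
#' brain-only ICs: components labeled ECC or PCC that match neither a planted
#' artifact source nor one of the auxiliary nECG/nAPS inputs.
#'
#' @param dec a [sobi_decompose()] result computed on the generated
#'   recording.
#' @param labels the per-IC labels (an `ic_classification` or a list of
#'   `ic_label`).
#' @param gt the `"ground_truth"` from [generate_recording()].
#' @return list with elements `ecc`, `pcc` (each: `best_ic`, `r`, `label`,
#'   `correct`), `false_alarms`, `n_brain_ics` (ICs matching neither a
#'   planted artifact nor an auxiliary input) and `n_ics`.
#' @export
score_against_truth <- function(dec, labels, gt) {
  stopifnot(inherits(dec, "sobi_decomposition"),
            inherits(gt, "ground_truth"))
  labs <- if (inherits(labels, "ic_classification"))
    vapply(labels$labels, `[[`, "", "label")
  else vapply(labels, `[[`, "", "label")
  S <- dec$sources
  match_one <- function(src, want) {
    r <- abs(as.numeric(stats::cor(t(S), src)))
    r[!is.finite(r)] <- 0
    i <- which.max(r)
    list(best_ic = i, r = r[i], label = labs[i],
         correct = identical(labs[i], want))
  }
  has_ecc <- any(gt$ecc_weights != 0)
  has_pcc <- any(gt$pcc_weights != 0)
  ecc <- if (has_ecc) match_one(gt$ecc_source, "ECC") else NULL
  pcc <- if (has_pcc) match_one(gt$pcc_source, "PCC") else NULL
  artefact_ics <- c(if (has_ecc) ecc$best_ic, if (has_pcc) pcc$best_ic)
  # ICs that capture the auxiliary nECG/nAPS inputs themselves (present for
  # G1/G2 groups regardless of planted leakage) are cardiac by construction,
  # not brain components: exclude them from the false-alarm count
  aux_ics <- integer(0)
  if (length(dec$group$aux_rows)) {
    ra <- abs(stats::cor(t(S),
                         t(dec$group$data[dec$group$aux_rows, ,
                                          drop = FALSE])))
    ra[!is.finite(ra)] <- 0
    aux_ics <- which(apply(ra, 1L, max) > 0.9)
  }
  brain_only <- setdiff(seq_along(labs), union(artefact_ics, aux_ics))
  fa <- sum(labs[brain_only] != "NCC")
  list(ecc = ecc, pcc = pcc, false_alarms = fa,
       n_brain_ics = length(brain_only), n_ics = length(labs))
}
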