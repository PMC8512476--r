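#' Artefactual Percentage Index of Components (APICs)
#'
#' For each IC, the PSD value at the grid bin nearest the heart-rate
#' frequency, expressed as a percentage of the summed value across all ICs:
#' `APICs_j = 100 * cPSDhr_j / sum_i cPSDhr_i`. This normalization makes the
#' per-IC cardiac-band power comparable across decompositions with different
#' IC counts (21/20/19). The vector sums to 100.
#'
#' @param psds list of [welch_psd()] estimates, one per IC, on a common grid.
#' @param hr_freq heart-rate frequency in Hz (within the PSD band).
#' @param band optional half-width in Hz; when positive, `cPSDhr` is the
#'   integral over `hr_freq +/- band` instead of the single nearest bin.
#' @return numeric vector of percentages, one per IC.
#' @export
compute_apics <- function(psds, hr_freq, band = 0) {
  stopifnot(length(psds) >= 1L)
  f0 <- psds[[1]]$freqs
  for (p in psds)
    if (length(p$freqs) != length(f0) || any(p$freqs != f0))
      stop("all PSDs must share one frequency grid")
  if (hr_freq < min(f0) || hr_freq > max(f0))
    stop("hr_freq (", hr_freq, " Hz) outside the PSD band")
  cpsd <- if (band > 0) {
    sel <- abs(f0 - hr_freq) <= band
    vapply(psds, function(p) sum(p$power[sel]), 0)
  } else {
    vapply(psds, psd_at, 0, freq = hr_freq)
  }
  tot <- sum(cpsd)
  if (tot <= 0) stop("no cardiac-band power: total PSD at hr_freq is zero")
  100 * cpsd / tot
}

#' Fraction of contaminated components (CC)
#'
#' `CC = K / N` where `K` counts the ICs whose APICs strictly exceeds
#' `threshold` percent and `N` is the total IC count. A low CC means the
#' cardiac-band power is concentrated in few components.
#'
#' @param apics an [compute_apics()] vector.
#' @param threshold percentage cut (strict inequality).
#' @return fraction in `[0, 1]`.
#' @export
contaminated_components <- function(apics, threshold = 1) {
  sum(apics > threshold) / length(apics)
}

#' Artefactual Percentage Index (API)
#'
#' The summed APICs over the ICs classified as artefactual: the percentage of
#' all heart-rate-frequency power captured by the components that will be
#' removed. Values near 100 mean the cardiac interference is almost entirely
#' contained in the labeled components.
#'
#' @param apics an [compute_apics()] vector.
#' @param artefactual_ics integer indices of the artefactual ICs (possibly
#'   empty).
#' @return percentage in `[0, 100]`.
#' @export
artefactual_percentage_index <- function(apics, artefactual_ics) {
  artefactual_ics <- as.integer(artefactual_ics)
  if (length(artefactual_ics) == 0L) return(0)
  if (min(artefactual_ics) < 1L || max(artefactual_ics) > length(apics))
    stop("artefactual_ics out of range")
  sum(apics[artefactual_ics])
}

#' Signal Power Variation (SPV)
#'
#' Per-channel percentage change in total power,
#' `(Power_b - Power_a) / Power_b * 100`, averaged over `channel_subset`.
#' Power is the sum of squared mean-removed samples. Large SPV indicates that
#' artifact removal discarded much of the channel's energy; small SPV that
#' the background EEG was preserved.
#'
#' @param eeg_before,eeg_after EEG matrices of identical shape.
#' @param channel_subset channel indices entering the average (default all;
#'   for seizure segments only the channels actually affected by cardiac
#'   interference are typically used).
#' @return percentage (may be negative if power increased).
#' @export
signal_power_variation <- function(eeg_before, eeg_after,
                                   channel_subset = seq_len(nrow(eeg_before))) {
  stopifnot(all(dim(eeg_before) == dim(eeg_after)))
  pow <- function(x) sum((x - mean(x))^2)
  pc <- vapply(channel_subset, function(i) {
    pb <- pow(eeg_before[i, ])
    if (pb <= 0) stop("zero power in channel ", i, " before removal")
    (pb - pow(eeg_after[i, ])) / pb * 100
  }, 0)
  mean(pc)
}

#' Variation of R Peak Power (varRPP)
#'
#' For each channel, the R-peak power `RPP = sum_j x[R_j]^2 / N_R` is
#' evaluated before and after artifact removal; varRPP is the mean over
#' channels of `(RPP_b - RPP_a) / RPP_b * 100`. Because the electrical
#' cardiac leak is QRS-locked, successful removal shows up as a large
#' reduction of EEG amplitude exactly at the R-peak samples.
#'
#' @param eeg_before,eeg_after EEG matrices of identical shape.
#' @param rp an [rpeaks()] series with indices within the matrix width.
#' @return percentage.
#' @export
var_r_peak_power <- function(eeg_before, eeg_after, rp) {
  stopifnot(all(dim(eeg_before) == dim(eeg_after)), inherits(rp, "rpeaks"))
  idx <- rp$indices
  if (min(idx) < 1L || max(idx) > ncol(eeg_before))
    stop("R-peak indices out of bounds")
  rpp <- function(x) sum(x[idx]^2) / length(idx)
  pc <- vapply(seq_len(nrow(eeg_before)), function(i) {
    rb <- rpp(eeg_before[i, ])
    if (rb <= 0) stop("zero R-peak power in channel ", i, " before removal")
    (rb - rpp(eeg_after[i, ])) / rb * 100
  }, 0)
  mean(pc)
}

#' Variation of PSD at the heart-rate frequency (varPSDhr)
#'
#' Per-channel percentage change of the Welch PSD at the bin nearest
#' `hr_freq`, averaged over `channel_subset`. Both the electrical and the
#' pulsatile interference beat at the heart rate, so effective removal
#' reduces this quantity toward 100%; negative values (power increase) are
#' reported as-is, never clamped.
#'
#' @param eeg_before,eeg_after EEG matrices of identical shape.
#' @param hr_freq heart-rate frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param channel_subset channel indices entering the average.
#' @return percentage.
#' @export
var_psd_hr <- function(eeg_before, eeg_after, hr_freq, fs,
                       channel_subset = seq_len(nrow(eeg_before))) {
  stopifnot(all(dim(eeg_before) == dim(eeg_after)))
  pc <- vapply(channel_subset, function(i) {
    pb <- psd_at(welch_psd(eeg_before[i, ], fs), hr_freq)
    if (pb <= 0) stop("zero PSD at hr_freq in channel ", i, " before removal")
    pa <- psd_at(welch_psd(eeg_after[i, ], fs), hr_freq)
    (pb - pa) / pb * 100
  }, 0)
  mean(pc)
}

#' Assemble an evaluation report
#'
#' Bundles the decomposition-quality metrics (APICs, CC, API) and the
#' reconstruction-quality metrics (SPV, varRPP, varPSDhr) for one
#' before/after pair.
#'
#' @param apics per-IC APICs vector.
#' @param artefactual_ics indices of the removed ICs.
#' @param eeg_before,eeg_after EEG before and after removal.
#' @param rp [rpeaks()] of the segment.
#' @param hr_freq heart-rate frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param channel_subset channels used for SPV/varPSDhr.
#' @param cc_threshold APICs percentage cut for CC.
#' @return An object of class `"evaluation_report"` with fields `apics`,
#'   `cc`, `api`, `spv`, `var_rpp`, `var_psd_hr`, `hr_freq`,
#'   `channel_subset`.
#' @export
evaluation_report <- function(apics, artefactual_ics, eeg_before, eeg_after,
                              rp, hr_freq, fs,
                              channel_subset = seq_len(nrow(eeg_before)),
                              cc_threshold = 1) {
  structure(list(
    apics = apics,
    cc = contaminated_components(apics, cc_threshold),
    api = artefactual_percentage_index(apics, artefactual_ics),
    spv = signal_power_variation(eeg_before, eeg_after, channel_subset),
    var_rpp = var_r_peak_power(eeg_before, eeg_after, rp),
    var_psd_hr = var_psd_hr(eeg_before, eeg_after, hr_freq, fs,
                            channel_subset),
    hr_freq = hr_freq, channel_subset = channel_subset),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<evaluation_report> hr = %.3f Hz\n",
    "  CC = %.3f  API = %.2f%%\n",
    "  SPV = %.2f%%  varRPP = %.2f%%  varPSDhr = %.2f%%\n"),
    x$hr_freq, x$cc, x$api, x$spv, x$var_rpp, x$var_psd_hr))
  invisible(x)
}

#' Write an evaluation report as a flat key-value text file
#'
#' Scalars are written unrounded as `key<TAB>value` lines, followed by a
#' per-IC APICs table.
#'
#' @param report an [evaluation_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("cc", "api", "spv", "var_rpp", "var_psd_hr", "hr_freq"))
    writeLines(paste(k, format(report[[k]], digits = 15), sep = "\t"), con)
  writeLines("ic\tapics", con)
  for (j in seq_along(report$apics))
    writeLines(paste(j, format(report$apics[j], digits = 15), sep = "\t"),
               con)
  invisible(path)
}
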