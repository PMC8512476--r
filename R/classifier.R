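#' Welch power spectral density on a 0.01 Hz grid
#'
#' Averaged modified periodogram with Hamming windowing and 50% overlap.
#' Segments of 100 s are used when available (the shortest window whose
#' native resolution reaches 0.01 Hz at 256 Hz); shorter signals fall back to
#' the largest power-of-two window and the FFT is zero-padded so the
#' returned grid always has a constant `resolution` spacing. The estimate is
#' one-sided density (power per Hz), restricted to `fmin`-`fmax`.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param fmin,fmax band limits of the returned grid, Hz.
#' @param resolution grid spacing in Hz.
#' @param window_s nominal segment length in seconds.
#' @return An object of class `"psd_estimate"`: `freqs` (Hz, constant
#'   `resolution` step), `power` (non-negative density values) and `window`
#'   (descriptor of the realized segmentation).
#' @examples
#' x <- sin(2 * pi * 2.4 * (0:76799) / 256)
#' p <- welch_psd(x, 256)
#' p$freqs[which.max(p$power)]  # 2.4
#' @export
welch_psd <- function(x, fs, fmin = 0.5, fmax = 45, resolution = 0.01,
                      window_s = 100) {
  n <- length(x)
  win <- round(window_s * fs)
  if (n < win) win <- 2L^floor(log2(n))
  min_win <- round(2 * fs)
  if (win < min_win)
    stop("signal too short for a Welch window: have ", n,
         " samples, need at least ", min_win)
  nfft0 <- round(fs / resolution)
  k <- max(1L, ceiling(win / nfft0))
  nfft <- k * nfft0                     # df = resolution / k
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  starts <- seq(1L, n - win + 1L, by = max(1L, floor(win / 2)))
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + win - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - win)))
    acc <- acc + Mod(X[1:(nfft %/% 2L + 1L)])^2
  }
  dens <- acc / (length(starts) * fs * sum(w^2))
  one_sided <- 2 * dens
  one_sided[1L] <- dens[1L]
  if (nfft %% 2L == 0L) one_sided[length(one_sided)] <- dens[length(dens)]
  df <- fs / nfft
  targets <- seq(ceiling(fmin / resolution), floor(fmax / resolution)) *
    resolution
  idx <- round(targets / df) + 1L
  structure(list(freqs = targets, power = one_sided[idx],
                 window = sprintf("hamming-%d/overlap50/nfft-%d/%d-segments",
                                  win, nfft, length(starts))),
            class = "psd_estimate")
}

# PSD value at the grid bin nearest a target frequency
psd_at <- function(psd, freq) {
  psd$power[which.min(abs(psd$freqs - freq))]
}

#' Per-IC classification features
#'
#' Computes the four Pearson correlation magnitudes used by the classifier
#' (IC vs normalized ECG and vs normalized APS, in both the PSD domain and
#' the time domain) plus the median per-beat peak delay of the IC relative to
#' the R peaks. The per-beat IC peak is the maximum of `|ic|` within
#' `[R_i, R_i + 0.9 RR_i]`; the delay is defined only when at least half of
#' the beat windows fit inside the signal. Correlations are absolute values,
#' so features are invariant to the arbitrary sign and scale of an IC.
#'
#' @param ic one IC time course.
#' @param nECG normalized ECG (same length).
#' @param nAPS normalized APS, or `NULL` (APS features are then `NA`).
#' @param rp the [rpeaks()] series of the segment.
#' @param fs sampling rate in Hz.
#' @param beat_window_frac fraction of the local R-R interval searched for
#'   the IC peak.
#' @param min_valid_frac minimum fraction of usable beats for the delay to be
#'   defined.
#' @return An object of class `"ic_features"`: `r_psd_ecg`, `r_tc_ecg`,
#'   `r_psd_aps`, `r_tc_aps` in `[0, 1]`; `delay_ms`; `delay_defined`.
#' @export
compute_ic_features <- function(ic, nECG, nAPS, rp, fs,
                                beat_window_frac = 0.9,
                                min_valid_frac = 0.5) {
  stopifnot(inherits(rp, "rpeaks"))
  n <- length(ic)
  if (length(nECG) != n || (!is.null(nAPS) && length(nAPS) != n))
    stop("ic, nECG and nAPS must have equal lengths")
  out <- list(r_psd_ecg = 0, r_tc_ecg = 0, r_psd_aps = NA_real_,
              r_tc_aps = NA_real_, delay_ms = NA_real_,
              delay_defined = FALSE)
  if (stats::sd(ic) == 0) return(structure(out, class = "ic_features"))
  p_ic <- welch_psd(ic, fs)
  p_ecg <- welch_psd(nECG, fs)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    abs(stats::cor(a, b))
  }
  out$r_psd_ecg <- safe_cor(p_ic$power, p_ecg$power)
  out$r_tc_ecg <- safe_cor(ic, nECG)
  if (!is.null(nAPS)) {
    p_aps <- welch_psd(nAPS, fs)
    out$r_psd_aps <- safe_cor(p_ic$power, p_aps$power)
    out$r_tc_aps <- safe_cor(ic, nAPS)
  }
  r <- rp$indices
  rr <- diff(r)
  rr <- c(rr, if (length(rr)) stats::median(rr) else round(fs / 2.4))
  delays <- rep(NA_real_, length(r))
  for (i in seq_along(r)) {
    a <- r[i]
    b <- r[i] + floor(beat_window_frac * rr[i])
    if (a < 1L || b > n) next
    delays[i] <- (which.max(abs(ic[a:b])) - 1L) / fs * 1000
  }
  ok <- !is.na(delays)
  if (mean(ok) >= min_valid_frac) {
    out$delay_ms <- stats::median(delays[ok])
    out$delay_defined <- TRUE
  }
  structure(out, class = "ic_features")
}

#' Default classifier thresholds
#'
#' @return the named list of cascade thresholds: `hi` (0.9), `lo` (0.75),
#'   `ecc_delay_tol_ms` (20), `pcc_delay_lo` (150), `pcc_delay_hi` (350).
#' @export
default_thresholds <- function() {
  list(hi = 0.9, lo = 0.75, ecc_delay_tol_ms = 20,
       pcc_delay_lo = 150, pcc_delay_hi = 350)
}

#' Classify one IC as ECC, PCC or NCC
#'
#' Implements the two-stage cascade, evaluated once against the ECG features
#' (target label ECC, electrical cardiac component) and once against the APS
#' features (target label PCC, pulsatile cardiac component):
#' \enumerate{
#'   \item correlation branch (`corr-high`): the IC is artefactual if one of
#'     the two correlations exceeds `hi` while the other exceeds `lo`;
#'   \item delay branch (`corr-delay`): otherwise, if `r_psd > hi` and the
#'     peak delay matches the artifact physiology -- within
#'     `ecc_delay_tol_ms` of zero for ECC (the electrical leak is QRS-locked)
#'     or inside `[pcc_delay_lo, pcc_delay_hi]` ms for PCC (the vascular
#'     pulse lags the R peak);
#'   \item otherwise the IC is a non-cardiac component (NCC).
#' }
#' If both target labels fire, the one with the larger PSD correlation wins
#' (ties go to ECC). With `literal_text_rule = TRUE` the correlation branch
#' instead requires only both correlations above `lo` (an alternative, more
#' permissive published reading of the rule set).
#'
#' @param f an [compute_ic_features()] result.
#' @param thresholds see [default_thresholds()].
#' @param literal_text_rule switch between the two published readings of the
#'   correlation branch.
#' @return An object of class `"ic_label"`: `label` in
#'   `{"ECC","PCC","NCC"}` and `rule_fired` in
#'   `{"corr-high","corr-delay","none"}`.
#' @export
classify_ic <- function(f, thresholds = default_thresholds(),
                        literal_text_rule = FALSE) {
  th <- utils::modifyList(default_thresholds(), as.list(thresholds))
  num <- function(v) if (is.null(v) || is.na(v)) 0 else v
  corr_branch <- function(r_psd, r_tc) {
    if (literal_text_rule)
      (r_psd > th$hi && r_tc > th$lo) || (r_psd > th$lo && r_tc > th$lo)
    else
      (r_psd > th$hi && r_tc > th$lo) || (r_psd > th$lo && r_tc > th$hi)
  }
  delay_ok <- function(target) {
    if (!isTRUE(f$delay_defined)) return(FALSE)
    if (target == "ECC") abs(f$delay_ms) <= th$ecc_delay_tol_ms
    else f$delay_ms >= th$pcc_delay_lo && f$delay_ms <= th$pcc_delay_hi
  }
  eval_target <- function(r_psd, r_tc, target) {
    if (corr_branch(r_psd, r_tc)) "corr-high"
    else if (r_psd > th$hi && delay_ok(target)) "corr-delay"
    else NA_character_
  }
  ecc_rule <- eval_target(num(f$r_psd_ecg), num(f$r_tc_ecg), "ECC")
  pcc_rule <- eval_target(num(f$r_psd_aps), num(f$r_tc_aps), "PCC")
  if (!is.na(ecc_rule) && !is.na(pcc_rule)) {
    if (num(f$r_psd_aps) > num(f$r_psd_ecg))
      ecc_rule <- NA_character_
    else
      pcc_rule <- NA_character_
  }
  lab <- if (!is.na(ecc_rule)) list(label = "ECC", rule_fired = ecc_rule)
         else if (!is.na(pcc_rule)) list(label = "PCC", rule_fired = pcc_rule)
         else list(label = "NCC", rule_fired = "none")
  structure(lab, class = "ic_label")
}

#' Classify every IC of a decomposition
#'
#' Runs [compute_ic_features()] and [classify_ic()] on each IC. For G2/G3
#' groups (no nAPS among the SOBI inputs) the APS is synthesized internally
#' from the R-peak series and normalized to the group's EEG rows, so
#' pulsatile components remain detectable; this is flagged in the result.
#'
#' @param dec a [sobi_decompose()] result.
#' @param nECG normalized ECG of the same segment.
#' @param nAPS normalized APS, or `NULL` to synthesize one from `rp`.
#' @param rp the segment's [rpeaks()].
#' @param thresholds,literal_text_rule passed to [classify_ic()].
#' @return An object of class `"ic_classification"`: `features` (list),
#'   `labels` (list), `table` (one row per IC with features, label and rule),
#'   `aps_synthesized`.
#' @export
classify_decomposition <- function(dec, nECG, nAPS = NULL, rp,
                                   thresholds = default_thresholds(),
                                   literal_text_rule = FALSE) {
  stopifnot(inherits(dec, "sobi_decomposition"), inherits(rp, "rpeaks"))
  fs <- dec$group$fs
  n <- ncol(dec$sources)
  aps_synthesized <- is.null(nAPS)
  if (aps_synthesized) {
    raw <- synthesize_aps(rp, n, fs)
    eeg <- dec$group$data[dec$group$eeg_row_indices, , drop = FALSE]
    nAPS <- normalize_amplitude(raw, eeg)
  }
  feats <- vector("list", nrow(dec$sources))
  labs <- vector("list", nrow(dec$sources))
  for (i in seq_len(nrow(dec$sources))) {
    feats[[i]] <- compute_ic_features(dec$sources[i, ], nECG, nAPS, rp, fs)
    labs[[i]] <- classify_ic(feats[[i]], thresholds, literal_text_rule)
  }
  tab <- data.frame(
    ic = seq_along(feats),
    r_psd_ecg = vapply(feats, `[[`, 0, "r_psd_ecg"),
    r_tc_ecg = vapply(feats, `[[`, 0, "r_tc_ecg"),
    r_psd_aps = vapply(feats, `[[`, 0, "r_psd_aps"),
    r_tc_aps = vapply(feats, `[[`, 0, "r_tc_aps"),
    delay_ms = vapply(feats, `[[`, 0, "delay_ms"),
    label = vapply(labs, `[[`, "", "label"),
    rule = vapply(labs, `[[`, "", "rule_fired"))
  structure(list(features = feats, labels = labs, table = tab,
                 aps_synthesized = aps_synthesized),
            class = "ic_classification")
}

#' @export
print.ic_classification <- function(x, ...) {
  cat("<ic_classification>", nrow(x$table), "ICs",
      if (x$aps_synthesized) "(APS synthesized internally)" else "", "\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Write a classification report as a tab-separated table
#'
#' @param cls an [classify_decomposition()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(cls, path) {
  stopifnot(inherits(cls, "ic_classification"))
  utils::write.table(cls$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
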