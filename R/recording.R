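#' Multichannel EEG + ECG recording container
#'
#' A `Recording` bundles a matrix of EEG channels (microvolt scale), the
#' simultaneously recorded ECG (kept separate, at its native scale, typically
#' millivolts), the common sampling rate and the ordered channel labels.
#' All downstream stages (filtering, R-peak detection, signal-group
#' construction, SOBI) operate on this container.
#'
#' @param eeg numeric matrix, `n_channels x n_samples`, EEG amplitudes in uV.
#' @param ecg numeric vector of length `n_samples`, the ECG channel.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector of unique EEG channel names
#'   (10-20 positions), one per EEG row. Defaults to `"EEG1"`, `"EEG2"`, ...
#' @param meta named list of free-form provenance (source file, filter
#'   settings, repairs applied by a loader).
#'
#' @return An object of class `"recording"` with fields `eeg`, `ecg`, `fs`,
#'   `channel_labels`, `meta`.
#' @examples
#' rec <- recording(matrix(rnorm(3 * 512), 3), rnorm(512), fs = 256)
#' n_samples(rec)
#' @export
recording <- function(eeg, ecg, fs, channel_labels = NULL, meta = list()) {
  eeg <- as.matrix(eeg)
  storage.mode(eeg) <- "double"
  ecg <- as.numeric(ecg)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (ncol(eeg) != length(ecg))
    stop("EEG and ECG sample counts differ (", ncol(eeg), " vs ",
         length(ecg), ")")
  if (anyNA(eeg) || any(!is.finite(eeg)))
    stop("non-finite values in EEG matrix")
  if (anyNA(ecg) || any(!is.finite(ecg)))
    stop("non-finite values in ECG")
  if (is.null(channel_labels))
    channel_labels <- paste0("EEG", seq_len(nrow(eeg)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(eeg))
    stop("need one label per EEG channel")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]),
               collapse = ", "))
  rownames(eeg) <- channel_labels
  structure(
    list(eeg = eeg, ecg = ecg, fs = fs,
         channel_labels = channel_labels, meta = meta),
    class = "recording")
}

#' @rdname recording
#' @param rec a `Recording`.
#' @export
n_samples <- function(rec) ncol(rec$eeg)

#' @rdname recording
#' @param x a `Recording`.
#' @param ... ignored.
#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d EEG channels + ECG, %d samples @ %g Hz (%.1f s)\n",
    nrow(x$eeg), ncol(x$eeg), x$fs, ncol(x$eeg) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Columnar fixture format: two header lines (tab-separated channel labels;
# sampling rate) followed by one row per sample, one column per channel.

read_fixture_recording <- function(path, ecg_label) {
  con <- file(path, "r")
  on.exit(close(con))
  labels <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1]]
  fs <- as.numeric(readLines(con, n = 1L))
  dat <- utils::read.table(con, sep = "\t", header = FALSE,
                           colClasses = "numeric")
  if (ncol(dat) != length(labels))
    stop("fixture column count (", ncol(dat),
         ") does not match header labels (", length(labels), ")")
  list(labels = labels, fs = fs, data = t(as.matrix(dat)))
}

write_fixture_recording <- function(labels, fs, data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = "\t"), con)
  writeLines(format(fs, digits = 15), con)
  utils::write.table(signif(t(data), 9), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
}

# ---------------------------------------------------------------------------
# Minimal EDF (16-bit) reader/writer. Signals are stored per data record as
# little-endian int16 mapped linearly from [physical min, physical max] to
# [-32768, 32767]. One data record per second; all signals must share fs.

edf_pad <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = width, flag = "-")
}

write_edf_recording <- function(labels, units, fs, data, path) {
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(data)
  n <- ncol(data)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs > n)  # pad the last partial record with zeros
    data <- cbind(data, matrix(0, ns, n_rec * fs - n))
  pmin <- apply(data, 1L, min)
  pmax <- apply(data, 1L, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  if (any(abs(c(pmin, pmax)) >= 1e7))
    stop("amplitude exceeds the representable EDF range; ",
         "rescale the signal (e.g. convert units) before writing")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("cardsobi export", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256L * (ns + 1L)), 8), edf_pad("", 44),
    edf_pad(as.character(n_rec), 8), edf_pad("1", 8),
    edf_pad(as.character(ns), 4))
  field <- function(vals, width)
    paste(vapply(as.character(vals), edf_pad, "", width = width),
          collapse = "")
  hdr <- paste0(
    hdr,
    field(labels, 16), field(rep("", ns), 80), field(units, 8),
    field(formatC(pmin, format = "g", digits = 7), 8),
    field(formatC(pmax, format = "g", digits = 7), 8),
    field(rep("-32768", ns), 8), field(rep("32767", ns), 8),
    field(rep("", ns), 80), field(rep(as.character(fs), ns), 8),
    field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  dig <- matrix(0L, ns, n_rec * fs)
  for (i in seq_len(ns)) {
    scaled <- (data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * 65535 - 32768
    dig[i, ] <- as.integer(pmin(32767, pmax(-32768, round(scaled))))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(NULL)
}

read_edf_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); units <- rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("channels with mismatched sampling rates: ",
         paste(labels[spr != spr[1]], collapse = ", "))
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    data[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- t(block)
  }
  for (i in seq_len(ns))
    data[i, ] <- pmin[i] +
      (data[i, ] - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
  list(labels = labels, units = units, fs = fs, data = data)
}

# ---------------------------------------------------------------------------

#' Read a multichannel recording from disk
#'
#' Reads either an EDF/EDF+ file (extension `.edf`/`.bdf` header layout,
#' 16-bit samples, physical min/max honored) or the columnar text fixture
#' format written by [write_recording()] (two header lines: tab-separated
#' channel labels, then the sampling rate; one column per channel). The
#' channel named `ecg_label` is split out of the EEG matrix and stored as the
#' ECG. EEG channels declared in volts or millivolts in an EDF header are
#' converted to microvolts; the ECG keeps its native scale.
#'
#' @param path path to an existing `.edf` or columnar `.tsv`/`.txt` file.
#' @param ecg_label name of the ECG channel within the file.
#' @return A [recording()].
#' @seealso [write_recording()], [bandpass_filter()]
#' @export
read_recording <- function(path, ecg_label = "ECG") {
  if (!file.exists(path)) stop("file not found: ", path)
  is_edf <- grepl("\\.(edf|bdf)$", tolower(path))
  raw <- if (is_edf) read_edf_recording(path)
         else read_fixture_recording(path, ecg_label)
  hits <- which(raw$labels == ecg_label)
  if (length(hits) == 0L)
    stop("ECG channel '", ecg_label, "' not found; available labels: ",
         paste(raw$labels, collapse = ", "))
  if (length(hits) > 1L)
    stop("duplicate ECG label '", ecg_label, "' in file")
  data <- raw$data
  meta <- list(source = path, format = if (is_edf) "edf" else "fixture")
  if (is_edf) {
    # unit harmonization for EEG rows only
    u <- tolower(raw$units)
    scale <- ifelse(u %in% c("v"), 1e6, ifelse(u %in% c("mv"), 1e3, 1))
    eeg_rows <- setdiff(seq_len(nrow(data)), hits)
    data[eeg_rows, ] <- data[eeg_rows, , drop = FALSE] * scale[eeg_rows]
  }
  bad <- !is.finite(data)
  if (any(bad)) {  # repair isolated non-finite samples, record in meta
    for (i in seq_len(nrow(data))) {
      v <- data[i, ]
      if (any(!is.finite(v))) {
        ok <- which(is.finite(v))
        if (length(ok) < 2L) stop("channel ", raw$labels[i],
                                  " contains no finite data")
        v[!is.finite(v)] <- stats::approx(ok, v[ok], xout = which(!is.finite(v)),
                                          rule = 2)$y
        data[i, ] <- v
      }
    }
    meta$repaired_samples <- sum(bad)
  }
  recording(eeg = data[-hits, , drop = FALSE], ecg = data[hits, ],
            fs = raw$fs, channel_labels = raw$labels[-hits], meta = meta)
}

#' Write a recording to disk
#'
#' Writes EDF (16-bit integer samples, physical min/max set from the data
#' range, one data record per second) when `path` ends in `.edf`, otherwise
#' the columnar text fixture format. The ECG is appended after the EEG
#' channels under `ecg_label`. A subsequent [read_recording()] reproduces
#' the samples within the format's quantization step (exact up to printed
#' precision for the text format).
#'
#' @param rec a [recording()].
#' @param path output path; extension selects the format.
#' @param ecg_label label under which the ECG channel is stored.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, ecg_label = "ECG") {
  stopifnot(inherits(rec, "recording"))
  if (n_samples(rec) == 0L) stop("refusing to write a zero-length recording")
  if (ecg_label %in% rec$channel_labels)
    stop("ecg_label '", ecg_label, "' collides with an EEG channel label")
  labels <- c(rec$channel_labels, ecg_label)
  data <- rbind(rec$eeg, rec$ecg)
  if (grepl("\\.edf$", tolower(path))) {
    units <- c(rep("uV", nrow(rec$eeg)), "mV")
    write_edf_recording(labels, units, rec$fs, data, path)
  } else {
    write_fixture_recording(labels, rec$fs, data, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# FIR band-pass machinery

# Windowed-sinc (Hamming) band-pass taps; even order -> odd tap count,
# linear phase type I, integer group delay.
design_fir_bandpass <- function(low, high, fs, transition = NULL) {
  if (is.null(transition)) transition <- min(low, 2)
  ord <- ceiling(3.3 * fs / transition)
  if (ord %% 2L == 1L) ord <- ord + 1L
  h <- signal::fir1(ord, c(low, high) / (fs / 2), type = "pass")
  as.numeric(h)
}

# Centered ("same") FFT convolution of x with an odd-length symmetric kernel.
fftconv_same <- function(x, h) {
  n <- length(x); L <- length(h)
  nfft <- stats::nextn(n + L - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(h, numeric(nfft - L))), inverse = TRUE)) / nfft
  y[(L - 1L) / 2L + seq_len(n)]
}

# Zero-phase application: mirror-pad by one filter length, convolve twice
# with the symmetric kernel (equivalent to forward-backward filtering, squared
# magnitude response), trim the padding.
apply_fir_zerophase <- function(x, h) {
  n <- length(x); L <- length(h)
  if (n < 2L * L) stop("signal too short for zero-phase filtering (need >= ",
                       2L * L, " samples); consider padding the recording")
  pre <- x[(L + 1L):2L]
  post <- x[(n - 1L):(n - L)]
  xp <- c(pre, x, post)
  y <- fftconv_same(fftconv_same(xp, h), h)
  y[L + seq_len(n)]
}

# Amplitude response of the zero-phase (twice-applied) filter at freqs f (Hz).
fir_zerophase_response <- function(h, f, fs) {
  k <- seq_along(h) - 1L
  H <- vapply(f, function(fi) abs(sum(h * exp(-2i * pi * fi * k / fs))), 0)
  H^2
}

#' Band-pass filter a recording (zero phase)
#'
#' Applies a windowed-sinc FIR band-pass (Hamming window) to every EEG
#' channel and to the ECG. The filter order follows a transition bandwidth of
#' `min(low, 2)` Hz at the low edge and the kernel is applied twice
#' (forward-backward equivalent) after mirror padding by one filter length,
#' so the output is strictly zero phase: peak latencies are preserved for the
#' downstream delay criteria. Output length equals input length. Defaults
#' retain the neonatal EEG band of interest (0.5-45 Hz).
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @return A filtered [recording()]; filter design parameters are appended to
#'   `meta$filter`.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 5120), 2), rnorm(5120), fs = 256)
#' filt <- bandpass_filter(rec)
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 45) {
  stopifnot(inherits(rec, "recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (fs = ", rec$fs, ")")
  h <- design_fir_bandpass(low, high, rec$fs)
  if (n_samples(rec) < 3L * length(h))
    stop("recording shorter than 3 filter lengths (", 3L * length(h),
         " samples); pad or use a wider transition band")
  eeg <- t(apply(rec$eeg, 1L, apply_fir_zerophase, h = h))
  dimnames(eeg) <- dimnames(rec$eeg)
  ecg <- apply_fir_zerophase(rec$ecg, h)
  meta <- rec$meta
  meta$filter <- list(type = "fir-hamming-zerophase", low = low, high = high,
                      n_taps = length(h), passes = 2L)
  recording(eeg, ecg, rec$fs, rec$channel_labels, meta)
}
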