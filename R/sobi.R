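#' Build a SOBI input signal group
#'
#' Stacks the filtered EEG channels with the normalized auxiliary cardiac
#' signals into the matrix handed to [sobi_decompose()]. Three group modes
#' are supported, mirroring how the augmentation is evaluated:
#' \describe{
#'   \item{G1}{21 rows: 19 EEG channels + normalized APS + normalized ECG.}
#'   \item{G2}{20 rows: EEG + normalized ECG only.}
#'   \item{G3}{19 rows: EEG channels only.}
#' }
#' `"G1s"` is accepted as an alias of G1 (same structure, seizure segments).
#' Auxiliary rows are appended after the EEG rows, in the order
#' `nAPS`, `nECG` for G1.
#'
#' @param rec a band-pass filtered [recording()].
#' @param mode `"G1"`, `"G2"`, `"G3"` (or `"G1s"`).
#' @param nECG normalized ECG vector (required for G1/G2).
#' @param nAPS normalized Artificial Pulse Signal (required for G1).
#' @return An object of class `"signal_group"` with fields `data`
#'   (`N x n_samples`), `N`, `row_labels`, `mode`, `eeg_row_indices`,
#'   `aux_rows` (named indices of nAPS/nECG rows) and `fs`.
#' @export
build_signal_group <- function(rec, mode, nECG = NULL, nAPS = NULL) {
  stopifnot(inherits(rec, "recording"))
  mode <- toupper(mode)
  if (!mode %in% c("G1", "G1S", "G2", "G3"))
    stop("mode must be one of G1, G2, G3 (or G1s)")
  base_mode <- if (mode == "G1S") "G1" else mode
  n <- n_samples(rec)
  chk <- function(v, what) {
    if (is.null(v)) stop("mode ", mode, " requires ", what)
    if (length(v) != n) stop(what, " length (", length(v),
                             ") does not match the recording (", n, ")")
    as.numeric(v)
  }
  if (is.null(rec$meta$filter))
    warning("recording carries no filter provenance; expected band-passed input")
  eeg_n <- nrow(rec$eeg)
  if (base_mode == "G1") {
    nAPS <- chk(nAPS, "a normalized APS (nAPS)")
    nECG <- chk(nECG, "a normalized ECG (nECG)")
    data <- rbind(rec$eeg, nAPS = nAPS, nECG = nECG)
    aux <- c(nAPS = eeg_n + 1L, nECG = eeg_n + 2L)
  } else if (base_mode == "G2") {
    nECG <- chk(nECG, "a normalized ECG (nECG)")
    data <- rbind(rec$eeg, nECG = nECG)
    aux <- c(nECG = eeg_n + 1L)
  } else {
    data <- rec$eeg
    aux <- integer(0)
  }
  structure(list(data = data, N = nrow(data), row_labels = rownames(data),
                 mode = if (mode == "G1S") "G1s" else mode,
                 eeg_row_indices = seq_len(eeg_n), aux_rows = aux,
                 fs = rec$fs),
            class = "signal_group")
}

#' Approximate joint diagonalization by Givens rotations
#'
#' Finds an orthogonal matrix `V` minimizing the sum of squared off-diagonal
#' entries of `t(V) %*% M_i %*% V` over a set of symmetric matrices, by
#' cyclic Jacobi-style sweeps of plane rotations (each angle is the
#' closed-form minimizer for its index pair). Iteration stops when every
#' rotation sine within a sweep falls below `tol`; the off-diagonal criterion
#' is non-increasing across sweeps.
#'
#' @param matrices list of symmetric `N x N` matrices (symmetrized on entry).
#' @param tol convergence tolerance on rotation sines.
#' @param max_sweeps sweep cap; if exceeded the best `V` so far is returned
#'   with attribute `converged = FALSE` and a warning.
#' @return orthogonal `N x N` matrix with attributes `sweeps` and
#'   `converged`.
#' @export
joint_diagonalize <- function(matrices, tol = 1e-8, max_sweeps = 100L) {
  stopifnot(is.list(matrices), length(matrices) >= 1L, tol > 0)
  N <- nrow(matrices[[1]])
  K <- length(matrices)
  for (m in matrices) {
    if (!is.matrix(m) || nrow(m) != N || ncol(m) != N)
      stop("all matrices must be square and of equal size")
    if (any(!is.finite(m))) stop("non-finite entries in input matrices")
  }
  # stacked form: M = [M1 | M2 | ... | MK], each symmetrized
  M <- do.call(cbind, lapply(matrices, function(m) (m + t(m)) / 2))
  V <- diag(N)
  off <- N * (0:(K - 1L))
  sweeps <- 0L
  converged <- FALSE
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    max_s <- 0
    for (p in 1:(N - 1L)) for (q in (p + 1L):N) {
      pc <- p + off; qc <- q + off
      u <- M[p, qc]                     # off-diagonal entries
      v <- (M[p, pc] - M[q, qc]) / 2    # half diagonal differences
      Cuv <- sum(u * v)
      theta <- 0.25 * atan2(2 * Cuv, sum(v * v) - sum(u * u))
      s <- sin(theta)
      if (abs(s) <= .Machine$double.eps) next
      max_s <- max(max_s, abs(s))
      cth <- cos(theta)
      rp <- M[p, ]; rq <- M[q, ]
      M[p, ] <- cth * rp + s * rq
      M[q, ] <- -s * rp + cth * rq
      cp <- M[, pc]; cq <- M[, qc]
      M[, pc] <- cth * cp + s * cq
      M[, qc] <- -s * cp + cth * cq
      vp <- V[, p]; vq <- V[, q]
      V[, p] <- cth * vp + s * vq
      V[, q] <- -s * vp + cth * vq
    }
    if (max_s < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("joint diagonalization did not converge within ", max_sweeps,
            " sweeps (last max rotation sine ", signif(max_s, 3), ")")
  attr(V, "sweeps") <- sweeps
  attr(V, "converged") <- converged
  V
}

# sum of squared off-diagonal entries of t(V) M V over a matrix list
joint_offdiag_criterion <- function(matrices, V) {
  sum(vapply(matrices, function(m) {
    d <- t(V) %*% ((m + t(m)) / 2) %*% V
    sum(d^2) - sum(diag(d)^2)
  }, 0))
}

#' SOBI square decomposition of a signal group
#'
#' Second-Order Blind Identification: rows are mean-centered and whitened via
#' the eigendecomposition of the zero-lag covariance; symmetrized covariances
#' at the requested time lags are then jointly diagonalized
#' ([joint_diagonalize()]), yielding a square unmixing matrix `W`, its
#' inverse mixing matrix `A` and unit-variance source time courses
#' `S = W (X - rowmeans)`. The decomposition is square and invertible: no
#' dimension reduction is performed, and a rank-deficient input (constant or
#' duplicated rows) is an error rather than a silent projection.
#'
#' Sources are ordered by decreasing fraction of power at `hr_freq` when a
#' heart-rate frequency is supplied (so cardiac components come first), else
#' by decreasing explained variance; each source's sign is fixed so its best
#' correlation with an input row is positive.
#'
#' @param group a [build_signal_group()] result.
#' @param lags integer sample lags for the covariance set (default 1:100,
#'   about 4-390 ms at 256 Hz, spanning cardiac timescales).
#' @param tol joint-diagonalization tolerance.
#' @param hr_freq optional heart-rate frequency in Hz used for the source
#'   ordering convention.
#' @return An object of class `"sobi_decomposition"`: `unmixing` (W),
#'   `mixing` (A, with `A %*% W` = identity), `sources` (S), `row_means`,
#'   `group`, `lags`, `converged`, `hr_freq`.
#' @export
sobi_decompose <- function(group, lags = 1:100, tol = 1e-8, hr_freq = NULL) {
  stopifnot(inherits(group, "signal_group"))
  X <- group$data
  N <- nrow(X); n <- ncol(X)
  lags <- as.integer(lags)
  if (any(lags <= 0L)) stop("lags must be positive integers")
  if (n <= 10L * max(lags))
    stop("too few samples (", n, ") for max lag ", max(lags),
         "; need > 10 x max(lags)")
  if (any(!is.finite(X))) stop("non-finite values in signal group")
  mu <- rowMeans(X)
  Xc <- X - mu
  C0 <- tcrossprod(Xc) / n
  ee <- eigen((C0 + t(C0)) / 2, symmetric = TRUE)
  floor_ev <- 1e-12 * sum(diag(C0))
  if (any(ee$values < floor_ev)) {
    vr <- apply(Xc, 1L, stats::var)
    bad <- group$row_labels[vr <= floor_ev]
    if (length(bad) == 0L) {
      cc <- suppressWarnings(stats::cor(t(Xc)))
      cc[!is.finite(cc)] <- 0
      diag(cc) <- 0
      pr <- which(abs(cc) > 1 - 1e-9, arr.ind = TRUE)
      bad <- unique(group$row_labels[pr])
    }
    stop("rank-deficient covariance; offending rows: ",
         if (length(bad)) paste(bad, collapse = ", ") else "<undetermined>")
  }
  Wh <- diag(1 / sqrt(ee$values)) %*% t(ee$vectors)
  Z <- Wh %*% Xc
  Rt <- lapply(lags, function(tau) {
    R <- tcrossprod(Z[, 1:(n - tau), drop = FALSE],
                    Z[, (1 + tau):n, drop = FALSE]) / (n - tau)
    (R + t(R)) / 2
  })
  V <- joint_diagonalize(Rt, tol = tol)
  W <- t(V) %*% Wh
  S <- W %*% Xc
  A <- ee$vectors %*% diag(sqrt(ee$values)) %*% V
  # enforce the exact unit-variance scaling convention
  sds <- sqrt(rowMeans(S^2))
  S <- S / sds
  W <- W / sds
  A <- A * rep(sds, each = N)
  # ordering convention
  ord <- if (!is.null(hr_freq)) {
    w <- exp(-2i * pi * hr_freq * (0:(n - 1)) / group$fs)
    frac <- abs(S %*% w)^2 / rowSums(S^2)
    order(frac, decreasing = TRUE)
  } else {
    order(colSums(A^2), decreasing = TRUE)
  }
  S <- S[ord, , drop = FALSE]
  W <- W[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  # sign convention: positive correlation with the best-matching input row
  cc <- stats::cor(t(S), t(Xc))
  for (i in seq_len(N)) {
    j <- which.max(abs(cc[i, ]))
    if (cc[i, j] < 0) { S[i, ] <- -S[i, ]; W[i, ] <- -W[i, ]; A[, i] <- -A[, i] }
  }
  rownames(S) <- paste0("IC", seq_len(N))
  structure(list(unmixing = W, mixing = A, sources = S, row_means = mu,
                 group = group, lags = lags,
                 converged = isTRUE(attr(V, "converged")),
                 hr_freq = hr_freq),
            class = "sobi_decomposition")
}

#' @export
print.sobi_decomposition <- function(x, ...) {
  cat(sprintf("<sobi_decomposition> %d ICs (%s), %d samples, %d lags%s\n",
              nrow(x$sources), x$group$mode, ncol(x$sources), length(x$lags),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Reconstruct EEG channels after removing ICs
#'
#' Re-projects the retained independent components onto the sensor space,
#' `A[, retained] %*% S[retained, ]` (plus the row means removed at
#' decomposition time), and returns only the true EEG rows -- the auxiliary
#' nAPS/nECG rows are never part of the reconstructed EEG.
#'
#' @param dec a [sobi_decompose()] result.
#' @param removed_ics integer indices of the ICs to discard (possibly empty;
#'   removing every IC is an error).
#' @return matrix `n_EEG x n_samples` of reconstructed EEG.
#' @export
reconstruct_channels <- function(dec, removed_ics = integer(0)) {
  stopifnot(inherits(dec, "sobi_decomposition"))
  N <- nrow(dec$sources)
  removed_ics <- as.integer(removed_ics)
  if (length(removed_ics) && (min(removed_ics) < 1L || max(removed_ics) > N))
    stop("removed_ics out of range 1..", N)
  retained <- setdiff(seq_len(N), removed_ics)
  if (length(retained) == 0L)
    stop("cannot remove every IC: nothing left to reconstruct")
  rec <- dec$mixing[, retained, drop = FALSE] %*%
    dec$sources[retained, , drop = FALSE] + dec$row_means
  idx <- dec$group$eeg_row_indices
  out <- rec[idx, , drop = FALSE]
  rownames(out) <- dec$group$row_labels[idx]
  out
}
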