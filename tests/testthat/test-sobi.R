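test_that("signal groups have the mode-defined size and row order", {
  withr::local_seed(1)
  eeg <- matrix(rnorm(19 * 2048), 19)
  rec <- recording(eeg, rnorm(2048), 256, neonatal_montage(),
                   meta = list(filter = list(type = "test")))
  nECG <- rnorm(2048); nAPS <- rnorm(2048)
  g1 <- build_signal_group(rec, "G1", nECG, nAPS)
  expect_equal(g1$N, 21)
  expect_identical(tail(g1$row_labels, 2), c("nAPS", "nECG"))
  expect_identical(g1$eeg_row_indices, 1:19)
  expect_equal(unname(g1$aux_rows), c(20L, 21L))
  g2 <- build_signal_group(rec, "G2", nECG)
  expect_equal(g2$N, 20)
  g3 <- build_signal_group(rec, "G3")
  expect_equal(g3$N, 19)
  expect_length(g3$aux_rows, 0)
  expect_error(build_signal_group(rec, "G1", nECG), "nAPS")
  expect_error(build_signal_group(rec, "G2"), "nECG")
  expect_error(build_signal_group(rec, "G1", nECG, nAPS[-1]), "length")
  expect_equal(build_signal_group(rec, "G1s", nECG, nAPS)$mode, "G1s")
})

test_that("already-diagonal matrices need no rotation", {
  Ms <- lapply(1:5, function(k) diag(c(3, 1, 2) * k))
  V <- joint_diagonalize(Ms)
  expect_true(attr(V, "converged"))
  # V is a signed permutation of the identity
  expect_equal(sort(abs(as.vector(V))), c(rep(0, 6), rep(1, 3)),
               tolerance = 1e-12)
  expect_lt(offdiag_criterion(Ms, V), 1e-20)
})

test_that("a planted orthogonal basis is recovered from congruent diagonals", {
  withr::local_seed(21)
  for (rep in 1:10) {
    N <- sample(3:8, 1)
    Q <- qr.Q(qr(matrix(rnorm(N * N), N)))
    Ms <- lapply(1:12, function(k) Q %*% diag(rnorm(N)) %*% t(Q))
    V <- joint_diagonalize(Ms)
    M <- abs(crossprod(V, Q))
    expect_true(all(apply(M, 1, max) > 0.999))
    expect_true(all(apply(M, 2, max) > 0.999))
  }
})

test_that("the 2x2 single-matrix rotation matches the eigendecomposition", {
  withr::local_seed(5)
  A <- crossprod(matrix(rnorm(4), 2))
  V <- joint_diagonalize(list(A))
  E <- eigen(A, symmetric = TRUE)$vectors
  M <- abs(crossprod(V, E))
  expect_true(all(apply(M, 1, max) > 1 - 1e-10))
  expect_error(joint_diagonalize(list(matrix(c(1, NA, NA, 1), 2))),
               "non-finite")
})

test_that("the off-diagonal criterion never increases across sweeps", {
  withr::local_seed(8)
  N <- 6
  Ms <- lapply(1:10, function(k) crossprod(matrix(rnorm(N * N), N)) / N)
  crits <- vapply(1:6, function(sw) {
    V <- suppressWarnings(joint_diagonalize(Ms, tol = 0 + 1e-300,
                                            max_sweeps = sw))
    offdiag_criterion(Ms, V)
  }, 0)
  expect_true(all(diff(crits) <= 1e-10))
})

test_that("SOBI separates mixed sources with distinct spectra", {
  withr::local_seed(33)
  n <- 6000
  # three AR(1)-filtered noises with clearly different spectra
  S <- rbind(
    as.numeric(stats::filter(rnorm(n), 0.95, method = "recursive")),
    as.numeric(stats::filter(rnorm(n), -0.7, method = "recursive")),
    as.numeric(stats::filter(rnorm(n), 0.3, method = "recursive")))
  A <- matrix(rnorm(9), 3)
  X <- A %*% S
  grp <- structure(list(data = X, N = 3, row_labels = paste0("r", 1:3),
                        mode = "G3", eeg_row_indices = 1:3,
                        aux_rows = integer(0), fs = 256),
                   class = "signal_group")
  dec <- sobi_decompose(grp, lags = 1:20)
  cc <- abs(stats::cor(t(dec$sources), t(S)))
  expect_true(all(apply(cc, 2, max) >= 0.99))
  # square invertible decomposition
  expect_lt(max(abs(dec$mixing %*% dec$unmixing - diag(3))), 1e-8)
  recon <- dec$mixing %*% dec$sources + dec$row_means
  expect_lt(max(abs(recon - X)), 1e-6 * max(abs(X)))
  expect_equal(unname(apply(dec$sources, 1, function(s) mean(s^2))),
               rep(1, 3), tolerance = 1e-10)
})

test_that("uncorrelated rows with distinct spectra are left unmixed", {
  withr::local_seed(14)
  n <- 8000
  X <- rbind(
    as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive")),
    as.numeric(stats::filter(rnorm(n), -0.9, method = "recursive")),
    rnorm(n))
  grp <- structure(list(data = X, N = 3, row_labels = paste0("r", 1:3),
                        mode = "G3", eeg_row_indices = 1:3,
                        aux_rows = integer(0), fs = 256),
                   class = "signal_group")
  dec <- sobi_decompose(grp, lags = 1:20)
  # mixing is a scaled permutation of the identity: one dominant entry
  # per column carrying nearly all the energy
  frac <- apply(dec$mixing^2, 2, function(c) max(c) / sum(c))
  expect_true(all(frac > 0.98))
})

test_that("rank deficiency is a hard error naming the offending rows", {
  withr::local_seed(2)
  n <- 4000
  x <- rnorm(n)
  X <- rbind(a = x, b = x, c = rnorm(n))
  grp <- structure(list(data = X, N = 3, row_labels = c("a", "b", "c"),
                        mode = "G3", eeg_row_indices = 1:3,
                        aux_rows = integer(0), fs = 256),
                   class = "signal_group")
  expect_error(sobi_decompose(grp, lags = 1:10), "rank-deficient.*a.*b")
  Xc <- rbind(a = rep(1, n), b = rnorm(n), c = rnorm(n))
  grp$data <- Xc
  expect_error(sobi_decompose(grp, lags = 1:10), "rank-deficient.*a")
})

test_that("reconstruction with no removal is the identity on EEG rows", {
  sim <- fast_sim(51, duration = 40)
  filt <- bandpass_filter(sim$recording)
  rp <- detect_r_peaks(filt$ecg, 256)
  nECG <- normalize_amplitude(filt$ecg, filt$eeg)
  nAPS <- normalize_amplitude(synthesize_aps(rp, n_samples(filt), 256), filt$eeg)
  grp <- build_signal_group(filt, "G1", nECG, nAPS)
  dec <- suppressWarnings(sobi_decompose(grp, lags = 1:50))
  recon <- reconstruct_channels(dec, integer(0))
  expect_lt(max(abs(recon - filt$eeg)), 1e-6 * max(abs(filt$eeg)))
  # removing all but one IC leaves a rank-1 EEG matrix (after recentering)
  r1 <- reconstruct_channels(dec, 2:21) - dec$row_means[1:19]
  expect_lt(svd(r1)$d[2] / svd(r1)$d[1], 1e-8)
  expect_error(reconstruct_channels(dec, 1:21), "every IC")
  expect_error(reconstruct_channels(dec, c(0, 5)), "out of range")
})

test_that("removing the cardiac-matched IC halves heart-rate-band power", {
  sim <- fast_sim(52, duration = 60)
  res <- run_fast(sim, "G1")
  hr <- res$hr_freq
  pow_hr <- function(M) mean(vapply(seq_len(nrow(M)), function(i) {
    p <- welch_psd(M[i, ], 256)
    p$power[which.min(abs(p$freqs - hr))]
  }, 0))
  filt <- bandpass_filter(sim$recording)
  expect_gt(1 - pow_hr(res$cleaned_eeg) / pow_hr(filt$eeg), 0.5)
})

test_that("relabeling sources leaves the reconstruction invariant", {
  withr::local_seed(9)
  n <- 5000
  X <- rbind(as.numeric(stats::filter(rnorm(n), 0.8, method = "recursive")),
             as.numeric(stats::filter(rnorm(n), -0.5, method = "recursive")),
             rnorm(n))
  grp <- structure(list(data = X, N = 3, row_labels = paste0("r", 1:3),
                        mode = "G3", eeg_row_indices = 1:3,
                        aux_rows = integer(0), fs = 256),
                   class = "signal_group")
  dec <- sobi_decompose(grp, lags = 1:15)
  perm <- c(3, 1, 2); sgn <- c(-1, 1, -1)
  A2 <- dec$mixing[, perm] %*% diag(sgn)
  S2 <- diag(sgn) %*% dec$sources[perm, ]
  expect_equal(A2 %*% S2, dec$mixing %*% dec$sources, tolerance = 1e-10)
})

test_that("SOBI beats random rotations on the joint-diagonality criterion", {
  withr::local_seed(77)
  n_inst <- 200
  for (i in seq_len(n_inst)) {
    N <- sample(3:5, 1)
    n <- 1500
    S <- t(vapply(seq_len(N), function(j)
      as.numeric(stats::filter(rnorm(n), runif(1, -0.95, 0.95),
                               method = "recursive")), numeric(n)))
    X <- matrix(rnorm(N * N), N) %*% S
    grp <- structure(list(data = X, N = N,
                          row_labels = paste0("r", seq_len(N)), mode = "G3",
                          eeg_row_indices = seq_len(N),
                          aux_rows = integer(0), fs = 256),
                     class = "signal_group")
    dec <- suppressWarnings(sobi_decompose(grp, lags = 1:10))
    # rebuild the whitened lagged covariances the decomposition diagonalized
    Xc <- X - rowMeans(X)
    C0 <- tcrossprod(Xc) / n
    ee <- eigen(C0, symmetric = TRUE)
    Z <- diag(1 / sqrt(ee$values)) %*% t(ee$vectors) %*% Xc
    Ms <- lapply(1:10, function(tau) {
      R <- tcrossprod(Z[, 1:(n - tau)], Z[, (1 + tau):n]) / (n - tau)
      (R + t(R)) / 2
    })
    # undo the whitening to recover the orthogonal factor (columns of V are
    # scaled by the source-ordering/scaling conventions; renormalize them)
    Vr <- t(dec$unmixing %*% ee$vectors %*% diag(sqrt(ee$values)))
    Vn <- sweep(Vr, 2, sqrt(colSums(Vr^2)), "/")
    crit_sobi <- offdiag_criterion(Ms, Vn)
    rand_best <- min(vapply(1:1000, function(k) {
      offdiag_criterion(Ms, qr.Q(qr(matrix(rnorm(N * N), N))))
    }, 0))
    expect_lte(crit_sobi, rand_best + 1e-12)
  }
})
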