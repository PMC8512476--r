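# Shared fixtures: everything is generated in code at test time.

# small random recording (band-limited so filtering tests are stable)
random_recording <- function(n_ch = 3, n = 6144, fs = 256, seed = 42) {
  withr::local_seed(seed)
  eeg <- matrix(stats::rnorm(n_ch * n, sd = 10), n_ch, n)
  recording(eeg, stats::rnorm(n, sd = 1), fs,
            channel_labels = paste0("Ch", seq_len(n_ch)))
}

# regular-rhythm synthetic ECG plus its true peak indices
regular_ecg <- function(hr = 2.4, dur = 30, fs = 256, snr_db = 20,
                        jitter = 0, seed = 1) {
  withr::local_seed(seed)
  rr <- fs / hr
  r <- round(cumsum(c(0.4 * fs, rr * (1 + stats::rnorm(200, sd = jitter)))))
  r <- r[r <= dur * fs - fs]
  n <- dur * fs
  wave <- synthetic_ecg_wave(r, n, fs)
  noise_sd <- sqrt(mean(wave^2)) * 10^(-snr_db / 20)
  list(ecg = wave + stats::rnorm(n, sd = noise_sd), r = r, n = n, fs = fs)
}

# small, fast simulated segment + G1 pipeline config used by unit tests
fast_config <- function(verbose = FALSE) {
  pipeline_config(lags = 1:50, verbose = verbose)
}

fast_sim <- function(seed, duration = 60, ...) {
  generate_recording(simulation_config(duration = duration, seed = seed, ...))
}

run_fast <- function(sim, mode = "G1") {
  suppressWarnings(run_pipeline(sim$recording, mode, fast_config()))
}

# sum of squared off-diagonal entries of t(V) M_k V, vectorized over k
offdiag_criterion <- function(matrices, V) {
  tot <- sum(vapply(matrices, function(m) sum(((m + t(m)) / 2)^2), 0))
  P <- crossprod(V, do.call(cbind, lapply(matrices, function(m) (m + t(m)) / 2)))
  N <- nrow(V)
  dsq <- 0
  for (i in seq_len(N)) {
    Pi <- matrix(P[i, ], N)
    dsq <- dsq + sum(colSums(Pi * V[, i])^2)
  }
  tot - dsq
}
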