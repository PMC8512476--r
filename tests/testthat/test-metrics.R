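fake_psd <- function(power, freqs = seq(0.5, 45, by = 0.01)) {
  structure(list(freqs = freqs, power = power, window = "synthetic"),
            class = "psd_estimate")
}

test_that("APICs normalizes per-IC cardiac-bin power to 100", {
  nf <- length(seq(0.5, 45, by = 0.01))
  hr_bin <- which(abs(seq(0.5, 45, by = 0.01) - 2.4) < 1e-9)
  one <- numeric(nf); one[hr_bin] <- 5
  psds <- list(fake_psd(one), fake_psd(numeric(nf)), fake_psd(numeric(nf)),
               fake_psd(numeric(nf)))
  expect_equal(compute_apics(psds, 2.4), c(100, 0, 0, 0))
  psds_eq <- rep(list(fake_psd(one)), 21)
  expect_equal(compute_apics(psds_eq, 2.4), rep(100 / 21, 21))
  expect_error(compute_apics(rep(list(fake_psd(numeric(nf))), 3), 2.4),
               "no cardiac-band power")
  expect_error(compute_apics(psds, 60), "outside")
})

test_that("APICs matches a one-line ratio oracle on random PSDs", {
  withr::local_seed(19)
  freqs <- seq(0.5, 45, by = 0.01)
  for (i in 1:20) {
    psds <- lapply(1:7, function(j) fake_psd(runif(length(freqs))))
    hr <- runif(1, 1.5, 4)
    got <- compute_apics(psds, hr)
    bin <- which.min(abs(freqs - hr))
    vals <- vapply(psds, function(p) p$power[bin], 0)
    expect_equal(got, 100 * vals / sum(vals), tolerance = 1e-9)
    expect_equal(sum(got), 100, tolerance = 1e-6)
  }
})

test_that("CC counts strictly-above-threshold components", {
  expect_equal(contaminated_components(c(100, 0, 0, 0)), 1 / 4)
  expect_equal(contaminated_components(rep(100 / 21, 21)), 1)
  # entries exactly at the threshold are excluded
  expect_equal(contaminated_components(c(1, 1, 98)), 1 / 3)
  # CC is non-increasing in the threshold
  apics <- c(40, 30, 15, 10, 4, 1, 0)
  th <- c(0.5, 1, 2, 5, 20)
  cc <- vapply(th, contaminated_components, 0, apics = apics)
  expect_true(all(diff(cc) <= 0))
})

test_that("API conserves and is additive over disjoint IC sets", {
  withr::local_seed(23)
  apics <- as.numeric(compute_apics(
    lapply(1:9, function(j) fake_psd(runif(4451))), 2.4))
  expect_equal(artefactual_percentage_index(apics, 1:9), 100,
               tolerance = 1e-6)
  expect_equal(artefactual_percentage_index(apics, integer(0)), 0)
  expect_equal(artefactual_percentage_index(apics, c(1, 3)) +
                 artefactual_percentage_index(apics, c(2, 9)),
               artefactual_percentage_index(apics, c(1, 2, 3, 9)))
  expect_error(artefactual_percentage_index(apics, 10), "out of range")
})

test_that("SPV measures per-channel relative power loss", {
  withr::local_seed(31)
  before <- matrix(rnorm(3 * 1000), 3)
  expect_equal(signal_power_variation(before, before), 0)
  expect_equal(signal_power_variation(before, before / sqrt(2)), 50,
               tolerance = 1e-9)
  after <- before + matrix(rnorm(3 * 1000, sd = 0.3), 3)
  oracle <- mean(vapply(1:3, function(i) {
    pb <- sum((before[i, ] - mean(before[i, ]))^2)
    pa <- sum((after[i, ] - mean(after[i, ]))^2)
    (pb - pa) / pb * 100
  }, 0))
  expect_equal(signal_power_variation(before, after), oracle,
               tolerance = 1e-9)
  expect_error(signal_power_variation(matrix(0, 2, 10), matrix(0, 2, 10)),
               "zero power")
})

test_that("varRPP isolates the power at R-peak samples", {
  withr::local_seed(37)
  before <- matrix(rnorm(4 * 2000), 4)
  rp <- rpeaks(seq(100, 1900, by = 107), 256)
  expect_equal(var_r_peak_power(before, before, rp), 0)
  after <- before
  after[, rp$indices] <- 0
  expect_equal(var_r_peak_power(before, after, rp), 100)
  expect_error(var_r_peak_power(before, before, rpeaks(c(1, 5000), 256)),
               "out of bounds")
})

test_that("varPSDhr reaches ~100 for an analytically removed sinusoid", {
  fs <- 256
  n <- 120 * fs
  withr::local_seed(41)
  noise <- matrix(rnorm(2 * n, sd = 1), 2)
  hr <- 2.4
  sine <- 50 * sin(2 * pi * hr * (0:(n - 1)) / fs)
  before <- noise + rep(1, 2) %o% sine
  expect_equal(var_psd_hr(before, before, hr, fs), 0)
  got <- var_psd_hr(before, noise, hr, fs)
  expect_equal(got, 100, tolerance = 2)
  # negative values are reported unclamped when power increases
  expect_lt(var_psd_hr(noise, before, hr, fs), 0)
})

test_that("metrics are invariant to a common amplitude rescaling", {
  sim <- fast_sim(71, duration = 20)
  eeg_b <- sim$recording$eeg
  withr::local_seed(2)
  eeg_a <- eeg_b * 0.7 + matrix(rnorm(length(eeg_b), sd = 2),
                                nrow(eeg_b))
  rp <- rpeaks(sim$truth$r_peak_indices, 256)
  for (k in c(1, 12.5)) {
    expect_equal(signal_power_variation(k * eeg_b, k * eeg_a),
                 signal_power_variation(eeg_b, eeg_a), tolerance = 1e-9)
    expect_equal(var_r_peak_power(k * eeg_b, k * eeg_a, rp),
                 var_r_peak_power(eeg_b, eeg_a, rp), tolerance = 1e-9)
    expect_equal(var_psd_hr(k * eeg_b, k * eeg_a, 2.4, 256),
                 var_psd_hr(eeg_b, eeg_a, 2.4, 256), tolerance = 1e-8)
  }
})

test_that("evaluation reports serialize to a flat key-value file", {
  sim <- fast_sim(72, duration = 40)
  res <- run_fast(sim, "G1")
  path <- withr::local_tempfile(fileext = ".txt")
  write_evaluation_report(res$report, path)
  lines <- readLines(path)
  kv <- lines[1:6]
  expect_true(all(grepl("^[a-z_]+\t", kv)))
  apics_rows <- length(lines) - 7
  expect_equal(apics_rows, length(res$report$apics))
})
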