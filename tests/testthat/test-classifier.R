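test_that("Welch PSD localizes a sinusoid and nulls the zero signal", {
  fs <- 256
  n <- 300 * fs
  x <- sin(2 * pi * 2.4 * (0:(n - 1)) / fs)
  p <- welch_psd(x, fs)
  expect_equal(p$freqs[which.max(p$power)], 2.4)
  expect_equal(diff(p$freqs), rep(0.01, length(p$freqs) - 1), tolerance = 1e-9)
  expect_true(all(p$power >= 0))
  z <- welch_psd(numeric(30 * fs), fs)
  expect_true(all(z$power == 0))
  expect_error(welch_psd(rnorm(100), fs), "too short")
})

test_that("white-noise PSD is flat and respects the variance bound", {
  fs <- 256
  withr::local_seed(4)
  bands <- cbind(c(0.5, 10, 25), c(10, 25, 45))
  acc <- numeric(3)
  for (r in 1:100) {
    x <- rnorm(fs * 100)
    p <- welch_psd(x, fs)
    for (b in 1:3)
      acc[b] <- acc[b] + mean(p$power[p$freqs >= bands[b, 1] &
                                      p$freqs < bands[b, 2]])
    if (r <= 10)  # band-integral never exceeds the total variance
      expect_lte(sum(p$power) * 0.01, stats::var(x) * (1 + 1e-6))
  }
  acc <- acc / 100
  expect_lt(max(abs(acc / mean(acc) - 1)), 0.1)
})

test_that("self- and sign-flipped correlations are exact", {
  e <- regular_ecg(dur = 120, snr_db = 30, jitter = 0.02, seed = 6)
  rp <- rpeaks(e$r, e$fs)
  nECG <- e$ecg
  nAPS <- synthesize_aps(rp, e$n, e$fs)
  f1 <- compute_ic_features(nECG, nECG, nAPS, rp, e$fs)
  expect_equal(f1$r_psd_ecg, 1)
  expect_equal(f1$r_tc_ecg, 1)
  expect_true(f1$delay_defined)
  expect_lte(abs(f1$delay_ms), 4)
  f2 <- compute_ic_features(-nAPS, nECG, nAPS, rp, e$fs)
  expect_equal(f2$r_tc_aps, 1)
  expect_equal(f2$r_psd_aps, 1)
  # the APS peak sits 250 ms after each R peak
  expect_lt(abs(f2$delay_ms - 250), 4.01)
  f3 <- compute_ic_features(rep(1, e$n), nECG, nAPS, rp, e$fs)
  expect_equal(f3$r_psd_ecg, 0)
  expect_false(f3$delay_defined)
})

test_that("classification is invariant to IC sign and scale", {
  e <- regular_ecg(dur = 60, snr_db = 25, jitter = 0.02, seed = 12)
  rp <- rpeaks(e$r, e$fs)
  nAPS <- synthesize_aps(rp, e$n, e$fs)
  withr::local_seed(3)
  ics <- list(e$ecg, nAPS, rnorm(e$n))
  for (ic in ics) {
    base <- classify_ic(compute_ic_features(ic, e$ecg, nAPS, rp, e$fs))
    for (a in c(-1, 0.01, 37)) {
      alt <- classify_ic(compute_ic_features(a * ic, e$ecg, nAPS, rp, e$fs))
      expect_identical(alt$label, base$label)
    }
  }
})

# straight-line re-encoding of the published cascade, kept independent of
# the package implementation
cascade_oracle <- function(rpe, rte, rpa, rta, delay, delay_def) {
  fire <- function(rp, rt, dlo, dhi) {
    if ((rp > 0.9 && rt > 0.75) || (rp > 0.75 && rt > 0.9)) return("corr-high")
    if (rp > 0.9 && delay_def && delay >= dlo && delay <= dhi)
      return("corr-delay")
    NA_character_
  }
  ecc <- fire(rpe, rte, -20, 20)
  pcc <- fire(rpa, rta, 150, 350)
  if (!is.na(ecc) && !is.na(pcc)) {
    if (rpa > rpe) ecc <- NA_character_ else pcc <- NA_character_
  }
  if (!is.na(ecc)) c("ECC", ecc) else if (!is.na(pcc)) c("PCC", pcc)
  else c("NCC", "none")
}

test_that("the cascade matches an independent encoding on a full grid", {
  vals <- c(0, 0.5, 0.76, 0.91, 1)
  delays <- c(0, 100, 250, 400, NA)
  n_checked <- 0
  for (rpe in vals) for (rte in vals) for (rpa in vals) for (rta in vals)
    for (d in delays) {
      f <- structure(list(r_psd_ecg = rpe, r_tc_ecg = rte, r_psd_aps = rpa,
                          r_tc_aps = rta,
                          delay_ms = if (is.na(d)) NA_real_ else d,
                          delay_defined = !is.na(d)),
                     class = "ic_features")
      got <- classify_ic(f)
      want <- cascade_oracle(rpe, rte, rpa, rta,
                             if (is.na(d)) -Inf else d, !is.na(d))
      expect_identical(c(got$label, got$rule_fired), want)
      n_checked <- n_checked + 1
    }
  expect_equal(n_checked, 5^4 * 5)
})

test_that("published worked examples of the cascade are reproduced", {
  mk <- function(rpe = 0, rte = 0, rpa = 0, rta = 0, d = NA)
    structure(list(r_psd_ecg = rpe, r_tc_ecg = rte, r_psd_aps = rpa,
                   r_tc_aps = rta, delay_ms = if (is.na(d)) NA_real_ else d,
                   delay_defined = !is.na(d)), class = "ic_features")
  r1 <- classify_ic(mk(rpe = 0.95, rte = 0.80))
  expect_identical(c(r1$label, r1$rule_fired), c("ECC", "corr-high"))
  r2 <- classify_ic(mk(rpa = 0.92, rta = 0.5, d = 250))
  expect_identical(c(r2$label, r2$rule_fired), c("PCC", "corr-delay"))
  r3 <- classify_ic(mk(rpe = 0.39, rte = 0.39, rpa = 0.39, rta = 0.39))
  expect_identical(r3$label, "NCC")
  # the alternative published reading is more permissive
  r4 <- classify_ic(mk(rpe = 0.8, rte = 0.8), literal_text_rule = TRUE)
  expect_identical(r4$label, "ECC")
  expect_identical(classify_ic(mk(rpe = 0.8, rte = 0.8))$label, "NCC")
})

test_that("raising thresholds only ever moves labels toward NCC", {
  withr::local_seed(10)
  for (i in 1:200) {
    f <- structure(list(r_psd_ecg = runif(1), r_tc_ecg = runif(1),
                        r_psd_aps = runif(1), r_tc_aps = runif(1),
                        delay_ms = runif(1, 0, 400), delay_defined = TRUE),
                   class = "ic_features")
    lo_th <- classify_ic(f)
    hi_th <- classify_ic(f, thresholds = list(hi = 0.95, lo = 0.85))
    if (lo_th$label == "NCC") expect_identical(hi_th$label, "NCC")
  }
})

test_that("a full synthetic G1 decomposition is classified correctly", {
  sim <- fast_sim(61, duration = 60)
  res <- run_fast(sim, "G1")
  sc <- score_against_truth(res$decomposition, res$classification, sim$truth)
  expect_true(sc$ecc$correct)
  expect_true(sc$pcc$correct)
  expect_equal(sc$false_alarms, 0)
  # determinism: identical inputs give identical labels
  res2 <- run_fast(sim, "G1")
  expect_identical(res$classification$table$label,
                   res2$classification$table$label)
})

test_that("classification reports serialize to a readable table", {
  sim <- fast_sim(62, duration = 40)
  res <- run_fast(sim, "G1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification(res$classification, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 21)
  expect_true(all(c("r_psd_ecg", "label", "rule") %in% names(tab)))
})
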