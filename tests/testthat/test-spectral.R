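test_that("Welch PSD peaks at the probe tone and satisfies Parseval", {
  x <- tone(10, 30, 240)
  p <- welch_psd(x, 240)
  expect_equal(p$freqs[which.max(p$power)], 10, tolerance = p$freqs[2])
  expect_true(all(p$power >= 0))
  expect_equal(p$freqs[1], 0)
  expect_equal(max(p$freqs), 120)
  set.seed(8)
  wn <- rnorm(60 * 240)
  pw <- welch_psd(wn, 240)
  df <- pw$freqs[2] - pw$freqs[1]
  expect_equal(sum(pw$power) * df, var(wn), tolerance = 0.05)
  # white noise is approximately flat over the analysis band
  sel <- pw$freqs >= 1 & pw$freqs <= 30
  expect_lt(max(pw$power[sel]) / min(pw$power[sel]), 10)
})

test_that("Welch segment count follows floor((N - L) / (0.25 L)) + 1", {
  for (n_s in c(2, 5, 7.5, 60)) {
    x <- rnorm(n_s * 240)
    L <- 480
    expect_equal(welch_psd(x, 240)$n_segments,
                 floor((length(x) - L) / (0.25 * L)) + 1)
  }
  expect_error(welch_psd(rnorm(100), 240), "shorter than one Welch window")
})

test_that("a single-window series gives the plain windowed periodogram", {
  set.seed(5)
  x <- rnorm(480)
  p <- welch_psd(x, 240)
  expect_equal(p$n_segments, 1L)
  # independent periodogram oracle
  w <- signal::hamming(480)
  xf <- fft((x - mean(x)) * w)
  nf <- 241
  dbl <- c(1, rep(2, 239), 1)
  oracle <- Mod(xf[1:nf])^2 / (240 * sum(w^2)) * dbl
  expect_equal(p$power, unname(oracle), tolerance = 1e-12)
})

test_that("dyadic band edges at 240 Hz reproduce the canonical EEG bands", {
  defs <- band_definitions(fs = 240, levels = 5)
  expect_equal(defs$band, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(defs$node, c("A5", "D5", "D4", "D3", "D2"))
  expect_equal(defs$f_lo, c(0, 3.75, 7.5, 15, 30))
  expect_equal(defs$f_hi, c(3.75, 7.5, 15, 30, 60))
  # generic dyadic rule: level-k detail spans [fs/2^(k+1), fs/2^k]
  for (k in 2:5) {
    row <- defs[defs$node == paste0("D", k), ]
    expect_equal(row$f_lo, 240 / 2^(k + 1))
    expect_equal(row$f_hi, 240 / 2^k)
  }
})

test_that("wavelet band components sum exactly back to the input", {
  set.seed(21)
  x <- rnorm(7200)
  b <- wavelet_band_split(x)
  recon <- Reduce(`+`, b) + attr(b, "residual")
  expect_lt(sqrt(mean((recon - x)^2)) / sqrt(mean(x^2)), 1e-9)
  expect_true(all(vapply(b, length, integer(1)) == length(x)))
  # zero in, zero out
  z <- wavelet_band_split(numeric(1000))
  expect_true(all(vapply(z, function(s) all(s == 0), logical(1))))
  expect_error(wavelet_band_split(x, fs = 250), "resample")
})

test_that("a 10 Hz tone concentrates in the alpha (D4) component", {
  x <- tone(10, 30, 240)
  b <- wavelet_band_split(x)
  fr <- vapply(b, function(s) sum(s^2), numeric(1)) / sum(x^2)
  # DB2 filters are short and leaky: the component captures about half the
  # tone's energy, but more than every other band combined
  expect_identical(names(which.max(fr)), "alpha")
  expect_gt(fr[["alpha"]], 0.45)
  expect_gt(fr[["alpha"]], sum(fr[setdiff(names(fr), "alpha")]))
})

test_that("each band component's spectral content is dominated by its nominal interval", {
  set.seed(22)
  x <- rnorm(60 * 240)
  b <- wavelet_band_split(x)
  defs <- band_definitions()
  for (i in seq_len(nrow(defs))) {
    p <- welch_psd(b[[defs$band[i]]], 240)
    f_peak <- p$freqs[which.max(p$power)]
    expect_gte(f_peak, defs$f_lo[i])
    expect_lte(f_peak, defs$f_hi[i])
  }
})

test_that("relative power resolves symmetric two-tone and single-tone probes", {
  fs <- 240
  rec <- eeg_recording(rbind(tone(2, 30, fs) + tone(20, 30, fs),
                             tone(10, 30, fs)),
                       c("Fp1", "Fp2"), fs)
  rp <- relative_power(rec)
  expect_equal(rp["Fp1", "delta"], 0.5, tolerance = 0.05)
  expect_equal(rp["Fp1", "beta"], 0.5, tolerance = 0.05)
  expect_gt(rp["Fp2", "alpha"], 0.8)
  expect_equal(unname(rowSums(rp)), c(1, 1), tolerance = 1e-9)
})

test_that("relative power is scale-invariant and rejects dead channels", {
  set.seed(23)
  x <- rnorm(20 * 240)
  rec1 <- eeg_recording(rbind(x), "Fp1", 240)
  rec2 <- eeg_recording(rbind(-7.3 * x), "Fp1", 240)
  expect_equal(relative_power(rec1), relative_power(rec2), tolerance = 1e-12)
  dead <- eeg_recording(rbind(x, numeric(length(x))), c("Fp1", "Fp2"), 240)
  expect_error(relative_power(dead), "Fp2")
})
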