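# Independent brute-force oracle: materialize every embedding vector as a
# string tuple, count with table(), take Shannon entropy in nats.
brute_disen <- function(z, m, c, d) {
  n <- length(z)
  n_emb <- n - (m - 1) * d
  pats <- vapply(seq_len(n_emb), function(i)
    paste(z[i + (0:(m - 1)) * d], collapse = "-"), character(1))
  p <- as.numeric(table(pats)) / n_emb
  -sum(p * log(p))
}

test_that("NCDF mapping is symmetric, covers all classes, and flags constants", {
  # symmetric about its mean, no value exactly at the mean (the class of
  # the midpoint y = 0.5 depends on the rounding convention)
  x <- c(-3, -1, 1, 3)
  z <- ncdf_map(x, c = 6)
  expect_equal(as.integer(z), rev(7L - as.integer(z)))
  set.seed(41)
  big <- ncdf_map(rnorm(1e4), c = 6)
  expect_setequal(unique(as.integer(big)), 1:6)
  const <- ncdf_map(rep(2.5, 100), c = 6)
  expect_true(attr(const, "degenerate"))
  expect_true(all(const == 1L))
})

test_that("dispersion entropy hits its analytic extremes", {
  cfg <- dispersion_config(m = 2, c = 6, d = 1)
  # single repeated pattern
  expect_equal(as.numeric(dispersion_entropy(rep(3L, 8), cfg, mapped = TRUE)), 0)
  expect_equal(as.numeric(dispersion_entropy(rep(4.2, 100), cfg)), 0)
  # alternating classes: patterns (1,2) and (2,1) equiprobable
  alt <- rep_len(c(1L, 2L), 101)
  expect_equal(as.numeric(dispersion_entropy(alt, cfg, mapped = TRUE)), log(2),
               tolerance = 1e-9)
  # maximum m*ln(c): a de Bruijn sequence visits every pattern exactly once
  debruijn <- c(1L, 1L, 2L, 2L, 1L)       # pairs (1,1),(1,2),(2,2),(2,1)
  expect_equal(as.numeric(dispersion_entropy(debruijn,
                                             dispersion_config(2, 2, 1),
                                             mapped = TRUE)),
               2 * log(2), tolerance = 1e-12)
  probs <- attr(dispersion_entropy(alt, cfg, mapped = TRUE), "pattern_probs")
  expect_equal(sum(probs), 1, tolerance = 1e-12)
})

test_that("dispersion entropy matches the brute-force oracle across parameter grids", {
  set.seed(42)
  worst <- 0
  for (m in c(2, 3)) for (cc in c(4, 6)) for (d in c(1, 2)) {
    cfg <- dispersion_config(m, cc, d)
    for (r in 1:25) {
      n <- sample(50:500, 1)
      x <- rnorm(n)
      z <- ncdf_map(x, cc)
      got <- as.numeric(dispersion_entropy(x, cfg))
      want <- brute_disen(as.integer(z), m, cc, d)
      worst <- max(worst, abs(got - want))
      expect_true(got >= 0 && got <= m * log(cc))
      expect_equal(sum(attr(dispersion_entropy(x, cfg), "pattern_probs")), 1,
                   tolerance = 1e-12)
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("dispersion entropy validates series length against (m-1)d", {
  expect_error(dispersion_entropy(c(1, 2), dispersion_config(3, 6, 2)), "too short")
})

test_that("spectral entropy matches hand-computed Shannon sums and bounds", {
  shannon <- qeeg:::.shannon
  expect_equal(shannon(c(0.5, 0.25, 0.25), base = 2), 1.5)
  expect_equal(shannon(c(0, 1, 0, 0), base = 2), 0)       # one-bin PSD
  expect_equal(shannon(rep(0.125, 8), base = 2), 3)       # flat over 8 bins
  # a noise series stays within [0, log2(bins in band)]
  set.seed(43)
  se <- spectral_entropy(rnorm(30 * 240), 240)
  n_bins <- sum(welch_psd(rnorm(30 * 240), 240)$freqs >= 1 &
                welch_psd(rnorm(30 * 240), 240)$freqs <= 30)
  expect_gt(se, 0)
  expect_lte(se, log2(n_bins))
  # a pure tone's spectrum is far more concentrated than noise
  expect_lt(spectral_entropy(tone(10, 30, 240), 240), se / 2)
})

test_that("spectral dispersion entropy: degenerate flat spectrum and oracle equivalence", {
  # flat PSD series is degenerate under the NCDF map
  expect_equal(as.numeric(dispersion_entropy(rep(1, 59))), 0)
  # strictly decreasing PSD with distinct classes equals the oracle
  p <- exp(-(1:59) / 8)
  z <- ncdf_map(p, 6)
  expect_equal(as.numeric(dispersion_entropy(p)),
               brute_disen(as.integer(z), 2, 6, 1), tolerance = 1e-12)
  expect_error(
    spectral_dispersion_entropy(tone(10, 30, 240), 240, f_lo = 10, f_hi = 10.4),
    "spectral bins")
})

test_that("white noise has higher spectral dispersion entropy than a tonal signal", {
  set.seed(44)
  sde_noise <- spectral_dispersion_entropy(rnorm(60 * 240), 240)
  sde_tone <- spectral_dispersion_entropy(
    tone(10, 60, 240) + 0.05 * rnorm(60 * 240), 240)
  expect_gt(sde_noise, sde_tone)
})

test_that("complexity features are named per channel in both families", {
  set.seed(45)
  rec <- eeg_recording(matrix(rnorm(19 * 20 * 240), 19), channels_1020(), 240)
  feats <- complexity_features(rec)
  expect_length(feats, 38)
  expect_equal(sum(grepl("^SPECEN_", names(feats))), 19)
  expect_equal(sum(grepl("^SPECDE_", names(feats))), 19)
  expect_true(all(feats[grepl("^SPECEN_", names(feats))] > 0))
})
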