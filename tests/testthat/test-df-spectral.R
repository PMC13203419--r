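# Botteron preprocessing, Welch spectra, DF picking, and the OI gate.

make_train <- function(df_hz, dur_s = 4, fs = 1000, seed = 5) {
  set.seed(seed)
  x <- numeric(dur_s * fs)
  wv <- hdfmap:::biphasic_wavelet()
  for (ev in hdfmap:::pulse_train_times(dur_s * 1000,
                                        function(t) df_hz, 0)) {
    x <- hdfmap:::add_at(x, as.integer(round(ev)) + 1L, wv)
  }
  x
}

# spectrum object on the package's 0.05 Hz grid up to 30 Hz
make_spec <- function(power) {
  structure(list(freq = (seq_along(power) - 1L) * 0.05, power = power),
            class = "power_spectrum")
}

test_that("out-of-band sinusoids are rejected by the envelope filter", {
  t <- (0:1999) / 1000
  x <- sin(2 * pi * 5 * t)
  env <- botteron_filter(x, 1000)
  expect_lt(sum(env^2), 0.01 * sum(x^2))
})

test_that("an all-zero window maps to an all-zero envelope", {
  env <- botteron_filter(numeric(2000), 1000)
  expect_equal(env, numeric(2000))
})

test_that("the envelope of a 6 Hz train peaks at 6 Hz", {
  x <- make_train(6)[1001:3000]
  env <- botteron_filter(x, 1000)
  expect_length(env, 2000)
  spec <- welch_psd(env, 1000)
  expect_lt(abs(pick_df(spec) - 6), 0.1)
})

test_that("too-low sampling rates for the bandpass are rejected", {
  expect_error(botteron_filter(numeric(800), 400), "too low")
  expect_error(botteron_filter(numeric(100), 1000), "window")
})

test_that("Welch spectrum localizes a pure tone to the 0.05 Hz grid", {
  t <- (0:1999) / 1000
  env <- sin(2 * pi * 6 * t)
  spec <- welch_psd(env, 1000)
  expect_equal(spec$freq[2] - spec$freq[1], 0.05)
  expect_equal(max(spec$freq), 30)
  expect_lt(abs(spec$freq[which.max(spec$power)] - 6), 0.05 + 1e-9)
  expect_true(all(spec$power >= 0))
})

test_that("a zero envelope has a zero spectrum", {
  spec <- welch_psd(numeric(2000), 1000)
  expect_equal(spec$power, rep(0, length(spec$freq)))
})

test_that("white-noise total power is stable across seeds (sanity bound)", {
  set.seed(31); a <- welch_psd(rnorm(2000), 1000)
  set.seed(32); b <- welch_psd(rnorm(2000), 1000)
  expect_false(isTRUE(all.equal(a$power, b$power)))
  expect_lt(sum(a$power) / sum(b$power), 3)
  expect_lt(sum(b$power) / sum(a$power), 3)
})

test_that("DF picking is restricted to the physiological band", {
  p <- numeric(601)
  p[round(3 / 0.05) + 1] <- 100 # huge 3 Hz peak, out of band
  p[round(5 / 0.05) + 1] <- 1   # small in-band peak
  expect_equal(pick_df(make_spec(p)), 5)
})

test_that("DF ties break to the lowest frequency", {
  p <- numeric(601)
  p[round(5 / 0.05) + 1] <- 1
  p[round(7 / 0.05) + 1] <- 1
  expect_equal(pick_df(make_spec(p)), 5)
})

test_that("a band with no power yields no DF", {
  p <- numeric(601)
  p[round(3 / 0.05) + 1] <- 1
  expect_true(is.na(pick_df(make_spec(p))))
})

test_that("a clean train reproduces the 6.7 Hz worked-example peak", {
  x <- make_train(6.7)
  res <- hdfmap:::df_point_core(x, 1000, 2000, spectral_config(), NULL)
  expect_true(res$valid)
  expect_lt(abs(res$df_hz - 6.7), 0.05 + 1e-9)
  expect_gte(res$oi, 0.2)
})

test_that("spectra concentrated in DF and harmonic bands have OI 1", {
  f <- (0:601) * 0.05
  p <- numeric(length(f))
  for (c0 in c(6, 12, 18)) p[abs(f - c0) <= 0.375] <- 1
  spec <- structure(list(freq = f, power = p), class = "power_spectrum")
  expect_equal(organization_index(spec, 6), 1.0)
})

test_that("spectra with no power near DF or harmonics have OI 0", {
  f <- (0:601) * 0.05
  p <- numeric(length(f))
  p[abs(f - 2) <= 0.2] <- 1 # below the DF band, inside 0-20 Hz
  spec <- structure(list(freq = f, power = p), class = "power_spectrum")
  expect_equal(organization_index(spec, 6), 0.0)
})

test_that("piecewise-constant OI example matches direct grid summation", {
  f <- (0:600) * 0.05
  p <- rep(0.1, length(f))
  p[f >= 5.625 - 1e-9 & f <= 6.375 + 1e-9] <- 1.0
  p[f > 20 + 1e-9] <- 0
  spec <- structure(list(freq = f, power = p), class = "power_spectrum")
  # direct summation: numerator bands at 6 +/- 0.375 and the flat-spectrum
  # harmonic fallbacks at 12 and 18 (no local maximum exists there, but the
  # band is still included, centered on the exact multiple)
  num_mask <- abs(f - 6) <= 0.375 + 1e-9
  for (h in c(12, 18)) num_mask <- num_mask | abs(f - h) <= 0.375 + 1e-9
  den_mask <- f <= 20 + 1e-9
  oracle <- sum(p[num_mask & den_mask]) / sum(p[den_mask])
  expect_equal(organization_index(spec, 6), oracle, tolerance = 1e-12)
})

test_that("OI uses detected harmonic peaks near inexact multiples", {
  f <- (0:600) * 0.05
  p <- rep(0.01, length(f))
  p[f > 15] <- 0 # keep the band around the (flat) third harmonic empty
  p[round(6.5 / 0.05) + 1] <- 1
  p[round(13.3 / 0.05) + 1] <- 0.8 # displaced by +0.3 Hz from 2 x 6.5
  spec <- structure(list(freq = f, power = p), class = "power_spectrum")
  oi_with <- organization_index(spec, 6.5)
  # oracle: band around the displaced peak is included
  num_mask <- abs(f - 6.5) <= 0.375 + 1e-9 | abs(f - 13.3) <= 0.375 + 1e-9
  den_mask <- f <= 20 + 1e-9
  expect_equal(oi_with, sum(p[num_mask & den_mask]) / sum(p[den_mask]),
               tolerance = 1e-12)
})

test_that("adding out-of-band power strictly decreases OI", {
  f <- (0:600) * 0.05
  p <- numeric(length(f))
  p[abs(f - 6) <= 0.375] <- 1
  spec <- structure(list(freq = f, power = p), class = "power_spectrum")
  oi0 <- organization_index(spec, 6)
  p2 <- p
  p2[f >= 2 & f <= 3] <- p2[f >= 2 & f <= 3] + 0.5
  spec2 <- structure(list(freq = f, power = p2), class = "power_spectrum")
  expect_lt(organization_index(spec2, 6), oi0)
})

test_that("added white noise lowers a pulse train's OI", {
  x <- make_train(6)
  r_clean <- hdfmap:::df_point_core(x, 1000, 2000, spectral_config(), NULL)
  set.seed(33)
  xn <- x + rnorm(length(x), 0, sd(x))
  r_noisy <- hdfmap:::df_point_core(xn, 1000, 2000, spectral_config(), NULL)
  expect_lt(r_noisy$oi, r_clean$oi)
})

test_that("OI preconditions are enforced", {
  f <- (0:100) * 0.05 # only up to 5 Hz: does not cover the OI range
  spec <- structure(list(freq = f, power = rep(1, length(f))),
                    class = "power_spectrum")
  expect_error(organization_index(spec, 4.5), "cover")
  full <- make_spec(rep(1, 601))
  expect_error(organization_index(full, 2), "df_hz")
})

test_that("per-point verdicts carry reasons for each failure mode", {
  rec <- clean_recording(6)
  good <- compute_df_point(rec, "ch_01", 2000)
  expect_true(good$valid)
  expect_lt(abs(good$df_hz - 6), 0.1)
  expect_gte(good$oi, 0.2)

  # dropout: same signal scaled below the amplitude floor
  rec_low <- rec
  rec_low$signals <- rec$signals * 0.05
  expect_equal(compute_df_point(rec_low, "ch_01", 2000)$reason, "low_amp")

  # window straddling the recording start
  expect_equal(compute_df_point(rec, "ch_01", 500)$reason, "bounds")

  # outside every fibrillation interval
  af <- structure(data.frame(start_ms = 0, end_ms = 900),
                  class = c("af_periods", "data.frame"))
  expect_equal(compute_df_point(rec, "ch_01", 2000,
                                af_periods = af)$reason, "non_af")

  expect_error(compute_df_point(rec, "nope", 2000), "unknown channel")
})

test_that("valid points always satisfy the DF band and OI gate", {
  rec <- clean_recording(6)
  coords <- data.frame(channel = "ch_01",
                       time_ms = seq(1100, 2900, by = 200),
                       x_mm = 0, y_mm = 0, z_mm = 0)
  pts <- compute_df_points(rec, coords)
  expect_equal(nrow(pts), nrow(coords))
  ok <- pts$valid
  expect_true(any(ok))
  expect_true(all(pts$df_hz[ok] >= 4 & pts$df_hz[ok] <= 10))
  expect_true(all(pts$oi[ok] >= 0.2))
})

test_that("the per-point cache is reused across calls", {
  rec <- clean_recording(6)
  coords <- data.frame(channel = "ch_01", time_ms = c(1500, 2000),
                       x_mm = 0, y_mm = 0, z_mm = 0)
  cache <- new.env(parent = emptyenv())
  a <- compute_df_points(rec, coords, cache = cache)
  expect_setequal(ls(cache), c("ch_01|1500", "ch_01|2000"))
  # poison the cache: a change must show up in the result, proving reuse
  cache[["ch_01|1500"]]$df_hz <- 9.99
  b <- compute_df_points(rec, coords, cache = cache)
  expect_equal(b$df_hz[1], 9.99)
  expect_equal(b$df_hz[2], a$df_hz[2])
})
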