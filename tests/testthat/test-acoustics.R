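hann_frame <- function(f, rate = 16000, n = 1024, amp = 1) {
  amp * sin(2 * pi * f * (seq_len(n) - 1) / rate)
}

test_that("the spectrum peaks at the input frequency and respects Parseval", {
  fr <- hann_frame(1000)
  sl <- short_term_spectrum(fr, 16000)
  peak <- sl$freqs[which.max(sl$log_mag)]
  expect_lt(abs(peak - 1000), 16000 / sl$nfft + 1e-9)
  # Parseval: band power sums reproduce the windowed-frame energy
  n <- length(fr)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  expect_equal(sum(sl$power) / sl$nfft, sum((fr * w)^2), tolerance = 0.01)
  z <- short_term_spectrum(numeric(512), 16000)
  expect_true(z$flagged)
  expect_error(short_term_spectrum(numeric(64), 16000), class = "prosodia_argument_error")
})

test_that("intensity follows the dB scaling laws with a silent floor", {
  t <- (0:15999) / 16000
  full <- sin(2 * pi * 100 * t) # exact integer periods
  expect_equal(intensity_db(full), 10 * log10(0.5), tolerance = 1e-6)
  expect_equal(round(intensity_db(full), 2), -3.01)
  expect_equal(intensity_db(full / 2) - intensity_db(full), -20 * log10(2),
    tolerance = 1e-9
  )
  sil <- intensity_db(numeric(100))
  expect_equal(as.numeric(sil), -120)
  expect_true(attr(sil, "flagged"))
  expect_error(intensity_db(numeric(0)), class = "prosodia_argument_error")
})

flat_slice <- function(rate = 16000, nfft = 2048) {
  half <- nfft %/% 2
  structure(
    list(
      freqs = (0:half) * rate / nfft,
      log_mag = rep(0, half + 1), power = rep(1, half + 1),
      nfft = nfft, rate = rate, center_time_s = NA, f0_hz = NA, flagged = FALSE
    ),
    class = "spectral_slice"
  )
}

test_that("SER is the band-width ratio on a flat spectrum and is monotone", {
  sl <- flat_slice()
  # equal power per bin: 0-1 kHz vs 1-5 kHz band widths are 1:4
  expect_equal(ser_db(sl), 10 * log10(sum(sl$freqs <= 1000) /
    sum(sl$freqs > 1000 & sl$freqs <= 5000)), tolerance = 1e-12)
  expect_equal(ser_db(sl), -6.02, tolerance = 0.03)
  lowonly <- sl
  lowonly$power[lowonly$freqs > 1000] <- 0
  v <- ser_db(lowonly)
  expect_equal(as.numeric(v), 60)
  expect_true(attr(v, "flagged"))
  # adding high-band energy strictly decreases SER
  more <- sl
  more$power[more$freqs > 1000 & more$freqs <= 5000] <- 2
  expect_lt(ser_db(more), ser_db(sl))
  low_rate <- flat_slice(rate = 8000)
  expect_error(ser_db(low_rate), class = "prosodia_argument_error")
})

test_that("harmonic levels recover planted harmonic amplitude ratios", {
  rate <- 16000
  n <- 2048
  t <- (seq_len(n) - 1) / rate
  fr <- 1.0 * sin(2 * pi * 125 * t) + 0.5 * sin(2 * pi * 250 * t) +
    0.25 * sin(2 * pi * 375 * t)
  sl <- short_term_spectrum(fr, rate)
  lv <- harmonic_levels(sl, 125)
  expect_equal(lv[["L2"]] - lv[["L1"]], -6.02, tolerance = 0.5)
  expect_equal(lv[["L3"]] - lv[["L1"]], -12.04, tolerance = 0.5)
  fr_eq <- sin(2 * pi * 125 * t) + sin(2 * pi * 250 * t) + sin(2 * pi * 375 * t)
  lv_eq <- harmonic_levels(short_term_spectrum(fr_eq, rate), 125)
  expect_equal(lv_eq[["L2"]] - lv_eq[["L1"]], 0, tolerance = 0.5)
  # third harmonic beyond Nyquist is undefined
  lv3 <- harmonic_levels(short_term_spectrum(sin(2 * pi * 2000 * (0:511) / 8000), 8000), 2000)
  expect_true(is.na(lv3[["L3"]]))
})

test_that("formant bandwidths match an independent transcription", {
  f0 <- 100
  bw <- hawks_miller_bandwidth(c(300, 500, 1000, 2500, 4000), f0)
  expect_true(all(is.finite(bw) & bw > 0))
  # independent re-transcription of the two-branch polynomial
  hm_ref <- function(f, f0) {
    s <- 1 + 0.25 * (f0 - 132) / 88
    if (f < 500) {
      co <- c(165.327516, -6.73636734e-1, 1.80874446e-3, -4.52201682e-6,
        7.49514000e-9, -4.70219241e-12)
    } else {
      co <- c(15.8146139, 8.10159009e-2, -9.79728215e-5, 5.28725064e-8,
        -1.07099364e-11, 7.91528509e-16)
    }
    s * sum(co * f^(0:5))
  }
  expect_equal(hawks_miller_bandwidth(500, 100), hm_ref(500, 100), tolerance = 1e-6)
  expect_equal(hawks_miller_bandwidth(499.9, 120), hm_ref(499.9, 120), tolerance = 1e-6)
  # continuity across the branch junction
  expect_lt(abs(hawks_miller_bandwidth(499.999, 100) - hawks_miller_bandwidth(500.001, 100)), 5)
  expect_error(hawks_miller_bandwidth(50, 100), class = "prosodia_range_error")
})

test_that("formant correction is identity without formants and small far away", {
  expect_identical(iseli_corrected_level(-20, 200, list(), 16000), -20)
  corr <- iseli_corrected_level(0, 100, list(c(4000, 300)), 16000)
  expect_lt(abs(corr), 1)
  # dual transcription on random (freq, F, B) triples
  ref_term <- function(f, Fi, Bi, fs) {
    r <- exp(-pi * Bi / fs)
    wi <- 2 * pi * Fi / fs
    w <- 2 * pi * f / fs
    10 * log10((1 - 2 * r * cos(wi) + r^2)^2 /
      ((1 - 2 * r * cos(w - wi) + r^2) * (1 - 2 * r * cos(w + wi) + r^2)))
  }
  withr::with_seed(5, {
    for (i in 1:20) {
      f <- stats::runif(1, 80, 600)
      Fi <- stats::runif(1, 300, 4500)
      Bi <- stats::runif(1, 40, 400)
      got <- iseli_corrected_level(0, f, list(c(Fi, Bi)), 16000)
      expect_equal(got, -ref_term(f, Fi, Bi, 16000), tolerance = 1e-9)
    }
  })
  expect_error(
    iseli_corrected_level(0, 100, list(c(500, -10)), 16000),
    class = "prosodia_argument_error"
  )
})

test_that("LPC formant estimation recovers a planted resonator cascade", {
  rate <- 16000
  src <- make_sawtooth(110, 0.25, rate, n_harm = 60)
  x <- src
  for (fm in list(c(500, 60), c(1500, 90), c(2500, 120))) {
    r <- exp(-pi * fm[2] / rate)
    th <- 2 * pi * fm[1] / rate
    x <- as.numeric(stats::filter(x * (1 - r), c(2 * r * cos(th), -r^2),
      method = "recursive"
    ))
  }
  fr <- x[2000:3023]
  est <- estimate_formants(fr, rate, f0_hz = 110)
  expect_gte(length(est), 3L)
  ff <- vapply(est, `[`, numeric(1), 1)
  expect_true(all(diff(ff) > 0))
  expect_lt(abs(ff[1] - 500) / 500, 0.08)
  expect_lt(abs(ff[2] - 1500) / 1500, 0.08)
  expect_lt(abs(ff[3] - 2500) / 2500, 0.08)
  noise <- withr::with_seed(2, stats::rnorm(1024, 0, 0.3))
  nf <- estimate_formants(noise, rate)
  ffn <- vapply(nf, `[`, numeric(1), 1)
  if (length(ffn) > 1) expect_true(all(diff(ffn) > 0))
})

test_that("C1 tracks spectral tilt and ignores gain", {
  rate <- 16000
  mk_tilt <- function(slope_db_oct) {
    sl <- flat_slice(rate)
    half <- length(sl$freqs)
    withr::with_seed(3, {
      n <- 2048
      X <- complex(
        modulus = 10^((slope_db_oct * log2(pmax(sl$freqs, 50) / 500)) / 20),
        argument = stats::runif(half, -pi, pi)
      )
      full <- c(X, Conj(rev(X[2:(half - 1)])))
      Re(stats::fft(full, inverse = TRUE)) / n
    })
  }
  c_flat <- mfcc_c1(mk_tilt(0), rate)
  c_mid <- mfcc_c1(mk_tilt(-6), rate)
  c_steep <- mfcc_c1(mk_tilt(-18), rate)
  # steeper negative tilt gives strictly larger C1 (fixed convention)
  expect_gt(c_steep, c_mid)
  expect_gt(c_mid, c_flat)
  expect_lt(abs(c_flat), 0.5)
  fr <- mk_tilt(-12)
  expect_equal(mfcc_c1(fr, rate), mfcc_c1(3.7 * fr, rate), tolerance = 1e-6)
  expect_error(mfcc_c1(numeric(128), rate), class = "prosodia_argument_error")
})

test_that("spectral polynomial fits recover planted slopes and coefficients", {
  sl <- flat_slice()
  expect_equal(spectral_poly_fit(sl, 1L), 0, tolerance = 1e-9)
  lin <- sl
  lin$log_mag <- -5 * lin$freqs / 1000
  expect_equal(spectral_poly_fit(lin, 1L), -5, tolerance = 1e-6)
  # order-6 fit equals an independent normal-equations solution
  withr::with_seed(9, {
    for (i in 1:3) {
      sl2 <- flat_slice()
      sl2$log_mag <- stats::rnorm(length(sl2$freqs), 0, 5)
      co <- spectral_poly_fit(sl2, 6L)
      sel <- sl2$freqs <= 5000
      X <- outer(sl2$freqs[sel] / 1000, 0:6, `^`)
      ref <- solve(crossprod(X), crossprod(X, sl2$log_mag[sel]))[2:7]
      expect_equal(co, as.numeric(ref), tolerance = 1e-6)
    }
  })
})

test_that("gain shifts levels by 20 log10(g) and leaves ratios unchanged", {
  g <- 2.5
  fr <- make_sawtooth(140, 0.1, 16000, n_harm = 40)[1:1024]
  expect_equal(intensity_db(g * fr) - intensity_db(fr), 20 * log10(g),
    tolerance = 1e-9
  )
  sl1 <- short_term_spectrum(fr, 16000)
  slg <- short_term_spectrum(g * fr, 16000)
  expect_equal(ser_db(slg), ser_db(sl1), tolerance = 1e-9)
  expect_equal(spectral_poly_fit(slg, 1L), spectral_poly_fit(sl1, 1L), tolerance = 1e-6)
  lv1 <- harmonic_levels(sl1, 140)
  lvg <- harmonic_levels(slg, 140)
  expect_equal(lvg[["L2"]] - lvg[["L1"]], lv1[["L2"]] - lv1[["L1"]], tolerance = 1e-9)
})
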