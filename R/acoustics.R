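#' Short-term log-magnitude spectrum of a frame
#'
#' Hann-windowed one-sided magnitude spectrum. `power` is scaled so that
#' `sum(power) / nfft` equals the windowed-frame energy (Parseval), which
#' makes band-energy sums meaningful.
#'
#' @param frame Numeric vector of samples (length >= 128).
#' @param rate Sampling rate in Hz.
#' @param center_time_s Optional frame center time carried along.
#' @param f0_hz Optional f0 at the frame, carried along for harmonic
#'   measurements.
#' @return A `spectral_slice`: list with `freqs` (Hz), `log_mag` (dB),
#'   `power` (one-sided, Parseval-scaled), `nfft`, `rate`, `flagged`.
#' @export
short_term_spectrum <- function(frame, rate, center_time_s = NA_real_, f0_hz = NA_real_) {
  n <- length(frame)
  if (n < 128L) {
    rlang::abort("Frame must have at least 128 samples.", class = "prosodia_argument_error")
  }
  flagged <- all(frame == 0)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- frame * w
  nfft <- 2^ceiling(log2(n))
  X <- stats::fft(c(xw, numeric(nfft - n)))
  half <- nfft %/% 2L
  mag <- Mod(X[1:(half + 1L)])
  power <- mag^2
  power[2:half] <- 2 * power[2:half] # fold the negative frequencies
  structure(
    list(
      freqs = (0:half) * rate / nfft,
      log_mag = 20 * log10(mag + 1e-12),
      power = power,
      nfft = nfft, rate = rate,
      center_time_s = center_time_s, f0_hz = f0_hz,
      flagged = flagged
    ),
    class = "spectral_slice"
  )
}

#' Frame intensity in dB re digital full scale
#'
#' `10 * log10` of the mean squared amplitude; a full-scale square wave is
#' 0 dB, a full-scale sine -3.01 dB. Silent frames return the floor value
#' -120 dB with attribute `flagged = TRUE`.
#'
#' @param frame Numeric vector of samples.
#' @return Intensity in dB (scalar, possibly with attribute `flagged`).
#' @export
intensity_db <- function(frame) {
  if (length(frame) == 0L) {
    rlang::abort("Empty frame.", class = "prosodia_argument_error")
  }
  ms <- mean(frame^2)
  if (ms <= 0) {
    return(structure(-120, flagged = TRUE))
  }
  10 * log10(ms)
}

#' Spectral energy ratio (SER) between the 0-1 kHz and 1-5 kHz bands
#'
#' `10 * log10(E[0, 1 kHz] / E(1 kHz, 5 kHz])` over linear power band sums.
#' A degenerate band (zero energy) caps the value at +/-60 dB with
#' attribute `flagged = TRUE`.
#'
#' @param slice A [short_term_spectrum()] slice; Nyquist must exceed 5 kHz.
#' @return SER in dB.
#' @export
ser_db <- function(slice) {
  if (max(slice$freqs) <= 5000) {
    rlang::abort("SER needs a Nyquist frequency above 5 kHz.", class = "prosodia_argument_error")
  }
  lo <- sum(slice$power[slice$freqs <= 1000])
  hi <- sum(slice$power[slice$freqs > 1000 & slice$freqs <= 5000])
  if (hi <= 0) return(structure(60, flagged = TRUE))
  if (lo <= 0) return(structure(-60, flagged = TRUE))
  10 * log10(lo / hi)
}

#' Levels of the first three harmonics
#'
#' For each harmonic `k * f0` (k = 1..3) the level is the log-magnitude at
#' the spectral peak nearest `k * f0` within plus/minus `f0/4`, refined by
#' parabolic interpolation over three bins. `L3` is `NA` when `3 * f0`
#' reaches Nyquist.
#'
#' @param slice A [short_term_spectrum()] slice.
#' @param f0 Fundamental frequency in Hz.
#' @return Named numeric vector `c(L1, L2, L3)` in dB.
#' @export
harmonic_levels <- function(slice, f0) {
  if (!is.finite(f0) || f0 <= 0) {
    rlang::abort("`f0` must be positive.", class = "prosodia_argument_error")
  }
  nyq <- max(slice$freqs)
  one <- function(k) {
    target <- k * f0
    if (target >= nyq) return(NA_real_)
    sel <- which(abs(slice$freqs - target) <= f0 / 4)
    if (length(sel) == 0L) sel <- which.min(abs(slice$freqs - target))
    j <- sel[which.max(slice$log_mag[sel])]
    if (j <= 1L || j >= length(slice$log_mag)) return(slice$log_mag[j])
    a <- slice$log_mag[j - 1L]; b <- slice$log_mag[j]; cc <- slice$log_mag[j + 1L]
    den <- a - 2 * b + cc
    if (!is.finite(den) || abs(den) < 1e-12) return(b)
    p <- 0.5 * (a - cc) / den
    b - 0.25 * (a - cc) * p
  }
  c(L1 = one(1), L2 = one(2), L3 = one(3))
}

#' Formant bandwidth from formant frequency and f0 (Hawks-Miller)
#'
#' Two-branch fifth-order polynomial in the formant frequency with an
#' f0-dependent scaling factor, valid for formants between 100 and 5000 Hz.
#'
#' @param formant_hz Formant frequency in Hz, in (100, 5000).
#' @param f0_hz Fundamental frequency in Hz.
#' @return Bandwidth in Hz.
#' @export
hawks_miller_bandwidth <- function(formant_hz, f0_hz) {
  if (any(formant_hz <= 100 | formant_hz >= 5000)) {
    rlang::abort("Formant frequency must be in (100, 5000) Hz.", class = "prosodia_range_error")
  }
  s <- 1 + 0.25 * (f0_hz - 132) / 88
  low <- c(165.327516, -6.73636734e-1, 1.80874446e-3, -4.52201682e-6,
           7.49514000e-9, -4.70219241e-12)
  high <- c(15.8146139, 8.10159009e-2, -9.79728215e-5, 5.28725064e-8,
            -1.07099364e-11, 7.91528509e-16)
  vapply(formant_hz, function(f) {
    co <- if (f < 500) low else high
    s * sum(co * f^(0:5))
  }, numeric(1))
}

#' Formant-influence correction of a harmonic level (Iseli)
#'
#' Removes the boost each nearby formant (modelled as a second-order
#' resonator with pole radius `exp(-pi * B / rate)`) contributes to the
#' measured level at `freq_hz`, normalized to the resonator's DC gain.
#' With an empty formant list the level is returned unchanged.
#'
#' @param level_db Measured level in dB.
#' @param freq_hz Frequency of the measured harmonic in Hz.
#' @param formants List of `c(F, B)` pairs (frequency and bandwidth, Hz).
#' @param rate Sampling rate in Hz.
#' @return Corrected level in dB.
#' @export
iseli_corrected_level <- function(level_db, freq_hz, formants, rate) {
  if (freq_hz <= 0) {
    rlang::abort("`freq_hz` must be positive.", class = "prosodia_argument_error")
  }
  if (length(formants) == 0L) return(level_db)
  corr <- 0
  for (fm in formants) {
    Fi <- fm[[1]]; Bi <- fm[[2]]
    if (!is.finite(Bi) || Bi <= 0) {
      rlang::abort("Formant bandwidth must be positive.", class = "prosodia_argument_error")
    }
    r <- exp(-pi * Bi / rate)
    wi <- 2 * pi * Fi / rate
    w <- 2 * pi * freq_hz / rate
    num <- (1 - 2 * r * cos(wi) + r^2)^2
    den <- (1 - 2 * r * cos(w - wi) + r^2) * (1 - 2 * r * cos(w + wi) + r^2)
    corr <- corr + 10 * log10(num / den)
  }
  level_db - corr
}

# Levinson-Durbin recursion: autocorrelation -> LPC coefficients a_1..a_p
# for the predictor x[n] ~ sum a_k x[n-k].
.levinson <- function(r, p) {
  a <- numeric(p)
  e <- r[1]
  if (e <= 0) return(NULL)
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[1:(i - 1)] * r[i:2])
    k <- acc / e
    new_a <- a
    new_a[i] <- k
    if (i > 1) new_a[1:(i - 1)] <- a[1:(i - 1)] - k * a[(i - 1):1]
    a <- new_a
    e <- e * (1 - k^2)
    if (e <= 0) return(NULL)
  }
  a
}

#' Formant estimation by linear prediction
#'
#' Pre-emphasis (0.97), Hann window, autocorrelation LPC of order
#' `round(2 + rate/1000)`, roots converted to formant candidates with
#' frequency in (90, 5000) Hz and raw bandwidth below 700 Hz. The first
#' three candidates (ascending) are kept and their bandwidths replaced by
#' [hawks_miller_bandwidth()].
#'
#' @param frame Voiced frame samples.
#' @param rate Sampling rate in Hz.
#' @param f0_hz f0 used for the bandwidth model (default 100 Hz when
#'   unknown).
#' @return List of up to three `c(F, B)` pairs (possibly empty, with
#'   attribute `flagged = TRUE` when no stable structure was found).
#' @export
estimate_formants <- function(frame, rate, f0_hz = 100) {
  n <- length(frame)
  if (n < 64L) return(structure(list(), flagged = TRUE))
  x <- frame - c(0, 0.97 * frame[-n])
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  x <- x * w
  p <- as.integer(round(2 + rate / 1000))
  if (all(x == 0) || p >= n - 1L) return(structure(list(), flagged = TRUE))
  r <- as.numeric(stats::acf(x, lag.max = p, type = "covariance",
    plot = FALSE, demean = FALSE)$acf)
  a <- .levinson(r, p)
  if (is.null(a)) return(structure(list(), flagged = TRUE))
  # A(z) = 1 - sum a_k z^-k ; roots of z^p - a_1 z^(p-1) - ... - a_p
  rts <- tryCatch(polyroot(rev(c(1, -a))), error = function(e) NULL)
  if (is.null(rts)) return(structure(list(), flagged = TRUE))
  freq <- Arg(rts) * rate / (2 * pi)
  bw <- -rate / pi * log(pmin(Mod(rts), 1 - 1e-12))
  keep <- freq > 90 & freq < 5000 & bw < 700
  if (!any(keep)) return(structure(list(), flagged = TRUE))
  cand <- sort(freq[keep])
  # one formant per peak of the LPC spectral envelope: a high model order
  # can split a resonance into close pole pairs, which share one peak
  fg <- seq(90, min(5000, rate / 2 - 100), by = 10)
  wg <- 2 * pi * fg / rate
  Aw <- vapply(wg, function(w) {
    abs(1 - sum(a * exp(-1i * w * seq_len(p))))
  }, numeric(1))
  env <- -20 * log10(pmax(Aw, 1e-12))
  pk <- which(diff(sign(diff(env))) < 0) + 1L
  if (length(pk) == 0L) return(structure(list(), flagged = TRUE))
  ff <- numeric(0)
  for (fpk in fg[pk]) {
    j <- which.min(abs(cand - fpk))
    if (length(j) && abs(cand[j] - fpk) < 200) ff <- c(ff, cand[j])
  }
  ff <- sort(unique(ff))
  if (length(ff) == 0L) return(structure(list(), flagged = TRUE))
  ff <- ff[seq_len(min(3L, length(ff)))]
  # bandwidth model is valid on (100, 5000); clamp edge candidates into it
  lapply(ff, function(f) {
    c(f, hawks_miller_bandwidth(min(max(f, 100.5), 4999.5), f0_hz))
  })
}

#' First Mel-frequency cepstral coefficient (C1)
#'
#' 26 triangular Mel filters spanning 0 Hz to Nyquist, each normalized to
#' unit weight so a flat power spectrum yields (near) equal filterbank
#' energies, log energies, orthonormal DCT-II; returns coefficient index 1
#' (index 0, the frame gain, is excluded, which makes C1 invariant to
#' amplitude scaling). C1 summarizes spectral tilt: steeper negative tilt
#' gives larger C1.
#'
#' @param frame Frame samples (length >= 256).
#' @param rate Sampling rate in Hz.
#' @param n_filters Number of Mel filters (default 26).
#' @return C1 (dimensionless scalar; attribute `flagged` on silent frames).
#' @export
mfcc_c1 <- function(frame, rate, n_filters = 26L) {
  if (length(frame) < 256L) {
    rlang::abort("Frame must have at least 256 samples.", class = "prosodia_argument_error")
  }
  if (all(frame == 0)) return(structure(0, flagged = TRUE))
  sl <- short_term_spectrum(frame, rate)
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- mel_to_hz(seq(0, hz_to_mel(rate / 2), length.out = n_filters + 2L))
  f <- sl$freqs
  energies <- vapply(seq_len(n_filters), function(i) {
    lo <- edges[i]; ce <- edges[i + 1L]; hi <- edges[i + 2L]
    w <- numeric(length(f))
    up <- f >= lo & f <= ce
    dn <- f > ce & f <= hi
    if (ce > lo) w[up] <- (f[up] - lo) / (ce - lo)
    if (hi > ce) w[dn] <- (hi - f[dn]) / (hi - ce)
    s <- sum(w)
    if (s > 0) w <- w / s
    sum(w * sl$power)
  }, numeric(1))
  loge <- log(energies + 1e-30)
  n <- n_filters
  # orthonormal DCT-II, coefficient k = 1
  c1 <- sqrt(2 / n) * sum(loge * cos(pi * 1 * (seq_len(n) - 0.5) / n))
  c1
}

#' Polynomial fit to the short-term log-magnitude spectrum
#'
#' Least-squares polynomial in frequency (kHz units, fit restricted to
#' 0-5 kHz). Order 1 returns the slope only (SLF, dB/kHz); order 6 returns
#' the six non-constant coefficients (SLF6D) -- the constant term is frame
#' gain, already captured by intensity.
#'
#' @param slice A [short_term_spectrum()] slice.
#' @param order 1 or 6.
#' @return Order 1: scalar slope (dB/kHz). Order 6: numeric vector of 6
#'   coefficients (dB/kHz^k, k = 1..6).
#' @export
spectral_poly_fit <- function(slice, order) {
  if (!order %in% c(1L, 6L)) {
    rlang::abort("`order` must be 1 or 6.", class = "prosodia_argument_error")
  }
  sel <- slice$freqs <= 5000
  x <- slice$freqs[sel] / 1000
  y <- slice$log_mag[sel]
  if (length(x) < order + 1L) {
    rlang::abort("Not enough spectral bins for the requested order.",
      class = "prosodia_argument_error"
    )
  }
  X <- outer(x, 0:order, `^`)
  co <- qr.coef(qr(X), y)
  co[!is.finite(co)] <- 0
  if (order == 1L) unname(co[2]) else unname(co[2:7])
}
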