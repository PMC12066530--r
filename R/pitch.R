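#' Single-pass fundamental-frequency estimation
#'
#' Normalized-autocorrelation pitch tracker on 40 ms windows with a 10 ms
#' hop. The candidate lag search is restricted to `[1/hi, 1/lo]`; a frame is
#' voiced when its normalized autocorrelation peak reaches
#' `voicing_threshold`. Peak lags are refined by parabolic interpolation.
#'
#' @param sig An [audio_signal()].
#' @param lo,hi Search bounds in Hz; `0 < lo < hi < rate/2`.
#' @param voicing_threshold Normalized autocorrelation peak required to call
#'   a frame voiced (default 0.45).
#' @param win_s,hop_s Analysis window and hop in seconds.
#' @return A `pitch_track`: tibble with columns `time_s` and `f0_hz`
#'   (`NA` for unvoiced frames), attributes `lo`, `hi`, `rate`.
#' @export
estimate_f0_once <- function(sig, lo, hi, voicing_threshold = 0.45,
                             win_s = 0.040, hop_s = 0.010) {
  if (!(lo > 0 && lo < hi)) {
    rlang::abort("Need 0 < lo < hi.", class = "prosodia_argument_error")
  }
  if (hi >= sig$rate / 2) {
    rlang::abort("`hi` must be below the Nyquist frequency.", class = "prosodia_argument_error")
  }
  fr <- frame_signal(sig, win_s, hop_s)
  x <- fr$frames
  x <- sweep(x, 2, colMeans(x)) # remove DC per frame
  win_n <- fr$win_n
  nfft <- 2^ceiling(log2(2L * win_n))
  pad <- rbind(x, matrix(0, nfft - win_n, ncol(x)))
  X <- stats::mvfft(pad)
  acf <- Re(stats::mvfft(X * Conj(X), inverse = TRUE)) / nfft
  r0 <- acf[1L, ]
  lag_min <- max(2L, as.integer(floor(sig$rate / hi)))
  lag_max <- min(win_n - 1L, as.integer(ceiling(sig$rate / lo)))
  if (lag_max <= lag_min) {
    rlang::abort("Lag search range is empty at this rate.", class = "prosodia_argument_error")
  }
  lags <- lag_min:lag_max
  seg <- acf[lags + 1L, , drop = FALSE]
  denom <- ifelse(r0 > 0, r0, Inf)
  nacf <- sweep(seg, 2, denom, "/")
  best <- apply(nacf, 2, which.max)
  n_fr <- ncol(x)
  peak_val <- nacf[cbind(best, seq_len(n_fr))]
  lag_best <- lags[best]
  # parabolic refinement of the peak lag
  can_interp <- best > 1L & best < length(lags)
  a <- ifelse(can_interp, nacf[cbind(pmax(best - 1L, 1L), seq_len(n_fr))], NA_real_)
  b <- peak_val
  cc <- ifelse(can_interp, nacf[cbind(pmin(best + 1L, length(lags)), seq_len(n_fr))], NA_real_)
  denom2 <- a - 2 * b + cc
  delta <- ifelse(can_interp & is.finite(denom2) & abs(denom2) > 1e-12,
    0.5 * (a - cc) / denom2, 0
  )
  delta[!is.finite(delta)] <- 0
  delta <- pmax(pmin(delta, 0.5), -0.5)
  lag_ref <- lag_best + delta
  f0 <- sig$rate / lag_ref
  f0 <- pmax(pmin(f0, hi), lo)
  voiced <- is.finite(peak_val) & peak_val >= voicing_threshold & r0 > 0
  f0[!voiced] <- NA_real_
  out <- tibble::tibble(time_s = fr$centers_s, f0_hz = f0)
  structure(out,
    lo = lo, hi = hi, rate = sig$rate, q1 = NA_real_,
    class = c("pitch_track", class(out))
  )
}

#' Second-pass f0 search bounds from the first-pass quartile
#'
#' The narrowed search space is `0.75 * q1` Hz up to 1.5 octaves above `q1`,
#' which removes octave errors without speaker-specific (age/sex) tuning.
#'
#' @param q1 First quartile of the first-pass voiced f0 distribution, Hz.
#' @return Numeric vector `c(lo, hi)` in Hz.
#' @export
second_pass_bounds <- function(q1) {
  if (!is.numeric(q1) || length(q1) != 1L || !is.finite(q1) || q1 <= 0) {
    rlang::abort("`q1` must be a single positive number.", class = "prosodia_argument_error")
  }
  c(0.75 * q1, q1 * 2^1.5)
}

#' Two-pass fundamental-frequency estimation
#'
#' Pass one searches a very wide space (60-750 Hz by default). The first
#' quartile `q1` of the voiced pass-one estimates (after a width-5 median
#' filter that suppresses octave jumps) defines the narrowed pass-two search
#' space via [second_pass_bounds()]; the returned track comes from pass two
#' and carries `q1` and the bounds used.
#'
#' @inheritParams estimate_f0_once
#' @param lo,hi First-pass search bounds in Hz.
#' @param smooth_width Median filter width (frames) applied to voiced f0
#'   before computing `q1`; must be odd.
#' @return A `pitch_track` tibble (`time_s`, `f0_hz`) with attributes `q1`,
#'   `lo`, `hi` (the pass-two bounds) and `rate`.
#' @export
estimate_f0 <- function(sig, lo = 60, hi = 750, voicing_threshold = 0.45,
                        win_s = 0.040, hop_s = 0.010, smooth_width = 5L) {
  pass1 <- estimate_f0_once(sig, lo, hi,
    voicing_threshold = voicing_threshold, win_s = win_s, hop_s = hop_s
  )
  v <- pass1$f0_hz[!is.na(pass1$f0_hz)]
  if (length(v) == 0L) {
    rlang::abort(
      sprintf("Unvoiced utterance: no voiced frames found in '%s'.", sig$id),
      class = "prosodia_unvoiced_error"
    )
  }
  if (length(v) >= smooth_width) v <- stats::runmed(v, smooth_width)
  q1 <- as.numeric(stats::quantile(v, 0.25, type = 7, names = FALSE))
  b <- second_pass_bounds(q1)
  lo2 <- b[1]
  hi2 <- min(b[2], sig$rate / 2 - 1)
  track <- estimate_f0_once(sig, lo2, hi2,
    voicing_threshold = voicing_threshold, win_s = win_s, hop_s = hop_s
  )
  attr(track, "q1") <- q1
  track
}

#' Write a pitch track to CSV
#'
#' Columns `time_s,f0_hz`, with empty cells for unvoiced frames.
#'
#' @param track A `pitch_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pitch_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE, na = "")
  invisible(path)
}
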