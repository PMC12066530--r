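.stat6 <- c("min", "max", "mean", "sd", "cv", "iqr")
.s6names <- function(prefix) paste0(prefix, .stat6)

#' Six summary statistics of a value series
#'
#' Minimum, maximum, mean, sample standard deviation (n-1 denominator, 0
#' for a single value), coefficient of variability (`sd/mean`, `NA` when
#' the mean is numerically zero), and inter-quartile range with
#' linear-interpolation quantiles.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Named numeric vector `min, max, mean, sd, cv, iqr`.
#' @export
summarize6 <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) {
    rlang::abort("Need at least one finite value.", class = "prosodia_argument_error")
  }
  m <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  c(
    min = min(v), max = max(v), mean = m, sd = s,
    cv = if (abs(m) < 1e-12) NA_real_ else s / m,
    iqr = q[2] - q[1]
  )
}

#' Names of the 205 utterance predictors, in frozen order
#'
#' The battery covers four domains: MTP timing (15), Momel f0 (16),
#' intensity (16), and spectral tilt (158). Two slots are reconstructions
#' of ambiguous rows in the source battery and are documented as such:
#' `utt_duration2_s` (the duration appears twice in the timing domain) and
#' `int_mean_db` (utterance mean intensity). The utterance-level
#' long-term-average-spectrum slots are `ser_ltas_db` (SER of the
#' utterance-averaged spectrum) and `dser_sd_ltas_db` (root mean squared
#' deviation of the per-MTP SER changes about the LTAS SER).
#'
#' @return Character vector of length 205.
#' @export
feature_names <- function() {
  c(
    # -- time (15)
    .s6names("mtp_time_"), .s6names("mtp_dtime_"),
    "utt_duration_s", "mtp_per_s", "utt_duration2_s",
    # -- f0 (16)
    .s6names("mtp_f0_"), .s6names("mtp_df0_"),
    "f0_key_hz", "f0_range_hz", "f0_min_hz", "f0_max_hz",
    # -- intensity (16)
    .s6names("mtp_int_"), .s6names("mtp_dint_"),
    "int_mean_db", "int_range_db", "int_min_db", "int_max_db",
    # -- spectral tilt (158)
    .s6names("mtp_ser_"), "ser_ltas_db",
    .s6names("mtp_dser_"), "dser_sd_ltas_db",
    .s6names("mtp_l2l1_raw_"), .s6names("mtp_l2l1_corr_"),
    .s6names("mtp_l3l1_raw_"), .s6names("mtp_l3l1_corr_"),
    .s6names("mtp_dl2l1_raw_"), .s6names("mtp_dl2l1_corr_"),
    .s6names("mtp_dl3l1_raw_"), .s6names("mtp_dl3l1_corr_"),
    .s6names("mtp_c1_"), .s6names("mtp_dc1_"),
    .s6names("mtp_slf_"), .s6names("mtp_dslf_"),
    unlist(lapply(1:6, function(k) .s6names(sprintf("mtp_slf6d%d_", k)))),
    unlist(lapply(1:6, function(k) .s6names(sprintf("mtp_dslf6d%d_", k))))
  )
}

#' Domain of each predictor
#'
#' @return Tibble with columns `feature`, `domain`
#'   (`time`/`f0`/`intensity`/`tilt`).
#' @export
feature_domains <- function() {
  tibble::tibble(
    feature = feature_names(),
    domain = rep(c("time", "f0", "intensity", "tilt"), times = c(15, 16, 16, 158))
  )
}

#' Checksum of the frozen feature-name list
#'
#' Used to guard models against being applied to feature tables produced
#' under a different battery layout.
#'
#' @return Character hash.
#' @export
feature_checksum <- function() {
  rlang::hash(paste(feature_names(), collapse = ","))
}

# Acoustic measurements in a 30 ms Hann-centred window at each MTP.
.measure_mtps <- function(sig, curve, mtp_win_s = 0.030) {
  mtps <- curve$mtps
  n <- nrow(mtps)
  win_n <- max(256L, as.integer(round(mtp_win_s * sig$rate)))
  half <- win_n %/% 2L
  padded <- c(numeric(half), sig$samples, numeric(win_n))
  grab <- function(t) {
    c0 <- as.integer(round(t * sig$rate))
    padded[(c0 + 1L):(c0 + win_n)]
  }
  rows <- lapply(seq_len(n), function(i) {
    fr <- grab(mtps$time_s[i])
    f0 <- mtps$f0_hz[i]
    sl <- short_term_spectrum(fr, sig$rate, center_time_s = mtps$time_s[i], f0_hz = f0)
    lv <- harmonic_levels(sl, f0)
    fmts <- estimate_formants(fr, sig$rate, f0_hz = f0)
    l2l1_raw <- lv["L2"] - lv["L1"]
    l3l1_raw <- lv["L3"] - lv["L1"]
    corr1 <- iseli_corrected_level(lv["L1"], f0, fmts, sig$rate)
    corr2 <- iseli_corrected_level(lv["L2"], 2 * f0, fmts, sig$rate)
    corr3 <- if (is.na(lv["L3"])) NA_real_ else {
      iseli_corrected_level(lv["L3"], 3 * f0, fmts, sig$rate)
    }
    sl6 <- spectral_poly_fit(sl, 6L)
    tibble::tibble(
      time_s = mtps$time_s[i], f0_hz = f0,
      intensity_db = as.numeric(intensity_db(fr)),
      ser_db = as.numeric(ser_db(sl)),
      l2l1_raw = unname(l2l1_raw), l3l1_raw = unname(l3l1_raw),
      l2l1_corr = unname(corr2 - corr1), l3l1_corr = unname(corr3 - corr1),
      c1 = as.numeric(mfcc_c1(fr, sig$rate)),
      slf = spectral_poly_fit(sl, 1L),
      slf6d1 = sl6[1], slf6d2 = sl6[2], slf6d3 = sl6[3],
      slf6d4 = sl6[4], slf6d5 = sl6[5], slf6d6 = sl6[6]
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-MTP measurement series with first differences
#'
#' Level quantities are defined at every MTP; change quantities (prefix
#' `d_`) for MTPs 2..n as the difference from the previous MTP.
#'
#' @param mtp_tbl Tibble of per-MTP measurements (one row per MTP, ordered
#'   in time; must have >= 2 rows).
#' @return The input with `d_<col>` columns appended (first row `NA`).
#' @export
mtp_series <- function(mtp_tbl) {
  if (nrow(mtp_tbl) < 2L) {
    rlang::abort("Need at least 2 MTPs for change series.", class = "prosodia_argument_error")
  }
  num <- names(mtp_tbl)[vapply(mtp_tbl, is.numeric, logical(1))]
  for (cn in num) {
    mtp_tbl[[paste0("d_", cn)]] <- c(NA_real_, diff(mtp_tbl[[cn]]))
  }
  mtp_tbl
}

# Utterance-level intensity series and long-term average spectrum.
.utterance_level <- function(sig, win_s = 0.030, hop_s = 0.010) {
  fr <- frame_signal(sig, max(win_s, 256 / sig$rate), hop_s)
  ints <- apply(fr$frames, 2, function(f) as.numeric(intensity_db(f)))
  voiced_like <- ints > -80
  n <- nrow(fr$frames)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  nfft <- 2^ceiling(log2(n))
  pw <- NULL
  for (j in which(voiced_like)) {
    X <- stats::fft(c(fr$frames[, j] * w, numeric(nfft - n)))
    half <- nfft %/% 2L
    p <- Mod(X[1:(half + 1L)])^2
    p[2:half] <- 2 * p[2:half]
    pw <- if (is.null(pw)) p else pw + p
  }
  ltas <- NULL
  if (!is.null(pw)) {
    pw <- pw / sum(voiced_like)
    half <- nfft %/% 2L
    ltas <- structure(
      list(
        freqs = (0:half) * sig$rate / nfft,
        log_mag = 10 * log10(pw + 1e-24),
        power = pw, nfft = nfft, rate = sig$rate,
        center_time_s = NA_real_, f0_hz = NA_real_, flagged = FALSE
      ),
      class = "spectral_slice"
    )
  }
  list(intensity_db = ints[voiced_like], ltas = ltas)
}

#' Assemble the 205-predictor feature vector for one utterance
#'
#' @param sig Utterance [audio_signal()] (already cropped to its span).
#' @param curve A [momel_curve()] for the utterance.
#' @param annotation An `intsint_annotation` for the curve.
#' @param mtp_win_s Analysis window around each MTP in seconds
#'   (default 0.030).
#' @return One-row tibble with `n_mtps` plus the 205 named predictors of
#'   [feature_names()].
#' @export
build_feature_vector <- function(sig, curve, annotation, mtp_win_s = 0.030) {
  mtps <- curve$mtps
  if (nrow(mtps) < 2L) {
    rlang::abort("Utterance has fewer than 2 MTPs; change features undefined.",
      class = "prosodia_too_short_error"
    )
  }
  meas <- .measure_mtps(sig, curve, mtp_win_s = mtp_win_s)
  ser_vals <- meas$ser_db
  ul <- .utterance_level(sig)
  dur <- signal_duration(sig)
  grid <- seq(min(mtps$time_s), max(mtps$time_s), by = 0.010)
  curve_f0 <- spline_eval(curve, grid)
  s6 <- function(v) unname(summarize6(v))
  s6_or_na <- function(v) {
    if (!any(is.finite(v))) rep(NA_real_, 6L) else unname(summarize6(v))
  }
  d <- function(v) diff(v)
  ltas_ser <- if (is.null(ul$ltas)) NA_real_ else as.numeric(ser_db(ul$ltas))
  dser <- d(ser_vals)
  out <- c(
    # time
    s6(meas$time_s), s6(d(meas$time_s)),
    dur, nrow(mtps) / dur, dur,
    # f0
    s6(meas$f0_hz), s6(d(meas$f0_hz)),
    annotation$key_hz, max(curve_f0) - min(curve_f0), min(curve_f0), max(curve_f0),
    # intensity
    s6(meas$intensity_db), s6(d(meas$intensity_db)),
    mean(ul$intensity_db), max(ul$intensity_db) - min(ul$intensity_db),
    min(ul$intensity_db), max(ul$intensity_db),
    # tilt
    s6(ser_vals), ltas_ser,
    s6(dser), sqrt(mean((dser - ltas_ser)^2)),
    s6_or_na(meas$l2l1_raw), s6_or_na(meas$l2l1_corr),
    s6_or_na(meas$l3l1_raw), s6_or_na(meas$l3l1_corr),
    s6_or_na(d(meas$l2l1_raw)), s6_or_na(d(meas$l2l1_corr)),
    s6_or_na(d(meas$l3l1_raw)), s6_or_na(d(meas$l3l1_corr)),
    s6(meas$c1), s6(d(meas$c1)),
    s6(meas$slf), s6(d(meas$slf)),
    unlist(lapply(1:6, function(k) s6(meas[[sprintf("slf6d%d", k)]]))),
    unlist(lapply(1:6, function(k) s6(d(meas[[sprintf("slf6d%d", k)]]))))
  )
  nm <- feature_names()
  stopifnot(length(out) == length(nm))
  names(out) <- nm
  dplyr::bind_cols(
    tibble::tibble(n_mtps = nrow(mtps)),
    tibble::as_tibble(as.list(out))
  )
}

#' Extract the full feature battery from a recording
#'
#' Runs the complete per-recording pipeline: utterance detection, two-pass
#' f0 tracking, Momel stylization, INTSINT annotation, per-MTP acoustics,
#' and feature assembly. Utterances that cannot be processed (unvoiced,
#' too short to stylize, fewer than 2 MTPs) are skipped and logged in the
#' `skipped` attribute with a reason code.
#'
#' @param sig An [audio_signal()].
#' @param detector Span detector; default [detect_utterances()]. Use
#'   [register_external_vad()] to plug an external one.
#' @param mtp_win_s Analysis window around each MTP (seconds).
#' @param ... Further arguments passed to [estimate_f0()].
#' @return Tibble: one row per utterance with `recording_id`,
#'   `utterance_id`, `start_s`, `end_s`, `n_mtps` and the 205 predictors.
#'   Attribute `skipped`: tibble of skipped spans and reasons.
#' @export
extract_features <- function(sig, detector = detect_utterances,
                             mtp_win_s = 0.030, ...) {
  spans <- detector(sig)
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(spans))) {
    utt <- crop_signal(sig, spans$start_s[i], spans$end_s[i])
    res <- tryCatch(
      {
        track <- estimate_f0(utt, ...)
        curve <- momel_targets(track)
        ann <- intsint_annotate(curve)
        fv <- build_feature_vector(utt, curve, ann, mtp_win_s = mtp_win_s)
        dplyr::bind_cols(
          tibble::tibble(
            recording_id = sig$id,
            utterance_id = sprintf("%s_u%02d", sig$id, i),
            start_s = spans$start_s[i], end_s = spans$end_s[i]
          ),
          fv
        )
      },
      prosodia_unvoiced_error = function(e) structure("unvoiced", class = "skip"),
      prosodia_too_short_error = function(e) structure("too_short", class = "skip"),
      prosodia_argument_error = function(e) structure("degenerate", class = "skip")
    )
    if (inherits(res, "skip")) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        recording_id = sig$id, span = i,
        start_s = spans$start_s[i], end_s = spans$end_s[i],
        reason = unclass(res)
      )
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else NULL
  out
}

#' Extract features for every signal in a synthetic corpus
#'
#' @param corpus Result of [synth_corpus()].
#' @param ... Passed to [extract_features()].
#' @return Tibble of per-utterance features joined with `speaker_id` and
#'   `severity` from the corpus manifest.
#' @export
extract_corpus_features <- function(corpus, ...) {
  feats <- purrr::map(corpus$signals, function(s) extract_features(s, ...))
  feats <- dplyr::bind_rows(feats)
  feats$utterance_id <- NULL
  dplyr::inner_join(
    dplyr::select(
      corpus$manifest, recording_id = "utterance_id", "speaker_id",
      "severity", "planted_step_sd_st", "empirical_step_sd_st"
    ),
    feats,
    by = "recording_id"
  )
}
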