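# Run code with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Frequency-domain spectral tilt: gain slope_db_per_oct relative to 500 Hz.
.apply_tilt <- function(x, rate, slope_db_per_oct) {
  if (length(x) < 8L || slope_db_per_oct == 0) return(x)
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * rate / n
  fa <- pmax(abs(f), 50)
  gain <- 10^((slope_db_per_oct * log2(fa / 500)) / 20)
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

# Second-order resonator cascade (source-filter vowel coloring).
.apply_formants <- function(x, rate, formants) {
  for (fm in formants) {
    r <- exp(-pi * fm[[2]] / rate)
    th <- 2 * pi * fm[[1]] / rate
    x <- as.numeric(stats::filter(x * (1 - r), c(2 * r * cos(th), -r^2),
      method = "recursive"))
  }
  x
}

#' Specification of one synthetic utterance
#'
#' @param planted_targets Data frame with `time_s`, `f0_hz`: the
#'   ground-truth intonation anchors (time-ordered; f0 in \[60, 500\] Hz).
#' @param tilt_db_per_oct Source spectral slope in dB/octave. A scalar, or
#'   one value per planted target for within-utterance tilt dynamics
#'   (applied per inter-target segment with short crossfades).
#' @param formants List of `c(F, B)` resonator pairs (Hz); default a
#'   neutral-vowel cascade at 500/1500/2500 Hz.
#' @param intensity_env Data frame with `time_s`, `db`: piecewise-linear
#'   intensity contour in dB (0 dB = envelope peak). `NULL` for flat.
#' @param pauses List of `c(start_s, dur_s)` silent spans.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed for any stochastic component.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(planted_targets, tilt_db_per_oct = -12,
                       formants = list(c(500, 80), c(1500, 120), c(2500, 180)),
                       intensity_env = NULL, pauses = list(),
                       rate = 16000, seed = 1L) {
  planted_targets <- tibble::as_tibble(planted_targets)
  stopifnot(all(diff(planted_targets$time_s) > 0))
  if (any(planted_targets$f0_hz < 60 | planted_targets$f0_hz > 500)) {
    rlang::abort("Planted f0 targets must lie in [60, 500] Hz.",
      class = "prosodia_argument_error"
    )
  }
  structure(
    list(
      planted_targets = planted_targets, tilt_db_per_oct = tilt_db_per_oct,
      formants = formants, intensity_env = intensity_env, pauses = pauses,
      rate = rate, seed = seed
    ),
    class = "synth_spec"
  )
}

#' Synthesize one utterance from a specification
#'
#' A sawtooth glottal source follows the quadratic-spline interpolation of
#' the planted (time, f0) targets; spectral tilt shaping and a resonator
#' cascade color the source; the intensity envelope and silent pauses are
#' applied; 0.1 s of silence precedes the first and follows the last target.
#'
#' @param spec A [synth_spec()].
#' @return List with `signal` (an [audio_signal()]) and `truth` (the spec's
#'   planted parameters, for validity checks without audio).
#' @export
synth_utterance <- function(spec) {
  rate <- spec$rate
  tg <- spec$planted_targets
  if (any(tg$f0_hz > rate / 4)) {
    rlang::abort("Planted f0 above rate/4.", class = "prosodia_argument_error")
  }
  t0 <- max(0, tg$time_s[1] - 0.1)
  t1 <- tg$time_s[nrow(tg)] + 0.1
  n <- as.integer(round((t1 + 0.3) * rate))
  tt <- (seq_len(n) - 1L) / rate
  f0_fun <- if (nrow(tg) >= 2L) {
    .quad_spline_fun(tg$time_s, tg$f0_hz)
  } else {
    function(x) rep(tg$f0_hz[1], length(x))
  }
  f0 <- f0_fun(pmin(pmax(tt, tg$time_s[1]), tg$time_s[nrow(tg)]))
  f0 <- pmax(f0, 40) # spline excursions cannot drop below a sane floor
  phase <- cumsum(2 * pi * f0 / rate)
  src <- 2 * ((phase / (2 * pi)) %% 1) - 1
  voiced <- tt >= t0 & tt <= t1
  # 10 ms raised-cosine onset/offset to avoid clicks
  ramp_n <- as.integer(0.010 * rate)
  env_v <- as.numeric(voiced)
  on_i <- which(voiced)[1]
  off_i <- which(voiced)[sum(voiced)]
  if (!is.na(on_i) && on_i + ramp_n <= n) {
    env_v[on_i:(on_i + ramp_n - 1L)] <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
  }
  if (!is.na(off_i) && off_i - ramp_n >= 1) {
    env_v[(off_i - ramp_n + 1L):off_i] <- rev((1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2)
  }
  src <- src * env_v
  # tilt shaping: sawtooth harmonics fall at -6 dB/oct already
  tilt <- spec$tilt_db_per_oct
  extra <- tilt + 6
  if (length(tilt) == 1L) {
    x <- .apply_tilt(src, rate, extra)
  } else {
    # per-target segments split at inter-target midpoints, 10 ms crossfade
    bounds <- c(0, (tg$time_s[-nrow(tg)] + tg$time_s[-1]) / 2, t1 + 0.1)
    x <- numeric(n)
    wsum <- numeric(n)
    fade <- 0.010
    for (i in seq_len(nrow(tg))) {
      lo <- max(0, bounds[i] - fade)
      hi <- min(t1 + 0.1, bounds[i + 1] + fade)
      sel <- which(tt >= lo & tt < hi)
      if (length(sel) < 8L) next
      seg <- .apply_tilt(src[sel], rate, extra[i])
      w <- rep(1, length(sel))
      nf <- as.integer(fade * rate)
      if (nf > 1 && length(sel) > 2 * nf) {
        w[seq_len(nf)] <- seq(0, 1, length.out = nf)
        w[(length(sel) - nf + 1L):length(sel)] <- seq(1, 0, length.out = nf)
      }
      x[sel] <- x[sel] + seg * w
      wsum[sel] <- wsum[sel] + w
    }
    x <- ifelse(wsum > 0, x / pmax(wsum, 1e-9), 0)
  }
  x <- .apply_formants(x, rate, spec$formants)
  x[!voiced] <- 0
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak * 0.5
  # intensity envelope: absolute gain in dB (0 dB = the normalized peak)
  if (!is.null(spec$intensity_env)) {
    env <- spec$intensity_env
    db <- stats::approx(env$time_s, env$db, xout = tt, rule = 2)$y
    x <- x * 10^(db / 20)
  }
  for (p in spec$pauses) {
    x[tt >= p[[1]] & tt < p[[1]] + p[[2]]] <- 0
  }
  list(
    signal = audio_signal(x, rate, id = sprintf("synth_%d", spec$seed)),
    truth = list(
      planted_targets = tg, tilt_db_per_oct = tilt,
      intensity_env = spec$intensity_env, pauses = spec$pauses,
      voiced_span = c(t0, t1)
    )
  )
}

#' Specification of a synthetic labelled corpus
#'
#' Severity effects mirror the structure dysprosody imposes on read speech:
#' higher severity multiplies down (i) the standard deviation of f0 steps
#' between successive intonation targets, (ii) the within-utterance dynamic
#' range of spectral tilt (hence C1 dynamics), and (iii) the intensity
#' range. Labels are assigned at the speaker level: all of one speaker's
#' utterances share a severity, as clinical ratings are per recording.
#'
#' @param n_speakers Number of speakers.
#' @param utterances_per_speaker Utterances synthesized per speaker.
#' @param proportions Severity class proportions over codes 0, 1, 2
#'   (must sum to 1).
#' @param df0_sd_mult,c1_dyn_mult,int_range_mult Per-severity multipliers
#'   (length 3, in (0, 1]) on the f0 step SD, tilt dynamic range, and
#'   intensity range.
#' @param base_step_sd_st Baseline SD of inter-target f0 steps in semitones
#'   (severity 0).
#' @param base_tilt_dyn Baseline SD of per-target tilt excursions in
#'   dB/octave.
#' @param base_int_range_db Baseline intensity range in dB.
#' @param speaker_jitter_sd Log-normal SD of the per-speaker jitter on the
#'   baseline parameters (default 0.10; 0 disables inter-speaker
#'   variation).
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_speakers = 20L, utterances_per_speaker = 5L,
                        proportions = c(1 / 3, 1 / 3, 1 / 3),
                        df0_sd_mult = c(1, 0.45, 0.18),
                        c1_dyn_mult = c(1, 0.50, 0.20),
                        int_range_mult = c(1, 0.50, 0.25),
                        base_step_sd_st = 2.5, base_tilt_dyn = 4,
                        base_int_range_db = 18, speaker_jitter_sd = 0.10,
                        rate = 16000, seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    rlang::abort("`proportions` must sum to 1.", class = "prosodia_argument_error")
  }
  for (m in list(df0_sd_mult, c1_dyn_mult, int_range_mult)) {
    if (length(m) != 3L || any(m <= 0 | m > 1)) {
      rlang::abort("Effect multipliers must be length 3 in (0, 1].",
        class = "prosodia_argument_error"
      )
    }
  }
  structure(
    list(
      n_speakers = as.integer(n_speakers),
      utterances_per_speaker = as.integer(utterances_per_speaker),
      proportions = proportions,
      df0_sd_mult = df0_sd_mult, c1_dyn_mult = c1_dyn_mult,
      int_range_mult = int_range_mult,
      base_step_sd_st = base_step_sd_st, base_tilt_dyn = base_tilt_dyn,
      base_int_range_db = base_int_range_db,
      speaker_jitter_sd = speaker_jitter_sd,
      rate = rate, seed = as.integer(seed)
    ),
    class = "corpus_spec"
  )
}

#' Generate a deterministic synthetic labelled corpus
#'
#' Per speaker, a base key is drawn uniformly from \[100, 220\] Hz and all
#' of that speaker's draws come from a speaker-specific seeded generator.
#' Per utterance, 4-9 intonation targets are planted on a stationary AR(1)
#' walk in log-f0 around the key whose inter-target steps are
#' `Normal(0, base_sd * effect(severity))` on the semitone scale; the
#' walk's stationary spread is the same for every severity, so
#' utterance-wide f0 variability is uninformative by construction while
#' the local change dynamics carry the class signal. Per-target tilt
#' excursions and the intensity range are scaled by their severity
#' multipliers.
#'
#' @param spec A [corpus_spec()].
#' @param dir Optional directory: when given, WAV files and
#'   `manifest.csv` are written there.
#' @return List with `signals` (list of [audio_signal()]), `manifest`
#'   (tibble: utterance_id, speaker_id, severity, planted parameters as a
#'   JSON column, plus the planted step SD).
#' @export
synth_corpus <- function(spec, dir = NULL) {
  n_spk <- spec$n_speakers
  counts <- floor(spec$proportions * n_spk)
  while (sum(counts) < n_spk) counts[which.max(spec$proportions * n_spk - counts)] <-
    counts[which.max(spec$proportions * n_spk - counts)] + 1
  severities <- rep(0:2, times = counts)[seq_len(n_spk)]
  signals <- list()
  rows <- list()
  for (s in seq_len(n_spk)) {
    spk_seed <- (spec$seed * 7919 + s * 104729) %% 2147483647
    sev <- severities[s]
    spk <- .with_seed(spk_seed, {
      key <- stats::runif(1, 100, 220)
      jit <- spec$speaker_jitter_sd
      step_mult <- spec$df0_sd_mult[sev + 1]
      # AR(1) with stationary SD sd_z and step SD = base_step_sd * mult:
      # step SD = sd_z * sqrt(2 * (1 - phi)) with phi = 1 - mult^2.
      sd_z <- spec$base_step_sd_st / sqrt(2) * exp(stats::rnorm(1, 0, jit))
      phi <- 1 - step_mult^2
      step_sd <- sd_z * sqrt(2) * step_mult
      tilt_dyn <- spec$base_tilt_dyn * spec$c1_dyn_mult[sev + 1] *
        exp(stats::rnorm(1, 0, jit))
      int_range <- spec$base_int_range_db * spec$int_range_mult[sev + 1] *
        exp(stats::rnorm(1, 0, jit))
      utts <- lapply(seq_len(spec$utterances_per_speaker), function(u) {
        n_tg <- sample(4:9, 1)
        gaps <- stats::runif(n_tg - 1, 0.30, 0.50)
        times <- 0.45 + c(0, cumsum(gaps))
        # log-f0 targets follow a stationary AR(1) walk around the speaker
        # key. Severity changes the step-to-step f0-change variability via
        # the autocorrelation phi while the stationary (utterance-wide)
        # spread stays fixed, so overall pitch variability carries no class
        # signal -- only the local change dynamics do.
        z <- numeric(n_tg)
        z[1] <- stats::rnorm(1, 0, sd_z)
        for (i in 2:n_tg) {
          z[i] <- phi * z[i - 1] + stats::rnorm(1, 0, sd_z * sqrt(1 - phi^2))
        }
        f0 <- pmin(pmax(key * 2^(z / 12), 65), 460)
        steps_st <- 12 * diff(log2(f0))
        tilts <- -12 + stats::rnorm(n_tg, 0, tilt_dyn)
        env_db <- -stats::runif(n_tg, 0, int_range)
        env_db[which.max(env_db)] <- 0 # anchor the peak
        list(
          targets = tibble::tibble(time_s = times, f0_hz = f0),
          tilts = tilts,
          env = tibble::tibble(time_s = times, db = env_db),
          steps_st = steps_st, key = key,
          step_sd = step_sd, tilt_dyn = tilt_dyn, int_range = int_range
        )
      })
      utts
    })
    for (u in seq_along(spk)) {
      gu <- spk[[u]]
      sp <- synth_spec(gu$targets,
        tilt_db_per_oct = gu$tilts,
        intensity_env = gu$env, rate = spec$rate,
        seed = spk_seed + u
      )
      syn <- synth_utterance(sp)
      uid <- sprintf("spk%02d_utt%02d", s, u)
      syn$signal$id <- uid
      signals[[uid]] <- syn$signal
      rows[[uid]] <- tibble::tibble(
        utterance_id = uid,
        speaker_id = sprintf("spk%02d", s),
        severity = sev,
        planted_step_sd_st = gu$step_sd,
        planted_tilt_dyn = gu$tilt_dyn,
        planted_int_range_db = gu$int_range,
        empirical_step_sd_st = stats::sd(gu$steps_st),
        planted_json = as.character(jsonlite::toJSON(
          list(
            targets = gu$targets, tilts = gu$tilts, env = gu$env,
            steps_st = gu$steps_st, key = gu$key
          ),
          digits = NA, auto_unbox = TRUE
        ))
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest$path <- file.path(dir, paste0(manifest$utterance_id, ".wav"))
    purrr::walk2(signals, manifest$path, write_wav)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(signals = signals, manifest = manifest)
}
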