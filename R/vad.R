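#' Detect utterance-like vocal activity spans
#'
#' Built-in energy detector: frame RMS (25 ms window, 10 ms hop) in dB re
#' full scale; the detection threshold is
#' `max(noise_floor + margin_db, floor_db)` where the noise floor is the
#' 10th percentile of frame dB. Above-threshold frames are merged when the
#' gap between runs is shorter than `max_gap_s`; spans shorter than
#' `min_dur_s` are dropped; `pad_s` is added to both ends and clipped to
#' the signal bounds.
#'
#' An external (e.g. neural overlap-aware) detector registered with
#' [register_external_vad()] can be passed as `detector` to any pipeline
#' entry point; its spans are used verbatim after validation.
#'
#' @param sig An [audio_signal()] of at least 0.1 s.
#' @param margin_db Margin above the noise floor in dB (default 12).
#' @param max_gap_s Gaps shorter than this are bridged (default 0.3 s).
#' @param min_dur_s Minimum span duration kept (default 0.25 s).
#' @param pad_s Padding added to both span ends (default 0.05 s).
#' @param floor_db Absolute detection floor in dB re full scale
#'   (default -55).
#' @param win_s,hop_s RMS analysis window and hop (defaults 25 ms, 10 ms).
#' @return Tibble with columns `start_s`, `end_s`, `recording_id`; zero
#'   rows for all-silent input.
#' @export
detect_utterances <- function(sig, margin_db = 12, max_gap_s = 0.3,
                              min_dur_s = 0.25, pad_s = 0.05,
                              floor_db = -55, win_s = 0.025, hop_s = 0.010) {
  if (signal_duration(sig) < 0.1) {
    rlang::abort("Signal must be at least 0.1 s long.", class = "prosodia_argument_error")
  }
  fr <- frame_signal(sig, win_s, hop_s)
  ms <- colMeans(fr$frames^2)
  db <- ifelse(ms > 0, 10 * log10(ms), -120)
  noise <- as.numeric(stats::quantile(db, 0.10, type = 7, names = FALSE))
  thr <- max(noise + margin_db, floor_db)
  active <- db > thr
  if (!any(active)) {
    return(tibble::tibble(
      start_s = numeric(0), end_s = numeric(0),
      recording_id = character(0)
    ))
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(
    start_s = fr$centers_s[starts[r$values]],
    end_s = fr$centers_s[ends[r$values]]
  )
  # bridge short gaps
  merged <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start_s[i] - merged$end_s[nrow(merged)] < max_gap_s) {
        merged$end_s[nrow(merged)] <- runs$end_s[i]
      } else {
        merged <- dplyr::bind_rows(merged, runs[i, ])
      }
    }
  }
  merged <- dplyr::filter(merged, .data$end_s - .data$start_s >= min_dur_s)
  if (nrow(merged) == 0) {
    return(tibble::tibble(
      start_s = numeric(0), end_s = numeric(0),
      recording_id = character(0)
    ))
  }
  dur <- signal_duration(sig)
  merged$start_s <- pmax(0, merged$start_s - pad_s)
  merged$end_s <- pmin(dur, merged$end_s + pad_s)
  merged$recording_id <- sig$id
  merged
}

#' Register an external voice-activity detector
#'
#' Wraps a user-supplied callable (e.g. a neural overlap-aware detector
#' run out of process) so the pipeline can consume its spans. The callable
#' receives an [audio_signal()] and must return ordered, non-overlapping
#' `(start_s, end_s)` pairs (a two-column matrix or data frame).
#'
#' @param fun Callable `audio_signal -> spans`.
#' @return A detector function with the same contract as
#'   [detect_utterances()]: `audio_signal -> tibble(start_s, end_s,
#'   recording_id)`. Spans are validated; overlapping or reversed spans
#'   raise a validation error, an empty result yields zero utterances with
#'   a warning.
#' @export
register_external_vad <- function(fun) {
  if (!is.function(fun)) {
    rlang::abort("`fun` must be a function.", class = "prosodia_argument_error")
  }
  function(sig, ...) {
    out <- fun(sig)
    m <- as.data.frame(out)
    if (nrow(m) == 0) {
      rlang::warn("External VAD returned no spans; zero utterances emitted.")
      return(tibble::tibble(
        start_s = numeric(0), end_s = numeric(0),
        recording_id = character(0)
      ))
    }
    names(m)[1:2] <- c("start_s", "end_s")
    if (any(m$end_s <= m$start_s)) {
      rlang::abort("External VAD produced reversed or empty spans.",
        class = "prosodia_validation_error"
      )
    }
    if (is.unsorted(m$start_s) ||
      (nrow(m) > 1 && any(m$start_s[-1] < m$end_s[-nrow(m)]))) {
      rlang::abort("External VAD produced unordered or overlapping spans.",
        class = "prosodia_validation_error"
      )
    }
    dur <- signal_duration(sig)
    if (any(m$start_s < 0) || any(m$end_s > dur + 1e-9)) {
      rlang::abort("External VAD spans fall outside the recording.",
        class = "prosodia_validation_error"
      )
    }
    tibble::tibble(
      start_s = m$start_s, end_s = pmin(m$end_s, dur),
      recording_id = sig$id
    )
  }
}

#' Extract the audio of one utterance span
#'
#' @param sig An [audio_signal()].
#' @param start_s,end_s Span bounds in seconds.
#' @return An [audio_signal()] holding the span samples.
#' @export
crop_signal <- function(sig, start_s, end_s) {
  i0 <- max(1L, as.integer(round(start_s * sig$rate)) + 1L)
  i1 <- min(length(sig$samples), as.integer(round(end_s * sig$rate)))
  audio_signal(sig$samples[i0:i1], sig$rate,
    id = sprintf("%s[%.2f-%.2f]", sig$id, start_s, end_s)
  )
}

#' Write utterance spans to CSV
#'
#' @param spans Tibble from [detect_utterances()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spans_csv <- function(spans, path) {
  utils::write.csv(
    spans[, c("recording_id", "start_s", "end_s")], path,
    row.names = FALSE
  )
  invisible(path)
}
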