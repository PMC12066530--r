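# Shared fixtures, all generated in code.

# A pitch-track tibble from explicit times/f0 (NA = unvoiced).
make_track <- function(time_s, f0_hz) {
  tr <- tibble::tibble(time_s = time_s, f0_hz = f0_hz)
  class(tr) <- c("pitch_track", class(tr))
  tr
}

# Band-limited sawtooth at a fixed f0 (voiced-vowel stand-in).
make_sawtooth <- function(f0, dur, rate = 16000, amp = 0.5, n_harm = 20) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- numeric(length(t))
  for (k in seq_len(min(n_harm, floor(rate / 2 / f0) - 1))) {
    x <- x + sin(2 * pi * k * f0 * t) / k
  }
  x / max(abs(x)) * amp
}

# Sine burst embedded in silence, for VAD boundary fixtures.
make_burst_signal <- function(bursts, total_dur, rate = 16000, f0 = 200, amp = 0.5) {
  n <- round(total_dur * rate)
  x <- numeric(n)
  t <- (seq_len(n) - 1) / rate
  for (b in bursts) {
    sel <- t >= b[1] & t < b[2]
    x[sel] <- amp * sin(2 * pi * f0 * t[sel])
  }
  audio_signal(x, rate, id = "burst_fixture")
}

# The seeded study corpus and its extracted features are expensive
# (~40 s); compute once per test session and share.
.fixture_env <- new.env(parent = emptyenv())

get_study_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- synth_corpus(corpus_spec(seed = 1))
  }
  .fixture_env$corpus
}

get_study_features <- function() {
  if (is.null(.fixture_env$features)) {
    .fixture_env$features <- extract_corpus_features(get_study_corpus())
  }
  .fixture_env$features
}

# Small gaussian-blob tabular fixture for the model-layer tests: three
# ordered classes separated along a few informative dimensions.
make_blob_data <- function(n_per_class = 30, p_noise = 5, sep = 2.5, seed = 7) {
  withr::with_seed(seed, {
    y <- rep(0:2, each = n_per_class)
    n <- length(y)
    X <- cbind(
      sep * y + stats::rnorm(n),
      -sep * y + stats::rnorm(n),
      matrix(stats::rnorm(n * p_noise), n)
    )
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    list(X = tibble::as_tibble(as.data.frame(X)), y = y)
  })
}
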