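# Quadratic interpolating spline with knots at midpoints between anchors.
# Slopes at anchors follow the parabola through each anchor triple (Bessel);
# with two anchors the construction collapses to the connecting line. On each
# inter-anchor interval two quadratic pieces meet C1 at the midpoint knot.
.quad_spline_slopes <- function(t, y) {
  n <- length(t)
  if (n == 2L) {
    s <- (y[2] - y[1]) / (t[2] - t[1])
    return(c(s, s))
  }
  d <- numeric(n)
  h <- diff(t)
  sec <- diff(y) / h
  for (i in 2:(n - 1)) {
    d[i] <- (sec[i] * h[i - 1] + sec[i - 1] * h[i]) / (h[i - 1] + h[i])
  }
  # end slopes from the parabola through the first/last three anchors
  d[1] <- 2 * sec[1] - d[2]
  d[n] <- 2 * sec[n - 1] - d[n - 1]
  d
}

.quad_spline_fun <- function(t, y) {
  n <- length(t)
  stopifnot(n >= 2L, all(diff(t) > 0))
  d <- .quad_spline_slopes(t, y)
  h <- diff(t)
  dy <- diff(y)
  # q_a(s) = y_i + d_i s + A s^2 on [t_i, m]; q_b(s) = y_{i+1} + d_{i+1} s + B s^2
  # on [m, t_{i+1}] with s measured from t_i resp. t_{i+1}.
  apb <- (d[-1] - d[-n]) / h
  amb <- 4 * (dy - (d[-n] + d[-1]) * h / 2) / h^2
  A <- (apb + amb) / 2
  B <- (apb - amb) / 2
  force(t); force(y); force(d)
  function(tt) {
    iv <- findInterval(tt, t, all.inside = TRUE)
    mid <- (t[iv] + t[iv + 1L]) / 2
    lower <- tt <= mid
    out <- numeric(length(tt))
    s1 <- tt - t[iv]
    s2 <- tt - t[iv + 1L]
    out[lower] <- y[iv[lower]] + d[iv[lower]] * s1[lower] + A[iv[lower]] * s1[lower]^2
    out[!lower] <- y[iv[!lower] + 1L] + d[iv[!lower] + 1L] * s2[!lower] +
      B[iv[!lower]] * s2[!lower]^2
    out
  }
}

#' Construct a Momel curve from target points
#'
#' A `momel_curve` is the macro-prosodic stylization: an ordered set of
#' (time, f0) target points (MTPs) joined by a C1 piecewise-quadratic spline
#' with knots at the midpoints between consecutive MTPs. The spline passes
#' exactly through every MTP.
#'
#' @param mtps Data frame with columns `time_s`, `f0_hz` (strictly
#'   increasing times, positive frequencies).
#' @return A `momel_curve` with fields `mtps` (tibble) and `evaluator`
#'   (function time -> f0 Hz).
#' @export
momel_curve <- function(mtps) {
  mtps <- tibble::as_tibble(mtps)[, c("time_s", "f0_hz")]
  if (nrow(mtps) < 2L) {
    rlang::abort("A Momel curve needs at least 2 target points.", class = "prosodia_argument_error")
  }
  if (any(diff(mtps$time_s) <= 0) || any(mtps$f0_hz <= 0)) {
    rlang::abort("MTP times must be strictly increasing and f0 positive.",
      class = "prosodia_argument_error"
    )
  }
  ev <- .quad_spline_fun(mtps$time_s, mtps$f0_hz)
  structure(list(mtps = mtps, evaluator = ev), class = "momel_curve")
}

#' @export
print.momel_curve <- function(x, ...) {
  cat(sprintf(
    "<momel_curve: %d MTPs on [%.3f, %.3f] s, f0 %.1f-%.1f Hz>\n",
    nrow(x$mtps), min(x$mtps$time_s), max(x$mtps$time_s),
    min(x$mtps$f0_hz), max(x$mtps$f0_hz)
  ))
  invisible(x)
}

#' Evaluate a Momel curve at given times
#'
#' @param curve A [momel_curve()].
#' @param t Times in seconds, inside the curve domain
#'   (first to last MTP time).
#' @return f0 values in Hz.
#' @export
spline_eval <- function(curve, t) {
  dom <- range(curve$mtps$time_s)
  if (any(t < dom[1] - 1e-9 | t > dom[2] + 1e-9)) {
    rlang::abort("Evaluation time outside the curve domain.", class = "prosodia_domain_error")
  }
  curve$evaluator(pmin(pmax(t, dom[1]), dom[2]))
}

#' Reduce a pitch track to Momel target points
#'
#' Candidate targets are obtained by local quadratic regression of the
#' voiced f0 values in a sliding window; frames deviating more than
#' `outlier_frac` from the local fit are excluded and the fit repeated once.
#' Candidates are then partitioned over non-overlapping reduction windows
#' and averaged into the final MTPs.
#'
#' @param track A `pitch_track` (see [estimate_f0()]).
#' @param win_s Local regression window in seconds (default 0.3).
#' @param outlier_frac Relative deviation beyond which a frame is excluded
#'   from the refit (default 0.05).
#' @param reduce_s Reduction (candidate averaging) window in seconds
#'   (default 0.2).
#' @return A [momel_curve()].
#' @export
momel_targets <- function(track, win_s = 0.3, outlier_frac = 0.05, reduce_s = 0.2) {
  voiced <- !is.na(track$f0_hz)
  if (sum(voiced) < 3L) {
    rlang::abort("Too short to stylize: fewer than 3 voiced frames.",
      class = "prosodia_too_short_error"
    )
  }
  tv <- track$time_s[voiced]
  fv <- track$f0_hz[voiced]
  half <- win_s / 2
  # local quadratic fit around tc; candidate target = the parabola vertex
  # when it falls near the window (tonal turning points attract vertices),
  # otherwise the fitted value at the window center.
  fit_local <- function(tc) {
    sel <- which(tv >= tc - half & tv <= tc + half)
    if (length(sel) < 3L) return(c(NA_real_, NA_real_))
    tt <- tv[sel] - tc
    yy <- fv[sel]
    co <- .polyfit_safe(tt, yy, 2L)
    pred <- co[1] + co[2] * tt + co[3] * tt^2
    keep <- abs(yy - pred) / pmax(pred, 1e-9) <= outlier_frac
    if (sum(keep) >= 3L && any(!keep)) {
      co <- .polyfit_safe(tt[keep], yy[keep], 2L)
    }
    if (abs(co[3]) > 1e-6) {
      sv <- -co[2] / (2 * co[3])
      if (abs(sv) <= half) {
        return(c(tc + sv, co[1] + co[2] * sv + co[3] * sv^2, 1))
      }
    }
    c(tc, co[1], 0)
  }
  grid_t <- track$time_s[track$time_s >= min(tv) & track$time_s <= max(tv)]
  cand <- vapply(grid_t, fit_local, numeric(3))
  ok <- is.finite(cand[2, ]) & cand[2, ] > 0 & is.finite(cand[1, ])
  cand_t <- cand[1, ok]
  cand_f <- cand[2, ok]
  cand_v <- cand[3, ok] > 0
  if (length(cand_t) < 2L) {
    rlang::abort("Too short to stylize: no stable local fits.", class = "prosodia_too_short_error")
  }
  o <- order(cand_t)
  cand_t <- cand_t[o]
  cand_f <- cand_f[o]
  cand_v <- cand_v[o]
  bin <- floor((cand_t - min(cand_t)) / reduce_s + 1e-9)
  # vertex candidates concentrate on tonal turning points; when a bin holds
  # enough of them they define its target, otherwise all candidates do
  agg <- function(val) {
    vapply(split(seq_along(bin), bin), function(ix) {
      vx <- ix[cand_v[ix]]
      use <- if (length(vx) >= 3L) vx else ix
      mean(val[use])
    }, numeric(1))
  }
  mt <- as.numeric(agg(cand_t))
  mf <- as.numeric(agg(cand_f))
  # keep dedicated boundary targets: the first/last local fits at the track ends
  first_c <- fit_local(min(tv))
  last_c <- fit_local(max(tv))
  mt <- c(min(tv), mt, max(tv))
  mf <- c(first_c[2], mf, last_c[2])
  # merge targets closer than a quarter reduction window
  keep_t <- mt[1]
  keep_f <- mf[1]
  for (i in seq_along(mt)[-1]) {
    j <- length(keep_t)
    if (mt[i] - keep_t[j] < reduce_s / 4) {
      keep_t[j] <- (keep_t[j] + mt[i]) / 2
      keep_f[j] <- (keep_f[j] + mf[i]) / 2
    } else {
      keep_t <- c(keep_t, mt[i])
      keep_f <- c(keep_f, mf[i])
    }
  }
  if (length(keep_t) < 2L) {
    keep_t <- c(min(tv), max(tv))
    keep_f <- c(first_c[2], last_c[2])
  }
  momel_curve(tibble::tibble(time_s = keep_t, f0_hz = keep_f))
}

# Least-squares polynomial fit that falls back to lower degree when the
# design is singular (e.g. coincident times).
.polyfit_safe <- function(x, y, degree) {
  for (dg in seq(degree, 0)) {
    X <- outer(x, 0:dg, `^`)
    co <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (!is.null(co) && all(is.finite(co))) {
      return(c(co, numeric(degree + 1L - length(co))))
    }
  }
  c(mean(y), numeric(degree))
}

.intsint_labels <- c("T", "H", "U", "S", "M", "D", "L", "B")

#' Predict the f0 of an INTSINT-labelled target point
#'
#' Absolute labels are defined on the speaker's key/span model:
#' `T = key * 2^(span/2)`, `M = key`, `B = key * 2^(-span/2)`. Relative
#' labels depend on the preceding target's f0: `S` repeats it, `H`/`L` sit
#' at the log-scaled midpoint between it and the T/B level, and `U`/`D` a
#' quarter of the log-scaled distance toward T/B.
#'
#' @param label One of `"T","H","U","S","M","D","L","B"`.
#' @param prev_f0 f0 of the preceding target point in Hz (required for
#'   relative labels `H,U,S,D,L`; ignored for `T,M,B`).
#' @param key Speaker key in Hz.
#' @param span Speaker span in octaves.
#' @return Predicted f0 in Hz.
#' @export
intsint_predict <- function(label, prev_f0 = NULL, key, span) {
  if (!label %in% .intsint_labels) {
    rlang::abort(sprintf("Unknown INTSINT label '%s'.", label), class = "prosodia_argument_error")
  }
  top <- key * 2^(span / 2)
  bot <- key * 2^(-span / 2)
  if (label %in% c("T", "M", "B")) {
    return(switch(label, T = top, M = key, B = bot))
  }
  if (is.null(prev_f0) || !is.finite(prev_f0) || prev_f0 <= 0) {
    rlang::abort(sprintf("Relative label '%s' requires a positive prev_f0.", label),
      class = "prosodia_argument_error"
    )
  }
  lp <- log(prev_f0)
  switch(label,
    S = prev_f0,
    H = exp((lp + log(top)) / 2),
    L = exp((lp + log(bot)) / 2),
    U = exp(lp + (log(top) - lp) / 4),
    D = exp(lp + (log(bot) - lp) / 4)
  )
}

# All 8 label predictions at once (prev may be NA -> relative labels NA).
.intsint_predict_all <- function(prev, top, key, bot) {
  lp <- log(prev)
  c(
    T = top,
    H = exp((lp + log(top)) / 2),
    U = exp(lp + (log(top) - lp) / 4),
    S = prev,
    M = key,
    D = exp(lp + (log(bot) - lp) / 4),
    L = exp((lp + log(bot)) / 2),
    B = bot
  )
}

#' INTSINT annotation of a Momel curve by key/span optimization
#'
#' Performs a grid search over the speaker key (plus/minus half an octave
#' around the mean MTP f0, `key_steps` steps) and span (0.5-2.5 octaves in
#' `span_step` steps). For each (key, span), labels are assigned left to
#' right greedily -- the first MTP restricted to the absolute labels
#' `{M, T, B}`, later MTPs free over all 8 -- choosing the label whose
#' predicted f0 is closest to the observed MTP f0 on the log-frequency
#' scale. The (key, span) pair minimizing the summed squared log-frequency
#' error is returned.
#'
#' @param curve A [momel_curve()] (or a data frame of MTPs with `time_s`,
#'   `f0_hz`).
#' @param key_steps Number of key grid steps (default 50).
#' @param key_range_oct Half-width of the key grid in octaves (default 0.5).
#' @param span_min,span_max,span_step Span grid in octaves
#'   (defaults 0.5, 2.5, 0.05).
#' @return An `intsint_annotation`: list with `key_hz`, `span_oct`,
#'   `labels`, `predicted_f0`, `objective`, and the `mtps` tibble.
#' @export
intsint_annotate <- function(curve, key_steps = 50L, key_range_oct = 0.5,
                             span_min = 0.5, span_max = 2.5, span_step = 0.05) {
  mtps <- if (inherits(curve, "momel_curve")) curve$mtps else tibble::as_tibble(curve)
  n <- nrow(mtps)
  if (n < 2L) {
    rlang::abort("INTSINT annotation needs at least 2 MTPs.", class = "prosodia_argument_error")
  }
  obs <- log(mtps$f0_hz)
  # stepwise search originating from the mean f0: the grid covers +/- half
  # an octave in key_steps steps and is traversed outward from the center,
  # with strict-improvement updates, so ties resolve toward the mean.
  offs <- seq(-key_range_oct, key_range_oct, by = 2 * key_range_oct / key_steps)
  offs <- offs[order(abs(offs))]
  keys <- mean(mtps$f0_hz) * 2^offs
  spans <- seq(span_min, span_max, by = span_step)
  best <- list(obj = Inf)
  first_idx <- c(T = 1L, M = 5L, B = 8L) # absolute labels within the 8-vector
  for (key in keys) {
    lk <- log(key)
    for (span in spans) {
      top <- key * 2^(span / 2)
      bot <- key * 2^(-span / 2)
      labs <- character(n)
      pred <- numeric(n)
      # first MTP: absolute labels only
      p3 <- c(T = top, M = key, B = bot)
      e3 <- (log(p3) - obs[1])^2
      j <- which.min(e3)
      labs[1] <- names(p3)[j]
      pred[1] <- p3[[j]]
      obj <- e3[[j]]
      prev <- pred[1]
      for (i in 2:n) {
        p8 <- .intsint_predict_all(prev, top, key, bot)
        e8 <- (log(p8) - obs[i])^2
        j <- which.min(e8)
        labs[i] <- names(p8)[j]
        pred[i] <- p8[[j]]
        obj <- obj + e8[[j]]
        prev <- pred[i]
        if (obj >= best$obj) { # prune: objective only grows
          obj <- Inf
          break
        }
      }
      if (obj < best$obj) {
        best <- list(obj = obj, key = key, span = span, labels = labs, pred = pred)
      }
    }
  }
  structure(
    list(
      key_hz = best$key, span_oct = best$span, labels = best$labels,
      predicted_f0 = best$pred, objective = best$obj, mtps = mtps
    ),
    class = "intsint_annotation"
  )
}

#' @export
print.intsint_annotation <- function(x, ...) {
  cat(sprintf(
    "<intsint_annotation: key %.1f Hz, span %.2f oct, %d MTPs [%s]>\n",
    x$key_hz, x$span_oct, length(x$labels), paste(x$labels, collapse = " ")
  ))
  invisible(x)
}

#' @export
#' @method tidy intsint_annotation
tidy.intsint_annotation <- function(x, ...) {
  tibble::tibble(
    time_s = x$mtps$time_s,
    f0_hz = x$mtps$f0_hz,
    label = x$labels,
    predicted_f0_hz = x$predicted_f0
  )
}

#' @export
#' @method glance intsint_annotation
glance.intsint_annotation <- function(x, ...) {
  tibble::tibble(
    key_hz = x$key_hz, span_oct = x$span_oct,
    n_mtps = length(x$labels), objective = x$objective
  )
}
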