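test_that("a constant track stylizes to a constant curve", {
  tr <- make_track(seq(0, 1, 0.01), rep(150, 101))
  cv <- momel_targets(tr)
  expect_true(all(abs(cv$mtps$f0_hz - 150) < 1))
  grid <- seq(min(cv$mtps$time_s), max(cv$mtps$time_s), by = 0.005)
  expect_true(all(abs(spline_eval(cv, grid) - 150) < 1))
})

test_that("planted spline anchors are recovered within 50 ms and 5%", {
  anchors <- tibble::tibble(time_s = c(0.1, 0.5, 0.9), f0_hz = c(120, 200, 130))
  truth <- momel_curve(anchors)
  tt <- seq(0.1, 0.9, 0.01)
  for (seed in 1:3) {
    f0 <- withr::with_seed(seed, {
      spline_eval(truth, tt) * (1 + stats::rnorm(length(tt), 0, 0.01))
    })
    cv <- momel_targets(make_track(tt, f0))
    for (i in seq_len(nrow(anchors))) {
      hit <- any(
        abs(cv$mtps$time_s - anchors$time_s[i]) <= 0.05 &
          abs(cv$mtps$f0_hz - anchors$f0_hz[i]) / anchors$f0_hz[i] <= 0.05
      )
      expect_true(hit, info = sprintf("seed %d anchor %d", seed, i))
    }
  }
})

test_that("an unvoiced gap still yields a continuous stylization", {
  tt <- seq(0, 1, 0.01)
  f0 <- 150 + 30 * sin(2 * pi * tt)
  f0[tt > 0.45 & tt < 0.55] <- NA
  cv <- momel_targets(make_track(tt, f0))
  expect_gte(nrow(cv$mtps), 2L)
  grid <- seq(min(cv$mtps$time_s), max(cv$mtps$time_s), length.out = 500)
  vals <- spline_eval(cv, grid)
  expect_true(all(is.finite(vals)))
  expect_lt(max(abs(diff(vals))), 5) # no jump across the gap
})

test_that("too few voiced frames refuse to stylize", {
  tr <- make_track(seq(0, 1, 0.01), c(150, 150, rep(NA, 99)))
  expect_error(momel_targets(tr), class = "prosodia_too_short_error")
})

test_that("the spline interpolates every MTP exactly and is C1 at knots", {
  mtps <- tibble::tibble(time_s = c(0.1, 0.3, 0.8, 1.2), f0_hz = c(120, 180, 140, 160))
  cv <- momel_curve(mtps)
  expect_equal(spline_eval(cv, mtps$time_s), mtps$f0_hz, tolerance = 1e-12)
  # C1 at midpoint knots: finite-difference slopes agree across the knot
  mid <- (mtps$time_s[-1] + mtps$time_s[-4]) / 2
  for (m in mid) {
    h <- 1e-6
    left <- (spline_eval(cv, m) - spline_eval(cv, m - h)) / h
    right <- (spline_eval(cv, m + h) - spline_eval(cv, m)) / h
    expect_equal(left, right, tolerance = 1e-3)
  }
  expect_error(spline_eval(cv, 2), class = "prosodia_domain_error")
})

test_that("two MTPs reduce to the straight segment through both", {
  cv <- momel_curve(tibble::tibble(time_s = c(0.2, 0.8), f0_hz = c(100, 160)))
  tt <- seq(0.2, 0.8, length.out = 50)
  expect_equal(spline_eval(cv, tt), 100 + (tt - 0.2) / 0.6 * 60, tolerance = 1e-9)
})

test_that("the evaluator matches an independent per-segment construction", {
  # independent route: solve the 6 coefficients of the two quadratic pieces
  # of each inter-anchor interval from value/slope/C1 constraints directly
  dense_eval <- function(t, y, tt) {
    n <- length(t)
    d <- prosodia:::.quad_spline_slopes(t, y)
    out <- numeric(length(tt))
    for (q in seq_along(tt)) {
      i <- max(1, min(n - 1, findInterval(tt[q], t)))
      m <- (t[i] + t[i + 1]) / 2
      A <- rbind(
        c(1, t[i], t[i]^2, 0, 0, 0),
        c(0, 1, 2 * t[i], 0, 0, 0),
        c(0, 0, 0, 1, t[i + 1], t[i + 1]^2),
        c(0, 0, 0, 0, 1, 2 * t[i + 1]),
        c(1, m, m^2, -1, -m, -m^2),
        c(0, 1, 2 * m, 0, -1, -2 * m)
      )
      b <- c(y[i], d[i], y[i + 1], d[i + 1], 0, 0)
      co <- solve(A, b)
      out[q] <- if (tt[q] <= m) {
        co[1] + co[2] * tt[q] + co[3] * tt[q]^2
      } else {
        co[4] + co[5] * tt[q] + co[6] * tt[q]^2
      }
    }
    out
  }
  for (seed in 1:5) {
    pts <- withr::with_seed(seed, {
      tibble::tibble(
        time_s = sort(stats::runif(5, 0, 2)),
        f0_hz = stats::runif(5, 90, 300)
      )
    })
    if (min(diff(pts$time_s)) < 0.05) next
    cv <- momel_curve(pts)
    tt <- seq(min(pts$time_s), max(pts$time_s), length.out = 200)
    ref <- dense_eval(pts$time_s, pts$f0_hz, tt)
    expect_lt(max(abs(spline_eval(cv, tt) - ref) / pmax(abs(ref), 1)), 1e-9)
  }
})

test_that("INTSINT level predictions follow their closed forms", {
  expect_equal(intsint_predict("T", key = 150, span = 1), 150 * 2^0.5)
  expect_equal(round(intsint_predict("T", key = 150, span = 1), 2), 212.13)
  expect_equal(intsint_predict("M", key = 150, span = 1), 150)
  expect_equal(round(intsint_predict("B", key = 150, span = 1), 2), 106.07)
  expect_equal(round(intsint_predict("H", 150, 150, 1), 2), 178.38)
  expect_equal(round(intsint_predict("L", 150, 150, 1), 2), 126.13)
  expect_equal(round(intsint_predict("U", 150, 150, 1), 2), 163.58)
  expect_equal(round(intsint_predict("D", 150, 150, 1), 2), 137.55)
  for (prev in c(100, 150, 280)) {
    expect_identical(intsint_predict("S", prev, 150, 1.2), prev)
  }
  expect_error(intsint_predict("H", key = 150, span = 1), class = "prosodia_argument_error")
  expect_error(intsint_predict("X", 100, 150, 1), class = "prosodia_argument_error")
})

test_that("a constant contour is coded M followed by S at its own key", {
  cv <- momel_curve(tibble::tibble(time_s = c(0.1, 0.4, 0.7, 1.0), f0_hz = rep(150, 4)))
  an <- intsint_annotate(cv)
  expect_equal(an$labels, c("M", "S", "S", "S"))
  expect_equal(an$key_hz, 150, tolerance = 1e-6)
  expect_lt(an$objective, 1e-12)
})

test_that("annotation round-trips contours generated by the coding model", {
  cases <- list(
    list(key = 140, span = 1.2, labels = c("M", "H", "D", "U", "B")),
    list(key = 180, span = 1.6, labels = c("M", "T", "L", "S", "D")),
    list(key = 110, span = 0.9, labels = c("B", "U", "U", "H", "M"))
  )
  for (cs in cases) {
    prev <- NULL
    f0 <- numeric(length(cs$labels))
    for (i in seq_along(cs$labels)) {
      f0[i] <- intsint_predict(cs$labels[i], prev, cs$key, cs$span)
      prev <- f0[i]
    }
    cv <- momel_curve(tibble::tibble(
      time_s = seq(0.1, by = 0.3, length.out = length(f0)), f0_hz = f0
    ))
    an <- intsint_annotate(cv)
    expect_equal(an$labels, cs$labels)
    grid_step <- mean(f0) * (2^(1 / 50) - 1) # one key grid step
    expect_lt(abs(an$key_hz - cs$key), grid_step + 1e-9)
    expect_lte(abs(an$span_oct - cs$span), 0.05 + 1e-9)
  }
})

test_that("greedy labelling matches exhaustive search on a small contour", {
  f0 <- c(intsint_predict("M", key = 150, span = 1.4))
  f0[2] <- intsint_predict("U", f0[1], 150, 1.4)
  f0[3] <- intsint_predict("L", f0[2], 150, 1.4)
  mtps <- tibble::tibble(time_s = c(0.1, 0.5, 0.9), f0_hz = f0)
  an <- intsint_annotate(momel_curve(mtps))

  # brute force over the full (key, span, label-sequence) space
  labs <- c("T", "H", "U", "S", "M", "D", "L", "B")
  offs <- seq(-0.5, 0.5, by = 1 / 50)
  keys <- mean(f0) * 2^offs
  spans <- seq(0.5, 2.5, by = 0.05)
  best <- Inf
  for (key in keys) {
    for (span in spans) {
      for (l1 in c("T", "M", "B")) {
        p1 <- intsint_predict(l1, key = key, span = span)
        e1 <- (log(p1) - log(f0[1]))^2
        for (l2 in labs) {
          p2 <- intsint_predict(l2, p1, key, span)
          e2 <- e1 + (log(p2) - log(f0[2]))^2
          for (l3 in labs) {
            p3 <- intsint_predict(l3, p2, key, span)
            e3 <- e2 + (log(p3) - log(f0[3]))^2
            if (e3 < best) best <- e3
          }
        }
      }
    }
  }
  expect_equal(an$objective, best, tolerance = 1e-12)
})

test_that("predicted f0 stays inside the key/span band and beats a global fit", {
  tt <- seq(0, 1.5, 0.01)
  f0 <- 160 + 50 * sin(2 * pi * 1.2 * tt) + 20 * sin(2 * pi * 2.7 * tt)
  cv <- momel_targets(make_track(tt, f0))
  an <- intsint_annotate(cv)
  top <- an$key_hz * 2^(an$span_oct / 2)
  bot <- an$key_hz * 2^(-an$span_oct / 2)
  expect_true(all(an$predicted_f0 >= bot - 1e-9 & an$predicted_f0 <= top + 1e-9))
  expect_true(an$span_oct >= 0.5 && an$span_oct <= 2.5)
  # stylization error vs a single global quadratic fit
  co <- stats::lm(f0 ~ tt + I(tt^2))$fitted.values
  dom <- range(cv$mtps$time_s)
  sel <- tt >= dom[1] & tt <= dom[2]
  err_sty <- sqrt(mean((spline_eval(cv, tt[sel]) - f0[sel])^2))
  err_glob <- sqrt(mean((co[sel] - f0[sel])^2))
  expect_lt(err_sty, err_glob)
})
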