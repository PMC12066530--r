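.severity_levels <- c("none", "mild", "moderate_severe")

#' Merge a four-level deviation rating to the three-level severity scale
#'
#' Moderate and severe deviation are merged into a single
#' "moderate to severe" category.
#'
#' @param rating Character vector with values in
#'   `none, mild, moderate, severe`.
#' @return Integer severity codes: 0 = no deviation, 1 = mild,
#'   2 = moderate to severe.
#' @export
merge_severity <- function(rating) {
  map <- c(none = 0L, mild = 1L, moderate = 2L, severe = 2L)
  bad <- setdiff(unique(rating), names(map))
  if (length(bad)) {
    rlang::abort(sprintf("Unknown rating level(s): %s", paste(bad, collapse = ", ")),
      class = "prosodia_argument_error"
    )
  }
  unname(map[rating])
}

#' Consensus severity rating across raters
#'
#' The mode of the rater labels; ties are broken toward the more severe
#' category.
#'
#' @param labels Integer severity codes in `{0, 1, 2}` from at least two
#'   raters.
#' @return A single severity code.
#' @export
consensus_rating <- function(labels) {
  if (length(labels) < 2L) {
    rlang::abort("Need at least 2 rater labels.", class = "prosodia_argument_error")
  }
  tab <- table(factor(labels, levels = 0:2))
  winners <- as.integer(names(tab)[tab == max(tab)])
  max(winners)
}

#' 3x3 confusion matrix (rows = truth, columns = prediction)
#'
#' Classes are ordered none < mild < moderate-severe (codes 0, 1, 2).
#'
#' @param truth,predicted Equal-length integer vectors with values in
#'   `{0, 1, 2}`.
#' @return A `prosodia_confusion` integer matrix.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    rlang::abort("`truth` and `predicted` must have equal length.",
      class = "prosodia_argument_error"
    )
  }
  if (!all(c(truth, predicted) %in% 0:2)) {
    rlang::abort("Labels must be in {0, 1, 2}.", class = "prosodia_argument_error")
  }
  m <- table(
    factor(truth, levels = 0:2, labels = .severity_levels),
    factor(predicted, levels = 0:2, labels = .severity_levels)
  )
  m <- matrix(as.integer(m), 3, 3, dimnames = list(
    truth = .severity_levels, predicted = .severity_levels
  ))
  structure(m, class = c("prosodia_confusion", "matrix"))
}

#' Coerce 3x3 counts to a confusion matrix object
#'
#' @param counts 3x3 numeric matrix, rows = truth, columns = prediction,
#'   class order none < mild < moderate-severe.
#' @return A `prosodia_confusion` matrix.
#' @export
as_confusion_matrix <- function(counts) {
  m <- as.matrix(counts)
  stopifnot(all(dim(m) == c(3L, 3L)), all(m >= 0))
  m <- matrix(as.integer(m), 3, 3, dimnames = list(
    truth = .severity_levels, predicted = .severity_levels
  ))
  structure(m, class = c("prosodia_confusion", "matrix"))
}

#' Macro one-vs-rest metric report from a confusion matrix
#'
#' Each class is scored one-vs-rest (sensitivity, specificity, positive
#' and negative predictive value, balanced accuracy, F score) and the
#' report is the unweighted mean over the three classes. When a class is
#' never predicted (TP + FP = 0) its PPV is undefined: the macro PPV is
#' reported `NA` and that class contributes an F score of 0.
#'
#' @param cm A [confusion_matrix()] (or any 3x3 count matrix).
#' @return A `metric_report`: one-row tibble with the six macro metrics;
#'   attribute `by_class` holds the per-class tibble.
#' @export
macro_ovr_report <- function(cm) {
  m <- as.matrix(unclass(cm))
  stopifnot(all(dim(m) == c(3L, 3L)))
  n <- sum(m)
  if (n <= 0) {
    rlang::abort("Empty confusion matrix.", class = "prosodia_argument_error")
  }
  per <- lapply(1:3, function(c) {
    tp <- m[c, c]
    fn <- sum(m[c, ]) - tp
    fp <- sum(m[, c]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    f1 <- if (is.na(ppv) || ppv + sens == 0) 0 else 2 * ppv * sens / (ppv + sens)
    tibble::tibble(
      class = .severity_levels[c], tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
      balanced_accuracy = (sens + spec) / 2, f_score = f1
    )
  })
  by_class <- dplyr::bind_rows(per)
  macro_ppv <- if (any(is.na(by_class$ppv))) NA_real_ else mean(by_class$ppv)
  rep <- tibble::tibble(
    sensitivity = mean(by_class$sensitivity),
    specificity = mean(by_class$specificity),
    ppv = macro_ppv,
    npv = mean(by_class$npv),
    balanced_accuracy = mean(by_class$balanced_accuracy),
    f_score = mean(by_class$f_score)
  )
  structure(rep, by_class = by_class, n = n, class = c("metric_report", class(rep)))
}

#' @export
#' @method tidy metric_report
tidy.metric_report <- function(x, ...) attr(x, "by_class")

#' @export
#' @method glance metric_report
glance.metric_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' Round half away from zero at a given number of decimals
#'
#' Display rounding used for metric tables: 0.675 prints as 0.68. A small
#' epsilon guards against binary-float boundary artifacts on exact halves.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percent agreement between two label sequences
#'
#' @param a,b Equal-length label vectors.
#' @return Percentage of positions where `a == b`.
#' @export
percent_agreement <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0L) {
    rlang::abort("Need equal-length, non-empty label vectors.",
      class = "prosodia_argument_error"
    )
  }
  100 * mean(a == b)
}

#' Cohen's kappa between two label sequences
#'
#' `(p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginal products. When both raters are constant and identical
#' (`p_e = 1`), kappa is defined as 1 by convention (attribute
#' `flagged = TRUE`).
#'
#' @param a,b Equal-length label vectors with at least 2 items.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    rlang::abort("Need equal-length label vectors with >= 2 items.",
      class = "prosodia_argument_error"
    )
  }
  lev <- sort(unique(c(a, b)))
  ta <- table(factor(a, lev), factor(b, lev))
  n <- sum(ta)
  po <- sum(diag(ta)) / n
  pe <- sum(rowSums(ta) * colSums(ta)) / n^2
  if (abs(1 - pe) < 1e-12) {
    return(structure(1, flagged = TRUE))
  }
  (po - pe) / (1 - pe)
}

#' Spearman rank correlation with mid-rank ties
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Returns `NA`
#' when either vector is constant.
#'
#' @param x,y Equal-length numeric vectors of length >= 3.
#' @return rho in \[-1, 1\] or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    rlang::abort("Need equal-length vectors of length >= 3.",
      class = "prosodia_argument_error"
    )
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' One-vs-rest ROC curve and area
#'
#' Threshold sweep on the class-`cls` probability with trapezoidal area.
#'
#' @param probs Matrix or data frame of class probabilities (columns in
#'   class order 0, 1, 2).
#' @param truth Integer truth labels in `{0, 1, 2}`.
#' @param cls Class of interest (0, 1 or 2).
#' @return List with `points` (tibble `threshold`, `fpr`, `tpr`) and
#'   `auc`; `auc` is `NA` when the class is absent from `truth`.
#' @export
roc_ovr <- function(probs, truth, cls) {
  p <- as.matrix(probs)[, cls + 1L]
  pos <- truth == cls
  if (!any(pos) || all(pos)) {
    return(list(points = tibble::tibble(), auc = NA_real_))
  }
  thr <- c(Inf, sort(unique(p), decreasing = TRUE), -Inf)
  pts <- lapply(thr, function(t) {
    pred <- p >= t
    c(fpr = sum(pred & !pos) / sum(!pos), tpr = sum(pred & pos) / sum(pos))
  })
  pts <- do.call(rbind, pts)
  o <- order(pts[, "fpr"], pts[, "tpr"])
  fpr <- pts[o, "fpr"]
  tpr <- pts[o, "tpr"]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(
    points = tibble::tibble(threshold = thr[o], fpr = fpr, tpr = tpr),
    auc = auc
  )
}
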