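#' Reference evaluation tables (re-entered published counts)
#'
#' Confusion matrices from a reference evaluation of dysprosody-severity
#' assessment on a 242-utterance held-out test set: four individual expert
#' raters, the pooled raters, four acoustic models (polynomial SVM,
#' penalized ordinal regression, kNN, random forest), their stacked
#' ensemble, and an f0-variability-only ordinal baseline. Useful for
#' validating [macro_ovr_report()] against independently printed metric
#' values (see [reference_metrics()]).
#'
#' @return Named list of `prosodia_confusion` matrices.
#' @export
reference_confusion_matrices <- function() {
  path <- system.file("extdata", "reference_confusion_matrices.csv",
    package = "prosodia", mustWork = TRUE
  )
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, factor(d$source, unique(d$source))), function(g) {
    m <- matrix(g$count, 3, 3, byrow = TRUE)
    as_confusion_matrix(m)
  })
  out[unique(d$source)]
}

#' Reference macro one-vs-rest metric values
#'
#' The published macro metrics matching [reference_confusion_matrices()],
#' rounded to two decimals as printed; the undefined PPV of the
#' f0-variability-only column is `NA`.
#'
#' @return Tibble with columns `source`, `metric`, `value`.
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.csv",
    package = "prosodia", mustWork = TRUE
  )
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
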