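#' Default pipeline configuration
#'
#' All stage parameters in one nested list, round-trippable through YAML.
#' Every default corresponds to a documented design choice of its module.
#'
#' @return A `prosodia_config` nested list.
#' @export
default_config <- function() {
  structure(
    list(
      vad = list(
        margin_db = 12, max_gap_s = 0.3, min_dur_s = 0.25, pad_s = 0.05,
        floor_db = -55, win_s = 0.025, hop_s = 0.010
      ),
      pitch = list(
        lo_hz = 60, hi_hz = 750, voicing_threshold = 0.45,
        win_s = 0.040, hop_s = 0.010, smooth_width = 5
      ),
      momel = list(win_s = 0.3, outlier_frac = 0.05, reduce_s = 0.2),
      intsint = list(
        key_steps = 50, key_range_oct = 0.5,
        span_min = 0.5, span_max = 2.5, span_step = 0.05
      ),
      acoustics = list(mtp_win_s = 0.030, n_mel_filters = 26),
      models = list(
        test_fraction = 0.25, n_candidates = 25, k_folds = 10,
        kinds = c("svm_poly", "ordinal_elasticnet", "random_forest", "knn"),
        firm_bins = 10
      ),
      seed = 1
    ),
    class = "prosodia_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected (fail fast); missing keys fall back to the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `prosodia_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merged <- unclass(base)
  for (sec in names(user)) {
    if (!sec %in% names(base)) {
      rlang::abort(sprintf("Unknown config section '%s'.", sec),
        class = "prosodia_config_error"
      )
    }
    if (is.list(base[[sec]])) {
      for (key in names(user[[sec]])) {
        if (!key %in% names(base[[sec]])) {
          rlang::abort(sprintf("Unknown config key '%s.%s'.", sec, key),
            class = "prosodia_config_error"
          )
        }
        merged[[sec]][[key]] <- user[[sec]][[key]]
      }
    } else {
      merged[[sec]] <- user[[sec]]
    }
  }
  structure(merged, class = "prosodia_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `prosodia_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
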