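#' Write tiers to a Praat TextGrid (long text format)
#'
#' @param tiers Named list of tiers. A point tier is
#'   `list(type = "point", times = ..., labels = ...)`; an interval tier is
#'   `list(type = "interval", starts = ..., ends = ..., labels = ...)`.
#' @param path Output path.
#' @param xmin,xmax Time domain of the grid; `xmax` defaults to the
#'   largest time found in the tiers.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tiers, path, xmin = 0, xmax = NULL) {
  if (is.null(xmax)) {
    xmax <- max(unlist(lapply(tiers, function(t) {
      if (identical(t$type, "point")) t$times else t$ends
    })), xmin + 1e-6)
  }
  q <- function(s) sprintf("\"%s\"", gsub("\"", "\"\"", s))
  ln <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    sprintf("xmin = %.6f", xmin),
    sprintf("xmax = %.6f", xmax),
    "tiers? <exists>",
    sprintf("size = %d", length(tiers)),
    "item []:"
  )
  for (i in seq_along(tiers)) {
    t <- tiers[[i]]
    nm <- names(tiers)[i]
    ln <- c(ln, sprintf("    item [%d]:", i))
    if (identical(t$type, "point")) {
      ln <- c(
        ln,
        "        class = \"TextTier\"",
        sprintf("        name = %s", q(nm)),
        sprintf("        xmin = %.6f", xmin),
        sprintf("        xmax = %.6f", xmax),
        sprintf("        points: size = %d", length(t$times))
      )
      for (j in seq_along(t$times)) {
        ln <- c(
          ln,
          sprintf("        points [%d]:", j),
          sprintf("            number = %.6f", t$times[j]),
          sprintf("            mark = %s", q(as.character(t$labels[j])))
        )
      }
    } else {
      ln <- c(
        ln,
        "        class = \"IntervalTier\"",
        sprintf("        name = %s", q(nm)),
        sprintf("        xmin = %.6f", xmin),
        sprintf("        xmax = %.6f", xmax),
        sprintf("        intervals: size = %d", length(t$starts))
      )
      for (j in seq_along(t$starts)) {
        ln <- c(
          ln,
          sprintf("        intervals [%d]:", j),
          sprintf("            xmin = %.6f", t$starts[j]),
          sprintf("            xmax = %.6f", t$ends[j]),
          sprintf("            text = %s", q(as.character(t$labels[j])))
        )
      }
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a Praat TextGrid (long text format)
#'
#' Minimal reader for grids produced by [write_textgrid()] and compatible
#' long-format files.
#'
#' @param path Path to a TextGrid file.
#' @return Named list of tiers; point tiers as tibbles
#'   (`time_s`, `label`), interval tiers as tibbles
#'   (`start_s`, `end_s`, `label`).
#' @export
read_textgrid <- function(path) {
  ln <- trimws(readLines(path))
  if (!any(grepl("^Object class = \"TextGrid\"", ln))) {
    rlang::abort(sprintf("Not a TextGrid file: %s", path), class = "prosodia_format_error")
  }
  unq <- function(s) gsub("\"\"", "\"", sub("^\"(.*)\"$", "\\1", s))
  num <- function(s) as.numeric(sub("^[^=]*= *", "", s))
  str <- function(s) unq(sub("^[^=]*= *", "", s))
  tiers <- list()
  i <- 1L
  cur <- NULL
  while (i <= length(ln)) {
    l <- ln[i]
    if (grepl("^class = ", l)) {
      if (!is.null(cur)) tiers[[cur$name]] <- cur$tbl
      cur <- list(
        type = if (grepl("TextTier", l)) "point" else "interval",
        name = NA_character_, tbl = NULL
      )
    } else if (!is.null(cur) && grepl("^name = ", l)) {
      cur$name <- str(l)
    } else if (!is.null(cur) && grepl("^number = ", l)) {
      cur$tbl <- dplyr::bind_rows(cur$tbl, tibble::tibble(
        time_s = num(l), label = str(ln[i + 1L])
      ))
      i <- i + 1L
    } else if (!is.null(cur) && grepl("^intervals \\[", l)) {
      cur$tbl <- dplyr::bind_rows(cur$tbl, tibble::tibble(
        start_s = num(ln[i + 1L]), end_s = num(ln[i + 2L]),
        label = str(ln[i + 3L])
      ))
      i <- i + 3L
    }
    i <- i + 1L
  }
  if (!is.null(cur)) tiers[[cur$name]] <- cur$tbl
  tiers
}

#' Export MTPs and INTSINT labels as a TextGrid
#'
#' Writes two point tiers, `MTP` (target f0 in Hz as the mark) and
#' `INTSINT` (the symbolic labels).
#'
#' @param annotation An `intsint_annotation`.
#' @param path Output path.
#' @param xmax Optional grid end time.
#' @return `path`, invisibly.
#' @export
write_annotation_textgrid <- function(annotation, path, xmax = NULL) {
  write_textgrid(
    list(
      MTP = list(
        type = "point", times = annotation$mtps$time_s,
        labels = sprintf("%.1f", annotation$mtps$f0_hz)
      ),
      INTSINT = list(
        type = "point", times = annotation$mtps$time_s,
        labels = annotation$labels
      )
    ),
    path,
    xmax = xmax
  )
}

#' Export utterance spans as a TextGrid interval tier
#'
#' @param spans Tibble from [detect_utterances()].
#' @param path Output path.
#' @param xmax Grid end time (defaults to the last span end).
#' @return `path`, invisibly.
#' @export
write_spans_textgrid <- function(spans, path, xmax = NULL) {
  write_textgrid(
    list(utterances = list(
      type = "interval", starts = spans$start_s, ends = spans$end_s,
      labels = rep("speech", nrow(spans))
    )),
    path,
    xmax = xmax
  )
}
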