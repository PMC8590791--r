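#' Pipeline configuration with field-standard defaults
#'
#' Central container for every tunable of the pipeline. Defaults follow the
#' measurement protocol the package implements: 50 Hz sampling, 5-s epochs,
#' ENMO cut-offs 0.03 / 0.1 / 0.4 g for LPA / MPA / VPA, 60-min non-wear
#' windows, 600-min (10-h) valid-day threshold, 10-h most-active window,
#' relative-intensity bands at 46 / 64 / 100 %VO2peak, 1 MET = 3.5
#' mL·kg^-1·min^-1.
#'
#' @param ... named overrides of any default listed below.
#' @return a named list of class `wpa_config`.
#' @examples
#' cfg <- pipeline_config(epoch_length = 5, seed = 7)
#' cfg$cutoffs$moderate
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fs = 50,                       # Hz
    epoch_length = 5,              # seconds
    truncate_per = "sample",       # negative ENMO zeroed per sample ("epoch" = after averaging)
    cutoffs = list(light = 0.03, moderate = 0.1, vigorous = 0.4),  # g
    met_anchors = c(light = 2, moderate = 3, vigorous = 6),        # METs
    nonwear = list(window = 60, step = 15,                         # minutes
                   sd_thresh = 0.013, range_thresh = 0.050,        # g
                   min_axes = 2),
    valid_day_minutes = 600,       # >= 10 h wear
    min_valid_weekdays = 4,        # per week
    min_valid_weekend = 1,         # per week
    n_analysis_days = 13,          # day 14 excluded
    min_bout = 10,                 # minutes of consecutive MVPA
    bout_tolerance = 0,            # interruption epochs tolerated inside a bout
    window_hours = 10,             # most-active window length
    window_metric = "tpa_minutes",
    window_wrap = FALSE,
    met_value = 3.5,               # mL O2 per kg per min per MET
    bands = list(lpa_upper = 46, mpa_upper = 64, capacity = 100),  # %VO2peak
    weights = "none",              # mixed-model heteroscedasticity: "none" | "by_factor_level"
    seed = 1L,
    # simulate-scale knobs (synthetic cohort sizes)
    sim = list(n_raw_subjects = 2, n_days = 14, raw_fs = 1,
               n_heart = 56, n_health = 299, start_date = "2019-03-04")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm, call. = FALSE)
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  stopifnot(cfg$fs > 0, cfg$epoch_length > 0,
            cfg$cutoffs$light < cfg$cutoffs$moderate,
            cfg$cutoffs$moderate < cfg$cutoffs$vigorous)
  structure(cfg, class = "wpa_config")
}

#' Read a key = value configuration file
#'
#' Flat text format: one `key = value` per line, `#` comments. Dotted keys
#' address nested lists (`nonwear.step = 15`). Values are parsed as numbers
#' when possible, `TRUE`/`FALSE` as logical, otherwise kept as strings.
#'
#' @param path file path.
#' @param base configuration to override; defaults to [pipeline_config()].
#' @return a `wpa_config` list.
#' @export
read_config <- function(path, base = pipeline_config()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(toupper(val))
      else val
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      if (!parts %in% names(base)) stop("unknown config key: ", key, call. = FALSE)
      base[[parts]] <- parsed
    } else if (length(parts) == 2L) {
      if (!parts[1] %in% names(base) || !is.list(base[[parts[1]]])) {
        stop("unknown config key: ", key, call. = FALSE)
      }
      base[[parts[1]]][[parts[2]]] <- parsed
    } else {
      stop("config keys nest at most one level: ", key, call. = FALSE)
    }
  }
  base
}

#' @export
print.wpa_config <- function(x, ...) {
  cat("<wpa_config>\n")
  str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
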