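#' Relative intensity bands in %VO2peak
#'
#' LPA: 0 to < 46%, MPA: 46 to < 64%, VPA: 64 to 100% of VO2peak; anything
#' above 100% exceeds the individual's aerobic capacity and cannot be
#' sustained.
#'
#' @param lpa_upper,mpa_upper,capacity band boundaries, %VO2peak.
#' @return a `relative_bands` list.
#' @export
relative_bands <- function(lpa_upper = 46, mpa_upper = 64, capacity = 100) {
  if (!(0 < lpa_upper && lpa_upper < mpa_upper && mpa_upper <= capacity)) {
    stop("bands must satisfy 0 < lpa_upper < mpa_upper <= capacity", call. = FALSE)
  }
  structure(list(lpa_upper = lpa_upper, mpa_upper = mpa_upper,
                 capacity = capacity),
            class = "relative_bands")
}

#' Convert an absolute MET level to %VO2peak
#'
#' `100 * mets * met_value / vo2peak`, with 1 MET = 3.5 mL·kg^-1·min^-1 by
#' convention. Vectorised over both `mets` and `vo2peak`.
#'
#' @param mets absolute intensity in METs (> 0).
#' @param vo2peak peak oxygen uptake, mL·kg^-1·min^-1 (> 0).
#' @param met_value oxygen cost of 1 MET, mL·kg^-1·min^-1.
#' @return relative intensity in %VO2peak.
#' @examples
#' met_to_pct(6, 35)   # 60% of VO2peak
#' met_to_pct(6, 21)   # exactly at capacity
#' @export
met_to_pct <- function(mets, vo2peak, met_value = 3.5) {
  if (any(mets <= 0) || any(vo2peak <= 0) || met_value <= 0) {
    stop("mets, vo2peak and met_value must be positive", call. = FALSE)
  }
  100 * (mets * met_value) / vo2peak
}

#' Band membership of a relative intensity
#'
#' `pct < 46` is LPA, `46 <= pct < 64` MPA, `64 <= pct <= 100` VPA
#' (capacity inclusive), `pct > 100` above capacity. Vectorised.
#'
#' @param pct %VO2peak (>= 0).
#' @param bands a [relative_bands()].
#' @return factor with levels `LPA, MPA, VPA, above_capacity`.
#' @export
band_of <- function(pct, bands = relative_bands()) {
  if (any(pct < 0)) stop("pct must be non-negative", call. = FALSE)
  lv <- c("LPA", "MPA", "VPA", "above_capacity")
  out <- ifelse(pct < bands$lpa_upper, "LPA",
         ifelse(pct < bands$mpa_upper, "MPA",
         ifelse(pct <= bands$capacity, "VPA", "above_capacity")))
  factor(out, levels = lv)
}

# which relative band each MET anchor is meant to capture
intended_band <- function(anchor) {
  if (anchor < 3) "LPA" else if (anchor < 6) "MPA" else "VPA"
}

#' Audit absolute cut-offs against relative intensity
#'
#' For each group and MET anchor, places every subject's relative cost of
#' exercising at that absolute level (via [met_to_pct()]) into a relative
#' band and reports band fractions, plus where the anchor lands relative to
#' its intended band (3 and 4.5 METs intend MPA, 6 and 8 METs intend VPA;
#' 2 METs intends LPA and is reported descriptively). `above` includes
#' intensities exceeding the subject's capacity.
#'
#' @param subjects data.frame with `subject_id, group, vo2peak` (optionally
#'   `age`, `sex`).
#' @param met_anchors MET levels to audit.
#' @param bands a [relative_bands()].
#' @param met_value mL·kg^-1·min^-1 per MET.
#' @return data.frame, one row per group x anchor: `n`, band fractions
#'   (`frac_lpa, frac_mpa, frac_vpa, frac_above_capacity`), and
#'   intended-band placement (`frac_below_intended, frac_within_intended,
#'   frac_above_intended`).
#' @examples
#' s <- data.frame(subject_id = 1:4, group = "HEART",
#'                 vo2peak = c(14, 21, 28, 42))
#' audit_cutoffs(s, met_anchors = 6)
#' @export
audit_cutoffs <- function(subjects, met_anchors = c(2, 3, 6),
                          bands = relative_bands(), met_value = 3.5) {
  stopifnot(all(c("group", "vo2peak") %in% names(subjects)))
  if (!nrow(subjects)) {
    warning("empty group skipped: no subjects supplied", call. = FALSE)
    return(data.frame(group = character(), met_anchor = numeric(),
                      intended_band = character(), n = integer(),
                      frac_lpa = numeric(), frac_mpa = numeric(),
                      frac_vpa = numeric(), frac_above_capacity = numeric(),
                      frac_below_intended = numeric(),
                      frac_within_intended = numeric(),
                      frac_above_intended = numeric()))
  }
  groups <- unique(subjects$group)
  lv <- c("LPA", "MPA", "VPA", "above_capacity")
  rows <- list()
  for (g in groups) {
    sub <- subjects[subjects$group == g, , drop = FALSE]
    if (!nrow(sub)) {
      warning("empty group skipped: ", g, call. = FALSE)
      next
    }
    for (a in met_anchors) {
      pct <- met_to_pct(a, sub$vo2peak, met_value)
      b <- band_of(pct, bands)
      frac <- as.numeric(table(b) / length(b))
      ib <- intended_band(a)
      ord <- as.integer(b)                 # LPA=1 .. above_capacity=4
      iord <- match(ib, lv)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, met_anchor = a, intended_band = ib, n = nrow(sub),
        frac_lpa = frac[1], frac_mpa = frac[2], frac_vpa = frac[3],
        frac_above_capacity = frac[4],
        frac_below_intended = mean(ord < iord),
        frac_within_intended = mean(ord == iord),
        frac_above_intended = mean(ord > iord)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative-intensity curves across a subject axis
#'
#' The scatter of per-subject relative cost at each MET anchor against age
#' or VO2peak: pure reshaping of [met_to_pct()] output for plotting.
#'
#' @param subjects data.frame with `subject_id, group, vo2peak` and the
#'   chosen axis column.
#' @param met_anchors MET levels.
#' @param axis `"age"` or `"vo2peak"`.
#' @param met_value mL·kg^-1·min^-1 per MET.
#' @return data.frame: `subject_id, group, axis, axis_value, met_anchor,
#'   pct`.
#' @export
sweep_pct_curves <- function(subjects, met_anchors = c(2, 3, 6),
                             axis = c("age", "vo2peak"), met_value = 3.5) {
  axis <- match.arg(axis)
  if (!axis %in% names(subjects)) {
    stop("axis column missing from subjects: ", axis, call. = FALSE)
  }
  if (!length(met_anchors)) {
    return(data.frame(subject_id = character(), group = character(),
                      axis = character(), axis_value = numeric(),
                      met_anchor = numeric(), pct = numeric()))
  }
  rows <- lapply(met_anchors, function(a) {
    data.frame(subject_id = subjects$subject_id, group = subjects$group,
               axis = axis, axis_value = subjects[[axis]], met_anchor = a,
               pct = met_to_pct(a, subjects$vo2peak, met_value))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
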