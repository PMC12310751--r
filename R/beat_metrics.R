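#' Derive the JT interval
#'
#' JT = QT - QRS, the ECG convention that isolates ventricular repolarization
#' (JT) from depolarization (QRS). Group means of JT published elsewhere may
#' differ by ~1 ms from subtraction of published group means because of
#' differing per-row sample sizes and rounding; this function operates on
#' per-measurement values.
#'
#' @param qt_ms QT interval in ms.
#' @param qrs_ms QRS duration in ms.
#' @return JT interval in ms. Vectorized; `NA` inputs propagate.
#' @export
#' @examples
#' derive_jt(443, 95)  # 348
derive_jt <- function(qt_ms, qrs_ms) {
  ok <- !is.na(qt_ms) & !is.na(qrs_ms)
  if (any(qt_ms[ok] <= qrs_ms[ok])) {
    stop("`qt_ms` must exceed `qrs_ms`", call. = FALSE)
  }
  qt_ms - qrs_ms
}

#' Heart-rate correction of repolarization intervals
#'
#' Corrects a repolarization interval (QT or JT) for heart rate. The default
#' is the Van de Water correction, the canonical choice for dogs:
#' \deqn{QTc = QT - 0.087 (RR - 1000)}
#' with all quantities in ms. Fridericia (`interval / (RR/1000)^{1/3}`) and
#' Bazett (`interval / sqrt(RR/1000)`) are available as alternatives.
#'
#' @param interval_ms Interval to correct (ms), e.g. QT or JT.
#' @param rr_ms RR interval (ms).
#' @param method One of `"van_de_water"` (default), `"fridericia"`,
#'   `"bazett"`.
#' @return Corrected interval in ms. Vectorized; `NA` inputs propagate.
#' @export
#' @examples
#' rate_correct(443, 1405)                 # 407.8
#' rate_correct(443, 1405, "fridericia")
rate_correct <- function(interval_ms, rr_ms,
                         method = c("van_de_water", "fridericia", "bazett")) {
  method <- match.arg(method)
  if (any(interval_ms <= 0, na.rm = TRUE) || any(rr_ms <= 0, na.rm = TRUE)) {
    stop("`interval_ms` and `rr_ms` must be positive", call. = FALSE)
  }
  switch(method,
    van_de_water = interval_ms - 0.087 * (rr_ms - 1000),
    fridericia   = interval_ms / (rr_ms / 1000)^(1 / 3),
    bazett       = interval_ms / sqrt(rr_ms / 1000))
}

#' Interventricular MAP duration difference
#'
#' Difference between left- and right-ventricular monophasic action potential
#' durations (LV MAP - RV MAP). May be negative for an individual animal.
#'
#' @param lv_map_ms LV MAP duration (ms).
#' @param rv_map_ms RV MAP duration (ms).
#' @return Difference in ms; `NA` inputs propagate.
#' @export
delta_map <- function(lv_map_ms, rv_map_ms) {
  ok <- !is.na(lv_map_ms) & !is.na(rv_map_ms)
  if (any(lv_map_ms[ok] <= 0) || any(rv_map_ms[ok] <= 0)) {
    stop("MAP durations must be positive", call. = FALSE)
  }
  lv_map_ms - rv_map_ms
}

#' Short-term variability of repolarization
#'
#' Beat-to-beat short-term variability (STV) of a series of repolarization
#' durations \eqn{D_1, \dots, D_N}:
#' \deqn{STV = \sum |D_{n+1} - D_n| / (N_{pairs} \sqrt{2})}
#' computed by convention over a window of 31 consecutive beats (30 pairs),
#' the distance to the identity line of the Poincare plot. Series longer
#' than the window use the last `window_beats` beats; shorter series use all
#' available pairs (with a warning).
#'
#' @param durations_ms Numeric vector of beat-to-beat durations (ms),
#'   length >= 2.
#' @param window_beats Window size in beats (default 31).
#' @return STV in ms (nonnegative; 0 iff the windowed series is constant).
#' @export
#' @examples
#' stv(rep(c(300, 310), length.out = 31))  # 30 pairs of |10| -> 7.071
stv <- function(durations_ms, window_beats = 31L) {
  if (length(durations_ms) < 2L) {
    stop("STV needs at least 2 beats", call. = FALSE)
  }
  if (any(is.na(durations_ms))) {
    stop("`durations_ms` must not contain NA", call. = FALSE)
  }
  if (length(durations_ms) > window_beats) {
    durations_ms <- utils::tail(durations_ms, window_beats)
  } else if (length(durations_ms) < window_beats) {
    warning("series shorter than the ", window_beats,
            "-beat window; using all ", length(durations_ms) - 1L, " pairs",
            call. = FALSE)
  }
  d <- diff(durations_ms)
  sum(abs(d)) / (length(d) * sqrt(2))
}

#' Augment a cohort table with derived repolarization metrics
#'
#' Adds (or recomputes) `jt_ms`, `qtc_ms`, `jtc_ms` and `delta_map_ms`
#' columns from the measured `qt_ms`, `qrs_ms`, `rr_ms`, `lv_map_ms` and
#' `rv_map_ms` columns. Rows where QT does not exceed QRS get `NA` JT/JTc
#' (with a warning) rather than an error, so one aberrant measurement does
#' not abort a cohort-level computation.
#'
#' @param animals Cohort `data.frame` in the long animal x condition layout
#'   (see [write_animals_csv()] for the schema).
#' @param method Rate-correction method passed to [rate_correct()].
#' @return `animals` with derived columns added.
#' @export
augment_metrics <- function(animals, method = "van_de_water") {
  qt <- animals$qt_ms
  qrs <- animals$qrs_ms
  rr <- animals$rr_ms
  bad_jt <- !is.na(qt) & !is.na(qrs) & qt <= qrs
  if (any(bad_jt)) {
    warning(sum(bad_jt), " row(s) with QT <= QRS; JT/JTc set to NA",
            call. = FALSE)
  }
  jt <- ifelse(bad_jt, NA_real_, qt - qrs)
  animals$jt_ms <- jt
  animals$qtc_ms <- ifelse(is.na(qt) | is.na(rr), NA_real_,
                           rate_correct(qt, rr, method))
  animals$jtc_ms <- ifelse(is.na(jt) | is.na(rr), NA_real_,
                           rate_correct(jt, rr, method))
  animals$delta_map_ms <- animals$lv_map_ms - animals$rv_map_ms
  animals
}

#' Compute STV per animal from a long beat-series table
#'
#' @param beats Long `data.frame` with columns `animal_id`, `condition`,
#'   `site`, `beat_index`, `duration_ms`.
#' @param window_beats STV window in beats (default 31).
#' @return `data.frame` with one row per (animal_id, condition, site) and an
#'   `stv_ms` column.
#' @export
stv_from_beats <- function(beats, window_beats = 31L) {
  key <- interaction(beats$animal_id, beats$condition, beats$site,
                     drop = TRUE)
  rows <- lapply(split(beats, key), function(b) {
    b <- b[order(b$beat_index), , drop = FALSE]
    data.frame(animal_id = b$animal_id[1], condition = b$condition[1],
               site = b$site[1],
               stv_ms = stv(b$duration_ms, window_beats),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
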