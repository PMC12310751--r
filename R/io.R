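events_schema_cols <- function() {
  c("animal_id", "onset_s", "kind", "run_beats", "n_defibs")
}

check_required_cols <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(what, " has unknown column(s), preserved: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Write / read the cohort animal table
#'
#' The `animals.csv` schema is one row per animal x condition with columns
#' `id, sex, age_months, body_weight_kg, condition, rr_ms, pp_ms, qrs_ms,
#' qt_ms, jt_ms, lv_map_ms, rv_map_ms, lv_stv_ms, rv_stv_ms, lvdpdt_max,
#' lv_edp, lv_esp, phenotype_true` (UTF-8, comma separated, `.` decimal;
#' intervals in ms, LVdP/dt_max in mmHg/s, pressures in mmHg). Additional
#' columns (organ weights, cellular APD) are preserved with a warning on
#' read.
#'
#' @param animals Cohort `data.frame`.
#' @param path File path.
#' @return `write_animals_csv` returns `path` invisibly; `read_animals_csv`
#'   returns the validated `data.frame`.
#' @export
write_animals_csv <- function(animals, path) {
  utils::write.csv(animals, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_animals_csv
#' @export
read_animals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  check_required_cols(df, animals_schema_cols(), "animals file")
  df$id <- as.character(df$id)
  bad_sex <- which(!df$sex %in% c("female", "male"))
  if (length(bad_sex)) {
    stop("malformed `sex` value at data line ", bad_sex[1], ": '",
         df$sex[bad_sex[1]], "'", call. = FALSE)
  }
  bad_cond <- which(!df$condition %in% c("baseline", "dofetilide"))
  if (length(bad_cond)) {
    stop("malformed `condition` value at data line ", bad_cond[1], ": '",
         df$condition[bad_cond[1]], "'", call. = FALSE)
  }
  bad_ph <- which(!is.na(df$phenotype_true) &
                    !df$phenotype_true %in% c("inducible", "non-inducible"))
  if (length(bad_ph)) {
    stop("malformed `phenotype_true` value at data line ", bad_ph[1], ": '",
         df$phenotype_true[bad_ph[1]], "'", call. = FALSE)
  }
  df
}

#' Write / read arrhythmic-event logs
#'
#' The `events.csv` schema is `animal_id, onset_s, kind, run_beats,
#' n_defibs`, time-ordered within each animal (onsets in seconds from the
#' start of dofetilide). Reading enforces the schema, the event-kind
#' enumeration and per-animal time ordering, reporting the offending line.
#'
#' @param events Event `data.frame`.
#' @param path File path.
#' @return `write_events_csv` returns `path` invisibly; `read_events_csv`
#'   the validated `data.frame`.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  check_required_cols(df, events_schema_cols(), "events file")
  if (nrow(df) == 0L) return(df)
  df$animal_id <- as.character(df$animal_id)
  bad_kind <- which(!df$kind %in% EVENT_KINDS)
  if (length(bad_kind)) {
    stop("malformed `kind` value at data line ", bad_kind[1], ": '",
         df$kind[bad_kind[1]], "'", call. = FALSE)
  }
  if (any(df$onset_s < 0, na.rm = TRUE)) {
    stop("negative `onset_s` at data line ", which(df$onset_s < 0)[1],
         call. = FALSE)
  }
  for (id in unique(df$animal_id)) {
    idx <- which(df$animal_id == id)
    o <- df$onset_s[idx]
    if (is.unsorted(o)) {
      bad <- idx[which(diff(o) < 0)[1] + 1L]
      stop("events for animal ", id, " out of time order at data line ",
           bad, call. = FALSE)
    }
  }
  df
}

#' Write / read long beat-series tables
#'
#' Long format: `animal_id, condition, site, beat_index, duration_ms`.
#'
#' @param beats Beat `data.frame`.
#' @param path File path.
#' @return Path (write) or validated `data.frame` (read).
#' @export
write_beats_csv <- function(beats, path) {
  utils::write.csv(beats, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  check_required_cols(df, c("animal_id", "condition", "site", "beat_index",
                            "duration_ms"), "beats file")
  df$animal_id <- as.character(df$animal_id)
  df
}
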