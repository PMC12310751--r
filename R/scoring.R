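#' Arrhythmic event kinds recognised by the scorer
#'
#' Severity-ordered event classes observed during the proarrhythmic window
#' after the start of dofetilide infusion.
#'
#' @format Character vector of the four event kinds.
#' @export
EVENT_KINDS <- c("single_ectopic", "multiple_ectopic",
                 "tdp_self_terminating", "tdp_defibrillated")

#' Construct and validate an arrhythmic event
#'
#' @param onset_s Onset time in seconds from the start of dofetilide infusion.
#' @param kind One of [EVENT_KINDS].
#' @param run_beats Number of beats in the run (multiple ectopic runs or TdP
#'   episodes). Single ectopic beats have `run_beats = 1`.
#' @param n_defibs Number of defibrillations needed to terminate the episode:
#'   1--3 for `tdp_defibrillated`, 0 otherwise.
#'
#' @return A one-row `data.frame` with columns `onset_s`, `kind`,
#'   `run_beats`, `n_defibs`.
#' @export
#' @examples
#' arrhythmic_event(12.5, "tdp_self_terminating", run_beats = 8)
arrhythmic_event <- function(onset_s, kind, run_beats = 1L, n_defibs = 0L) {
  kind <- match.arg(kind, EVENT_KINDS)
  if (!is.numeric(onset_s) || length(onset_s) != 1L || is.na(onset_s) ||
      onset_s < 0) {
    stop("`onset_s` must be a single nonnegative number", call. = FALSE)
  }
  run_beats <- as.integer(run_beats)
  n_defibs <- as.integer(n_defibs)
  if (is.na(run_beats) || run_beats < 1L) {
    stop("`run_beats` must be >= 1", call. = FALSE)
  }
  if (kind == "multiple_ectopic" && run_beats < 2L) {
    stop("a multiple-ectopic run needs `run_beats` >= 2", call. = FALSE)
  }
  if (kind == "tdp_defibrillated") {
    if (is.na(n_defibs) || n_defibs < 1L || n_defibs > 3L) {
      stop("`n_defibs` must be 1, 2 or 3 for a defibrillated TdP",
           call. = FALSE)
    }
  } else if (n_defibs != 0L) {
    stop("`n_defibs` must be 0 unless the event is a defibrillated TdP",
         call. = FALSE)
  }
  data.frame(onset_s = onset_s, kind = kind,
             run_beats = run_beats, n_defibs = n_defibs,
             stringsAsFactors = FALSE)
}

#' Construct and validate an event log for one animal
#'
#' @param animal_id Animal identifier.
#' @param events `data.frame` of events (as from [arrhythmic_event()] rows
#'   bound together), or `NULL`/empty for a quiet animal.
#' @param window_s Duration of the proarrhythmic observation window in
#'   seconds (default 600, i.e. the 10-min period after starting dofetilide).
#'
#' @return A `data.frame` of events with attributes `animal_id` and
#'   `window_s`, class `"event_log"`.
#' @export
event_log <- function(animal_id, events = NULL, window_s = 600) {
  if (window_s < 0) stop("`window_s` must be >= 0", call. = FALSE)
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(onset_s = numeric(0), kind = character(0),
                         run_beats = integer(0), n_defibs = integer(0),
                         stringsAsFactors = FALSE)
  }
  required <- c("onset_s", "kind", "run_beats", "n_defibs")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop("event log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(events$onset_s)) {
    stop("events must be ordered by `onset_s`", call. = FALSE)
  }
  if (any(events$onset_s > window_s)) {
    stop("all `onset_s` must lie within `window_s`", call. = FALSE)
  }
  bad <- !events$kind %in% EVENT_KINDS
  if (any(bad)) {
    stop("unknown event kind(s): ",
         paste(unique(events$kind[bad]), collapse = ", "), call. = FALSE)
  }
  structure(events, animal_id = as.character(animal_id),
            window_s = window_s, class = c("event_log", "data.frame"))
}

#' Score one arrhythmic event
#'
#' Implements the standard CAVB point table: a single ectopic beat scores 2
#' points, multiple ectopic beats 3--5 points, a self-terminating TdP episode
#' 6--49 points, and a TdP episode terminated by one, two or three
#' defibrillations 50, 75 or 100 points respectively. Within the 3--5 and
#' 6--49 ranges the score grows with run length as `1 + run_beats`, clamped
#' to the class range (a documented convention; the published table gives
#' only the ranges).
#'
#' @param kind One of [EVENT_KINDS], or a one-row event `data.frame`.
#' @param run_beats Beats in the run (ignored for single ectopics and
#'   defibrillated TdP).
#' @param n_defibs Defibrillation count (used for `tdp_defibrillated` only).
#'
#' @return Integer point score.
#' @export
#' @examples
#' score_event("single_ectopic")                      # 2
#' score_event("tdp_defibrillated", n_defibs = 2)     # 75
#' score_event("tdp_self_terminating", run_beats = 8) # 9
score_event <- function(kind, run_beats = 1L, n_defibs = 0L) {
  if (is.data.frame(kind)) {
    ev <- kind
    return(score_event(ev$kind, ev$run_beats, ev$n_defibs))
  }
  kind <- match.arg(kind, EVENT_KINDS)
  switch(kind,
    single_ectopic = 2L,
    multiple_ectopic = as.integer(pmin(5L, pmax(3L, 1L + run_beats))),
    tdp_self_terminating = as.integer(pmin(49L, pmax(6L, 1L + run_beats))),
    tdp_defibrillated = {
      if (!n_defibs %in% 1:3) {
        stop("`n_defibs` must be 1, 2 or 3 for a defibrillated TdP",
             call. = FALSE)
      }
      c(50L, 75L, 100L)[n_defibs]
    })
}

score_events_vec <- function(events) {
  if (nrow(events) == 0L) return(integer(0))
  vapply(seq_len(nrow(events)), function(i) {
    score_event(events$kind[i], events$run_beats[i], events$n_defibs[i])
  }, integer(1))
}

#' Per-animal arrhythmia score
#'
#' The arrhythmia score is the average of the three highest-scored arrhythmic
#' events in the proarrhythmic window. Animals with fewer than three events
#' are scored as the mean of the available event scores; an event-free animal
#' scores 0 (a convention that keeps the statistic defined for every animal).
#'
#' @param events Event `data.frame` for one animal (see [event_log()]).
#' @return Numeric score.
#' @export
#' @examples
#' ev <- rbind(arrhythmic_event(10, "tdp_defibrillated", 12, 1),
#'             arrhythmic_event(40, "tdp_self_terminating", 5),
#'             arrhythmic_event(70, "multiple_ectopic", 2),
#'             arrhythmic_event(90, "single_ectopic"))
#' arrhythmia_score(ev)  # (50 + 6 + 3) / 3
arrhythmia_score <- function(events) {
  scores <- score_events_vec(events)
  if (length(scores) == 0L) return(0)
  mean(utils::head(sort(scores, decreasing = TRUE), 3L))
}

#' Count TdP episodes in the proarrhythmic window
#'
#' Counts self-terminating and defibrillated TdP episodes with onset inside
#' the window.
#'
#' @inheritParams arrhythmia_score
#' @param window_s Window length in seconds (default 600). Events with
#'   `onset_s > window_s` are excluded.
#' @return Integer count.
#' @export
count_tdp_episodes <- function(events, window_s = 600) {
  if (nrow(events) == 0L) return(0L)
  tdp <- events$kind %in% c("tdp_self_terminating", "tdp_defibrillated")
  sum(tdp & events$onset_s <= window_s)
}

#' Classify TdP inducibility
#'
#' A CAVB dog is classified inducible when it shows at least three TdP
#' episodes within the 10-min window after starting dofetilide; two or fewer
#' episodes classify it non-inducible.
#'
#' @inheritParams count_tdp_episodes
#' @param threshold Minimum number of TdP episodes for inducibility
#'   (default 3).
#' @return `"inducible"` or `"non-inducible"`.
#' @export
classify_inducible <- function(events, window_s = 600, threshold = 3L) {
  if (count_tdp_episodes(events, window_s) >= threshold) "inducible"
  else "non-inducible"
}

#' Score a cohort's event logs
#'
#' Applies TdP counting, the arrhythmia score and the inducibility rule to a
#' long event table covering several animals.
#'
#' @param events Event `data.frame` with columns `animal_id`, `onset_s`,
#'   `kind`, `run_beats`, `n_defibs` (the `events.csv` schema).
#' @param animal_ids Optional vector of animal ids to score; defaults to the
#'   ids present in `events`. Ids without events score 0 / non-inducible.
#' @param window_s Proarrhythmic window in seconds.
#' @return `data.frame` with columns `animal_id`, `n_events`, `n_tdp`,
#'   `arrhythmia_score`, `time_to_first_tdp_s` (NA when no TdP occurred) and
#'   `inducible` (logical).
#' @export
score_cohort <- function(events, animal_ids = NULL, window_s = 600) {
  if (is.null(animal_ids)) animal_ids <- unique(events$animal_id)
  rows <- lapply(animal_ids, function(id) {
    ev <- events[events$animal_id == id & events$onset_s <= window_s, ,
                 drop = FALSE]
    tdp_times <- ev$onset_s[ev$kind %in%
                              c("tdp_self_terminating", "tdp_defibrillated")]
    data.frame(
      animal_id = id,
      n_events = nrow(ev),
      n_tdp = count_tdp_episodes(ev, window_s),
      arrhythmia_score = arrhythmia_score(ev),
      time_to_first_tdp_s = if (length(tdp_times)) min(tdp_times) else NA_real_,
      inducible = classify_inducible(ev, window_s) == "inducible",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
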