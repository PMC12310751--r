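# small event-log fixtures built in code

make_events <- function(...) {
  do.call(rbind, list(...))
}

tdp_log <- function(n_self = 0L, n_defib = 0L, spacing_s = 30) {
  evs <- list()
  t <- 0
  for (i in seq_len(n_self)) {
    t <- t + spacing_s
    evs[[length(evs) + 1L]] <- arrhythmic_event(t, "tdp_self_terminating",
                                                run_beats = 8L)
  }
  for (i in seq_len(n_defib)) {
    t <- t + spacing_s
    evs[[length(evs) + 1L]] <- arrhythmic_event(t, "tdp_defibrillated",
                                                run_beats = 20L,
                                                n_defibs = 1L)
  }
  if (length(evs) == 0L) {
    return(data.frame(onset_s = numeric(0), kind = character(0),
                      run_beats = integer(0), n_defibs = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, evs)
}

# Table-1 group-mean cells used across tests: (QT, JT, RR) -> (QTc, JTc)
table1_mean_cells <- function() {
  data.frame(
    cell = c("inducible.baseline", "non-inducible.baseline",
             "inducible.dofetilide", "non-inducible.dofetilide"),
    qt = c(443, 364, 613, 607),
    jt = c(347, 272, 520, 511),
    rr = c(1405, 1295, 1550, 1510),
    qtc = c(407, 338, 565, 562),
    jtc = c(312, 246, 473, 467))
}
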