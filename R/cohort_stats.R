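#' Mean +/- SD summary of a set of values
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @return List with `n`, `mean`, `sd` (`sd` is `NA` when `n < 2`).
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize", call. = FALSE)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}

comparison_row <- function(contrast, estimate, statistic, df, p_raw,
                           p_adjusted, method, n1, n2, alpha = 0.05) {
  data.frame(contrast = contrast, estimate = estimate, statistic = statistic,
             df = df, p_raw = p_raw, p_adjusted = p_adjusted,
             method = method, n1 = n1, n2 = n2,
             significant = !is.na(p_adjusted) & p_adjusted < alpha,
             stringsAsFactors = FALSE)
}

#' Unpaired two-sample t-test
#'
#' Two-sided unpaired t-test; the default Student variant pools the group
#' variances, the Welch variant does not assume them equal.
#'
#' @param a,b Numeric vectors (each `n >= 2` after dropping `NA`).
#' @param variant `"student"` (pooled, default) or `"welch"`.
#' @param alpha Significance level for the `significant` flag.
#' @param contrast Label for the comparison.
#' @return One-row `data.frame` (a `ComparisonResult`): `contrast`,
#'   `estimate` (mean(a) - mean(b)), `statistic`, `df`, `p_raw`,
#'   `p_adjusted` (equal to `p_raw`; no multiplicity here), `method`, `n1`,
#'   `n2`, `significant`.
#' @export
unpaired_t_test <- function(a, b, variant = c("student", "welch"),
                            alpha = 0.05, contrast = "a vs b") {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: no variance anywhere; equal means -> no evidence
    eq <- mean(a) == mean(b)
    return(comparison_row(contrast, mean(a) - mean(b),
                          if (eq) 0 else Inf,
                          length(a) + length(b) - 2,
                          if (eq) 1 else 0, if (eq) 1 else 0,
                          "t_test", length(a), length(b), alpha))
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  comparison_row(contrast, mean(a) - mean(b),
                 unname(ht$statistic), unname(ht$parameter),
                 ht$p.value, ht$p.value, "t_test",
                 length(a), length(b), alpha)
}

#' Bonferroni adjustment
#'
#' `p_adjusted = min(1, m * p_raw)`.
#'
#' @param p Raw p-values.
#' @param m Number of planned comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' Two-way ANOVA with planned Bonferroni contrasts
#'
#' Fits the cell-means model for `value ~ group x condition` on (possibly
#' unbalanced) data and computes the four planned contrasts of the standard
#' Table-1-style report: dofetilide vs baseline within each phenotype group
#' (the `*` marks) and non-inducible vs inducible within each condition (the
#' `^` marks), Bonferroni-adjusted over the four contrasts. The omnibus
#' table uses Type II sums of squares (the planned contrasts do not depend
#' on that choice).
#'
#' @param data `data.frame` with at least the columns named by `value`,
#'   `group`, `condition`; rows with `NA` in any of them are dropped.
#' @param value,group,condition Column names.
#' @param alpha Significance level.
#' @return List of class `"two_way_anova"` with elements `anova` (Type II
#'   omnibus table), `contrasts` (`data.frame` of `ComparisonResult` rows;
#'   contrasts touching an empty cell are `NA` rows, not errors),
#'   `cell_means` and `fit` (the underlying `lm`).
#' @export
two_way_anova <- function(data, value = "value", group = "group",
                          condition = "condition", alpha = 0.05) {
  d <- data.frame(value = data[[value]],
                  group = as.character(data[[group]]),
                  condition = as.character(data[[condition]]),
                  stringsAsFactors = FALSE)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  groups <- sort(unique(d$group))
  conditions <- sort(unique(d$condition))
  if (nrow(d) < 2L) stop("need at least 2 observations", call. = FALSE)
  d$cell <- factor(paste(d$group, d$condition, sep = "|"))
  fit <- stats::lm(value ~ 0 + cell, data = d)
  beta <- stats::coef(fit)
  # a perfect (zero-residual) fit warns in summary.lm; degeneracy is
  # handled explicitly below
  vc <- suppressWarnings(stats::vcov(fit))
  df_res <- stats::df.residual(fit)
  ns <- table(d$cell)
  cells <- data.frame(cell = levels(d$cell),
                      n = as.integer(ns[levels(d$cell)]),
                      mean = unname(beta[paste0("cell", levels(d$cell))]),
                      stringsAsFactors = FALSE)

  # scale for detecting numerically degenerate (zero-variance) designs
  scale0 <- mean(abs(d$value)) + 1

  one_contrast <- function(label, cell_hi, cell_lo) {
    k_hi <- paste0("cell", cell_hi)
    k_lo <- paste0("cell", cell_lo)
    if (!k_hi %in% names(beta) || !k_lo %in% names(beta)) {
      return(comparison_row(label, NA_real_, NA_real_, NA_real_, NA_real_,
                            NA_real_, "anova_contrast",
                            NA_integer_, NA_integer_, alpha))
    }
    est <- beta[[k_hi]] - beta[[k_lo]]
    se <- sqrt(max(vc[k_hi, k_hi] + vc[k_lo, k_lo] - 2 * vc[k_hi, k_lo], 0))
    if (se <= 1e-10 * scale0) {
      degenerate_null <- abs(est) <= 1e-10 * scale0
      tval <- if (degenerate_null) 0 else Inf * sign(est)
      p <- if (degenerate_null) 1 else 0
      if (degenerate_null) est <- 0
    } else {
      tval <- est / se
      p <- 2 * stats::pt(-abs(tval), df_res)
    }
    comparison_row(label, est, tval, df_res, p, NA_real_, "anova_contrast",
                   as.integer(ns[[cell_hi]]), as.integer(ns[[cell_lo]]),
                   alpha)
  }

  planned <- list()
  if (all(c("baseline", "dofetilide") %in% conditions)) {
    for (g in groups) {
      planned[[length(planned) + 1L]] <- one_contrast(
        paste0(g, ": dofetilide vs baseline"),
        paste(g, "dofetilide", sep = "|"), paste(g, "baseline", sep = "|"))
    }
  }
  if (all(c("inducible", "non-inducible") %in% groups)) {
    for (cond in conditions) {
      planned[[length(planned) + 1L]] <- one_contrast(
        paste0(cond, ": non-inducible vs inducible"),
        paste("non-inducible", cond, sep = "|"),
        paste("inducible", cond, sep = "|"))
    }
  }
  contrasts <- do.call(rbind, planned)
  if (!is.null(contrasts)) {
    m <- nrow(contrasts)
    contrasts$p_adjusted <- bonferroni_adjust(contrasts$p_raw, m)
    contrasts$significant <- !is.na(contrasts$p_adjusted) &
      contrasts$p_adjusted < alpha
  }
  omnibus <- tryCatch({
    fit2 <- stats::lm(value ~ group * condition, data = d)
    car::Anova(fit2, type = 2)
  }, error = function(e) NULL)
  structure(list(anova = omnibus, contrasts = contrasts, cell_means = cells,
                 fit = fit),
            class = "two_way_anova")
}

#' @export
print.two_way_anova <- function(x, ...) {
  cat("Two-way ANOVA (Type II) with planned Bonferroni contrasts\n")
  if (!is.null(x$anova)) print(x$anova)
  cat("\nPlanned contrasts:\n")
  print(x$contrasts[, c("contrast", "estimate", "statistic", "df",
                        "p_raw", "p_adjusted", "significant")])
  invisible(x)
}

table1_parameters <- function() {
  c("RR" = "rr_ms", "PP" = "pp_ms", "QRS" = "qrs_ms", "QT" = "qt_ms",
    "QTc" = "qtc_ms", "JT" = "jt_ms", "JTc" = "jtc_ms",
    "LV MAP" = "lv_map_ms", "RV MAP" = "rv_map_ms",
    "Delta MAP" = "delta_map_ms", "LV STV" = "lv_stv_ms",
    "RV STV" = "rv_stv_ms", "LVdP/dt_max" = "lvdpdt_max",
    "LV EDP" = "lv_edp", "LV ESP" = "lv_esp")
}

fmt_cell <- function(mean, sd, digits, mark = "") {
  if (is.na(mean)) return("")
  paste0(formatC(round(mean, digits), format = "f", digits = digits), " ± ",
         if (is.na(sd)) "NA"
         else formatC(round(sd, digits), format = "f", digits = digits),
         mark)
}

#' Build a Table-1-style report
#'
#' One row per electrophysiological / contractile parameter with
#' "mean +/- sd" cells for inducible and non-inducible groups at baseline
#' and during dofetilide, per-parameter group sizes, and the significance
#' marks from [two_way_anova()]: `*` (p < 0.05 vs baseline, shown on the
#' dofetilide cells) and `^` (p < 0.05 vs inducible dogs, shown on the
#' non-inducible cells). Intervals are displayed as integer ms, STV with 2
#' decimals; parameters absent from the cohort are omitted with a message.
#'
#' @param animals Cohort table augmented with derived metrics (see
#'   [augment_metrics()]).
#' @param group_col Column holding the group label; must use values
#'   `"inducible"` / `"non-inducible"`.
#' @param alpha Significance level for the marks.
#' @return `data.frame` with formatted columns (`parameter`,
#'   `baseline_inducible`, `baseline_noninducible`, `dofetilide_inducible`,
#'   `dofetilide_noninducible`, `n`) plus numeric mean/sd/n columns; the
#'   full contrast table is attached as attribute `"comparisons"`.
#' @export
build_table1 <- function(animals, group_col = "phenotype_true",
                         alpha = 0.05) {
  params <- table1_parameters()
  rows <- list()
  comparisons <- list()
  for (label in names(params)) {
    colname <- params[[label]]
    if (!colname %in% names(animals)) {
      message("parameter ", label, " absent from cohort; row omitted")
      next
    }
    digits <- if (grepl("STV", label)) 2L else 0L
    d <- data.frame(value = animals[[colname]],
                    group = animals[[group_col]],
                    condition = animals$condition,
                    stringsAsFactors = FALSE)
    d <- d[stats::complete.cases(d), , drop = FALSE]
    if (nrow(d) == 0L) {
      message("parameter ", label, " has no observations; row omitted")
      next
    }
    cell_stat <- function(g, cond) {
      v <- d$value[d$group == g & d$condition == cond]
      if (length(v) == 0L) list(n = 0L, mean = NA_real_, sd = NA_real_)
      else summarize_values(v)
    }
    bi <- cell_stat("inducible", "baseline")
    bn <- cell_stat("non-inducible", "baseline")
    di <- cell_stat("inducible", "dofetilide")
    dn <- cell_stat("non-inducible", "dofetilide")
    marks <- c(star_i = FALSE, star_ni = FALSE, hat_b = FALSE, hat_d = FALSE)
    ctr <- NULL
    enough <- sum(c(bi$n, bn$n, di$n, dn$n) >= 2) >= 2
    if (enough) {
      aov2 <- tryCatch(two_way_anova(d, alpha = alpha),
                       error = function(e) NULL)
      if (!is.null(aov2) && !is.null(aov2$contrasts)) {
        ctr <- cbind(parameter = label, aov2$contrasts)
        sig <- function(lbl) {
          s <- aov2$contrasts$significant[aov2$contrasts$contrast == lbl]
          length(s) == 1L && isTRUE(s)
        }
        marks["star_i"] <- sig("inducible: dofetilide vs baseline")
        marks["star_ni"] <- sig("non-inducible: dofetilide vs baseline")
        marks["hat_b"] <- sig("baseline: non-inducible vs inducible")
        marks["hat_d"] <- sig("dofetilide: non-inducible vs inducible")
      }
    }
    rows[[label]] <- data.frame(
      parameter = label,
      baseline_inducible = fmt_cell(bi$mean, bi$sd, digits),
      baseline_noninducible = fmt_cell(bn$mean, bn$sd, digits,
                                       if (marks["hat_b"]) "^" else ""),
      dofetilide_inducible = fmt_cell(di$mean, di$sd, digits,
                                      if (marks["star_i"]) "*" else ""),
      dofetilide_noninducible = fmt_cell(
        dn$mean, dn$sd, digits,
        paste0(if (marks["star_ni"]) "*" else "",
               if (marks["hat_d"]) "^" else "")),
      n = paste0(max(bi$n, di$n), ", ", max(bn$n, dn$n)),
      mean_baseline_inducible = bi$mean, sd_baseline_inducible = bi$sd,
      n_inducible = max(bi$n, di$n),
      mean_baseline_noninducible = bn$mean, sd_baseline_noninducible = bn$sd,
      n_noninducible = max(bn$n, dn$n),
      mean_dofetilide_inducible = di$mean, sd_dofetilide_inducible = di$sd,
      mean_dofetilide_noninducible = dn$mean,
      sd_dofetilide_noninducible = dn$sd,
      stringsAsFactors = FALSE)
    if (!is.null(ctr)) comparisons[[label]] <- ctr
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(parameter = character(0), baseline_inducible = character(0),
               baseline_noninducible = character(0),
               dofetilide_inducible = character(0),
               dofetilide_noninducible = character(0), n = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "comparisons") <-
    if (length(comparisons)) do.call(rbind, comparisons) else NULL
  out
}

#' Render a Table-1-style report as markdown
#'
#' @param table1 Output of [build_table1()].
#' @return Character vector of markdown lines.
#' @export
format_table1_md <- function(table1) {
  header <- c(
    "| Parameter | Baseline I | Baseline NI | Dofetilide I | Dofetilide NI | n (I, NI) |",
    "|---|---|---|---|---|---|")
  body <- apply(table1, 1, function(r) {
    paste0("| ", r[["parameter"]], " | ", r[["baseline_inducible"]], " | ",
           r[["baseline_noninducible"]], " | ",
           r[["dofetilide_inducible"]], " | ",
           r[["dofetilide_noninducible"]], " | ", r[["n"]], " |")
  })
  c(header, if (length(body)) body else character(0),
    "",
    paste0("Mean ± SD. Two-way ANOVA with Bonferroni planned contrasts; ",
           "* p < 0.05 vs baseline, ^ p < 0.05 vs inducible."))
}

#' Inducibility fractions by stratum
#'
#' Per-stratum counts and inducible fractions, e.g. by sex or by time of
#' day.
#'
#' @param animals Cohort table (one row per animal x condition is fine; the
#'   first row per id is used).
#' @param scores Per-animal classification from [score_cohort()] (columns
#'   `animal_id`, `inducible`); when `NULL` the latent `phenotype_true`
#'   column is used.
#' @param by Stratifying column name in `animals` (default `"sex"`).
#' @return `data.frame` with `stratum`, `n`, `n_inducible`,
#'   `fraction_inducible` (NA for an empty stratum).
#' @export
inducibility_breakdown <- function(animals, scores = NULL, by = "sex") {
  first <- animals[!duplicated(animals$id), , drop = FALSE]
  inducible <- if (!is.null(scores)) {
    scores$inducible[match(first$id, scores$animal_id)]
  } else {
    first$phenotype_true == "inducible"
  }
  strata <- unique(as.character(first[[by]]))
  rows <- lapply(strata, function(s) {
    sel <- as.character(first[[by]]) == s
    n <- sum(sel)
    k <- sum(inducible[sel], na.rm = TRUE)
    data.frame(stratum = s, n = n, n_inducible = k,
               fraction_inducible = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
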