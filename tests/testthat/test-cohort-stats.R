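test_that("mean +/- SD summaries use the n-1 denominator", {
  s <- summarize_values(c(1, 2, 3))
  expect_identical(s$n, 3L)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  s1 <- summarize_values(5)
  expect_identical(s1$n, 1L)
  expect_true(is.na(s1$sd))
  expect_equal(summarize_values(rep(4.2, 10))$sd, 0)
  expect_error(summarize_values(numeric(0)), "no values")
  expect_equal(summarize_values(c(1, NA, 3))$n, 2L)
})

test_that("pooled t-test matches the closed-form oracle", {
  # independent oracle: pooled-variance formulas written out
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), length(a) + length(b) - 2)
  r <- unpaired_t_test(a, b, "student")
  expect_equal(r$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(r$statistic, -1.095445, tolerance = 1e-6)
  expect_equal(r$df, 6)
  expect_equal(r$p_raw, p_oracle, tolerance = 1e-12)
  expect_equal(r$p_raw, 0.3153336, tolerance = 1e-6)
  expect_equal(r$estimate, -1)
})

test_that("t-test degenerate and monotone behaviour", {
  a <- c(3, 1, 4, 1, 5)
  r <- unpaired_t_test(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 1)
  expect_error(unpaired_t_test(c(1), c(1, 2)), "at least 2")
  # p decreases monotonically as one group shifts away
  set.seed(81)
  base <- stats::rnorm(10)
  ps <- vapply(c(0.5, 1, 2, 4),
               function(sh) unpaired_t_test(base + sh, base)$p_raw,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # welch variant reported with fractional df
  rw <- unpaired_t_test(c(1, 2, 3, 9), c(2, 3, 4, 5), "welch")
  expect_false(rw$df == 6)
})

test_that("t-test holds its type-I error under the null", {
  set.seed(91)
  n_rep <- 1e4
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- stats::rnorm(10)
    b <- stats::rnorm(10)
    rej[i] <- unpaired_t_test(a, b)$p_raw < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("Bonferroni adjustment is min(1, m p) and never below raw", {
  p <- c(0.001, 0.04, 0.2, 0.9)
  adj <- bonferroni_adjust(p, 4)
  expect_equal(adj, pmin(1, 4 * p))
  expect_true(all(adj >= p))
  expect_equal(bonferroni_adjust(0.5, 4), 1)
})

test_that("planned contrasts match an independent cell-means oracle", {
  skip_if_not_installed("emmeans")
  set.seed(101)
  d <- data.frame(
    value = stats::rnorm(40, rep(c(10, 12, 15, 11), each = 10), 2),
    group = rep(rep(c("inducible", "non-inducible"), each = 10), 2),
    condition = rep(c("baseline", "dofetilide"), each = 20))
  # unbalance it
  d <- d[-c(1, 2, 21), ]
  a <- two_way_anova(d)
  fit <- stats::lm(value ~ group * condition, data = d)
  em <- emmeans::emmeans(fit, ~ condition | group)
  ref <- summary(emmeans::contrast(em, method = "revpairwise"),
                 adjust = "none")
  for (g in c("inducible", "non-inducible")) {
    mine <- a$contrasts[a$contrasts$contrast ==
                          paste0(g, ": dofetilide vs baseline"), ]
    theirs <- ref[ref$group == g, ]
    expect_equal(mine$estimate, theirs$estimate, tolerance = 1e-10)
    expect_equal(mine$statistic, theirs$t.ratio, tolerance = 1e-10)
    expect_equal(mine$p_raw, theirs$p.value, tolerance = 1e-10)
  }
  em2 <- emmeans::emmeans(fit, ~ group | condition)
  ref2 <- summary(emmeans::contrast(em2, method = "revpairwise"),
                  adjust = "none")
  for (cond in c("baseline", "dofetilide")) {
    mine <- a$contrasts[a$contrasts$contrast ==
                          paste0(cond, ": non-inducible vs inducible"), ]
    theirs <- ref2[ref2$condition == cond, ]
    expect_equal(mine$estimate, theirs$estimate, tolerance = 1e-10)
    expect_equal(mine$p_raw, theirs$p.value, tolerance = 1e-10)
  }
  # Bonferroni over the four planned contrasts
  expect_equal(a$contrasts$p_adjusted,
               pmin(1, 4 * a$contrasts$p_raw))
})

test_that("ANOVA contrasts handle degenerate and missing-cell designs", {
  # all observations equal: every contrast p_adjusted = 1
  d <- data.frame(value = rep(7, 20),
                  group = rep(c("inducible", "non-inducible"), 10),
                  condition = rep(c("baseline", "dofetilide"), each = 10))
  a <- two_way_anova(d)
  expect_true(all(a$contrasts$p_adjusted == 1))
  expect_true(all(!a$contrasts$significant))
  # empty cell: contrast missing, not an error
  d2 <- d[!(d$group == "non-inducible" & d$condition == "dofetilide"), ]
  d2$value <- seq_len(nrow(d2))
  a2 <- two_way_anova(d2)
  row <- a2$contrasts[a2$contrasts$contrast ==
                        "non-inducible: dofetilide vs baseline", ]
  expect_true(is.na(row$p_raw))
  expect_false(row$significant)
})

test_that("a pure condition effect is detected and no group effect invented", {
  set.seed(111)
  hits_cond <- 0L
  hits_group <- 0L
  n_sim <- 40L
  for (i in seq_len(n_sim)) {
    d <- data.frame(
      value = c(stats::rnorm(40, 0, 1), stats::rnorm(40, 3, 1)),
      group = rep(rep(c("inducible", "non-inducible"), each = 20), 2),
      condition = rep(c("baseline", "dofetilide"), each = 40))
    a <- two_way_anova(d)
    ct <- a$contrasts
    hits_cond <- hits_cond +
      all(ct$significant[grepl("dofetilide vs baseline", ct$contrast)])
    hits_group <- hits_group +
      any(ct$significant[grepl("non-inducible vs inducible", ct$contrast)])
  }
  # 3 SD condition effect at n = 20/cell: essentially always detected
  expect_gte(hits_cond / n_sim, 0.95)
  # spurious group differences stay near the Bonferroni-controlled rate
  expect_lte(hits_group / n_sim, 0.2)
})

test_that("Table-1-style report has the expected layout and marks", {
  co <- sample_cohort(generator_config(58, n_inducible = 40, seed = 121))
  m <- augment_metrics(co$animals)
  tab <- build_table1(m)
  expect_true(all(c("RR", "QT", "QTc", "JT", "JTc", "LV STV",
                    "LVdP/dt_max", "LV ESP") %in% tab$parameter))
  expect_match(tab$n[tab$parameter == "RR"], "^40, 18$")
  # formatted cells look like "mean ± sd" with optional marks
  expect_match(tab$baseline_inducible,
               "^[0-9]+(\\.[0-9]{2})? ± [0-9]+(\\.[0-9]{2})?$")
  expect_match(tab$dofetilide_inducible,
               "^[0-9]+(\\.[0-9]{2})? ± [0-9]+(\\.[0-9]{2})?\\*?$")
  cmp <- attr(tab, "comparisons")
  expect_true(all(c("parameter", "contrast", "p_adjusted") %in% names(cmp)))
  md <- format_table1_md(tab)
  expect_match(md[1], "^\\| Parameter")
  expect_length(md, nrow(tab) + 4L)
})

test_that("Table-1 report edge cases: empty and constant cohorts", {
  co <- sample_cohort(generator_config(0, seed = 1))
  m <- augment_metrics(co$animals)
  suppressMessages(tab <- build_table1(m))
  expect_identical(nrow(tab), 0L)
  # constant cohort: all sd cells 0
  an <- data.frame(
    id = rep(c("a", "b", "c", "d"), each = 2), sex = "female",
    age_months = 17, body_weight_kg = 20,
    condition = rep(c("baseline", "dofetilide"), 4),
    rr_ms = 1200, pp_ms = NA_real_, qrs_ms = 90, qt_ms = 400,
    jt_ms = 310, lv_map_ms = NA_real_, rv_map_ms = NA_real_,
    lv_stv_ms = NA_real_, rv_stv_ms = NA_real_, lvdpdt_max = NA_real_,
    lv_edp = NA_real_, lv_esp = NA_real_,
    phenotype_true = rep(c("inducible", "inducible", "non-inducible",
                           "non-inducible"), 2),
    stringsAsFactors = FALSE)
  suppressMessages(tab2 <- build_table1(augment_metrics(an)))
  expect_match(tab2$baseline_inducible[tab2$parameter == "RR"],
               "1200 ± 0")
})

test_that("inducibility breakdown stratifies counts and fractions", {
  an <- data.frame(
    id = rep(sprintf("d%02d", 1:6), each = 2),
    sex = rep(c("female", "female", "female", "male", "male", "male"),
              each = 2),
    condition = rep(c("baseline", "dofetilide"), 6),
    phenotype_true = rep(c("inducible", "inducible", "non-inducible",
                           "inducible", "non-inducible", "non-inducible"),
                         each = 2),
    stringsAsFactors = FALSE)
  bd <- inducibility_breakdown(an)
  expect_equal(bd$fraction_inducible[bd$stratum == "female"], 2 / 3)
  expect_equal(bd$fraction_inducible[bd$stratum == "male"], 1 / 3)
  # all-inducible cohort: every stratum 100%
  an2 <- an
  an2$phenotype_true <- "inducible"
  expect_true(all(inducibility_breakdown(an2)$fraction_inducible == 1))
  # classified scores override the latent label
  sc <- data.frame(animal_id = sprintf("d%02d", 1:6),
                   inducible = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  bd3 <- inducibility_breakdown(an, sc)
  expect_equal(bd3$fraction_inducible, c(1, 0))
})
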