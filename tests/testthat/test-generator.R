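test_that("generator configuration is validated field by field", {
  expect_error(generator_config(-1), "n_animals")
  expect_error(generator_config(10, p_inducible = 1.2), "p_inducible")
  expect_error(generator_config(10, window_s = -5), "window_s")
  expect_error(generator_config(10, beats_per_series = 1), "beats_per_series")
  expect_error(generator_config(10, lag1_rho = 2), "lag1_rho")
  expect_error(generator_config(10, n_inducible = 11), "n_inducible")
  tp <- default_trait_params()
  tp$sd[3] <- -1
  expect_error(generator_config(10, trait_params = tp), "sd")
})

test_that("degenerate cohort sizes behave", {
  co <- sample_cohort(generator_config(0, seed = 1))
  expect_identical(nrow(co$animals), 0L)
  expect_identical(nrow(co$events), 0L)
  co1 <- sample_cohort(generator_config(1000, p_inducible = 1, seed = 2))
  expect_true(all(co1$animals$phenotype_true == "inducible"))
  co0 <- sample_cohort(generator_config(50, p_inducible = 0, seed = 3))
  expect_true(all(co0$animals$phenotype_true == "non-inducible"))
})

test_that("cohort generation is deterministic given the seed", {
  a <- sample_cohort(generator_config(25, seed = 77))
  b <- sample_cohort(generator_config(25, seed = 77))
  expect_identical(a, b)
  c <- sample_cohort(generator_config(25, seed = 78))
  expect_false(identical(a, c))
})

test_that("phenotype prevalence follows the binomial at p = 0.75", {
  co <- sample_cohort(generator_config(78, p_inducible = 0.75, seed = 11))
  ph <- co$animals$phenotype_true[!duplicated(co$animals$id)]
  frac <- mean(ph == "inducible")
  se <- sqrt(0.75 * 0.25 / 78)
  expect_lt(abs(frac - 0.75), 3 * se)
})

test_that("truncated-normal draws respect bound, zero-variance and LLN", {
  expect_equal(sample_trait(407, 0, 0), 407)
  expect_error(sample_trait(-1, 0, 0), "truncation")
  set.seed(5)
  x <- sample_trait(407, 68, 0, n = 1e4)
  # truncation negligible here: untruncated normal is the oracle
  expect_lt(abs(mean(x) - 407), 3 * 68 / 100)
  set.seed(6)
  y <- sample_trait(1.70, 1.24, 0, n = 1e4)
  expect_true(all(y >= 0))
})

test_that("calibrated locations give truncated normals with the target mean", {
  # analytic check of the location solver
  for (cell in list(c(1.70, 1.24), c(0.80, 0.42), c(3.79, 2.41))) {
    loc <- tn_location(cell[1], cell[2], 0)
    a <- (0 - loc) / cell[2]
    m <- loc + cell[2] * dnorm(a) / (1 - pnorm(a))
    expect_equal(m, cell[1], tolerance = 1e-8)
    expect_lte(loc, cell[1])
  }
  # no-op when truncation is negligible
  expect_equal(tn_location(407, 68, 0), 407)
  expect_error(tn_location(-1, 1, 0), "exceed")
})

test_that("trait cell means are recovered across the parameter table", {
  n <- 4000L
  co_i <- sample_cohort(generator_config(n, n_inducible = n, seed = 21))
  co_n <- sample_cohort(generator_config(n, n_inducible = 0L, seed = 22))
  tp <- default_trait_params()
  check <- c("rr_ms", "qt_ms", "lv_map_ms", "lv_stv_ms", "rv_stv_ms",
             "lvdpdt_max", "lv_edp", "lv_esp")
  for (ph in c("inducible", "non-inducible")) {
    an <- if (ph == "inducible") co_i$animals else co_n$animals
    for (cond in c("baseline", "dofetilide")) {
      sub <- an[an$condition == cond, ]
      for (p in check) {
        cell <- tp[tp$parameter == p & tp$phenotype == ph &
                     !is.na(tp$condition) & tp$condition == cond, ]
        v <- sub[[p]][!is.na(sub[[p]])]
        se <- cell$sd / sqrt(length(v))
        expect_lt(abs(mean(v) - cell$mean), 3 * se,
                  label = paste(p, ph, cond, "mean"))
      }
    }
  }
})

test_that("dofetilide shifts point the published direction in expectation", {
  co <- sample_cohort(generator_config(600, seed = 31))
  an <- co$animals
  up <- c("rr_ms", "qt_ms", "jt_ms", "lv_map_ms", "rv_map_ms",
          "lv_stv_ms", "rv_stv_ms", "lvdpdt_max", "lv_esp")
  b <- an[an$condition == "baseline", ]
  d <- an[an$condition == "dofetilide", ]
  for (p in up) {
    expect_gt(mean(d[[p]], na.rm = TRUE), mean(b[[p]], na.rm = TRUE),
              label = paste(p, "dofetilide > baseline"))
  }
  m <- augment_metrics(an)
  mb <- m[m$condition == "baseline", ]
  md <- m[m$condition == "dofetilide", ]
  for (p in c("qtc_ms", "jtc_ms")) {
    expect_gt(mean(md[[p]], na.rm = TRUE), mean(mb[[p]], na.rm = TRUE),
              label = paste(p, "dofetilide > baseline"))
  }
})

test_that("per-parameter missingness mirrors the reference sample sizes", {
  n <- 2000L
  co <- sample_cohort(generator_config(n, n_inducible = n, seed = 41))
  b <- co$animals[co$animals$condition == "baseline", ]
  miss <- default_missingness()
  for (p in c("pp_ms", "lv_map_ms", "lv_stv_ms", "lvdpdt_max")) {
    frac <- miss$frac_inducible[miss$parameter == p]
    got <- mean(!is.na(b[[p]]))
    se <- sqrt(frac * (1 - frac) / n)
    expect_lt(abs(got - frac), 4 * se, label = paste(p, "observed fraction"))
  }
  # both conditions of an animal share the observation pattern (paired)
  d <- co$animals[co$animals$condition == "dofetilide", ]
  expect_identical(is.na(b$lvdpdt_max), is.na(d$lvdpdt_max))
})

test_that("beat series hit the STV calibration and preserve the mean", {
  set.seed(51)
  expect_equal(synth_beat_series(306, 0, rho = 0.3), rep(306, 31))
  expect_error(synth_beat_series(306, 1.7, rho = 1), "rho")
  expect_error(synth_beat_series(306, -1), "target_stv_ms")
  # calibration: mean computed STV within 5% of target over 2000 series
  for (rho in c(0, 0.5)) {
    set.seed(52)
    s <- replicate(2000, stv(synth_beat_series(306, 1.70, rho, 31)))
    expect_lt(abs(mean(s) - 1.70) / 1.70, 0.05,
              label = paste("STV calibration at rho", rho))
  }
  # mean preservation within 3 sigma/sqrt(n)
  sigma <- 1.70 * sqrt(pi / (2 * (1 - 0.3)))
  set.seed(53)
  ser <- synth_beat_series(306, 1.70, 0.3, 31)
  expect_lt(abs(mean(ser) - 306), 3 * sigma / sqrt(31) * 3)
})

test_that("event logs obey phenotype contracts and window semantics", {
  expect_identical(nrow(synth_event_log("inducible", window_s = 0)), 0L)
  ep0 <- default_event_params()
  ep0$rates[["non-inducible"]]["tdp_self_terminating"] <- 0
  set.seed(61)
  for (k in 1:20) {
    ev <- synth_event_log("non-inducible", ep0)
    expect_identical(count_tdp_episodes(ev), 0L)
  }
  # onsets within window and sorted
  set.seed(62)
  ev <- synth_event_log("inducible")
  expect_true(all(ev$onset_s >= 0 & ev$onset_s <= 600))
  expect_false(is.unsorted(ev$onset_s))
  # classification contract: >= 0.95 each way over 1000 logs
  set.seed(63)
  ind <- replicate(1000, classify_inducible(synth_event_log("inducible")))
  expect_gte(mean(ind == "inducible"), 0.95)
  set.seed(64)
  ni <- replicate(1000, classify_inducible(synth_event_log("non-inducible")))
  expect_gte(mean(ni == "non-inducible"), 0.95)
})

test_that("downstream classification recovers the latent phenotype", {
  co <- sample_cohort(generator_config(1000, seed = 71))
  sc <- score_cohort(co$events, unique(co$animals$id))
  ph <- co$animals$phenotype_true[!duplicated(co$animals$id)]
  agree <- mean((ph == "inducible") == sc$inducible)
  expect_gte(agree, 0.95)
})
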