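#' Default trait parameterization for the synthetic CAVB cohort
#'
#' Phenotype- and condition-specific mean/SD/lower-truncation parameters for
#' every generated trait. Electrophysiological and contractile cells carry
#' the published group summaries for inducible vs non-inducible CAVB dogs at
#' baseline and during dofetilide; intervals are in ms, LVdP/dt_max in
#' mmHg/s, pressures in mmHg, age in months, body weight in kg, cellular
#' APD90/STV in ms. Body-weight and organ-ratio parameters are not published
#' as numbers and are set to realistic values for adult mongrel dogs.
#'
#' @return `data.frame` with columns `parameter`, `phenotype`, `condition`
#'   (`NA` for condition-invariant traits), `mean`, `sd`, `lower`.
#' @export
default_trait_params <- function() {
  cell <- function(parameter, phenotype, condition, mean, sd, lower = 0) {
    data.frame(parameter = parameter, phenotype = phenotype,
               condition = condition, mean = mean, sd = sd, lower = lower,
               stringsAsFactors = FALSE)
  }
  both <- function(parameter, i_b, i_b_sd, ni_b, ni_b_sd,
                   i_d, i_d_sd, ni_d, ni_d_sd, lower = 0) {
    rbind(cell(parameter, "inducible", "baseline", i_b, i_b_sd, lower),
          cell(parameter, "non-inducible", "baseline", ni_b, ni_b_sd, lower),
          cell(parameter, "inducible", "dofetilide", i_d, i_d_sd, lower),
          cell(parameter, "non-inducible", "dofetilide", ni_d, ni_d_sd, lower))
  }
  fixed <- function(parameter, i_m, i_sd, ni_m, ni_sd, lower = 0) {
    rbind(cell(parameter, "inducible", NA_character_, i_m, i_sd, lower),
          cell(parameter, "non-inducible", NA_character_, ni_m, ni_sd, lower))
  }
  rbind(
    both("rr_ms",       1405, 280, 1295, 157, 1550, 294, 1510, 191),
    both("pp_ms",        543,  74,  574,  68,  635,  98,  704, 127),
    both("qrs_ms",        95,  19,   91,  17,   96,  21,   96,  17),
    both("qt_ms",        443,  75,  364,  40,  613, 102,  607,  69),
    both("lv_map_ms",    306,  50,  288,  20,  479, 118,  485,  98),
    both("rv_map_ms",    260,  37,  250,  29,  361,  99,  400,  78),
    both("lv_stv_ms",   1.70, 1.24, 0.80, 0.42, 3.57, 1.92, 2.54, 1.04),
    both("rv_stv_ms",   1.25, 0.99, 0.76, 0.18, 2.99, 1.70, 3.79, 2.41),
    both("lvdpdt_max",  2047, 416, 1368, 205, 2724, 520, 2474, 554),
    both("lv_edp",        11,   6,    8,   5,   12,   5,    9,   3),
    both("lv_esp",        91,   8,   85,  11,  100,   7,  102,   9),
    fixed("age_months",      16.9, 4.9, 17.4, 6.8, lower = 6),
    fixed("body_weight_kg",  23.5, 3.5, 21.5, 3.0, lower = 10),
    fixed("hw_bw_g_kg",       8.5, 1.2,  8.5, 1.2, lower = 4),
    fixed("lungw_bw_g_kg",    9.0, 1.5,  9.0, 1.5, lower = 4),
    fixed("liverw_bw_g_kg",  28.0, 4.0, 28.0, 4.0, lower = 12),
    fixed("apd90_lv_ms",     439,  72,  390,  63),
    fixed("apd90_rv_ms",     434, 128,  381,  64),
    fixed("apd_stv_lv_ms",    37,  20,   25,  11),
    fixed("apd_stv_rv_ms",    49,  61,   15,   6))
}

#' Default per-parameter observation fractions
#'
#' Hemodynamic and cellular measurements exist only for subsets of a cohort;
#' these fractions mirror the per-parameter sample sizes of the reference
#' cohort (40 inducible, 18 non-inducible dogs for the electrophysiology
#' block) so that downstream statistics are exercised on unbalanced designs.
#'
#' @return `data.frame` with columns `parameter`, `frac_inducible`,
#'   `frac_noninducible`.
#' @export
default_missingness <- function() {
  m <- function(parameter, n_i, n_ni, ref_i = 40, ref_ni = 18) {
    data.frame(parameter = parameter, frac_inducible = n_i / ref_i,
               frac_noninducible = n_ni / ref_ni, stringsAsFactors = FALSE)
  }
  rbind(m("rr_ms", 40, 18), m("pp_ms", 28, 15), m("qrs_ms", 39, 18),
        m("qt_ms", 40, 18), m("lv_map_ms", 27, 9), m("rv_map_ms", 23, 10),
        m("lv_stv_ms", 26, 9), m("rv_stv_ms", 15, 7),
        m("lvdpdt_max", 10, 5), m("lv_edp", 13, 4), m("lv_esp", 13, 4),
        m("apd90_lv_ms", 14, 12), m("apd90_rv_ms", 14, 12),
        m("apd_stv_lv_ms", 13, 11), m("apd_stv_rv_ms", 13, 11))
}

#' Default arrhythmic-event process rates
#'
#' Expected event counts per phenotype over the 600-s proarrhythmic window,
#' one homogeneous Poisson process per event class. Rates are chosen so that
#' an inducible animal shows >= 3 TdP episodes, and a non-inducible animal
#' <= 2, each with probability >= 0.95 — inducible CAVB dogs typically show
#' many repetitive TdP episodes under dofetilide while non-inducible dogs
#' show at most sporadic ones.
#'
#' @return Named list with per-phenotype rate vectors plus the `run_beats`
#'   ranges for multiple-ectopic runs and TdP episodes.
#' @export
default_event_params <- function() {
  list(
    rates = list(
      "inducible" = c(single_ectopic = 10, multiple_ectopic = 5,
                      tdp_self_terminating = 8, tdp_defibrillated = 0.5),
      "non-inducible" = c(single_ectopic = 5, multiple_ectopic = 1.5,
                          tdp_self_terminating = 0.5, tdp_defibrillated = 0)),
    multiple_run_beats = c(2L, 4L),
    tdp_run_beats = c(5L, 30L),
    defib_probs = c(0.6, 0.3, 0.1))
}

#' Generator configuration for a synthetic CAVB cohort
#'
#' @param n_animals Number of animals (>= 0).
#' @param p_inducible Probability an animal carries the inducible phenotype
#'   (default 0.75, the prevalence of dofetilide-induced TdP in the model).
#' @param seed Integer master seed; per-animal substreams are derived from it
#'   (see Details).
#' @param n_inducible Optional fixed number of inducible animals; when given,
#'   exactly `n_inducible` of `n_animals` are inducible (phenotype order
#'   randomized) and `p_inducible` is ignored.
#' @param trait_params Trait parameter table, see [default_trait_params()].
#' @param event_params Event process parameters, see [default_event_params()].
#' @param missingness Per-parameter observation fractions, see
#'   [default_missingness()].
#' @param window_s Proarrhythmic window duration in seconds (default 600).
#' @param beats_per_series Beats per generated MAP series (default 31, the
#'   STV convention).
#' @param lag1_rho Lag-1 autocorrelation of generated beat series in
#'   \[-1, 1\] (default 0.3, a modest beat-to-beat memory).
#' @param within_rho Latent within-animal correlation between the baseline
#'   and dofetilide value of a trait (default 0.7); the paired draws go
#'   through a Gaussian copula so both marginal mean/SD columns are
#'   preserved.
#' @param qt_rr_rho Latent correlation between QT and RR within a condition
#'   (default 0.5): QT tracks cycle length physiologically, and without it
#'   the dispersion of derived QTc would exceed the published one.
#' @param male_weight_offset_kg Added to body weight for males (default 2).
#'
#' @details Reproducibility uses a master-seed / substream scheme: cohort
#' level draws (phenotypes, sexes) consume `seed` itself, then animal `i`
#' uses substream seed `(seed + 1000003 * i) mod (2^31 - 1)`, so a record
#' can be regenerated without replaying the whole cohort.
#'
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_animals,
                             p_inducible = 0.75,
                             seed = 1L,
                             n_inducible = NULL,
                             trait_params = default_trait_params(),
                             event_params = default_event_params(),
                             missingness = default_missingness(),
                             window_s = 600,
                             beats_per_series = 31L,
                             lag1_rho = 0.3,
                             within_rho = 0.7,
                             qt_rr_rho = 0.5,
                             male_weight_offset_kg = 2) {
  if (!is.numeric(n_animals) || length(n_animals) != 1L || is.na(n_animals) ||
      n_animals < 0 || n_animals != round(n_animals)) {
    stop("invalid `n_animals`: must be a nonnegative integer", call. = FALSE)
  }
  if (!is.numeric(p_inducible) || is.na(p_inducible) ||
      p_inducible < 0 || p_inducible > 1) {
    stop("invalid `p_inducible`: must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(n_inducible) &&
      (n_inducible < 0 || n_inducible > n_animals)) {
    stop("invalid `n_inducible`: must lie in [0, n_animals]", call. = FALSE)
  }
  if (!is.numeric(window_s) || is.na(window_s) || window_s < 0) {
    stop("invalid `window_s`: must be >= 0", call. = FALSE)
  }
  if (beats_per_series < 2L) {
    stop("invalid `beats_per_series`: must be >= 2", call. = FALSE)
  }
  if (!is.numeric(lag1_rho) || is.na(lag1_rho) ||
      lag1_rho < -1 || lag1_rho > 1) {
    stop("invalid `lag1_rho`: must lie in [-1, 1]", call. = FALSE)
  }
  if (any(trait_params$sd < 0)) {
    stop("invalid `trait_params`: all sd must be >= 0", call. = FALSE)
  }
  for (r in c(within_rho, qt_rr_rho)) {
    if (!is.numeric(r) || is.na(r) || r < -1 || r > 1) {
      stop("invalid correlation: `within_rho` and `qt_rr_rho` must lie in ",
           "[-1, 1]", call. = FALSE)
    }
  }
  structure(list(n_animals = as.integer(n_animals),
                 p_inducible = p_inducible,
                 seed = as.integer(seed),
                 n_inducible = if (is.null(n_inducible)) NULL
                               else as.integer(n_inducible),
                 trait_params = trait_params,
                 event_params = event_params,
                 missingness = missingness,
                 window_s = window_s,
                 beats_per_series = as.integer(beats_per_series),
                 lag1_rho = lag1_rho,
                 within_rho = within_rho,
                 qt_rr_rho = qt_rr_rho,
                 male_weight_offset_kg = male_weight_offset_kg),
            class = "generator_config")
}

substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * i) %% (2^31 - 1))
}

#' Location parameter matching a target truncated-normal mean
#'
#' A normal truncated below has a mean above its location parameter, so a
#' generator that must reproduce a published sample mean from nonnegative
#' data needs the location calibrated: this solves for `loc` such that
#' `E[TruncNormal(loc, sd, lower)] = target_mean`.
#'
#' @param target_mean Desired post-truncation mean (must exceed `lower`).
#' @param sd Standard deviation of the untruncated normal (>= 0).
#' @param lower Lower truncation bound.
#' @return Location (mean of the untruncated parent).
#' @export
tn_location <- function(target_mean, sd, lower = -Inf) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (!is.finite(lower) || sd == 0) return(target_mean)
  if (target_mean <= lower) {
    stop("`target_mean` must exceed `lower`", call. = FALSE)
  }
  # truncation negligible beyond ~6 sigma
  if (stats::pnorm((lower - target_mean) / sd) < 1e-9) return(target_mean)
  tn_mean <- function(loc) {
    a <- (lower - loc) / sd
    loc + sd * exp(stats::dnorm(a, log = TRUE) -
                     stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  }
  stats::uniroot(function(loc) tn_mean(loc) - target_mean,
                 lower = target_mean - 8 * sd - 1,
                 upper = target_mean, tol = 1e-10)$root
}

# quantile transform: standard-normal draw -> truncated normal draw
ztn <- function(z, loc, sd, lower) {
  if (sd == 0) return(loc)
  if (!is.finite(lower)) return(loc + sd * z)
  p_lo <- stats::pnorm(lower, loc, sd)
  if (p_lo < 1e-12) return(max(loc + sd * z, lower))
  u <- p_lo + stats::pnorm(z) * (1 - p_lo)
  max(stats::qnorm(u, loc, sd), lower)
}

#' Draw from a lower-truncated normal distribution
#'
#' Inverse-CDF sampling from `Normal(mean, sd)` truncated below at `lower`.
#' With `sd = 0` the mean is returned (and `mean < lower` is an error).
#' Consumes the current R random-number stream.
#'
#' @param mean,sd Mean and standard deviation of the untruncated normal.
#' @param lower Lower truncation bound (`-Inf` for no truncation).
#' @param n Number of draws.
#' @return Numeric vector of `n` draws, all `>= lower`.
#' @export
sample_trait <- function(mean, sd, lower = -Inf, n = 1L) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (sd == 0) {
    if (mean < lower) {
      stop("degenerate draw below truncation bound: mean < lower with sd = 0",
           call. = FALSE)
    }
    return(rep(mean, n))
  }
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  pmax(stats::qnorm(u, mean, sd), lower)
}

trait_cell <- function(trait_params, parameter, phenotype, condition = NA) {
  sel <- trait_params$parameter == parameter &
    trait_params$phenotype == phenotype &
    (if (is.na(condition)) is.na(trait_params$condition)
     else !is.na(trait_params$condition) & trait_params$condition == condition)
  row <- trait_params[sel, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("trait_params has ", nrow(row), " rows for (", parameter, ", ",
         phenotype, ", ", condition, ")", call. = FALSE)
  }
  row
}

# Paired baseline -> dofetilide draw through a Gaussian copula: both
# marginals are truncated normals whose locations are calibrated so the
# post-truncation means hit the configured cell means exactly, and the
# within-animal pairing comes from correlated latent normals (rho_w). This
# matches both marginal (mean, sd) columns even where the dofetilide SD is
# smaller than the baseline SD, which an additive independent shift cannot.
sample_paired_trait <- function(base_row, dof_row, rho_w) {
  z_b <- stats::rnorm(1)
  z_d <- rho_w * z_b + sqrt(1 - rho_w^2) * stats::rnorm(1)
  c(baseline = ztn(z_b, base_row$loc, base_row$sd, base_row$lower),
    dofetilide = ztn(z_d, dof_row$loc, dof_row$sd, dof_row$lower))
}

#' Simulate one animal's arrhythmic-event log
#'
#' Event onsets follow one homogeneous Poisson process per event class over
#' the proarrhythmic window, with phenotype-specific rates; TdP episode
#' lengths are uniform on a configured beat range and defibrillation counts
#' are drawn from a configured distribution. Consumes the current R
#' random-number stream.
#'
#' @param phenotype `"inducible"` or `"non-inducible"`.
#' @param event_params See [default_event_params()].
#' @param window_s Window duration in seconds; 0 gives an empty log.
#' @return Event `data.frame` (columns `onset_s`, `kind`, `run_beats`,
#'   `n_defibs`) sorted by onset.
#' @export
synth_event_log <- function(phenotype = c("inducible", "non-inducible"),
                            event_params = default_event_params(),
                            window_s = 600) {
  phenotype <- match.arg(phenotype)
  if (window_s < 0) stop("`window_s` must be >= 0", call. = FALSE)
  empty <- data.frame(onset_s = numeric(0), kind = character(0),
                      run_beats = integer(0), n_defibs = integer(0),
                      stringsAsFactors = FALSE)
  if (window_s == 0) return(empty)
  rates <- event_params$rates[[phenotype]] * (window_s / 600)
  onset <- numeric(0); kinds <- character(0)
  run_beats <- integer(0); n_defibs <- integer(0)
  for (kind in names(rates)) {
    n <- stats::rpois(1, rates[[kind]])
    if (n == 0L) next
    rb <- switch(kind,
      single_ectopic = rep(1L, n),
      multiple_ectopic = sample(
        seq(event_params$multiple_run_beats[1],
            event_params$multiple_run_beats[2]), n, replace = TRUE),
      sample(seq(event_params$tdp_run_beats[1],
                 event_params$tdp_run_beats[2]), n, replace = TRUE))
    nd <- if (kind == "tdp_defibrillated") {
      sample(1:3, n, replace = TRUE, prob = event_params$defib_probs)
    } else rep(0L, n)
    onset <- c(onset, stats::runif(n, 0, window_s))
    kinds <- c(kinds, rep(kind, n))
    run_beats <- c(run_beats, as.integer(rb))
    n_defibs <- c(n_defibs, as.integer(nd))
  }
  if (length(onset) == 0L) return(empty)
  o <- order(onset)
  data.frame(onset_s = onset[o], kind = kinds[o], run_beats = run_beats[o],
             n_defibs = n_defibs[o], stringsAsFactors = FALSE)
}

#' Simulate a beat-to-beat repolarization series with a target STV
#'
#' Generates a stationary AR(1) series with the requested mean whose
#' innovation scale is calibrated so that the expected value of the STV
#' statistic equals `target_stv_ms`. For an AR(1) process with marginal SD
#' \eqn{\sigma} and lag-1 correlation \eqn{\rho}, successive differences are
#' normal with SD \eqn{\sigma\sqrt{2(1-\rho)}}, so
#' \eqn{E|D_{n+1}-D_n| = 2\sigma\sqrt{(1-\rho)/\pi}} and
#' \eqn{E[STV] = \sigma\sqrt{2(1-\rho)/\pi}}; the generator inverts this:
#' \eqn{\sigma = STV \sqrt{\pi / (2(1-\rho))}}. Consumes the current R
#' random-number stream.
#'
#' @param mean_ms Series mean (ms).
#' @param target_stv_ms Target expected STV (ms, >= 0).
#' @param rho Lag-1 autocorrelation in \[-1, 1\]; `rho = 1` with a positive
#'   target is an error (a constant series has STV 0).
#' @param n_beats Series length (>= 2).
#' @return Numeric vector of `n_beats` durations in ms.
#' @export
synth_beat_series <- function(mean_ms, target_stv_ms, rho = 0.3,
                              n_beats = 31L) {
  if (n_beats < 2L) stop("`n_beats` must be >= 2", call. = FALSE)
  if (target_stv_ms < 0) stop("`target_stv_ms` must be >= 0", call. = FALSE)
  if (rho < -1 || rho > 1) stop("`rho` must lie in [-1, 1]", call. = FALSE)
  if (target_stv_ms == 0) return(rep(mean_ms, n_beats))
  if (rho == 1) {
    stop("`rho` = 1 cannot realize a positive target STV", call. = FALSE)
  }
  sigma <- target_stv_ms * sqrt(pi / (2 * (1 - rho)))
  innov_sd <- sigma * sqrt(1 - rho^2)
  x <- numeric(n_beats)
  x[1] <- stats::rnorm(1, 0, sigma)
  for (i in seq_len(n_beats - 1L)) {
    x[i + 1L] <- rho * x[i] + stats::rnorm(1, 0, innov_sd)
  }
  mean_ms + x
}

animals_schema_cols <- function() {
  c("id", "sex", "age_months", "body_weight_kg", "condition",
    "rr_ms", "pp_ms", "qrs_ms", "qt_ms", "jt_ms",
    "lv_map_ms", "rv_map_ms", "lv_stv_ms", "rv_stv_ms",
    "lvdpdt_max", "lv_edp", "lv_esp", "phenotype_true")
}

# fast lookup of calibrated trait cells: key "parameter|phenotype|condition"
trait_lut <- function(tp) {
  keys <- paste(tp$parameter, tp$phenotype,
                ifelse(is.na(tp$condition), "fixed", tp$condition),
                sep = "|")
  lut <- vector("list", nrow(tp))
  for (i in seq_len(nrow(tp))) {
    lut[[i]] <- list(loc = tp$loc[i], sd = tp$sd[i], lower = tp$lower[i])
  }
  names(lut) <- keys
  lut
}

# one animal's draws as a flat numeric vector:
# bw, fixed traits, baseline cond traits, dofetilide cond traits
sample_animal <- function(config, lut, chol4, phenotype, sex, observed) {
  cond_params <- c("rr_ms", "pp_ms", "qrs_ms", "qt_ms", "lv_map_ms",
                   "rv_map_ms", "lv_stv_ms", "rv_stv_ms", "lvdpdt_max",
                   "lv_edp", "lv_esp")
  fixed_params <- c("age_months", "hw_bw_g_kg", "lungw_bw_g_kg",
                    "liverw_bw_g_kg", "apd90_lv_ms", "apd90_rv_ms",
                    "apd_stv_lv_ms", "apd_stv_rv_ms")
  cell <- function(p, cond = "fixed") lut[[paste(p, phenotype, cond,
                                                 sep = "|")]]
  bw_row <- cell("body_weight_kg")
  bw_loc <- bw_row$loc +
    if (sex == "male") config$male_weight_offset_kg else 0
  bw <- ztn(stats::rnorm(1), bw_loc, bw_row$sd, bw_row$lower)
  fixed <- vapply(fixed_params, function(p) {
    row <- cell(p)
    ztn(stats::rnorm(1), row$loc, row$sd, row$lower)
  }, numeric(1))
  # RR and QT share latent correlation (qt_rr_rho) within each condition,
  # so that derived QTc reproduces the published QTc dispersion; the four
  # latents (rr_b, qt_b, rr_d, qt_d) have the Kronecker covariance of the
  # within-animal and cross-parameter correlations.
  z4 <- as.vector(chol4 %*% stats::rnorm(4))
  rr_b_row <- cell("rr_ms", "baseline")
  rr_d_row <- cell("rr_ms", "dofetilide")
  qt_b_row <- cell("qt_ms", "baseline")
  qt_d_row <- cell("qt_ms", "dofetilide")
  rr_qt <- cbind(
    rr_ms = c(ztn(z4[1], rr_b_row$loc, rr_b_row$sd, rr_b_row$lower),
              ztn(z4[3], rr_d_row$loc, rr_d_row$sd, rr_d_row$lower)),
    qt_ms = c(ztn(z4[2], qt_b_row$loc, qt_b_row$sd, qt_b_row$lower),
              ztn(z4[4], qt_d_row$loc, qt_d_row$sd, qt_d_row$lower)))
  other <- setdiff(cond_params, c("rr_ms", "qt_ms"))
  paired <- vapply(other, function(p) {
    sample_paired_trait(cell(p, "baseline"), cell(p, "dofetilide"),
                        config$within_rho)
  }, numeric(2))
  paired <- cbind(paired, rr_qt)[, cond_params, drop = FALSE]
  # apply per-parameter missingness
  for (p in names(observed)) {
    if (!observed[[p]]) {
      if (p %in% cond_params) paired[, p] <- NA_real_
      if (p %in% names(fixed)) fixed[[p]] <- NA_real_
    }
  }
  c(bw = bw, fixed, stats::setNames(paired[1, ], paste0("b_", cond_params)),
    stats::setNames(paired[2, ], paste0("d_", cond_params)))
}

#' Simulate a synthetic CAVB-dog cohort
#'
#' Draws phenotypes (Bernoulli with prevalence `p_inducible`, or fixed group
#' sizes via `n_inducible`), per-animal traits from phenotype/condition
#' specific truncated normals with paired baseline-to-dofetilide shifts,
#' per-parameter missingness mirroring the reference cohort's unbalanced
#' sample sizes, and one arrhythmic-event log per animal. Fully
#' deterministic given the configuration (including its seed).
#'
#' @param config A [generator_config()].
#' @return List of class `"tdp_cohort"` with elements `animals` (long
#'   `data.frame`, one row per animal x condition) and `events` (long event
#'   `data.frame` with `animal_id`).
#' @export
#' @examples
#' cohort <- sample_cohort(generator_config(10, seed = 42))
#' table(unique(cohort$animals[c("id", "phenotype_true")])$phenotype_true)
sample_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_animals
  empty_events <- data.frame(animal_id = character(0), onset_s = numeric(0),
                             kind = character(0), run_beats = integer(0),
                             n_defibs = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    empty <- sample_cohort(generator_config(1, seed = config$seed))
    return(structure(list(animals = empty$animals[0, , drop = FALSE],
                          events = empty_events),
                     class = "tdp_cohort"))
  }
  set.seed(config$seed)
  phenotypes <- if (!is.null(config$n_inducible)) {
    sample(rep(c("inducible", "non-inducible"),
               c(config$n_inducible, n - config$n_inducible)))
  } else {
    ifelse(stats::runif(n) < config$p_inducible, "inducible", "non-inducible")
  }
  sexes <- ifelse(stats::runif(n) < 27 / 61, "male", "female")
  miss <- config$missingness
  # calibrate truncated-normal locations once per cohort
  tp <- config$trait_params
  tp$loc <- vapply(seq_len(nrow(tp)), function(i) {
    tn_location(tp$mean[i], tp$sd[i], tp$lower[i])
  }, numeric(1))
  lut <- trait_lut(tp)
  # latent covariance for (rr_b, qt_b, rr_d, qt_d)
  rw <- config$within_rho
  rx <- config$qt_rr_rho
  sigma4 <- matrix(c(1, rx, rw, rw * rx,
                     rx, 1, rw * rx, rw,
                     rw, rw * rx, 1, rx,
                     rw * rx, rw, rx, 1), 4, 4)
  chol4 <- t(chol(sigma4))
  ids <- sprintf("dog%03d", seq_len(n))
  vals <- matrix(NA_real_, nrow = n, ncol = 31)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    frac <- if (phenotypes[i] == "inducible") miss$frac_inducible
            else miss$frac_noninducible
    observed <- stats::setNames(as.list(stats::runif(nrow(miss)) < frac),
                                miss$parameter)
    v <- sample_animal(config, lut, chol4, phenotypes[i], sexes[i],
                       observed)
    if (i == 1L) colnames(vals) <- names(v)
    vals[i, ] <- v
    ev <- synth_event_log(phenotypes[i], config$event_params,
                          config$window_s)
    if (nrow(ev)) {
      ev$animal_id <- ids[i]
      events[[i]] <- ev[, c("animal_id", "onset_s", "kind", "run_beats",
                            "n_defibs")]
    }
  }
  cond_params <- c("rr_ms", "pp_ms", "qrs_ms", "qt_ms", "lv_map_ms",
                   "rv_map_ms", "lv_stv_ms", "rv_stv_ms", "lvdpdt_max",
                   "lv_edp", "lv_esp")
  # long layout: baseline rows for all animals, then interleave by id
  long_one <- function(cond_prefix, cond_name) {
    df <- data.frame(id = ids, sex = sexes,
                     age_months = vals[, "age_months"],
                     body_weight_kg = vals[, "bw"],
                     condition = cond_name, stringsAsFactors = FALSE)
    for (p in cond_params) df[[p]] <- vals[, paste0(cond_prefix, p)]
    df
  }
  animals <- rbind(long_one("b_", "baseline"), long_one("d_", "dofetilide"))
  animals <- animals[order(match(animals$id, ids), animals$condition), ,
                     drop = FALSE]
  animals$jt_ms <- ifelse(!is.na(animals$qt_ms) & !is.na(animals$qrs_ms) &
                            animals$qt_ms > animals$qrs_ms,
                          animals$qt_ms - animals$qrs_ms, NA_real_)
  animals$phenotype_true <- rep(phenotypes, each = 2L)
  rep2 <- function(col) rep(vals[, col], each = 2L)
  animals$heart_weight_g <- rep2("hw_bw_g_kg") * animals$body_weight_kg
  animals$lung_weight_g <- rep2("lungw_bw_g_kg") * animals$body_weight_kg
  animals$liver_weight_g <- rep2("liverw_bw_g_kg") * animals$body_weight_kg
  animals$apd90_lv_ms <- rep2("apd90_lv_ms")
  animals$apd90_rv_ms <- rep2("apd90_rv_ms")
  animals$apd_stv_lv_ms <- rep2("apd_stv_lv_ms")
  animals$apd_stv_rv_ms <- rep2("apd_stv_rv_ms")
  animals <- animals[, c(animals_schema_cols(),
                         setdiff(names(animals), animals_schema_cols()))]
  rownames(animals) <- NULL
  structure(list(animals = animals,
                 events = do.call(rbind, c(list(empty_events), events))),
            class = "tdp_cohort")
}

#' @export
print.tdp_cohort <- function(x, ...) {
  ids <- unique(x$animals$id)
  ph <- x$animals$phenotype_true[!duplicated(x$animals$id)]
  cat("Synthetic CAVB cohort: ", length(ids), " animals (",
      sum(ph == "inducible"), " inducible, ",
      sum(ph == "non-inducible"), " non-inducible), ",
      nrow(x$events), " arrhythmic events\n", sep = "")
  invisible(x)
}
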