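#' Specify a synthetic survival cohort
#'
#' Defines the generative model for a cohort of sleep-laboratory patients with
#' planted risk-group structure: group membership, baseline covariates
#' (age, sex, BMI, six cardiometabolic comorbidity flags, apnea-hypopnea
#' index, PAP prescription, years of pre-study medical history), and a
#' right-censored time-to-event outcome drawn from an exponential
#' proportional-hazards model. The linear predictor is the group log hazard
#' ratio (reference group fixed at 0) plus optional covariate effects, so
#' adjusted and unadjusted fits are distinguishable downstream.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param group_proportions Probability vector over groups; must sum to 1.
#'   The default emulates a five-group split with a large low-risk reference
#'   group and a small high-risk group.
#' @param group_log_hazard_ratios Log hazard ratio per non-reference group
#'   (length `length(group_proportions) - 1`); the reference group is 0.
#' @param baseline_hazard Events per person-year for the reference group.
#' @param censoring_rate Rate (events per person-year) of the independent
#'   exponential censoring process. 0 disables random censoring; the
#'   administrative horizon still censors.
#' @param covariate_effects Optional named numeric vector of log-hazard
#'   effects for covariates (`age`, `sex`, `bmi`, comorbidity flags);
#'   defaults to all zero.
#' @param followup_horizon Administrative censoring horizon in years.
#' @param seed Integer seed; identical specs with identical seeds generate
#'   byte-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        group_proportions = c(0.38, 0.22, 0.18, 0.14, 0.08),
                        group_log_hazard_ratios = log(c(1.5, 2, 3, 5)),
                        baseline_hazard = 0.01,
                        censoring_rate = 0.02,
                        covariate_effects = NULL,
                        followup_horizon = 15,
                        seed = 1L) {
  assert_that(length(n_subjects) == 1 && n_subjects >= 1,
              "`n_subjects` must be a single value >= 1")
  assert_that(all(group_proportions >= 0),
              "`group_proportions` must be non-negative")
  assert_that(abs(sum(group_proportions) - 1) < 1e-9,
              "`group_proportions` must sum to 1")
  assert_that(length(group_log_hazard_ratios) == length(group_proportions) - 1,
              "`group_log_hazard_ratios` must have one entry per non-reference group")
  assert_that(baseline_hazard > 0, "`baseline_hazard` must be > 0")
  assert_that(censoring_rate >= 0, "`censoring_rate` must be >= 0")
  assert_that(followup_horizon > 0, "`followup_horizon` must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 group_proportions = group_proportions,
                 group_log_hazard_ratios = group_log_hazard_ratios,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 covariate_effects = covariate_effects,
                 followup_horizon = followup_horizon,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of subject records
#'
#' Draws one subject table from a [cohort_spec()]: group assignment, baseline
#' covariates, and a right-censored survival outcome. Death times are
#' exponential with hazard `baseline_hazard * exp(lp)` where `lp` is the group
#' log hazard ratio plus any configured covariate effects; censoring is the
#' minimum of an independent exponential and the administrative horizon.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `id`, `group` (factor
#'   `G1..Gk`), `age`, `sex`, `bmi`, comorbidity flags (`hypertension`,
#'   `diabetes2`, `heart_failure`, `afib`, `cad`, `hyperlipidemia`), `ahi`,
#'   `pap_prescribed`, `history_years`, `prevalent`, `time_years`, `event`.
#' @export
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_subjects
  k <- length(spec$group_proportions)
  group <- factor(sample(paste0("G", seq_len(k)), n, replace = TRUE,
                         prob = spec$group_proportions),
                  levels = paste0("G", seq_len(k)))
  subjects <- tibble(
    id = sprintf("S%05d", seq_len(n)),
    group = group,
    age = pmin(pmax(rnorm(n, 55, 12), 18), 95),
    sex = rbinom(n, 1, 0.5),
    bmi = pmin(pmax(rnorm(n, 32, 6), 16), 65),
    hypertension = rbinom(n, 1, 0.45),
    diabetes2 = rbinom(n, 1, 0.2),
    heart_failure = rbinom(n, 1, 0.08),
    afib = rbinom(n, 1, 0.07),
    cad = rbinom(n, 1, 0.12),
    hyperlipidemia = rbinom(n, 1, 0.4),
    ahi = rlnorm(n, meanlog = log(12), sdlog = 0.9),
    pap_prescribed = rbinom(n, 1, 0.3),
    history_years = rgamma(n, shape = 1.8, scale = 5.5),
    prevalent = rbinom(n, 1, 0.05) == 1
  )
  log_hr <- c(0, spec$group_log_hazard_ratios)[as.integer(group)]
  if (!is.null(spec$covariate_effects)) {
    for (nm in names(spec$covariate_effects)) {
      assert_that(nm %in% names(subjects),
                  paste0("unknown covariate in `covariate_effects`: ", nm))
      x <- subjects[[nm]]
      log_hr <- log_hr + spec$covariate_effects[[nm]] * (x - mean(x))
    }
  }
  death_time <- rexp(n, rate = spec$baseline_hazard * exp(log_hr))
  censor_time <- if (spec$censoring_rate > 0) {
    rexp(n, rate = spec$censoring_rate)
  } else {
    rep(Inf, n)
  }
  censor_time <- pmin(censor_time, spec$followup_horizon)
  subjects$time_years <- pmin(death_time, censor_time)
  subjects$event <- as.integer(death_time <= censor_time)
  subjects
}
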