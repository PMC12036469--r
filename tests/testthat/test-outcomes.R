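toy_subjects <- function() {
  tibble::tibble(
    id = sprintf("S%02d", 1:10),
    risk_group = factor(rep(c("RG1", "RG2"), 5)),
    age = seq(40, 76, length.out = 10),
    sex = rep(0:1, 5), bmi = rep(30, 10),
    hypertension = 0, diabetes2 = 0, heart_failure = 0, afib = 0,
    cad = 0, hyperlipidemia = 0, ahi = rep(c(3, 25), 5),
    pap_prescribed = rep(c(0, 0, 1, 0, 0), 2),
    history_years = c(4, 2, 3, rep(10, 7)),
    prevalent = c(FALSE, FALSE, TRUE, TRUE, rep(FALSE, 6)),
    time_years = rep(5, 10), event = rep(c(0, 1), 5))
}

test_that("eligibility filtering applies the history and prevalence rules", {
  s <- toy_subjects()
  # 3 short-history, 2 prevalent, 1 both -> 4 distinct exclusions, 6 retained
  elig <- build_outcome_cohort(s)
  expect_equal(nrow(elig), 6)
  expect_true(all(elig$history_years >= 5))
  expect_true(!any(elig$prevalent))
  expect_error(build_outcome_cohort(dplyr::select(s, -event, -prevalent),
                                    outcome = "stroke"), "stroke")
})

test_that("the product-limit estimate matches the hand calculation", {
  cohort <- tibble::tibble(id = c("a", "b", "c"),
                           risk_group = factor(rep("RG1", 3)),
                           time_years = c(1, 2, 3), event = c(1, 1, 0))
  km <- km_disease_free_survival(cohort, horizons = 2)
  expect_equal(km$survival$surv, (1 - 1 / 3) * (1 - 1 / 2))
})

test_that("no events means flat survival and log-rank p of 1", {
  cohort <- tibble::tibble(id = as.character(1:40),
                           risk_group = factor(rep(c("RG1", "RG2"), 20)),
                           time_years = runif(40, 5, 10), event = 0)
  km <- km_disease_free_survival(cohort, horizons = c(2, 4, 6))
  expect_true(all(km$survival$surv == 1))
  expect_equal(km$logrank$p_value, 1)
})

test_that("KM estimates are non-increasing and match the ECDF uncensored", {
  set.seed(31)
  cohort <- tibble::tibble(id = as.character(1:300),
                           risk_group = factor("RG1"),
                           time_years = rexp(300, 0.2), event = 1)
  km <- km_disease_free_survival(cohort, horizons = c(1, 2, 4, 6))
  expect_true(all(diff(km$survival$surv) <= 1e-12))
  expect_equal(km$survival$surv, 1 - stats::ecdf(cohort$time_years)(c(1, 2, 4, 6)),
               tolerance = 1e-12)
})

test_that("model exclusions are bookkept (PAP and age 55)", {
  set.seed(4)
  sp <- cohort_spec(1500, group_proportions = c(0.6, 0.4),
                    group_log_hazard_ratios = log(2),
                    baseline_hazard = 0.03, seed = 9)
  d <- generate_cohort(sp)
  d$risk_group <- factor(ifelse(d$group == "G1", "RG1", "RG2"))
  elig <- build_outcome_cohort(d)
  f5 <- fit_cox_model(elig, 5)
  expect_equal(f5$n, sum(elig$pap_prescribed == 0))
  f6 <- fit_cox_model(elig, 6)
  expect_equal(f6$n, sum(elig$age >= 55))
})

test_that("a planted HR of 2 is recovered with a covering CI (model 1)", {
  sp <- cohort_spec(5000, group_proportions = c(0.5, 0.5),
                    group_log_hazard_ratios = log(2),
                    baseline_hazard = 0.04, censoring_rate = 0.02,
                    seed = 77)
  d <- generate_cohort(sp)
  d$risk_group <- factor(ifelse(d$group == "G1", "RG1", "RG2"))
  fit <- fit_cox_model(build_outcome_cohort(d), 1)
  hr <- tidy(fit)$hr[tidy(fit)$is_exposure]
  expect_gt(hr, 1.8)
  expect_lt(hr, 2.2)
  tb <- tidy(fit)
  expect_true(tb$ci_lower[1] <= 2 && 2 <= tb$ci_upper[1])
  g <- glance(fit)
  expect_equal(g$n_events, sum(build_outcome_cohort(d)$event))
  expect_true(is.numeric(g$ph_global_p))
})

test_that("adjusted models estimate exposure and covariate effects together", {
  sp <- cohort_spec(4000, group_proportions = c(0.5, 0.5),
                    group_log_hazard_ratios = log(1.8),
                    baseline_hazard = 0.04,
                    covariate_effects = c(age = 0.03), seed = 13)
  d <- generate_cohort(sp)
  d$risk_group <- factor(ifelse(d$group == "G1", "RG1", "RG2"))
  fit <- fit_cox_model(build_outcome_cohort(d), 4)
  tb <- tidy(fit)
  expect_true(all(c("age", "sex", "bmi", "ahi") %in% tb$term))
  age_hr <- tb$hr[tb$term == "age"]
  expect_gt(age_hr, exp(0.02))
  expect_lt(age_hr, exp(0.04))
  f_ahi <- fit_cox_model(build_outcome_cohort(d), 4, exposure = "ahi_severity")
  expect_true(any(grepl("severe", tidy(f_ahi)$term)))
})

test_that("an exposure group with zero events is flagged", {
  cohort <- tibble::tibble(
    id = as.character(1:80),
    risk_group = factor(rep(c("RG1", "RG2"), each = 40)),
    time_years = c(rexp(40, 0.3), rep(10, 40)),
    event = c(rep(1, 40), rep(0, 40)))
  expect_warning(fit_cox_model(cohort, 1), "unbounded|no events")
})

test_that("weight trimming clips to the empirical percentiles", {
  raw <- c(0.1, rep(1, 8), 10)
  tr <- somnotype:::trim_weights(raw)
  expect_equal(max(tr$weight), unname(quantile(raw, 0.95)))
  expect_equal(min(tr$weight), unname(quantile(raw, 0.05)))
  expect_true(all(tr$retained))
  ex <- somnotype:::trim_weights(raw, method = "exclude")
  expect_equal(sum(ex$retained), 8)
})

test_that("stabilized weights balance a randomized cohort", {
  sp <- cohort_spec(4000, group_proportions = c(0.5, 0.3, 0.2),
                    group_log_hazard_ratios = c(0.3, 0.8),
                    baseline_hazard = 0.03, seed = 19)
  d <- generate_cohort(sp)
  pw <- estimate_propensity_weights(d, group_col = "group")
  w <- pw$weights
  expect_true(all(w$weight > 0))
  expect_true(all(w$weight >= pw$trim_bounds[1] - 1e-12 &
                    w$weight <= pw$trim_bounds[2] + 1e-12))
  for (g in levels(d$group)) {
    expect_lt(abs(mean(w$raw_weight[d$group == g]) - 1), 0.05)
  }
  bal <- covariate_balance(d, c("age", "bmi", "sex"), w$weight, "group")
  expect_true(all(bal$max_smd < 0.1))
})

test_that("weighted Cox and KM accept propensity weights", {
  sp <- cohort_spec(2000, group_proportions = c(0.6, 0.4),
                    group_log_hazard_ratios = log(2.5),
                    baseline_hazard = 0.04, seed = 23)
  d <- generate_cohort(sp)
  d$risk_group <- factor(ifelse(d$group == "G1", "RG1", "RG2"))
  elig <- build_outcome_cohort(d)
  pw <- estimate_propensity_weights(elig)
  fit <- fit_cox_model(elig, 3, weights = pw)
  expect_true(fit$weighted)
  hr <- tidy(fit)$hr[tidy(fit)$is_exposure]
  expect_gt(hr, 1.8)
  km <- km_disease_free_survival(elig, weights = pw)
  expect_true(km$weighted)
  expect_true(all(km$logrank$p_value >= 0 & km$logrank$p_value <= 1))
})
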