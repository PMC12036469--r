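test_that("cohort specs validate their fields", {
  expect_error(cohort_spec(0), "n_subjects")
  expect_error(cohort_spec(10, group_proportions = c(0.6, 0.5),
                           group_log_hazard_ratios = 0), "sum to 1")
  expect_error(cohort_spec(10, group_proportions = c(0.5, 0.5),
                           group_log_hazard_ratios = c(1, 2)),
               "non-reference")
  expect_error(cohort_spec(10, baseline_hazard = 0), "baseline_hazard")
})

test_that("identical cohort specs and seeds give identical tables", {
  sp <- cohort_spec(500, seed = 21)
  expect_identical(generate_cohort(sp), generate_cohort(sp))
})

test_that("survival times respect the horizon and events are consistent", {
  sp <- cohort_spec(2000, followup_horizon = 10, seed = 3)
  d <- generate_cohort(sp)
  expect_true(all(d$time_years >= 0 & d$time_years <= 10))
  expect_true(all(d$event %in% 0:1))
  expect_true(all(table(d$group) > 0))
})

test_that("a planted two-group hazard ratio of 2 is recovered by Cox", {
  sp <- cohort_spec(5000, group_proportions = c(0.5, 0.5),
                    group_log_hazard_ratios = log(2),
                    baseline_hazard = 0.05, censoring_rate = 0,
                    followup_horizon = 30, seed = 8)
  d <- generate_cohort(sp)
  fit <- survival::coxph(survival::Surv(time_years, event) ~ group, data = d)
  hr <- unname(exp(coef(fit)))
  expect_gt(hr, 1.8)
  expect_lt(hr, 2.2)
})

test_that("log-rank rejects at roughly the nominal rate under the null", {
  reject <- vapply(1:200, function(s) {
    d <- generate_cohort(cohort_spec(2000, group_proportions = c(0.5, 0.5),
                                     group_log_hazard_ratios = 0,
                                     baseline_hazard = 0.03, seed = 1000 + s))
    sd <- survival::survdiff(survival::Surv(time_years, event) ~ group,
                             data = d)
    pchisq(sd$chisq, 1, lower.tail = FALSE) < 0.05
  }, TRUE)
  expect_gt(mean(reject), 0.005)
  expect_lt(mean(reject), 0.12)
})

test_that("zero-effect survival tracks the theoretical exponential curve", {
  sp <- cohort_spec(3000, group_proportions = 1,
                    group_log_hazard_ratios = numeric(0),
                    baseline_hazard = 0.08, censoring_rate = 0.02,
                    followup_horizon = 20, seed = 5)
  d <- generate_cohort(sp)
  sf <- survival::survfit(survival::Surv(time_years, event) ~ 1, data = d)
  sm <- summary(sf, times = c(1, 2, 5))
  expect_true(all(exp(-0.08 * c(1, 2, 5)) >= sm$lower &
                    exp(-0.08 * c(1, 2, 5)) <= sm$upper))
})

test_that("larger planted hazards increase the crude death rate", {
  rates <- sapply(c(0, 0.7, 1.4), function(lhr) {
    mean(vapply(1:100, function(s) {
      d <- generate_cohort(cohort_spec(300, group_proportions = c(0.5, 0.5),
                                       group_log_hazard_ratios = lhr,
                                       baseline_hazard = 0.02,
                                       seed = 400 + s))
      g2 <- d[d$group == "G2", ]
      sum(g2$event) / sum(g2$time_years)
    }, 0))
  })
  expect_true(all(diff(rates) > 0))
})

test_that("recording generation is deterministic and keeps lengths exact", {
  sp <- recording_spec(n_epochs = 240, channels = test_channels, seed = 17)
  r1 <- generate_recording(sp)
  r2 <- generate_recording(sp)
  expect_identical(r1$psg$signals, r2$psg$signals)
  expect_identical(r1$events, r2$events)
  for (nm in names(r1$psg$signals)) {
    expect_length(r1$psg$signals[[nm]], 240 * 30 * r1$psg$rates[[nm]])
  }
})

test_that("annotations stay inside the recording span", {
  sp <- recording_spec(n_epochs = 100, channels = "C4",
                       respiratory_event_rate = 40,
                       desaturation_event_rate = 40, seed = 12)
  r <- generate_recording(sp, signals = FALSE)
  expect_true(all(r$events$start_s >= 0))
  expect_true(all(r$events$duration_s > 0))
  expect_true(all(r$events$start_s + r$events$duration_s <= 100 * 30))
})

test_that("unknown channel names are rejected with the valid list", {
  expect_error(recording_spec(10, channels = c("C4", "Cz")), "Cz")
  expect_error(recording_spec(10, channels = c("C4", "Cz")), "C4")
})

test_that("fragmented regimes score higher sleep fragmentation", {
  frag <- function(rate, s) {
    r <- generate_recording(recording_spec(n_epochs = 200, channels = "C4",
                                           stage_transition_rate = rate,
                                           seed = s), signals = FALSE)
    sleep_fragmentation(r$hypnogram)
  }
  f_hi <- vapply(1:20, function(s) frag(30, 600 + s), 0)
  f_lo <- vapply(1:20, function(s) frag(2, 600 + s), 0)
  expect_gt(mean(f_hi), mean(f_lo))
})

test_that("the planted respiratory rate is recovered by the computed AHI", {
  ahis <- vapply(1:20, function(s) {
    r <- generate_recording(recording_spec(n_epochs = 960, channels = "C4",
                                           stage_transition_rate = 4,
                                           respiratory_event_rate = 5,
                                           seed = 700 + s), signals = FALSE)
    summarize_psg(r$hypnogram, r$events)$ahi
  }, 0)
  expect_gt(mean(ahis), 3)
  expect_lt(mean(ahis), 7)
})

test_that("SpO2 dips coincide with desaturation annotations", {
  sp <- recording_spec(n_epochs = 40, channels = "SpO2",
                       stage_transition_rate = 2,
                       desaturation_event_rate = 30, spo2_baseline = 96,
                       seed = 31)
  r <- generate_recording(sp)
  x <- r$psg$signals$SpO2
  ev <- r$events[r$events$type == "desaturation", ]
  expect_gt(nrow(ev), 0)
  in_ev <- rep(FALSE, length(x))
  for (i in seq_len(nrow(ev))) {
    a <- floor(ev$start_s[i]) + 1
    b <- min(length(x), ceiling(ev$start_s[i] + ev$duration_s[i]))
    in_ev[a:b] <- TRUE
  }
  expect_lt(mean(x[in_ev]), mean(x[!in_ev]) - 1)
})
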