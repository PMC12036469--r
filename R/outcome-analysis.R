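#' Filter a subject table to the outcome-eligible cohort
#'
#' Eligibility for a time-to-event analysis: at least five years of medical
#' history before the sleep study, and no prevalent occurrence of the
#' outcome at baseline. Outcome-specific columns (`event_<outcome>`,
#' `time_<outcome>`, `prevalent_<outcome>`) are used when present; otherwise
#' the generic `event`, `time_years`, `prevalent` columns.
#'
#' @param subjects Subject tibble (see [generate_cohort()]).
#' @param outcome Outcome name, default `"all_cause_mortality"`.
#' @param min_history_years Minimum pre-study history.
#' @return The eligible subset with harmonized `event` and `time_years`
#'   columns.
#' @export
build_outcome_cohort <- function(subjects, outcome = "all_cause_mortality",
                                 min_history_years = 5) {
  ev_col <- if (paste0("event_", outcome) %in% names(subjects)) {
    paste0("event_", outcome)
  } else if ("event" %in% names(subjects)) "event" else
    abort(paste0("unknown outcome: ", outcome,
                 " (no event column found for it)"))
  tm_col <- if (paste0("time_", outcome) %in% names(subjects)) {
    paste0("time_", outcome)
  } else "time_years"
  pv_col <- if (paste0("prevalent_", outcome) %in% names(subjects)) {
    paste0("prevalent_", outcome)
  } else if ("prevalent" %in% names(subjects)) "prevalent" else NULL
  out <- subjects[subjects$history_years >= min_history_years, , drop = FALSE]
  if (!is.null(pv_col)) out <- out[!as.logical(out[[pv_col]]), , drop = FALSE]
  out$event <- out[[ev_col]]
  out$time_years <- out[[tm_col]]
  out
}

comorbidity_set <- function() {
  c("hypertension", "diabetes2", "heart_failure", "afib", "cad",
    "hyperlipidemia")
}

model_covariates <- function(model_id) {
  switch(as.character(model_id),
         "1" = character(),
         "2" = c("age", "sex", "bmi"),
         "3" = c("age", "sex", "bmi", comorbidity_set()),
         "4" = c("age", "sex", "bmi", comorbidity_set(), "ahi"),
         "5" = c("age", "sex", "bmi", comorbidity_set()),
         "6" = c("age", "sex", "bmi", comorbidity_set()),
         abort("`model_id` must be 1..6"))
}

#' Fit one of the six sensitivity Cox models
#'
#' Cox proportional-hazards fits of the exposure (ordinal risk groups with
#' RG1 as reference, or AHI severity bands with normal < 5 as reference)
#' against a time-to-event outcome, under six covariate/exclusion schemes:
#' model 1 unadjusted; 2 adds age, sex, BMI; 3 adds the six comorbidities;
#' 4 adds AHI; 5 is model 3 excluding PAP-prescribed patients; 6 is model 3
#' restricted to age >= 55. Ties use the Efron approximation. With weights a
#' robust (sandwich) variance is used. A Schoenfeld-residual proportionality
#' test is attached as an advisory diagnostic.
#'
#' @param cohort Eligible cohort (see [build_outcome_cohort()]) with an
#'   exposure column.
#' @param model_id Integer 1..6.
#' @param exposure `"risk_group"` (column `risk_group`) or `"ahi_severity"`
#'   (derived from `ahi`).
#' @param weights Optional [estimate_propensity_weights()] result or numeric
#'   vector aligned with `cohort`.
#' @return An object of class `cox_risk_fit`.
#' @export
fit_cox_model <- function(cohort, model_id = 1,
                          exposure = c("risk_group", "ahi_severity"),
                          weights = NULL) {
  exposure <- match.arg(exposure)
  covs <- model_covariates(model_id)
  dat <- cohort
  if (model_id == 5) dat <- dat[dat$pap_prescribed == 0, , drop = FALSE]
  if (model_id == 6) dat <- dat[dat$age >= 55, , drop = FALSE]
  if (exposure == "ahi_severity") {
    dat$exposure <- classify_ahi(dat$ahi)
    covs <- setdiff(covs, "ahi")
  } else {
    assert_that("risk_group" %in% names(dat),
                "`cohort` must carry a `risk_group` column")
    dat$exposure <- factor(dat$risk_group)
  }
  assert_that(nrow(dat) > 0, "cohort empty after the model's exclusions")
  dat$exposure <- droplevels(dat$exposure)
  w <- NULL
  if (!is.null(weights)) {
    if (inherits(weights, "propensity_weights")) {
      w <- weights$weights$weight[match(dat$id, weights$weights$id)]
      assert_that(!anyNA(w), "weights missing for some cohort subjects")
    } else {
      w <- weights
      assert_that(length(w) == nrow(cohort), "weight length mismatch")
      w <- w[match(dat$id, cohort$id)]
    }
    dat$.w <- w
  }
  rhs <- paste(c("exposure", covs), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time_years, event) ~", rhs))
  fit <- tryCatch(
    if (is.null(w)) {
      survival::coxph(fml, data = dat, ties = "efron")
    } else {
      survival::coxph(fml, data = dat, weights = dat$.w, robust = TRUE,
                      ties = "efron")
    },
    warning = function(cond) {
      if (grepl("did not converge", conditionMessage(cond))) {
        abort(paste0("Cox fit did not converge: ", conditionMessage(cond)))
      }
      suppressWarnings(if (is.null(w)) {
        survival::coxph(fml, data = dat, ties = "efron")
      } else {
        survival::coxph(fml, data = dat, weights = dat$.w, robust = TRUE,
                        ties = "efron")
      })
    })
  sm <- summary(fit)
  is_exp <- grepl("^exposure", rownames(sm$coefficients))
  terms <- sub("^exposure", "", rownames(sm$coefficients))
  se_col <- if ("robust se" %in% colnames(sm$coefficients)) "robust se" else "se(coef)"
  co <- sm$coefficients
  hr_tbl <- tibble(
    term = terms,
    is_exposure = is_exp,
    hr = unname(co[, "exp(coef)"]),
    ci_lower = unname(exp(co[, "coef"] - qnorm(0.975) * co[, se_col])),
    ci_upper = unname(exp(co[, "coef"] + qnorm(0.975) * co[, se_col])),
    p_value = unname(co[, ncol(co)])
  )
  # a group with zero events yields an unbounded Wald CI; flag it
  ev_by_grp <- tapply(dat$event, dat$exposure, sum)
  sep_groups <- names(ev_by_grp)[ev_by_grp == 0]
  if (length(sep_groups) > 0) {
    warn(paste0("no events in group(s) ", paste(sep_groups, collapse = ", "),
                "; their confidence intervals are unbounded"))
  }
  zph <- tryCatch(survival::cox.zph(fit)$table["GLOBAL", "p"],
                  error = function(e) NA_real_)
  structure(list(model_id = model_id, exposure = exposure, fit = fit,
                 hr_table = hr_tbl, n = sm$n, n_events = sm$nevent,
                 weighted = !is.null(w), ph_global_p = zph),
            class = "cox_risk_fit")
}

#' @export
print.cox_risk_fit <- function(x, ...) {
  cat("<cox_risk_fit> model ", x$model_id, ", exposure = ", x$exposure,
      if (x$weighted) " (propensity-weighted)", "\n",
      "  n = ", x$n, ", events = ", x$n_events, "\n", sep = "")
  tb <- x$hr_table[x$hr_table$is_exposure, ]
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-10s HR %.2f (%.2f-%.2f) p=%.3g\n", tb$term[i], tb$hr[i],
                tb$ci_lower[i], tb$ci_upper[i], tb$p_value[i]))
  }
  invisible(x)
}

#' @rdname fit_cox_model
#' @param x A `cox_risk_fit`.
#' @param ... Unused.
#' @export
tidy.cox_risk_fit <- function(x, ...) {
  x$hr_table
}

#' @rdname fit_cox_model
#' @export
glance.cox_risk_fit <- function(x, ...) {
  tibble(model_id = x$model_id, exposure = x$exposure, n = x$n,
         n_events = x$n_events, weighted = x$weighted,
         concordance = unname(summary(x$fit)$concordance[1]),
         ph_global_p = x$ph_global_p)
}

#' Stabilized, percentile-trimmed inverse propensity weights
#'
#' Fits a multinomial logistic model of group membership on baseline
#' covariates; the stabilized weight of subject i in group g is the marginal
#' group probability divided by the fitted conditional probability
#' P(G = g | x_i). Weights are then trimmed at their empirical 5th and 95th
#' percentiles — by default clipped to the percentile values (preserving the
#' sample), optionally excluding subjects outside them.
#'
#' @param cohort Subject tibble with a `group` or `risk_group` column.
#' @param covariates Covariate column names.
#' @param trim Percentile pair for trimming.
#' @param trim_method `"clip"` (default) or `"exclude"`.
#' @param group_col Grouping column; defaults to `risk_group` when present,
#'   else `group`.
#' @return An object of class `propensity_weights`: list with `weights`
#'   (tibble `id`, `raw_weight`, `weight`), `trim_bounds`, and the fitted
#'   multinomial model.
#' @export
estimate_propensity_weights <- function(cohort,
                                        covariates = c("age", "bmi", "sex",
                                                       comorbidity_set(),
                                                       "history_years"),
                                        trim = c(0.05, 0.95),
                                        trim_method = c("clip", "exclude"),
                                        group_col = NULL) {
  trim_method <- match.arg(trim_method)
  group_col <- group_col %||%
    (if ("risk_group" %in% names(cohort)) "risk_group" else "group")
  g <- droplevels(factor(cohort[[group_col]]))
  assert_that(nlevels(g) >= 2, "need at least two groups")
  covariates <- intersect(covariates, names(cohort))
  dat <- cohort[covariates]
  assert_that(!anyNA(dat), "covariates must be complete")
  dat$.g <- g
  fit <- nnet::multinom(.g ~ ., data = dat, trace = FALSE, maxit = 500)
  probs <- predict(fit, newdata = dat, type = "probs")
  if (nlevels(g) == 2) probs <- cbind(1 - probs, probs)
  colnames(probs) <- levels(g)
  p_assigned <- probs[cbind(seq_len(nrow(probs)), as.integer(g))]
  if (any(p_assigned < 1e-10)) {
    abort(paste0("fitted propensities numerically zero for some subjects ",
                 "(perfect separation?); consider fewer covariates"))
  }
  marg <- as.numeric(table(g) / length(g))[as.integer(g)]
  raw <- marg / p_assigned
  tr <- trim_weights(raw, trim, trim_method)
  bounds <- tr$bounds
  wt <- tr$weight
  keep <- tr$retained
  structure(list(weights = tibble(id = cohort$id, raw_weight = raw,
                                  weight = wt, retained = keep),
                 trim_bounds = bounds, trim_method = trim_method,
                 model = fit, group_col = group_col),
            class = "propensity_weights")
}

#' @export
print.propensity_weights <- function(x, ...) {
  cat("<propensity_weights> ", nrow(x$weights), " subjects, trim bounds [",
      signif(x$trim_bounds[1], 4), ", ", signif(x$trim_bounds[2], 4),
      "] (", x$trim_method, ")\n", sep = "")
  invisible(x)
}

# Percentile trimming of raw weights: clip to the empirical percentile
# values (preserving n), or exclude subjects outside them.
trim_weights <- function(raw, trim = c(0.05, 0.95), method = "clip") {
  bounds <- quantile(raw, trim, names = FALSE)
  if (method == "clip") {
    list(weight = pmin(pmax(raw, bounds[1]), bounds[2]),
         retained = rep(TRUE, length(raw)), bounds = bounds)
  } else {
    keep <- raw >= bounds[1] & raw <= bounds[2]
    list(weight = ifelse(keep, raw, NA_real_), retained = keep,
         bounds = bounds)
  }
}

#' Standardized mean differences of covariates across groups
#'
#' Balance diagnostic for propensity weighting: for each covariate, the
#' maximum pairwise absolute standardized mean difference across groups,
#' optionally weighted.
#'
#' @param cohort Subject tibble.
#' @param covariates Covariate columns.
#' @param weights Optional numeric weights.
#' @param group_col Grouping column.
#' @return Tibble with `covariate`, `max_smd`.
#' @export
covariate_balance <- function(cohort, covariates, weights = NULL,
                              group_col = "group") {
  g <- factor(cohort[[group_col]])
  w <- weights %||% rep(1, nrow(cohort))
  wmean <- function(x, w) sum(w * x) / sum(w)
  wvar <- function(x, w) sum(w * (x - wmean(x, w))^2) / sum(w)
  rows <- lapply(covariates, function(cv) {
    x <- as.numeric(cohort[[cv]])
    ms <- vapply(levels(g), function(lv) wmean(x[g == lv], w[g == lv]), 0)
    vs <- vapply(levels(g), function(lv) wvar(x[g == lv], w[g == lv]), 0)
    pair <- utils::combn(seq_along(ms), 2)
    smd <- apply(pair, 2, function(ij) {
      pooled <- sqrt((vs[ij[1]] + vs[ij[2]]) / 2)
      if (pooled == 0) 0 else abs(ms[ij[1]] - ms[ij[2]]) / pooled
    })
    tibble(covariate = cv, max_smd = max(smd))
  })
  bind_rows(rows)
}

#' Kaplan-Meier disease-free survival at fixed horizons
#'
#' Product-limit estimates per group evaluated at the requested horizons
#' (2, 4 and 6 years by default), with pairwise log-rank tests of each group
#' against the reference. When weights are supplied the estimates use the
#' weighted product-limit formula and the pairwise tests come from the
#' robust score test of a weighted Cox fit.
#'
#' @param cohort Eligible cohort with `time_years`, `event`, and a grouping
#'   column.
#' @param group_col Grouping column name.
#' @param horizons Evaluation times in years.
#' @param weights Optional [estimate_propensity_weights()] result or numeric
#'   vector.
#' @param reference Reference group label; defaults to the first level.
#' @return An object of class `km_summary`: list with `survival` (tibble
#'   `group`, `time`, `surv`, `lower`, `upper`), `logrank` (tibble `group`,
#'   `chisq`, `p_value`), and the underlying `survfit`.
#' @export
km_disease_free_survival <- function(cohort, group_col = "risk_group",
                                     horizons = c(2, 4, 6), weights = NULL,
                                     reference = NULL) {
  assert_that(nrow(cohort) > 0, "cohort is empty")
  g <- droplevels(factor(cohort[[group_col]]))
  empty <- setdiff(levels(factor(cohort[[group_col]])), levels(g))
  if (length(empty) > 0) {
    warn(paste0("omitting empty group(s): ", paste(empty, collapse = ", ")))
  }
  reference <- reference %||% levels(g)[1]
  dat <- tibble(time = cohort$time_years, event = cohort$event, group = g)
  w <- NULL
  if (!is.null(weights)) {
    w <- if (inherits(weights, "propensity_weights")) {
      weights$weights$weight[match(cohort$id, weights$weights$id)]
    } else {
      weights
    }
    dat$.w <- w
  }
  sf <- if (is.null(w)) {
    survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  } else {
    survival::survfit(survival::Surv(time, event) ~ group, data = dat,
                      weights = dat$.w)
  }
  sm <- summary(sf, times = horizons, extend = TRUE)
  grp_col <- if (is.null(sm$strata)) {
    rep(levels(g)[1], length(sm$time))   # single-group fit has no strata
  } else {
    sub("^group=", "", as.character(sm$strata))
  }
  surv_tbl <- tibble(group = grp_col, time = sm$time, surv = sm$surv,
                     lower = sm$lower, upper = sm$upper)
  lr <- lapply(setdiff(levels(g), reference), function(lv) {
    sub <- dat[dat$group %in% c(reference, lv), , drop = FALSE]
    sub$group <- droplevels(sub$group)
    if (sum(sub$event) == 0) {
      return(tibble(group = lv, chisq = 0, p_value = 1))
    }
    if (is.null(w)) {
      sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = sub)
      tibble(group = lv, chisq = sd$chisq,
             p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
    } else {
      cf <- survival::coxph(survival::Surv(time, event) ~ group, data = sub,
                            weights = sub$.w, robust = TRUE)
      sc <- summary(cf)$robscore
      tibble(group = lv, chisq = unname(sc["test"]),
             p_value = unname(sc["pvalue"]))
    }
  })
  structure(list(survival = surv_tbl, logrank = bind_rows(lr),
                 reference = reference, fit = sf, weighted = !is.null(w)),
            class = "km_summary")
}

#' @export
print.km_summary <- function(x, ...) {
  cat("<km_summary> reference = ", x$reference,
      if (x$weighted) " (weighted)", "\n", sep = "")
  print(tidyr::pivot_wider(x$survival[, c("group", "time", "surv")],
                           names_from = "time", values_from = "surv",
                           names_prefix = "S("))
  invisible(x)
}
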