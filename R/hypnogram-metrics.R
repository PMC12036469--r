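#' Spectral sleep-fragmentation statistic
#'
#' The hypnogram is encoded as a numeric series (one sample per 30-s epoch),
#' mean-removed, and its periodogram computed; fragmentation is the fraction
#' of total spectral power at frequencies above the cutoff (transitions
#' faster than 10 minutes, i.e. f > 1/600 Hz, strict inequality). A constant
#' hypnogram has zero variance and scores 0 by convention.
#'
#' The default encoding is an ordinal depth scale (W = 0, N1 = 1, N2 = 2,
#' N3 = 3, REM = 1.5). The statistic is invariant to affine re-encodings;
#' the `"transitions"` method instead analyzes the binary stage-change
#' indicator series and is invariant to any relabeling.
#'
#' @param hypnogram Tibble with a `stage` column, or a vector of stages.
#' @param cutoff_minutes Period cutoff separating "fast" transitions.
#' @param epoch_s Epoch duration in seconds.
#' @param encoding Named numeric encoding of the five stages.
#' @param method `"hypnogram"` (encoded stage series, default) or
#'   `"transitions"` (stage-change indicator).
#' @return Fragmentation in [0, 1].
#' @export
sleep_fragmentation <- function(hypnogram, cutoff_minutes = 10, epoch_s = 30,
                                encoding = c(W = 0, N1 = 1, N2 = 2, N3 = 3,
                                             REM = 1.5),
                                method = c("hypnogram", "transitions")) {
  method <- match.arg(method)
  stages <- if (is.data.frame(hypnogram)) hypnogram$stage else hypnogram
  n <- length(stages)
  assert_that(n >= 2, "need at least two epochs")
  if (method == "hypnogram") {
    x <- unname(encoding[as.character(stages)])
    assert_that(!anyNA(x), "hypnogram contains stages outside the encoding")
  } else {
    x <- c(0, as.numeric(stages[-1] != stages[-n]))
  }
  x <- x - mean(x)
  if (all(x == 0)) return(0)
  p <- Mod(fft(x))^2
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  p <- p[k + 1]                      # drop the (zero) DC bin
  f <- k / (n * epoch_s)
  total <- sum(p)
  if (total == 0) return(0)
  sum(p[f > 1 / (60 * cutoff_minutes)]) / total
}

#' Classify apnea-hypopnea index severity
#'
#' Standard bands: normal < 5, mild 5 to < 15, moderate 15 to < 30,
#' severe >= 30 events per hour.
#'
#' @param ahi Numeric AHI values (events/hour).
#' @return Factor with levels normal/mild/moderate/severe.
#' @export
classify_ahi <- function(ahi) {
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Summary metrics for one recording
#'
#' Standard polysomnography summaries: total sleep time (non-wake epochs),
#' sleep-stage percentages of TST, apnea-hypopnea index, arousal index, SpO2
#' minimum/mean, and the spectral fragmentation statistic. When TST is zero
#' the per-hour indices are undefined and reported as `NA` with
#' `indices_defined = FALSE`.
#'
#' @param hypnogram Tibble with columns `epoch`, `stage`.
#' @param events Tibble with columns `start_s`, `duration_s`, `type`.
#' @param spo2 Optional numeric SpO2 signal in percent (raw scale).
#' @param epoch_s Epoch duration in seconds.
#' @return One-row tibble of summary metrics.
#' @export
summarize_psg <- function(hypnogram, events, spo2 = NULL, epoch_s = 30) {
  span <- nrow(hypnogram) * epoch_s
  assert_that(all(events$start_s >= 0 &
                    events$start_s + events$duration_s <= span + 1e-9),
              "annotations fall outside the recording span")
  stages <- as.character(hypnogram$stage)
  n_sleep <- sum(stages != "W")
  tst_min <- n_sleep * epoch_s / 60
  pct <- function(s) if (n_sleep == 0) NA_real_ else 100 * sum(stages == s) / n_sleep
  tst_h <- tst_min / 60
  defined <- tst_min > 0
  n_resp <- sum(events$type == "respiratory")
  n_arous <- sum(events$type == "arousal")
  tibble(
    tst_min = tst_min,
    pct_n1 = pct("N1"), pct_n2 = pct("N2"), pct_n3 = pct("N3"),
    pct_rem = pct("REM"),
    ahi = if (defined) n_resp / tst_h else NA_real_,
    arousal_index = if (defined) n_arous / tst_h else NA_real_,
    spo2_min = if (is.null(spo2)) NA_real_ else min(spo2),
    spo2_mean = if (is.null(spo2)) NA_real_ else mean(spo2),
    fragmentation = sleep_fragmentation(hypnogram, epoch_s = epoch_s),
    ahi_severity = if (defined) classify_ahi(n_resp / tst_h) else
      factor(NA, levels = levels(classify_ahi(0))),
    indices_defined = defined
  )
}
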