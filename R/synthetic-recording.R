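#' Polysomnography channel catalogue
#'
#' The channel set of a standard in-laboratory montage: three EEG derivations,
#' two EOG channels, chin EMG, EKG, nasal pressure, oral airflow, chest and
#' abdominal effort belts, snore, end-tidal CO2, and pulse-oximetry SpO2.
#' Native sampling rates are representative acquisition rates; preprocessing
#' resamples everything to a common 128 Hz.
#'
#' @return A tibble with columns `channel`, `class`, `rate_hz`.
#' @export
channel_catalogue <- function() {
  tibble(
    channel = c("C4", "F4", "O2_M2", "E1", "E2", "chin_EMG", "EKG",
                "nasal_pressure", "airflow", "chest", "abdomen", "snore",
                "EtCO2", "SpO2"),
    class = c("EEG", "EEG", "EEG", "EOG", "EOG", "EMG", "EKG",
              "nasal_pressure", "airflow", "effort", "effort", "snore",
              "etco2", "spo2"),
    rate_hz = c(128, 128, 128, 128, 128, 128, 128, 32, 32, 32, 32, 128, 32, 1)
  )
}

#' Specify a synthetic PSG recording
#'
#' Defines the generative model for one overnight recording: a sleep-stage
#' Markov chain whose switch probability per 30-s epoch is governed by
#' `stage_transition_rate`, stage-dependent multichannel signals, and
#' respiratory / desaturation / arousal annotations placed by a homogeneous
#' Poisson process restricted to sleep epochs (durations uniform on 10-60 s;
#' arousals 3-15 s). SpO2 dips co-occur with desaturation annotations.
#'
#' @param n_epochs Number of 30-s epochs (>= 2).
#' @param channels Character vector of channel names from
#'   [channel_catalogue()], or a named numeric vector of sampling rates (Hz).
#' @param stage_transition_rate Expected stage switches per hour.
#' @param respiratory_event_rate Respiratory events per hour of sleep.
#' @param desaturation_event_rate Desaturation events per hour of sleep.
#' @param arousal_event_rate Arousal events per hour of sleep.
#' @param spo2_baseline Baseline oxygen saturation in percent.
#' @param seed Integer seed; identical specs and seeds give identical output.
#' @return An object of class `recording_spec`.
#' @export
recording_spec <- function(n_epochs,
                           channels = channel_catalogue()$channel,
                           stage_transition_rate = 10,
                           respiratory_event_rate = 5,
                           desaturation_event_rate = 5,
                           arousal_event_rate = 10,
                           spo2_baseline = 96,
                           seed = 1L) {
  assert_that(n_epochs >= 2, "`n_epochs` must be >= 2")
  assert_that(all(c(stage_transition_rate, respiratory_event_rate,
                    desaturation_event_rate, arousal_event_rate) >= 0),
              "all rates must be >= 0")
  cat_tbl <- channel_catalogue()
  if (is.numeric(channels)) {
    assert_that(!is.null(names(channels)), "named rates required")
    nm <- names(channels)
    rates <- channels
  } else {
    nm <- channels
    rates <- cat_tbl$rate_hz[match(nm, cat_tbl$channel)]
  }
  unknown <- setdiff(nm, cat_tbl$channel)
  if (length(unknown) > 0) {
    abort(paste0("unknown channel(s): ", paste(unknown, collapse = ", "),
                 ". Valid channels: ", paste(cat_tbl$channel, collapse = ", ")))
  }
  assert_that(length(nm) >= 1, "`channels` must be non-empty")
  structure(list(n_epochs = as.integer(n_epochs),
                 channels = setNames(rates, nm),
                 stage_transition_rate = stage_transition_rate,
                 respiratory_event_rate = respiratory_event_rate,
                 desaturation_event_rate = desaturation_event_rate,
                 arousal_event_rate = arousal_event_rate,
                 spo2_baseline = spo2_baseline,
                 seed = as.integer(seed)),
            class = "recording_spec")
}

#' Multichannel PSG signal container
#'
#' A light-weight per-channel array container: named list of numeric signal
#' vectors with per-channel sampling rates and a 30-s epoch grid.
#'
#' @param signals Named list of numeric vectors.
#' @param rates Named numeric vector of sampling rates (Hz), same names.
#' @param n_epochs Number of 30-s epochs spanned by every channel.
#' @return An object of class `psg_recording`.
#' @export
psg_recording <- function(signals, rates, n_epochs) {
  assert_that(identical(sort(names(signals)), sort(names(rates))),
              "`signals` and `rates` must share names")
  for (nm in names(signals)) {
    assert_that(length(signals[[nm]]) == n_epochs * 30 * rates[[nm]],
                paste0("channel ", nm, " length does not match the epoch grid"))
  }
  structure(list(signals = signals, rates = rates,
                 n_epochs = as.integer(n_epochs), epoch_s = 30),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", length(x$signals), " channels, ",
      x$n_epochs, " x 30-s epochs\n", sep = "")
  for (nm in names(x$signals))
    cat("  ", format(nm, width = 16), x$rates[[nm]], "Hz\n")
  invisible(x)
}

# Stage Markov chain: switch with probability rate/120 per epoch, then move
# according to a stage-specific proposal kernel (depth-adjacent moves favored).
simulate_hypnogram <- function(n_epochs, transition_rate) {
  st <- stage_levels()
  kern <- rbind(
    W   = c(0, .8, .1, 0, .1),
    N1  = c(.2, 0, .5, .1, .2),
    N2  = c(.15, .25, 0, .35, .25),
    N3  = c(.15, .15, .7, 0, 0),
    REM = c(.3, .4, .3, 0, 0)
  )
  p_switch <- min(transition_rate / 120, 1)
  stage <- integer(n_epochs)
  stage[1] <- 1L  # start awake
  for (i in seq_len(n_epochs - 1)) {
    if (runif(1) < p_switch) {
      stage[i + 1] <- sample.int(5, 1, prob = kern[stage[i], ])
    } else {
      stage[i + 1] <- stage[i]
    }
  }
  factor(st[stage], levels = st)
}

place_events <- function(hypnogram, rate_per_h, dur_range, span_s) {
  sleep_epochs <- which(hypnogram != "W")
  if (length(sleep_epochs) == 0 || rate_per_h == 0) {
    return(tibble(start_s = numeric(), duration_s = numeric()))
  }
  tst_h <- length(sleep_epochs) * 30 / 3600
  n_ev <- stats::rpois(1, rate_per_h * tst_h)
  if (n_ev == 0) return(tibble(start_s = numeric(), duration_s = numeric()))
  ep <- sample(sleep_epochs, n_ev, replace = TRUE)
  start <- (ep - 1) * 30 + runif(n_ev, 0, 30)
  dur <- runif(n_ev, dur_range[1], dur_range[2])
  dur <- pmin(dur, span_s - start)
  tibble(start_s = start, duration_s = dur) |> arrange(.data$start_s)
}

#' Generate a synthetic PSG recording
#'
#' Simulates the hypnogram, event annotations, and (optionally) the raw
#' multichannel signals described by a [recording_spec()]. EEG channels carry
#' elevated slow-wave (delta) amplitude in N3 and an alpha component in wake;
#' EMG tone decreases from wake to REM; respiratory channels are a breathing
#' oscillation whose amplitude collapses during respiratory events; SpO2 dips
#' during desaturation annotations.
#'
#' @param spec A [recording_spec()].
#' @param signals If `FALSE`, skip signal synthesis and return only the
#'   hypnogram and annotations (fast path for metric-level studies).
#' @return A list with elements `psg` ([psg_recording()] or `NULL`),
#'   `hypnogram` (tibble `epoch`, `stage`), and `events` (tibble `start_s`,
#'   `duration_s`, `type` with types `respiratory`, `desaturation`,
#'   `arousal`).
#' @export
generate_recording <- function(spec, signals = TRUE) {
  assert_that(inherits(spec, "recording_spec"), "`spec` must be a recording_spec")
  set.seed(spec$seed)
  n_ep <- spec$n_epochs
  span_s <- n_ep * 30
  hyp <- simulate_hypnogram(n_ep, spec$stage_transition_rate)
  resp <- place_events(hyp, spec$respiratory_event_rate, c(10, 60), span_s)
  desat <- place_events(hyp, spec$desaturation_event_rate, c(10, 60), span_s)
  arous <- place_events(hyp, spec$arousal_event_rate, c(3, 15), span_s)
  events <- bind_rows(
    mutate(resp, type = "respiratory"),
    mutate(desat, type = "desaturation"),
    mutate(arous, type = "arousal")
  ) |> arrange(.data$start_s)
  hyp_tbl <- tibble(epoch = seq_len(n_ep), stage = hyp)
  psg <- NULL
  if (signals) {
    cat_tbl <- channel_catalogue()
    sigs <- list()
    for (nm in names(spec$channels)) {
      r <- spec$channels[[nm]]
      cls <- cat_tbl$class[match(nm, cat_tbl$channel)]
      sigs[[nm]] <- synth_channel(cls, hyp, r, span_s, events, spec$spo2_baseline)
    }
    psg <- psg_recording(sigs, spec$channels, n_ep)
  }
  list(psg = psg, hypnogram = hyp_tbl, events = events)
}

# Per-sample stage index vector at a given rate.
stage_per_sample <- function(hypnogram, rate) {
  rep(as.integer(hypnogram), each = 30 * rate)
}

event_mask <- function(events, type, rate, n_samples) {
  m <- rep(FALSE, n_samples)
  ev <- events[events$type == type, , drop = FALSE]
  if (nrow(ev) == 0) return(m)
  for (i in seq_len(nrow(ev))) {
    a <- max(1L, floor(ev$start_s[i] * rate) + 1L)
    b <- min(n_samples, ceiling((ev$start_s[i] + ev$duration_s[i]) * rate))
    if (b >= a) m[a:b] <- TRUE
  }
  m
}

synth_channel <- function(class, hypnogram, rate, span_s, events, spo2_baseline) {
  n <- span_s * rate
  t <- seq_len(n) / rate
  si <- stage_per_sample(hypnogram, rate)  # 1=W .. 5=REM
  if (class == "spo2") {
    x <- spo2_baseline + rnorm(n, 0, 0.3)
    ev <- events[events$type == "desaturation", , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      a <- max(1L, floor(ev$start_s[i] * rate) + 1L)
      b <- min(n, ceiling((ev$start_s[i] + ev$duration_s[i]) * rate))
      if (b > a) {
        depth <- runif(1, 4, 9)
        prof <- sin(pi * seq(0, 1, length.out = b - a + 1))
        x[a:b] <- x[a:b] - depth * prof
      }
    }
    return(pmin(pmax(x, 50), 100))
  }
  if (class %in% c("nasal_pressure", "airflow", "effort")) {
    amp <- ifelse(event_mask(events, "respiratory", rate, n), 0.15, 1)
    base <- sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi))
    return(amp * base + rnorm(n, 0, 0.08))
  }
  if (class == "EEG") {
    delta_amp <- c(0.25, 0.45, 1.1, 2.6, 0.35)[si]
    alpha_amp <- c(1.1, 0.25, 0.1, 0.05, 0.2)[si]
    return(delta_amp * sin(2 * pi * 1.2 * t + runif(1, 0, 2 * pi)) +
             alpha_amp * sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)) +
             rnorm(n, 0, 0.5))
  }
  if (class == "EOG") {
    rem_amp <- c(0.3, 0.3, 0.2, 0.1, 1.4)[si]
    return(rem_amp * sin(2 * pi * 0.4 * t + runif(1, 0, 2 * pi)) +
             rnorm(n, 0, 0.3))
  }
  if (class == "EMG") {
    tone <- c(1.5, 0.8, 0.6, 0.5, 0.15)[si]
    return(tone * rnorm(n, 0, 1))
  }
  if (class == "EKG") {
    hr <- 2 * pi * 1.1 * t
    return(sin(hr) + 0.5 * sin(2 * hr) + 0.25 * sin(3 * hr) + rnorm(n, 0, 0.1))
  }
  if (class == "snore") {
    amp <- c(0.1, 0.2, 0.9, 0.9, 0.1)[si]
    burst <- pmax(sin(2 * pi * 0.25 * t), 0)
    return(amp * burst * rnorm(n, 0, 1) + rnorm(n, 0, 0.05))
  }
  if (class == "etco2") {
    return(40 + 4 * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi)) + rnorm(n, 0, 0.5))
  }
  abort(paste0("unknown channel class: ", class))
}
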