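#' Specify an IIR filter for one channel class
#'
#' Elliptic (Cauer) designs throughout: order 16, at most 1 dB passband
#' ripple and at least 40 dB stopband attenuation as single-pass targets.
#' Forward-backward application then squares the magnitude response, doubling
#' attenuation in dB. "Order" is the total filter order: a band-pass is
#' realized from an order/2 low-pass prototype.
#'
#' @param kind One of `"band-pass"`, `"high-pass"`, `"none"`.
#' @param low_cut_hz,high_cut_hz Cutoff frequencies in Hz (as applicable).
#' @param order Total filter order (> 0, even for band-pass).
#' @param passband_ripple_db Maximum passband ripple in dB (> 0).
#' @param stopband_attenuation_db Minimum stopband attenuation in dB (> 0).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("band-pass", "high-pass", "none"),
                        low_cut_hz = NULL, high_cut_hz = NULL,
                        order = 16, passband_ripple_db = 1,
                        stopband_attenuation_db = 40) {
  kind <- match.arg(kind)
  assert_that(order > 0, "`order` must be > 0")
  assert_that(passband_ripple_db > 0, "`passband_ripple_db` must be > 0")
  assert_that(stopband_attenuation_db > 0, "`stopband_attenuation_db` must be > 0")
  if (kind == "band-pass") {
    assert_that(!is.null(low_cut_hz) && !is.null(high_cut_hz),
                "band-pass requires both cutoffs")
    assert_that(low_cut_hz > 0 && high_cut_hz > low_cut_hz,
                "cutoffs must satisfy 0 < low < high")
    assert_that(order %% 2 == 0, "band-pass `order` must be even")
  }
  if (kind == "high-pass") {
    assert_that(!is.null(low_cut_hz) && low_cut_hz > 0,
                "high-pass requires `low_cut_hz` > 0")
  }
  structure(list(kind = kind, low_cut_hz = low_cut_hz,
                 high_cut_hz = high_cut_hz, order = order,
                 passband_ripple_db = passband_ripple_db,
                 stopband_attenuation_db = stopband_attenuation_db),
            class = "filter_spec")
}

#' Per-channel-class filter table
#'
#' EEG and EOG: band-pass 0.3-45 Hz; EMG: high-pass 10 Hz; EKG: high-pass
#' 0.3 Hz; nasal pressure: high-pass 0.1 Hz; airflow and effort belts:
#' band-pass 0.1-15 Hz; SpO2: no filtering. Snore and EtCO2 carry no
#' published specification and are assigned the airflow band-pass.
#'
#' @return A named list mapping channel class to [filter_spec()].
#' @export
channel_filter_table <- function() {
  bp_eeg <- filter_spec("band-pass", 0.3, 45)
  bp_air <- filter_spec("band-pass", 0.1, 15)
  list(
    EEG = bp_eeg,
    EOG = bp_eeg,
    EMG = filter_spec("high-pass", 10),
    EKG = filter_spec("high-pass", 0.3),
    nasal_pressure = filter_spec("high-pass", 0.1),
    airflow = bp_air,
    effort = bp_air,
    snore = bp_air,
    etco2 = bp_air,
    spo2 = filter_spec("none")
  )
}

# Pair conjugate roots; real roots are paired with each other (NA-padded if odd).
pair_roots <- function(r) {
  used <- rep(FALSE, length(r))
  pairs <- list()
  ord <- order(Re(r), Im(r))
  r <- r[ord]
  for (i in seq_along(r)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(r[i])) < 1e-8 * max(1, abs(r[i]))) {
      j <- which(!used & abs(Im(r)) < 1e-8 * pmax(1, abs(r)))[1]
      if (is.na(j)) {
        pairs[[length(pairs) + 1]] <- c(r[i], NA)
      } else {
        used[j] <- TRUE
        pairs[[length(pairs) + 1]] <- c(r[i], r[j])
      }
    } else {
      j <- which(!used & abs(r - Conj(r[i])) < 1e-6 * max(1, abs(r[i])))[1]
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(r[i], r[j])
    }
  }
  pairs
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Zero-pole-gain to second-order sections. Pole pairs are ordered by radius
# (closest to the unit circle last) and matched to the nearest zero pair;
# the overall gain sits on the first section. Keeping the cascade in biquads
# is what makes an order-16 elliptic design numerically usable.
zpk_to_sos <- function(zero, pole, gain) {
  pp <- pair_roots(pole)
  zp <- pair_roots(zero)
  pp <- pp[order(vapply(pp, function(q) max(abs(q), na.rm = TRUE), 0))]
  sos <- matrix(0, length(pp), 6)
  for (i in seq_along(pp)) {
    pr <- pp[[i]]
    d <- vapply(zp, function(q) abs(mean(q[!is.na(q)]) - pr[1]), 0)
    j <- which.min(d)
    zr <- zp[[j]]
    zp <- zp[-j]
    bz <- Re(poly_from_roots(zr[!is.na(zr)]))
    az <- Re(poly_from_roots(pr[!is.na(pr)]))
    sos[i, 1:3] <- c(bz, rep(0, 3 - length(bz)))
    sos[i, 4:6] <- c(az, rep(0, 3 - length(az)))
  }
  sos[1, 1:3] <- sos[1, 1:3] * Re(gain)
  sos
}

#' Design a zero-phase elliptic filter
#'
#' Designs the elliptic filter described by a [filter_spec()] at a given
#' sampling rate. The analog low-pass prototype and the frequency transforms
#' come from the `signal` package; the digital design is kept in
#' zero-pole-gain form and realized as cascaded second-order sections.
#'
#' @param spec A [filter_spec()].
#' @param sample_rate_hz Sampling rate of the signal the filter will run at.
#' @return An object of class `sos_filter` (or `"identity"` kind for
#'   `kind = "none"`).
#' @export
design_filter <- function(spec, sample_rate_hz) {
  assert_that(inherits(spec, "filter_spec"), "`spec` must be a filter_spec")
  nyq <- sample_rate_hz / 2
  if (spec$kind == "none") {
    return(structure(list(kind = "identity", spec = spec,
                          sample_rate_hz = sample_rate_hz),
                     class = "sos_filter"))
  }
  cuts <- c(spec$low_cut_hz, spec$high_cut_hz)
  if (any(cuts >= nyq)) {
    abort(sprintf("cutoff %.3g Hz is at or above the Nyquist frequency %.3g Hz",
                  max(cuts), nyq))
  }
  ncauer <- utils::getFromNamespace("ncauer", "signal")
  Tbl <- 2
  W <- (2 / Tbl) * tan(pi * (cuts / nyq) / Tbl)
  if (spec$kind == "band-pass") {
    zpg <- ncauer(spec$passband_ripple_db, spec$stopband_attenuation_db,
                  spec$order / 2)
    zpg <- signal::sftrans(zpg, W = W, stop = FALSE)
  } else {
    zpg <- ncauer(spec$passband_ripple_db, spec$stopband_attenuation_db,
                  spec$order)
    zpg <- signal::sftrans(zpg, W = W, stop = TRUE)
  }
  zpg <- signal::bilinear(zpg, T = Tbl)
  sos <- zpk_to_sos(zpg$zero, zpg$pole, zpg$gain)
  structure(list(kind = spec$kind, sos = sos, spec = spec,
                 sample_rate_hz = sample_rate_hz),
            class = "sos_filter")
}

#' Single-pass magnitude response of a designed filter
#'
#' @param filt An [design_filter()] result.
#' @param f Frequencies in Hz at which to evaluate.
#' @return Magnitude response in dB (0 everywhere for an identity filter).
#' @export
filter_response_db <- function(filt, f) {
  assert_that(inherits(filt, "sos_filter"), "`filt` must be a sos_filter")
  if (filt$kind == "identity") return(rep(0, length(f)))
  z <- exp(1i * 2 * pi * f / filt$sample_rate_hz)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(filt$sos))) {
    b <- filt$sos[i, 1:3]
    a <- filt$sos[i, 4:6]
    h <- h * (b[1] + b[2] / z + b[3] / z^2) / (a[1] + a[2] / z + a[3] / z^2)
  }
  20 * log10(abs(h))
}

sos_filter_once <- function(sos, x) {
  cpp_sosfilt(sos, x)
}

#' Apply a designed filter forward and backward (zero phase)
#'
#' Odd-reflection padding at both ends suppresses edge transients; the
#' effective magnitude response is the square of the single-pass response.
#'
#' @param filt A [design_filter()] result.
#' @param x Numeric signal.
#' @return Filtered signal of the same length.
#' @export
sos_filtfilt <- function(filt, x) {
  assert_that(inherits(filt, "sos_filter"), "`filt` must be a sos_filter")
  if (filt$kind == "identity") return(x)
  n <- length(x)
  np <- min(30 * nrow(filt$sos), n - 1)
  assert_that(np >= 1, "signal shorter than the filter warm-up length")
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- sos_filter_once(filt$sos, c(pre, x, post))
  y <- rev(sos_filter_once(filt$sos, rev(y)))
  y[(np + 1):(np + n)]
}

#' Preprocess one channel
#'
#' Resamples to the target rate (windowed-sinc rational resampling with
#' anti-aliasing), applies the zero-phase elliptic filter for the channel
#' class, and normalizes amplitudes: the 5th and 95th percentiles map to -1
#' and +1 for every class except SpO2, which is unfiltered and mapped so 60%
#' saturation is -1 and 100% is +1.
#'
#' @param x Numeric signal at `native_rate_hz`.
#' @param native_rate_hz Native sampling rate in Hz.
#' @param spec [filter_spec()] for the channel class (ignored for SpO2-style
#'   fixed normalization when `channel_class = "spo2"`).
#' @param channel_class Channel class label (`"spo2"` selects the fixed
#'   saturation mapping).
#' @param target_rate_hz Output rate, 128 Hz by default.
#' @return Normalized numeric signal at `target_rate_hz`.
#' @export
preprocess_channel <- function(x, native_rate_hz, spec,
                               channel_class = "EEG", target_rate_hz = 128) {
  if (native_rate_hz != target_rate_hz) {
    x <- cpp_resample(x, native_rate_hz, target_rate_hz)
  }
  if (channel_class == "spo2") {
    return((x - 80) / 20)
  }
  filt <- design_filter(spec, target_rate_hz)
  x <- sos_filtfilt(filt, x)
  q <- quantile(x, c(0.05, 0.95), names = FALSE)
  if (q[2] - q[1] < .Machine$double.eps * max(1, abs(q[2]))) {
    warn("degenerate amplitude distribution (5th percentile equals 95th); channel zeroed")
    return(rep(0, length(x)))
  }
  (2 * x - q[1] - q[2]) / (q[2] - q[1])
}

#' Preprocess a full recording
#'
#' Applies [preprocess_channel()] to every channel using the per-class filter
#' table; all channels come out at 128 Hz with the epoch grid preserved.
#'
#' @param rec A [psg_recording()].
#' @param table Filter table as from [channel_filter_table()].
#' @param target_rate_hz Common output rate.
#' @param require_spo2 Require an SpO2 channel (saturation summaries and the
#'   desaturation task depend on it); set `FALSE` for partial montages.
#' @return A [psg_recording()] with processed channels.
#' @export
preprocess_recording <- function(rec, table = channel_filter_table(),
                                 target_rate_hz = 128, require_spo2 = TRUE) {
  assert_that(inherits(rec, "psg_recording"), "`rec` must be a psg_recording")
  cat_tbl <- channel_catalogue()
  classes <- cat_tbl$class[match(names(rec$signals), cat_tbl$channel)]
  if (require_spo2 && !"spo2" %in% classes) {
    abort("recording has no SpO2 channel")
  }
  out <- list()
  for (nm in names(rec$signals)) {
    cls <- cat_tbl$class[match(nm, cat_tbl$channel)]
    if (is.na(cls) || is.null(table[[cls]])) {
      abort(paste0("channel ", nm, " has no entry in the filter table"))
    }
    out[[nm]] <- preprocess_channel(rec$signals[[nm]], rec$rates[[nm]],
                                    table[[cls]], channel_class = cls,
                                    target_rate_hz = target_rate_hz)
  }
  psg_recording(out, setNames(rep(target_rate_hz, length(out)), names(out)),
                rec$n_epochs)
}
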