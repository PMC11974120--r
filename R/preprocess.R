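# zero-phase forward-backward application of an IIR filter designed by
# signal::butter / notch_biquad (compiled kernel, odd-reflection padding)
zp_filter <- function(flt, x) {
  filtfilt_cpp(as.numeric(flt$b), as.numeric(flt$a), as.numeric(x))
}

#' Canonical SEEG frequency bands
#'
#' The four analysis bands: the full filtered band (0.5--250 Hz) and its
#' three sub-bands -- low frequency (0.5--50 Hz), high gamma (50--80 Hz) and
#' ripple (80--250 Hz).
#'
#' @param name Optional band name; if given, returns that single band spec.
#' @return A named list of band specs (`name`, `low_hz`, `high_hz`), or a
#'   single spec when `name` is supplied.
#' @export
#' @examples
#' canonical_bands()
#' canonical_bands("ripple")
canonical_bands <- function(name = NULL) {
  bands <- list(
    filtered   = list(name = "filtered",   low_hz = 0.5, high_hz = 250),
    low        = list(name = "low",        low_hz = 0.5, high_hz = 50),
    high_gamma = list(name = "high_gamma", low_hz = 50,  high_hz = 80),
    ripple     = list(name = "ripple",     low_hz = 80,  high_hz = 250)
  )
  if (is.null(name)) return(bands)
  if (!name %in% names(bands)) {
    stop("unknown band '", name, "'; known bands: ",
         paste(names(bands), collapse = ", "))
  }
  bands[[name]]
}

band_names <- function() c("filtered", "low", "high_gamma", "ripple")

#' Average-reference montage
#'
#' Re-references every channel against the instantaneous mean across all
#' channels, so that at each sample the across-channel mean of the output
#' is zero.
#'
#' @param rec A [seeg_recording()].
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  assert_recording(rec)
  if (nrow(rec$data) < 2) {
    stop("average reference requires at least 2 channels")
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data), "-")
  rec
}

#' Mark artifact-contaminated spans for exclusion
#'
#' Records manually identified bad spans on a recording; windows overlapping
#' a marked span on a channel are dropped for that channel by
#' [extract_windows()]. Spans are half-open intervals `[start_s, end_s)` in
#' seconds from the start of the recording. Spans are an input (manual
#' rejection), not detected automatically.
#'
#' @param rec A [seeg_recording()].
#' @param bad_spans Data frame with columns `channel_name`, `start_s`,
#'   `end_s`. An empty data frame (or `NULL`) leaves the recording
#'   unchanged.
#' @return The recording with an `artifact_mask` attribute (a normalized
#'   span table).
#' @export
reject_artifacts <- function(rec, bad_spans = NULL) {
  assert_recording(rec)
  if (is.null(bad_spans) || nrow(bad_spans) == 0) return(rec)
  req <- c("channel_name", "start_s", "end_s")
  if (!all(req %in% names(bad_spans))) {
    stop("`bad_spans` must have columns: ", paste(req, collapse = ", "))
  }
  dur <- duration_s(rec)
  spans <- tibble::as_tibble(bad_spans[, req])
  unknown <- setdiff(unique(spans$channel_name), rec$channel_names)
  if (length(unknown)) {
    stop("artifact spans refer to unknown channels: ",
         paste(unknown, collapse = ", "))
  }
  if (any(spans$end_s <= spans$start_s)) {
    stop("artifact spans must satisfy start_s < end_s")
  }
  # clip to the recording and merge overlaps per channel
  spans$start_s <- pmax(spans$start_s, 0)
  spans$end_s <- pmin(spans$end_s, dur)
  spans <- spans[spans$end_s > spans$start_s, , drop = FALSE]
  spans <- dplyr::arrange(spans, .data$channel_name, .data$start_s)
  merged <- dplyr::group_modify(
    dplyr::group_by(spans, .data$channel_name),
    function(df, key) {
      out <- df[1, c("start_s", "end_s")]
      if (nrow(df) > 1) {
        for (i in 2:nrow(df)) {
          last <- nrow(out)
          if (df$start_s[i] <= out$end_s[last]) {
            out$end_s[last] <- max(out$end_s[last], df$end_s[i])
          } else {
            out <- rbind(out, df[i, c("start_s", "end_s")])
          }
        }
      }
      out
    }
  )
  merged <- dplyr::ungroup(merged)
  fully_masked <- merged$channel_name[
    merged$start_s <= 0 & merged$end_s >= dur]
  if (length(fully_masked)) {
    warning("artifact mask covers all data for channel(s): ",
            paste(unique(fully_masked), collapse = ", "),
            "; they will contribute no windows")
  }
  attr(rec, "artifact_mask") <- merged
  rec
}

#' Resample recordings to the common 500 Hz analysis rate
#'
#' Recordings at 1000 or 2000 Hz are decimated to 500 Hz through cascaded
#' anti-aliased factor-2 FIR stages (30th-order low-pass at 0.8 times the
#' target Nyquist per stage, linear-phase). Recordings already at or below
#' 512 Hz are passed through unchanged at their native rate.
#'
#' @param rec A [seeg_recording()].
#' @return The recording at 500 Hz (or unchanged when `fs <= 512`).
#' @export
resample_to_500 <- function(rec) {
  assert_recording(rec)
  fs <- rec$fs
  if (!fs %in% c(512, 1000, 2000)) {
    warning("unusual sampling rate ", fs,
            " Hz (expected 512, 1000 or 2000 Hz)")
  }
  if (fs <= 512) return(rec)
  q_total <- fs / 500
  if (abs(q_total - round(q_total)) > 1e-9) {
    stop("sampling rate ", fs, " Hz is not an integer multiple of 500 Hz")
  }
  q_total <- as.integer(round(q_total))
  stages <- integer(0)
  while (q_total %% 2L == 0L && q_total > 1L) {
    stages <- c(stages, 2L)
    q_total <- q_total %/% 2L
  }
  if (q_total > 1L) stages <- c(stages, q_total)
  dat <- rec$data
  for (q in stages) {
    dat <- t(apply(dat, 1, function(x) signal::decimate(x, q, ftype = "fir")))
  }
  mask <- attr(rec, "artifact_mask")
  rec$data <- dat
  rec$fs <- 500
  rownames(rec$data) <- rec$channel_names
  attr(rec, "artifact_mask") <- mask  # spans are in seconds, rate-invariant
  rec
}

# second-order IIR notch (biquad), standard audio-EQ design
notch_biquad <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Remove power-line interference
#'
#' Applies zero-phase second-order IIR notches (quality factor 30) at the
#' 50 Hz mains frequency and its odd harmonics strictly below the Nyquist
#' frequency (50 and 150 Hz at a 500 Hz rate; 250 Hz is added only when the
#' sampling rate exceeds 500 Hz).
#'
#' @param rec A [seeg_recording()].
#' @param mains_hz Mains frequency (Hz), 50 by default.
#' @param q Notch quality factor.
#' @return The notch-filtered recording.
#' @export
notch_power_line <- function(rec, mains_hz = 50, q = 30) {
  assert_recording(rec)
  nyq <- rec$fs / 2
  freqs <- mains_hz * c(1, 3, 5)
  freqs <- freqs[freqs < nyq]
  if (rec$fs <= 500) freqs <- freqs[freqs <= 150]
  for (f0 in freqs) {
    flt <- notch_biquad(f0, rec$fs, Q = q)
    rec$data <- t(apply(rec$data, 1, function(x) zp_filter(flt, x)))
  }
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Zero-phase band-pass filtering into an analysis band
#'
#' Filters every channel with a zero-phase forward-backward 4th-order
#' Butterworth band-pass (unit gain at the geometric band centre). An
#' upper edge at or above 0.99 times Nyquist is unrealizable as a
#' band-pass and the filter degrades to a high-pass at the lower edge
#' (e.g. the 80--250 Hz ripple band at a 500 Hz rate).
#'
#' @param rec A [seeg_recording()].
#' @param band A band spec from [canonical_bands()], or a band name.
#' @return The band-filtered recording, with the band recorded in the
#'   `band` attribute.
#' @export
band_filter <- function(rec, band) {
  assert_recording(rec)
  if (is.character(band)) band <- canonical_bands(band)
  nyq <- rec$fs / 2
  if (band$low_hz >= nyq) {
    stop("band '", band$name, "' (", band$low_hz, "-", band$high_hz,
         " Hz) lies entirely at/above Nyquist (", nyq, " Hz) for fs = ",
         rec$fs, " Hz")
  }
  flt <- if (band$high_hz >= 0.99 * nyq) {
    signal::butter(4, band$low_hz / nyq, type = "high")
  } else {
    signal::butter(4, c(band$low_hz, band$high_hz) / nyq, type = "pass")
  }
  rec$data <- t(apply(rec$data, 1, function(x) zp_filter(flt, x)))
  rownames(rec$data) <- rec$channel_names
  attr(rec, "band") <- band
  rec
}

#' Cut a recording into fixed non-overlapping windows
#'
#' Tiles 10 s non-overlapping windows from the start of the recording and
#' keeps, per channel, the first `total_s / window_s` windows that do not
#' overlap any artifact span (see [reject_artifacts()]). Channels without
#' enough clean windows are dropped with a warning.
#'
#' @param rec A (typically band-filtered) [seeg_recording()].
#' @param window_s Window length in seconds (default 10).
#' @param total_s Total analysed duration in seconds (default 200, i.e. 20
#'   windows).
#' @return A `windowed_signal` object: list with `windows` (named list of
#'   n_windows x samples matrices per channel), `window_index` (original
#'   window positions per channel), `fs`, `window_s`, `band`, `period`,
#'   `patient_id`.
#' @export
extract_windows <- function(rec, window_s = 10, total_s = 200) {
  assert_recording(rec)
  n_win <- total_s / window_s
  if (abs(n_win - round(n_win)) > 1e-9 || n_win < 1) {
    stop("`total_s` must be a positive multiple of `window_s`")
  }
  n_win <- as.integer(round(n_win))
  wlen <- window_s * rec$fs
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop("window length in samples (window_s * fs) must be an integer")
  }
  wlen <- as.integer(round(wlen))
  n_avail <- ncol(rec$data) %/% wlen
  mask <- attr(rec, "artifact_mask")
  windows <- list()
  kept_index <- list()
  for (ch in rec$channel_names) {
    ok <- rep(TRUE, n_avail)
    if (!is.null(mask)) {
      sp <- mask[mask$channel_name == ch, , drop = FALSE]
      if (nrow(sp)) {
        for (w in seq_len(n_avail)) {
          w0 <- (w - 1) * window_s
          w1 <- w * window_s
          if (any(sp$start_s < w1 & sp$end_s > w0)) ok[w] <- FALSE
        }
      }
    }
    usable <- which(ok)
    if (length(usable) < n_win) {
      warning("channel ", ch, ": only ", length(usable),
              " clean windows available (need ", n_win, "); channel dropped")
      next
    }
    take <- usable[seq_len(n_win)]
    mat <- matrix(0, n_win, wlen)
    for (i in seq_along(take)) {
      s0 <- (take[i] - 1L) * wlen
      mat[i, ] <- rec$data[ch, (s0 + 1):(s0 + wlen)]
    }
    windows[[ch]] <- mat
    kept_index[[ch]] <- take - 1L  # 0-based window positions
  }
  if (!length(windows)) {
    stop("no channel retains ", n_win, " clean windows of ", window_s, " s")
  }
  structure(
    list(windows = windows, window_index = kept_index, fs = rec$fs,
         window_s = window_s, band = attr(rec, "band"),
         period = rec$period, patient_id = rec$patient_id),
    class = "windowed_signal"
  )
}

#' @export
print.windowed_signal <- function(x, ...) {
  cat(sprintf("<windowed_signal> patient %s, period %s, band %s: %d channels x %d windows of %g s @ %g Hz\n",
              x$patient_id, x$period,
              if (is.null(x$band)) "<none>" else x$band$name,
              length(x$windows), nrow(x$windows[[1]]), x$window_s, x$fs))
  invisible(x)
}

#' Remove thermocoagulated contacts from post-operative recordings
#'
#' After thermocoagulation only noise remains on RF-TC contacts, so their
#' channels are removed from post-operative data. Pre-operative recordings
#' pass through unchanged.
#'
#' @param rec A [seeg_recording()].
#' @param contacts Contact metadata with columns `patient_id`,
#'   `channel_name`, `is_tc`.
#' @return The recording without TC channels (when `period == "post"`).
#' @export
drop_tc_channels_post <- function(rec, contacts) {
  assert_recording(rec)
  if (rec$period != "post") return(rec)
  ci <- contacts[contacts$patient_id == rec$patient_id, , drop = FALSE]
  tc <- ci$channel_name[ci$is_tc]
  missing <- setdiff(tc, rec$channel_names)
  if (length(missing)) {
    stop("TC-flagged channel(s) absent from recording: ",
         paste(missing, collapse = ", "))
  }
  keep <- setdiff(rec$channel_names, tc)
  if (!length(keep)) stop("all channels are TC-flagged; nothing remains")
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channel_names <- keep
  rec
}

#' Full preprocessing chain for one recording
#'
#' Applies, in order: TC-channel removal (post-operative only), average
#' reference, artifact masking, resampling to 500 Hz (for 1000/2000 Hz
#' inputs), power-line notches, band-pass decomposition into the four
#' canonical bands, and fixed windowing.
#'
#' @param rec A [seeg_recording()].
#' @param contacts Contact metadata (see [drop_tc_channels_post()]).
#' @param bad_spans Optional artifact span table (see [reject_artifacts()]).
#' @param window_s,total_s Windowing parameters (see [extract_windows()]).
#' @return Named list of `windowed_signal` objects, one per band.
#' @export
preprocess_recording <- function(rec, contacts, bad_spans = NULL,
                                 window_s = 10, total_s = 200) {
  rec <- drop_tc_channels_post(rec, contacts)
  rec <- average_reference(rec)
  rec <- reject_artifacts(rec, bad_spans)
  rec <- resample_to_500(rec)
  rec <- notch_power_line(rec)
  lapply(canonical_bands(), function(b) {
    extract_windows(band_filter(rec, b), window_s = window_s,
                    total_s = total_s)
  })
}
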