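#' Configuration for the synthetic SEEG cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: a cohort of
#' 10 patients (8 responders, 2 non-responders) whose contact counts yield
#' on the order of 834 responder and 163 non-responder non-TC contacts, with
#' band-specific amplitude and irregularity effects on responder TC contacts
#' (pre-operative) and group-specific post-operative shifts on non-TC
#' contacts.
#'
#' Signals are built per channel as the sum of three sub-band components
#' (low 0.5--50, high-gamma 50--80, ripple 80--250 Hz). Each component
#' mixes a "regular" part -- `1/f^a`-coloured in-band noise
#' amplitude-modulated by a slow burst envelope, emulating waxing/waning
#' oscillatory background activity -- with an "irregular" part of
#' stationary white in-band noise. The irregular fraction (`irr`) raises
#' approximate entropy at fixed RMS (flatter in-band spectrum in wide
#' bands, loss of burst structure in narrow ones), while the component RMS
#' (`amp`) sets line length. Effects are therefore expressed as per-band
#' RMS multipliers (`amp`) and additive irregularity shifts (`irr`).
#'
#' @param n_patients Number of patients.
#' @param n_responders Number of responders (Engel class I); the remaining
#'   patients are non-responders.
#' @param contacts_per_patient Integer range (length 2) of contact counts
#'   for responder patients.
#' @param contacts_per_patient_nonresponder Integer range for non-responder
#'   patients (smaller montages, so that default totals approximate the
#'   834:163 non-TC contact split).
#' @param tc_fraction Fraction of each patient's contacts flagged as
#'   thermocoagulated, in (0, 1).
#' @param sampling_rate Hz, one of 512, 1000, 2000.
#' @param duration_s Seconds per period (>= 200).
#' @param band_amplitudes Baseline RMS (microvolts) of the three sub-band
#'   components, named `low`, `high_gamma`, `ripple`.
#' @param baseline_irregularity Baseline white-mixture fraction per
#'   sub-band, each in (0, 1).
#' @param tc_effect List with per-band `amp` multipliers and additive `irr`
#'   shifts applied to responder TC contacts pre-operatively.
#' @param post_shift_responder,post_shift_nonresponder Same structure,
#'   applied to non-TC contacts post-operatively for each outcome group.
#' @param amp_jitter_sd Log-normal SD of per-contact amplitude jitter.
#' @param irr_jitter_sd Normal SD of per-contact irregularity jitter.
#' @param line_noise_amp RMS amplitude (microvolts) of injected 50 Hz mains
#'   interference (odd harmonics at 1/3 and 1/5 amplitude).
#' @param noise_exponent Spectral slope `a` of the coloured (`1/f^a`)
#'   component.
#' @param seed Integer seed; identical seed and configuration give a
#'   bit-identical cohort.
#' @return A validated list with class `sim_config`.
#' @export
sim_config <- function(n_patients = 10,
                       n_responders = 8,
                       contacts_per_patient = c(125, 155),
                       contacts_per_patient_nonresponder = c(95, 120),
                       tc_fraction = 0.26,
                       sampling_rate = 512,
                       duration_s = 200,
                       band_amplitudes = c(low = 50, high_gamma = 6,
                                           ripple = 3),
                       baseline_irregularity = c(low = 0.30,
                                                 high_gamma = 0.30,
                                                 ripple = 0.30),
                       tc_effect = list(
                         amp = c(low = 1.00, high_gamma = 1.60,
                                 ripple = 1.60),
                         irr = c(low = 0.25, high_gamma = 0.00,
                                 ripple = 0.25)),
                       post_shift_responder = list(
                         amp = c(low = 0.75, high_gamma = 0.75,
                                 ripple = 0.75),
                         irr = c(low = 0.00, high_gamma = -0.15,
                                 ripple = -0.15)),
                       post_shift_nonresponder = list(
                         amp = c(low = 1.35, high_gamma = 1.00,
                                 ripple = 1.35),
                         irr = c(low = -0.15, high_gamma = 0.00,
                                 ripple = -0.15)),
                       amp_jitter_sd = 0.08,
                       irr_jitter_sd = 0.05,
                       line_noise_amp = 10,
                       noise_exponent = 1,
                       seed = 1) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_responders = as.integer(n_responders),
    contacts_per_patient = as.integer(contacts_per_patient),
    contacts_per_patient_nonresponder =
      as.integer(contacts_per_patient_nonresponder),
    tc_fraction = tc_fraction,
    sampling_rate = sampling_rate,
    duration_s = duration_s,
    band_amplitudes = band_amplitudes,
    baseline_irregularity = baseline_irregularity,
    tc_effect = tc_effect,
    post_shift_responder = post_shift_responder,
    post_shift_nonresponder = post_shift_nonresponder,
    amp_jitter_sd = amp_jitter_sd,
    irr_jitter_sd = irr_jitter_sd,
    line_noise_amp = line_noise_amp,
    noise_exponent = noise_exponent,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

sub_bands <- function() c("low", "high_gamma", "ripple")

validate_sim_config <- function(cfg) {
  if (cfg$n_responders <= 0 || cfg$n_responders > cfg$n_patients) {
    stop("need 0 < n_responders <= n_patients")
  }
  if (cfg$tc_fraction <= 0 || cfg$tc_fraction >= 1) {
    stop("tc_fraction must lie strictly between 0 and 1")
  }
  if (cfg$duration_s < 200) stop("duration_s must be >= 200 s")
  if (!cfg$sampling_rate %in% c(512, 1000, 2000)) {
    stop("sampling_rate must be one of 512, 1000, 2000 Hz")
  }
  nyq <- cfg$sampling_rate / 2
  if (nyq <= 80) {
    stop("configuration error: ripple band (80-250 Hz) is not resolvable ",
         "at sampling rate ", cfg$sampling_rate, " Hz")
  }
  for (nm in c("band_amplitudes", "baseline_irregularity")) {
    if (!all(sub_bands() %in% names(cfg[[nm]]))) {
      stop("`", nm, "` must be named with: ",
           paste(sub_bands(), collapse = ", "))
    }
  }
  for (nm in c("tc_effect", "post_shift_responder",
               "post_shift_nonresponder")) {
    eff <- cfg[[nm]]
    if (!is.list(eff) || !all(c("amp", "irr") %in% names(eff)) ||
        !all(sub_bands() %in% names(eff$amp)) ||
        !all(sub_bands() %in% names(eff$irr))) {
      stop("`", nm, "` must be list(amp = <named by band>, irr = <named by band>)")
    }
  }
  if (any(cfg$contacts_per_patient < 2) ||
      any(cfg$contacts_per_patient_nonresponder < 2)) {
    stop("contact count ranges must be >= 2")
  }
  invisible(cfg)
}

#' Effect-free (null) variant of a simulation configuration
#'
#' Sets all TC effects and post-operative shifts to zero (amplitude
#' multipliers 1, irregularity shifts 0), so TC and non-TC contacts are
#' exchangeable draws and pre/post periods are identically distributed.
#'
#' @param config A [sim_config()].
#' @return The configuration with all effects removed.
#' @export
null_effects <- function(config = sim_config()) {
  flat <- list(amp = c(low = 1, high_gamma = 1, ripple = 1),
               irr = c(low = 0, high_gamma = 0, ripple = 0))
  config$tc_effect <- flat
  config$post_shift_responder <- flat
  config$post_shift_nonresponder <- flat
  config
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Layout draws (contact structure + generative truth). Must be called
# inside the seeded RNG context; draw order defines the seed contract.
cohort_layout_impl <- function(cfg) {
  pid <- sprintf("P%02d", seq_len(cfg$n_patients))
  outcome <- ifelse(seq_len(cfg$n_patients) <= cfg$n_responders,
                    "responder", "non_responder")
  outcomes <- tibble::tibble(patient_id = pid, outcome = outcome)

  contacts <- list()
  truth <- list()
  for (i in seq_len(cfg$n_patients)) {
    rng <- if (outcome[i] == "responder") cfg$contacts_per_patient else
      cfg$contacts_per_patient_nonresponder
    n_c <- sample(rng[1]:rng[2], 1)
    # electrodes carry 8-18 contacts each
    sizes <- integer(0)
    while (sum(sizes) < n_c) sizes <- c(sizes, sample(8:18, 1))
    sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - n_c)
    sizes <- sizes[sizes > 0]
    electrode <- rep(LETTERS[seq_along(sizes)], sizes)
    contact_index <- unlist(lapply(sizes, seq_len))
    channel_name <- paste0(electrode, contact_index)
    n_tc <- max(1L, round(cfg$tc_fraction * n_c))
    is_tc <- rep(FALSE, n_c)
    is_tc[sample.int(n_c, n_tc)] <- TRUE
    contacts[[i]] <- tibble::tibble(
      patient_id = pid[i], channel_name = channel_name,
      electrode = electrode, contact_index = contact_index, is_tc = is_tc)

    shift <- if (outcome[i] == "responder") cfg$post_shift_responder else
      cfg$post_shift_nonresponder
    for (b in sub_bands()) {
      amp0 <- cfg$band_amplitudes[[b]] *
        exp(stats::rnorm(n_c, 0, cfg$amp_jitter_sd))
      irr0 <- clamp(cfg$baseline_irregularity[[b]] +
                      stats::rnorm(n_c, 0, cfg$irr_jitter_sd), 0.02, 0.95)
      amp_pre <- amp0
      irr_pre <- irr0
      if (outcome[i] == "responder") {
        amp_pre[is_tc] <- amp_pre[is_tc] * cfg$tc_effect$amp[[b]]
        irr_pre[is_tc] <- clamp(irr_pre[is_tc] + cfg$tc_effect$irr[[b]],
                                0.02, 0.95)
      }
      amp_post <- amp0
      irr_post <- irr0
      amp_post[!is_tc] <- amp_post[!is_tc] * shift$amp[[b]]
      irr_post[!is_tc] <- clamp(irr_post[!is_tc] + shift$irr[[b]],
                                0.02, 0.95)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        patient_id = pid[i], channel_name = channel_name, band = b,
        amp_pre = amp_pre, irr_pre = irr_pre,
        amp_post = amp_post, irr_post = irr_post)
    }
  }
  list(contacts = dplyr::bind_rows(contacts),
       outcomes = outcomes,
       truth = dplyr::bind_rows(truth))
}

#' Contact structure of a synthetic cohort (no signals)
#'
#' Draws the metadata layer of [generate_cohort()] -- contact metadata,
#' outcome labels and per-contact generative truth -- without synthesizing
#' any signal. Useful for design studies of contact counts and class
#' balance; under the same configuration the layout is identical to the one
#' inside [generate_cohort()].
#'
#' @param config A [sim_config()].
#' @return List with `contacts`, `outcomes` and `truth` tibbles.
#' @export
cohort_layout <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, cohort_layout_impl(config))
}

# Band-limiting power envelope for component synthesis: squared magnitude
# of a zero-phase 4th-order Butterworth high-pass/low-pass pair evaluated
# on a frequency grid (the generative band shape; the analysis band-pass
# in band_filter() is designed independently).
butter_power_env <- function(f, low_hz, high_hz, nyq) {
  fpos <- pmax(f, 1e-12)
  env <- (1 / (1 + (low_hz / fpos)^8))^2
  env[f <= 0] <- 0
  if (high_hz < 0.99 * nyq) {
    env <- env * (1 / (1 + (f / high_hz)^8))^2
  }
  env
}

# Per-band power spectra of the coloured (1/f^a) and white in-band
# components on the n-point FFT grid (mean-normalized), plus the slow
# (0.2-3 Hz) spectrum driving the burst envelopes.
make_band_spectra <- function(n, fs, alpha) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n   # two-sided (folded) frequency axis
  nyq <- fs / 2
  out <- list()
  for (b in sub_bands()) {
    spec <- canonical_bands(b)
    env <- butter_power_env(f, spec$low_hz, spec$high_hz, nyq)
    colored <- env * ifelse(f > 0, f^(-alpha), 0)
    out[[b]] <- list(colored = colored / mean(colored),
                     white = env / mean(env))
  }
  out$.envelope <- ifelse(f >= 0.2 & f <= 3, 1, 0)
  out
}

# draw a realization of a Gaussian process with the given (relative) PSD
synth_psd <- function(psd) {
  n <- length(psd)
  z <- stats::fft(stats::rnorm(n))
  Re(stats::fft(z * sqrt(psd), inverse = TRUE)) / n
}

# slow non-negative burst envelope with unit mean square
burst_envelope <- function(env_psd) {
  e <- pmax(synth_psd(env_psd), 0)
  e / sqrt(mean(e^2))
}

# One channel-period realization. Each sub-band component mixes a
# "regular" part -- coloured (1/f^a) in-band noise amplitude-modulated by a
# slow burst envelope, emulating waxing/waning oscillatory background --
# with an "irregular" part of stationary white in-band noise. The
# irregularity weight therefore raises approximate entropy in every band
# (it flattens the in-band spectrum in wide bands and removes burst
# structure in narrow ones) while band RMS is controlled separately.
synth_channel <- function(n, fs, truth_row_by_band, period, cfg,
                          band_spectra) {
  x <- numeric(n)
  for (b in sub_bands()) {
    tr <- truth_row_by_band[[b]]
    amp <- if (period == "pre") tr$amp_pre else tr$amp_post
    irr <- if (period == "pre") tr$irr_pre else tr$irr_post
    reg <- synth_psd(band_spectra[[b]]$colored) *
      burst_envelope(band_spectra$.envelope)
    reg <- reg / stats::sd(reg)
    wht <- synth_psd(band_spectra[[b]]$white)
    wht <- wht / stats::sd(wht)
    comp <- sqrt(1 - irr) * reg + sqrt(irr) * wht
    x <- x + amp * comp / stats::sd(comp)
  }
  if (cfg$line_noise_amp > 0) {
    t <- seq_len(n) / fs
    phase <- stats::runif(1, 0, 2 * pi)
    nyq <- fs / 2
    for (h in c(1, 3, 5)) {
      f0 <- 50 * h
      if (f0 < nyq) {
        x <- x + (cfg$line_noise_amp * sqrt(2) / h) *
          sin(2 * pi * f0 * t + phase)
      }
    }
  }
  x
}

#' Generate a synthetic pre/post SEEG cohort
#'
#' Produces one pre-operative and one post-operative recording per patient
#' with the contact structure, class imbalance and band-specific biomarker
#' effects configured in [sim_config()]. Every contact appears in both
#' periods with a consistent channel order; post-operative TC contacts are
#' generated (at baseline parameters) but are expected to be removed
#' downstream by [drop_tc_channels_post()].
#'
#' @param config A [sim_config()].
#' @return A `seeg_cohort`: list with `recordings` (named
#'   `"<patient>_<period>"`), `contacts`, `outcomes`, `truth` and `config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 2, n_responders = 1,
#'                   contacts_per_patient = c(4, 4),
#'                   contacts_per_patient_nonresponder = c(4, 4))
#' layout <- cohort_layout(cfg)
#' table(layout$contacts$is_tc)
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    layout <- cohort_layout_impl(config)
    n <- as.integer(round(config$duration_s * config$sampling_rate))
    band_spectra <- make_band_spectra(n, config$sampling_rate,
                                      config$noise_exponent)
    recordings <- list()
    for (pid in layout$outcomes$patient_id) {
      ci <- layout$contacts[layout$contacts$patient_id == pid, ]
      tr <- layout$truth[layout$truth$patient_id == pid, ]
      for (period in c("pre", "post")) {
        dat <- matrix(0, nrow(ci), n)
        for (j in seq_len(nrow(ci))) {
          ch <- ci$channel_name[j]
          rows <- lapply(stats::setNames(sub_bands(), sub_bands()),
                         function(b) tr[tr$channel_name == ch & tr$band == b, ])
          dat[j, ] <- synth_channel(n, config$sampling_rate, rows, period,
                                    config, band_spectra)
        }
        recordings[[paste0(pid, "_", period)]] <- seeg_recording(
          dat, fs = config$sampling_rate, channel_names = ci$channel_name,
          period = period, patient_id = pid)
      }
    }
    structure(list(recordings = recordings, contacts = layout$contacts,
                   outcomes = layout$outcomes, truth = layout$truth,
                   config = config),
              class = "seeg_cohort")
  })
}

#' @export
print.seeg_cohort <- function(x, ...) {
  nt <- table(x$outcomes$outcome)
  cat(sprintf("<seeg_cohort> %d patients (%s), %d contacts (%d TC), %d recordings @ %g Hz\n",
              nrow(x$outcomes),
              paste(sprintf("%d %s", nt, names(nt)), collapse = ", "),
              nrow(x$contacts), sum(x$contacts$is_tc),
              length(x$recordings), x$config$sampling_rate))
  invisible(x)
}

#' Write / read a synthetic cohort bundle
#'
#' Serializes a cohort to a directory: channel metadata, outcomes and
#' generative truth as tab-separated text, the configuration as YAML, and
#' the signal arrays as one RDS file per recording (a compact binary bundle
#' intended for fast intermediate storage, not for archival exchange).
#'
#' @param cohort A `seeg_cohort`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly (for `write_cohort`); a `seeg_cohort` (for
#'   `read_cohort`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$contacts, file.path(dir, "contacts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$outcomes, file.path(dir, "outcomes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  cfg$tc_effect <- lapply(cfg$tc_effect, as.list)
  cfg$post_shift_responder <- lapply(cfg$post_shift_responder, as.list)
  cfg$post_shift_nonresponder <- lapply(cfg$post_shift_nonresponder, as.list)
  cfg$band_amplitudes <- as.list(cfg$band_amplitudes)
  cfg$baseline_irregularity <- as.list(cfg$baseline_irregularity)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  sigdir <- file.path(dir, "signals")
  dir.create(sigdir, showWarnings = FALSE)
  for (nm in names(cohort$recordings)) {
    saveRDS(cohort$recordings[[nm]], file.path(sigdir, paste0(nm, ".rds")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  contacts <- tibble::as_tibble(utils::read.delim(
    file.path(dir, "contacts.tsv")))
  outcomes <- tibble::as_tibble(utils::read.delim(
    file.path(dir, "outcomes.tsv")))
  truth <- tibble::as_tibble(utils::read.delim(file.path(dir, "truth.tsv")))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  sigdir <- file.path(dir, "signals")
  files <- list.files(sigdir, pattern = "\\.rds$", full.names = TRUE)
  recordings <- lapply(files, readRDS)
  names(recordings) <- sub("\\.rds$", "", basename(files))
  structure(list(recordings = recordings, contacts = contacts,
                 outcomes = outcomes, truth = truth, config = cfg),
            class = "seeg_cohort")
}
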