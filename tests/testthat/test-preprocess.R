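make_rec <- function(data, fs = 500, period = "pre", pid = "P01") {
  data <- rbind(data)
  seeg_recording(data, fs = fs,
                 channel_names = paste0("A", seq_len(nrow(data))),
                 period = period, patient_id = pid)
}

test_that("average reference removes the instantaneous across-channel mean", {
  rec <- make_rec(rbind(c(1, 1, 1), c(3, 3, 3)))
  out <- average_reference(rec)
  expect_equal(unname(out$data[1, ]), c(-1, -1, -1))
  expect_equal(unname(out$data[2, ]), c(1, 1, 1))

  set.seed(1)
  rec2 <- make_rec(matrix(rnorm(5 * 100), 5, 100))
  out2 <- average_reference(rec2)
  expect_lt(max(abs(colSums(out2$data))), 1e-9)

  same <- make_rec(rbind(sin(1:50), sin(1:50), sin(1:50)))
  expect_lt(max(abs(average_reference(same)$data)), 1e-12)

  expect_error(average_reference(make_rec(matrix(1:10, 1))), "2 channels")
})

test_that("resampling to 500 Hz preserves in-band content", {
  t1k <- seq(0, 10 - 1 / 1000, by = 1 / 1000)
  rec <- make_rec(rbind(sin(2 * pi * 10 * t1k), cos(2 * pi * 10 * t1k)),
                  fs = 1000)
  out <- resample_to_500(rec)
  expect_equal(out$fs, 500)
  expect_equal(ncol(out$data), 5000)
  pk <- dominant_peak(out$data[1, ], fs = 500)
  expect_equal(pk$freq, 10, tolerance = 1e-6)
  expect_equal(pk$amp, 1, tolerance = 0.01)

  rec512 <- make_rec(matrix(rnorm(2 * 512), 2), fs = 512)
  expect_identical(resample_to_500(rec512), rec512)

  t2k <- seq(0, 4 - 1 / 2000, by = 1 / 2000)
  con <- make_rec(rbind(rep(3, length(t2k)), rep(-1, length(t2k))),
                  fs = 2000)
  outc <- resample_to_500(con)
  expect_equal(outc$fs, 500)
  interior <- 100:(ncol(outc$data) - 100)
  expect_equal(unname(outc$data[1, interior]),
               rep(3, length(interior)), tolerance = 0.01)

  odd <- make_rec(matrix(rnorm(2 * 1500), 2), fs = 1500)
  expect_warning(resample_to_500(odd), "unusual sampling rate")
})

test_that("power-line notches remove 50 Hz and harmonics, spare the passband", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  interior <- (5 * fs):(15 * fs)  # steady state, clear of edge transients
  mains <- sin(2 * pi * 50 * t)
  rec <- make_rec(rbind(mains, mains), fs = fs)
  out <- notch_power_line(rec)
  expect_lt(rms(out$data[1, interior]) / rms(mains[interior]), 0.032)

  probe <- sin(2 * pi * 40 * t)
  outp <- notch_power_line(make_rec(rbind(probe, probe), fs = fs))
  expect_equal(rms(outp$data[1, interior]) / rms(probe[interior]), 1,
               tolerance = 0.10)

  # periodogram dips at the notch centers, flat elsewhere
  set.seed(7)
  wn <- rnorm(fs * 40)
  outw <- notch_power_line(make_rec(rbind(wn, wn), fs = fs))
  p <- Mod(stats::fft(outw$data[1, ]))^2
  f <- (seq_along(p) - 1) * fs / length(p)
  bandpow <- function(lo, hi) mean(p[f >= lo & f <= hi])
  expect_lt(bandpow(49.5, 50.5), 0.2 * bandpow(42, 47))
  expect_lt(bandpow(149.5, 150.5), 0.2 * bandpow(142, 147))
  expect_equal(bandpow(55, 140) / bandpow(10, 45), 1, tolerance = 0.2)
})

test_that("band filters pass in-band probes and reject out-of-band probes", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  db <- function(ratio) 20 * log10(ratio)

  p10 <- sin(2 * pi * 10 * t)
  rec10 <- make_rec(rbind(p10, p10), fs = fs)
  low <- band_filter(rec10, "low")
  expect_lt(abs(db(rms(low$data[1, ]) / rms(p10))), 1)

  ripple <- band_filter(rec10, "ripple")
  expect_lt(db(rms(ripple$data[1, ]) / rms(p10)), -20)

  p65 <- sin(2 * pi * 65 * t)
  hg <- band_filter(make_rec(rbind(p65, p65), fs = fs), "high_gamma")
  expect_lt(abs(db(rms(hg$data[1, ]) / rms(p65))), 1)

  # an octave outside either edge of the high-gamma band: >= 20 dB down
  p25 <- sin(2 * pi * 25 * t)
  hg25 <- band_filter(make_rec(rbind(p25, p25), fs = fs), "high_gamma")
  expect_lt(db(rms(hg25$data[1, ]) / rms(p25)), -20)
  p160 <- sin(2 * pi * 160 * t)
  hg160 <- band_filter(make_rec(rbind(p160, p160), fs = fs), "high_gamma")
  expect_lt(db(rms(hg160$data[1, ]) / rms(p160)), -20)

  # band entirely above Nyquist
  rec_lofs <- make_rec(matrix(rnorm(2 * 1200), 2), fs = 120)
  expect_error(band_filter(rec_lofs, "ripple"), "Nyquist")
})

test_that("band-pass filtering is zero-phase", {
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  rec <- make_rec(rbind(x, x), fs = fs)
  y <- band_filter(rec, "low")$data[1, ]
  lags <- -10:10
  cc <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(x[1:(length(x) - l)], y[(1 + l):length(y)])
    else stats::cor(x[(1 - l):length(x)], y[1:(length(y) + l)])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("windowing yields the fixed non-overlapping partition", {
  fs <- 500
  rec <- make_rec(matrix(rnorm(2 * fs * 200), 2), fs = fs)
  ws <- extract_windows(rec)
  expect_length(ws$windows, 2)
  expect_equal(dim(ws$windows[["A1"]]), c(20, 5000))
  expect_equal(ws$window_index[["A1"]], 0:19)
  # partition conserves samples
  expect_equal(20 * 5000, 200 * fs)
  # windows tile the signal in order
  expect_equal(ws$windows[["A1"]][3, ], unname(rec$data[1, 10001:15000]))

  rec205 <- make_rec(matrix(rnorm(fs * 205 * 2), 2), fs = fs)
  ws205 <- extract_windows(rec205)
  expect_equal(dim(ws205$windows[["A1"]]), c(20, 5000))

  rec150 <- make_rec(matrix(rnorm(fs * 150 * 2), 2), fs = fs)
  suppressWarnings(expect_error(extract_windows(rec150), "clean windows"))
})

test_that("artifact spans exclude exactly the overlapping windows", {
  fs <- 100
  rec <- make_rec(matrix(rnorm(2 * fs * 210), 2), fs = fs)
  spans <- data.frame(channel_name = "A1", start_s = 0, end_s = 10)
  marked <- reject_artifacts(rec, spans)
  ws <- extract_windows(marked, window_s = 10, total_s = 200)
  # A1 skips the masked first window and still reaches 20 windows
  expect_equal(ws$window_index[["A1"]], 1:20)
  expect_equal(ws$window_index[["A2"]], 0:19)

  # empty span list is the identity
  expect_identical(reject_artifacts(rec, NULL), rec)
  expect_identical(reject_artifacts(rec, data.frame()), rec)

  # a span covering a whole channel removes it (with warnings)
  all_bad <- data.frame(channel_name = "A2", start_s = 0, end_s = 210)
  expect_warning(marked2 <- reject_artifacts(rec, all_bad), "no windows")
  expect_warning(ws2 <- extract_windows(marked2, 10, 200), "dropped")
  expect_false("A2" %in% names(ws2$windows))

  # invalid spans are rejected
  expect_error(reject_artifacts(rec, data.frame(channel_name = "zz",
                                                start_s = 0, end_s = 1)),
               "unknown channels")
  expect_error(reject_artifacts(rec, data.frame(channel_name = "A1",
                                                start_s = 5, end_s = 5)),
               "start_s < end_s")
})

test_that("TC channels are removed from post-operative recordings only", {
  contacts <- tibble::tibble(
    patient_id = "P01",
    channel_name = paste0("A", 1:10),
    electrode = "A", contact_index = 1:10,
    is_tc = c(rep(TRUE, 3), rep(FALSE, 7)))
  post <- make_rec(matrix(rnorm(10 * 100), 10), period = "post")
  kept <- drop_tc_channels_post(post, contacts)
  expect_equal(n_channels(kept), 7)
  expect_false(any(c("A1", "A2", "A3") %in% kept$channel_names))

  pre <- make_rec(matrix(rnorm(10 * 100), 10), period = "pre")
  expect_identical(drop_tc_channels_post(pre, contacts), pre)

  small_post <- make_rec(matrix(rnorm(5 * 100), 5), period = "post")
  contacts2 <- contacts
  contacts2$channel_name[1] <- "ZZ9"
  expect_error(drop_tc_channels_post(small_post, contacts2),
               "absent from recording")
})

test_that("the preprocessing chain is deterministic on identical input", {
  set.seed(11)
  rec <- make_rec(matrix(rnorm(3 * 512 * 30), 3), fs = 512)
  contacts <- tibble::tibble(patient_id = "P01",
                             channel_name = paste0("A", 1:3),
                             electrode = "A", contact_index = 1:3,
                             is_tc = FALSE)
  a <- preprocess_recording(rec, contacts, window_s = 5, total_s = 20)
  b <- preprocess_recording(rec, contacts, window_s = 5, total_s = 20)
  expect_identical(a, b)
  expect_named(a, c("filtered", "low", "high_gamma", "ripple"))
})
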