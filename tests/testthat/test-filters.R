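test_that("notch removes the target tone and spares neighbours", {
  fs <- 1000
  t <- seq_len(4 * fs) / fs
  tone50 <- sin(2 * pi * 50 * t)
  tone10 <- sin(2 * pi * 10 * t)
  y50 <- notch_filter(tone50, 50, fs = fs)
  y10 <- notch_filter(tone10, 50, fs = fs)
  rms <- function(x) sqrt(mean(x^2))
  core <- (fs + 1):(3 * fs)      # steady-state region away from the ends
  expect_lt(rms(y50[core]) / rms(tone50[core]), 0.03)
  expect_equal(rms(y10[core]) / rms(tone10[core]), 1, tolerance = 0.02)
  expect_equal(notch_filter(rep(0, 1000), 50, fs = fs), rep(0, 1000))
  expect_error(notch_filter(tone50, 600, fs = fs), "Nyquist")
})

test_that("band-pass design hits its passband and stopband", {
  f <- cheby1_bandpass(10, 0.5, 8, 10, 1000)
  resp <- sos_response(f, c(7, 8.5, 9, 9.5, 10.1, 50))
  expect_lt(resp[1], 0.01)
  expect_true(all(resp[2:4] > 10^(-0.5 / 20) - 0.01)) # within the 0.5 dB ripple
  expect_lt(resp[5], 0.2)
  expect_lt(resp[6], 1e-6)
  ## edge bands stay realisable
  expect_silent(cheby1_bandpass(10, 0.5, 0.5, 2, 1000))
  expect_error(cheby1_bandpass(10, 0.5, 58, 62, 120), "Nyquist|band")
})

test_that("zero-phase filtering leaves no group delay", {
  fs <- 250
  t <- seq_len(5 * fs) / fs
  probe <- sin(2 * pi * 9 * t) * exp(-((t - 2.5) / 0.5)^2)
  f <- cheby1_bandpass(10, 0.5, 8, 10, fs)
  y <- sos_filtfilt(probe, f)
  cc <- ccf(probe, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filterbank tiles the spectrum into (electrode, band) atoms", {
  ## component count: 25 channels x 30 bands of 2 Hz over 0-60
  mont <- montage_spec()
  ep <- structure(list(data = matrix(rnorm(25 * 500), 25,
                                     dimnames = list(mont$eeg_labels, NULL)),
                       mi_class = "right_hand", window = c(0, 0.5), fs = 1000),
                  class = "epoch")
  comps <- filterbank(ep)
  expect_length(comps, 750)
  expect_equal(comps[[1]]$band, c(0, 2))
  ## a pure 9 Hz tone concentrates in the 8-10 Hz band
  fs <- 250
  tone <- matrix(sin(2 * pi * 9 * seq_len(4 * fs) / fs), 1,
                 dimnames = list("Cz", NULL))
  ep2 <- structure(list(data = tone, mi_class = "idle", window = c(0, 4),
                        fs = fs), class = "epoch")
  comps2 <- filterbank(ep2, low = 0, high = 30, width = 2)
  vars <- vapply(comps2, function(cp) var(cp$signal), numeric(1))
  best <- comps2[[which.max(vars)]]
  expect_equal(best$band, c(8, 10))
  ## zero in, zero out
  ep0 <- ep2; ep0$data[] <- 0
  comps0 <- filterbank(ep0, low = 0, high = 30, width = 2)
  expect_true(all(vapply(comps0, function(cp) max(abs(cp$signal)), numeric(1)) < 1e-12))
  ## width must divide the range
  expect_error(filterbank(ep2, low = 0, high = 30, width = 7), "width")
})

test_that("filterbank nearly partitions broadband energy", {
  set.seed(4)
  fs <- 125
  x <- rnorm(12 * fs)
  total <- 0
  for (lo in seq(0, 58, 2)) {
    f <- cheby1_bandpass(10, 0.5, max(lo, 0.5), min(lo + 2, fs / 2 - 0.5), fs)
    total <- total + var(sos_filtfilt(x, f))
  }
  covered <- 60 / (fs / 2)   # fraction of the white spectrum inside 0-60 Hz
  expect_gt(total / (var(x) * covered), 0.70)
  expect_lt(total / (var(x) * covered), 1.10)
})

test_that("common average reference zeroes the instantaneous channel mean", {
  X <- matrix(rnorm(5 * 200), 5)
  Y <- car_filter(X)
  expect_lt(max(abs(colMeans(Y))), 1e-10)
  expect_equal(car_filter(matrix(c(1, 2, 3), 3, 10)),
               matrix(c(-1, 0, 1), 3, 10))
  expect_equal(car_filter(Y), Y)
  expect_error(car_filter(matrix(1, 1, 10)), "2 channels")
})

test_that("ocular regression removes shared EOG activity and nothing else", {
  mont <- small_montage(fs = 200)
  sch <- build_schedule(1, 1, 2, seed = 1)
  n <- round((schedule_duration_t(sch) + 2) * 200)
  set.seed(8)
  veog <- as.numeric(stats::filter(rnorm(n), 0.95, method = "recursive"))
  eeg <- matrix(rnorm(6 * n), 6)
  eeg[1, ] <- eeg[1, ] + 0.3 * veog   # C3 contaminated
  eog <- matrix(rnorm(4 * n, 0, 0.5), 4)
  eog[3, ] <- veog                    # VEOG-U carries the artifact source
  rec <- fake_recording(sch, fs = 200, montage = mont, data = rbind(eeg, eog))
  out <- regress_out_eog(rec)
  expect_lt(abs(cor(out$data["C3", ], veog)), 0.05)
  ## channels independent of EOG are nearly untouched
  delta <- out$data["Cz", ] - rec$data["Cz", ]
  expect_lt(sqrt(mean(delta^2)) / sd(rec$data["Cz", ]), 0.05)
  ## EOG rows preserved for blink detection
  expect_identical(out$data["VEOG-U", ], rec$data["VEOG-U", ])
  ## zero EOG: warning, identity
  rec0 <- rec; rec0$data[mont$eog_labels, ] <- 0
  expect_warning(out0 <- regress_out_eog(rec0), "zero")
  expect_identical(out0$data, rec0$data)
})

test_that("epoch extraction follows the schedule", {
  sch <- build_schedule(2, 2, 15, seed = 2)
  rec <- fake_recording(sch, fs = 100)
  eps <- extract_epochs(rec, c(0, 4), baseline_s = 0)
  expect_length(eps, 240)
  expect_equal(nrow(eps[[1]]$data), 25)
  ## idle epochs labelled and cut from the blanks
  eps2 <- extract_epochs(rec, c(0, 4), idle = TRUE, baseline_s = 0)
  labs <- vapply(eps2, `[[`, character(1), "mi_class")
  expect_equal(sum(labs == "idle"), 240)
  ## out-of-range window names the trial
  expect_error(extract_epochs(rec, c(0, 400)), "trial")
  ## a 4-s window at the full sampling rate holds 4000 samples
  sch1 <- build_schedule(1, 1, 1, seed = 3)
  rec1 <- fake_recording(sch1, fs = 1000)
  eps1 <- extract_epochs(rec1, c(0, 4), baseline_s = 0.5)
  expect_equal(ncol(eps1[[1]]$data), 4000)
})
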