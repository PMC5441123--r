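test_that("spectral power behaves like mean squared amplitude", {
  fs <- 250
  tone <- sin(2 * pi * 9 * seq_len(10 * fs) / fs)
  expect_equal(spectral_power(tone), 0.5, tolerance = 0.02)
  expect_equal(spectral_power(rep(0, 100)), 0)
  expect_error(spectral_power(numeric(0)), "empty")
  ## white noise through a 2 Hz band holds ~ bandwidth/Nyquist of its power
  set.seed(2)
  x <- rnorm(60 * fs, 0, 2)
  f <- cheby1_bandpass(10, 0.5, 10, 12, fs)
  p <- spectral_power(sos_filtfilt(x, f))
  expect_equal(p, 4 * 2 / (fs / 2), tolerance = 0.15)
})

test_that("r_squared is the squared point-biserial correlation", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 1, 1), c(2, 2, 2)), 1)
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  ## brute-force oracle: squared Pearson correlation against the label vector
  oracle <- cor(c(a, b), c(1, 1, 1, 0, 0, 0))^2
  expect_equal(r_squared(a, b), oracle)
  expect_error(r_squared(1, c(1, 2)), "at least 2")
  ## affine invariance: same shift/scale on both groups
  expect_equal(r_squared(a * 7 + 3, b * 7 + 3), r_squared(a, b))
  ## zero total variance
  expect_equal(r_squared(c(1, 1), c(1, 1)), 0)
})

make_band_epochs <- function(seed, n = 12, fs = 100, len = 200,
                             boost_class = "foot", boost = 3) {
  ## 2-channel epochs; channel "C3" carries a 10 Hz tone whose amplitude is
  ## boosted for one class -> (C3, 10-12 Hz) must rank first
  set.seed(seed)
  labs <- rep(mi_classes(), n)
  eps <- lapply(labs, function(cl) {
    amp <- if (cl == boost_class) boost else 1
    X <- matrix(rnorm(2 * len, 0, 0.5), 2)
    X[1, ] <- X[1, ] + amp * sin(2 * pi * 10.5 * seq_len(len) / fs +
                                   runif(1, 0, 2 * pi))
    rownames(X) <- c("C3", "Pz")
    structure(list(data = X, mi_class = cl, window = c(0, len / fs), fs = fs),
              class = "epoch")
  })
  list(epochs = eps, labels = labs)
}

test_that("planted separable component ranks first", {
  d <- make_band_epochs(1)
  map <- rank_components(d$epochs, low = 0, high = 20, width = 2)
  top <- map$scores[which.max(map$scores$score), ]
  expect_equal(top$electrode, "C3")
  expect_equal(top$band_lo, 10)
  ## permutation invariance in epoch order
  map2 <- rank_components(rev(d$epochs), low = 0, high = 20, width = 2)
  expect_equal(map$scores$score, map2$scores$score, tolerance = 1e-12)
})

test_that("all-noise data produces only small spurious scores", {
  set.seed(3)
  labs <- rep(mi_classes(), 60)
  eps <- lapply(labs, function(cl)
    structure(list(data = matrix(rnorm(2 * 100), 2,
                                 dimnames = list(c("C3", "Pz"), NULL)),
                   mi_class = cl, window = c(0, 1), fs = 100),
              class = "epoch"))
  map <- rank_components(eps, low = 0, high = 10, width = 2)
  expect_lt(max(map$scores$score), 0.2)
})

test_that("a single class cannot be ranked", {
  d <- make_band_epochs(1)
  solo <- d$epochs[d$labels == "foot"]
  expect_error(rank_components(solo, low = 0, high = 10, width = 2),
               "2 imagery classes")
})

fake_map <- function(scores, idle = NULL, class_power = NULL) {
  n <- nrow(scores)
  structure(list(scores = scores,
                 per_pair = array(0, dim = c(1, n, 6)),
                 class_power = class_power, idle_power = idle,
                 config = list(low = min(scores$band_lo), high = 60,
                               width = 2, order = 10)),
            class = "rsq_map")
}

test_that("selection keeps top_k with deterministic tie-breaks", {
  sc <- data.frame(electrode = rep(c("C3", "Cz", "Pz"), each = 4),
                   band_lo = rep(c(8, 10, 12, 14), 3),
                   band_hi = rep(c(10, 12, 14, 16), 3),
                   score = 0.5, stringsAsFactors = FALSE)
  map <- fake_map(sc)
  sel <- suppressWarnings(select_components(map, top_k = 10, screen = FALSE))
  expect_equal(nrow(sel$selected), 10)
  ## all scores equal: ordered by band then electrode name
  expect_equal(sel$selected$band_lo[1:3], rep(8, 3))
  expect_equal(sel$selected$electrode[1:3], c("C3", "Cz", "Pz"))
  sel2 <- suppressWarnings(select_components(map, top_k = 10, screen = FALSE))
  expect_identical(sel$selected, sel2$selected)
})

test_that("selection recovers the planted electrode-band pairs across seeds", {
  planted <- list(list("Cz", c(8, 12)), list("C3", c(12, 16)),
                  list("C4", c(12, 16)), list("Fz", c(14, 16)))
  mont <- montage_spec(eeg_labels = c("C3", "Cz", "C4", "Fz", "F4", "T7",
                                      "P3", "P4", "FC3", "CP4"),
                       fs = 128)
  recall <- vapply(1:10, function(s) {
    sch <- build_schedule(1, 1, 15, seed = s)
    rec <- render_recording(default_source_model(mont), sch, mont,
                            seed = s + 100)
    eps <- lapply(extract_epochs(regress_out_eog(notch_filter(rec)),
                                 idle = TRUE), car_filter)
    map <- rank_components(eps, low = 0, high = 18, width = 2)
    sel <- select_components(map, top_k = 10, screen = FALSE)$selected
    mean(vapply(planted, function(p)
      any(sel$electrode == p[[1]] & sel$band_lo >= p[[2]][1] - 2 &
            sel$band_hi <= p[[2]][2] + 2), logical(1)))
  }, numeric(1))
  expect_gte(mean(recall), 0.8)
})

test_that("ERD/ERS screening drops implausible components and flags them", {
  d <- make_band_epochs(5, boost = 3)   # foot *increases* C3 power: ERS-like
  rec_eps <- d$epochs
  ## add idle epochs with baseline power
  idle <- lapply(1:8, function(i) {
    X <- matrix(rnorm(2 * 200, 0, 0.5), 2, dimnames = list(c("C3", "Pz"), NULL))
    X[1, ] <- X[1, ] + sin(2 * pi * 10.5 * seq_len(200) / 100)
    structure(list(data = X, mi_class = "idle", window = c(0, 2), fs = 100),
              class = "epoch")
  })
  map <- rank_components(c(rec_eps, idle), low = 8, high = 14, width = 2)
  sel_all <- select_components(map, top_k = 3, screen = FALSE)
  sel_scr <- select_components(map, top_k = 3, screen = TRUE)
  expect_lte(nrow(sel_scr$selected), nrow(sel_all$selected))
  expect_equal(nrow(sel_scr$selected) + length(sel_scr$screen_notes), 3)
})
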