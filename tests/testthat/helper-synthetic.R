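## shared fixtures, all generated in code

## compact montage for fast preprocessing tests
small_montage <- function(fs = 160, n_eog = 4) {
  montage_spec(eeg_labels = c("C3", "Cz", "C4", "Fz", "P3", "P4"),
               fs = fs)
}

## a short rendered recording with the default source model
small_recording <- function(fs = 160, reps = 5, seed = 3, ...) {
  mont <- montage_spec(fs = fs)
  sch <- build_schedule(1, 1, reps, seed = seed + 1)
  render_recording(default_source_model(mont), sch, mont, seed = seed, ...)
}

## a recording-shaped object with arbitrary data (cheap epoch tests)
fake_recording <- function(schedule, fs = 1000, montage = montage_spec(fs = fs),
                           data = NULL) {
  n <- round((schedule_duration_t(schedule) + schedule$blank_s) * fs)
  labs <- c(montage$eeg_labels, montage$eog_labels)
  if (is.null(data)) data <- matrix(0, length(labs), n)
  rownames(data) <- labs
  structure(list(data = data, montage = montage, schedule = schedule,
                 blink_truth = data.frame(time_s = numeric(0),
                                          kind = character(0))),
            class = "recording")
}

schedule_duration_t <- function(schedule)
  max(schedule$entries$onset_s) + schedule$mi_s

## linear mixtures of AR sources with selectable innovation law
ar_mixture <- function(seed, M = 3, T = 20000, kind = c("laplace", "gauss"),
                       ar_list = NULL) {
  kind <- match.arg(kind)
  if (is.null(ar_list))
    ar_list <- list(c(1.6, -0.8), c(0.2, 0.5), c(-1.2, -0.6))
  set.seed(seed + 5000)
  S <- matrix(0, M, T)
  for (i in seq_len(M)) {
    innov <- if (kind == "laplace") {
      v <- rexp(T) - rexp(T); v / sqrt(2)
    } else rnorm(T)
    S[i, ] <- stats::filter(innov, ar_list[[i]], method = "recursive")
  }
  A <- matrix(rnorm(M * M), M)
  list(X = A %*% S, A = A, S = S)
}

## distinct-spectra AR(4) polynomials (two cascaded resonances each)
ar4_bank <- function() {
  res <- function(r, w) c(2 * r * cos(w), -r^2)
  casc <- function(a, b) {  # cascade two AR(2) filters into one AR(4)
    pa <- c(1, -a); pb <- c(1, -b)
    p <- convolve(pa, rev(pb), type = "open")
    -p[-1]
  }
  list(casc(res(0.9, 0.3), res(0.5, 1.2)),
       casc(res(0.85, 1.0), res(0.6, 2.2)),
       casc(res(0.9, 2.0), res(0.4, 0.6)))
}

## epochs with a planted variance difference on one channel for one class
planted_epochs <- function(seed, n_per_class = 20, C = 4, len = 100,
                           boost_channel = 1, boost_class = "right_hand",
                           boost = 2) {
  set.seed(seed)
  labels <- rep(mi_classes(), n_per_class)
  eps <- lapply(labels, function(cl) {
    X <- matrix(rnorm(C * len), C)
    if (cl == boost_class) X[boost_channel, ] <- X[boost_channel, ] * boost
    X
  })
  list(epochs = eps, labels = labels)
}
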