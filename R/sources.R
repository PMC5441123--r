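#' Autoregressive source model for synthetic EEG
#'
#' Cortical sources are modelled as independent stationary autoregressive
#' processes `s_t = sum_k a_k s_{t-k} + e_t` whose innovation scale is
#' multiplied, during an imagery epoch, by a class-specific gain. Gains below
#' one emulate event-related desynchronisation (ERD, a band-power decrease),
#' gains above one event-related synchronisation (ERS). A forward mixing
#' matrix projects the sources onto the scalp channels.
#'
#' @param ar_coeffs List of numeric AR coefficient vectors, one per source
#'   (lag 1 first). All polynomials must be stable.
#' @param innovation_scale Numeric vector of innovation standard deviations
#'   (recycled to the number of sources).
#' @param class_modulation Numeric matrix `4 x M` (rows named by
#'   [mi_classes()]): multiplicative innovation gain of source `m` during an
#'   epoch of each class.
#' @param mixing Numeric matrix `M x C`: forward projection of the `M`
#'   sources onto `C` channels. Must have full row rank.
#'
#' @return An object of class `"source_model"`.
#' @seealso [default_source_model()], [simulate_sources()]
#' @export
source_model <- function(ar_coeffs, innovation_scale, class_modulation, mixing) {
  if (!is.list(ar_coeffs)) ar_coeffs <- list(ar_coeffs)
  M <- length(ar_coeffs)
  innovation_scale <- rep_len(as.numeric(innovation_scale), M)
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != M)
    mibci_stop("mixing must have one row per source (", M, ")")
  if (qr(mixing)$rank < M)
    mibci_stop("mixing must have full row rank")
  class_modulation <- as.matrix(class_modulation)
  if (is.null(rownames(class_modulation)))
    rownames(class_modulation) <- mi_classes()
  if (!all(mi_classes() %in% rownames(class_modulation)) ||
      ncol(class_modulation) != M)
    mibci_stop("class_modulation must be a 4 x ", M,
               " matrix with rows named by mi_classes()")
  bad <- Filter(Negate(is.null), lapply(seq_len(M), function(i) {
    a <- ar_coeffs[[i]]
    if (length(a) == 0 || all(a == 0)) return(NULL)
    r <- polyroot(c(1, -a))
    if (any(Mod(r) <= 1 + 1e-10)) list(source = i, roots = r[Mod(r) <= 1 + 1e-10])
    else NULL
  }))
  if (length(bad))
    mibci_stop("unstable AR polynomial(s): ",
               paste(vapply(bad, function(b)
                 sprintf("source %d (|root| = %s)", b$source,
                         paste(format(Mod(b$roots), digits = 4), collapse = ", ")),
                 character(1)), collapse = "; "))
  structure(list(ar_coeffs = ar_coeffs,
                 model_order = max(vapply(ar_coeffs, length, integer(1))),
                 innovation_scale = innovation_scale,
                 class_modulation = class_modulation[mi_classes(), , drop = FALSE],
                 mixing = mixing),
            class = "source_model")
}

#' AR coefficients of a damped resonator
#'
#' Builds a stable AR polynomial with a spectral peak at `freq` Hz of
#' approximate bandwidth `bw` Hz (a conjugate pole pair), optionally cascaded
#' with a real pole that tilts the spectrum towards low frequencies. The
#' coefficient vector is zero-padded to `order`.
#'
#' @param freq Peak frequency in Hz (0 gives a purely low-pass source).
#' @param bw Resonance bandwidth in Hz.
#' @param fs Sampling rate in Hz.
#' @param pink Real pole in (0, 1) adding 1/f-like tilt; 0 to disable.
#' @param order Minimum length of the returned coefficient vector.
#' @return Numeric AR coefficient vector (lag 1 first).
#' @export
ar_resonator <- function(freq, bw, fs, pink = 0, order = 6) {
  r <- exp(-pi * bw / fs)
  poly <- if (freq > 0) {
    w <- 2 * pi * freq / fs
    c(1, -2 * r * cos(w), r^2)          # (1 - 2 r cos(w) z + r^2 z^2)
  } else c(1, -r)
  if (pink > 0) {
    poly <- convolve(poly, rev(c(1, -pink)), type = "open")
  }
  a <- -poly[-1]
  c(a, rep(0, max(0, order - length(a))))
}

#' Default synthetic source model
#'
#' Eight sources built to resemble the characteristic-component profile of a
#' well-performing participant: narrowband sensorimotor sources whose band
#' power is suppressed (ERD) or enhanced (ERS) by specific imagery classes,
#' plus unmodulated narrowband and broadband background activity.
#' Sources and their class gains:
#' \itemize{
#'   \item Cz 8-12 Hz: foot imagery ERD (gain 0.5)
#'   \item C3 12-16 Hz: right-hand imagery ERD (gain 0.5)
#'   \item C4 12-16 Hz: left-hand imagery ERD (gain 0.5)
#'   \item Fz 14-16 Hz: tongue imagery ERS (gain 1.5)
#'   \item F4 20-22 Hz and T7 24-26 Hz: unmodulated narrowband
#'   \item P3, P4: broadband 1/f background (larger amplitude)
#' }
#' Each source projects onto the scalp with a Gaussian spatial profile
#' centred at its electrode.
#'
#' @param montage A [montage_spec()]; the mixing targets its EEG channels and
#'   resonance frequencies adapt to its sampling rate.
#' @param spread Spatial standard deviation of the forward projection in
#'   head-radius units (default 0.35).
#' @return A [source_model()].
#' @export
default_source_model <- function(montage = montage_spec(), spread = 0.35) {
  fs <- montage$fs
  spec <- list(
    list(el = "Cz", f = 10, bw = 3, sd = 6,
         gain = c(right_hand = 1, left_hand = 1, foot = 0.5, tongue = 1)),
    list(el = "C3", f = 14, bw = 3, sd = 6,
         gain = c(right_hand = 0.5, left_hand = 1, foot = 1, tongue = 1)),
    list(el = "C4", f = 14, bw = 3, sd = 6,
         gain = c(right_hand = 1, left_hand = 0.5, foot = 1, tongue = 1)),
    list(el = "Fz", f = 15, bw = 2, sd = 5,
         gain = c(right_hand = 1, left_hand = 1, foot = 1, tongue = 1.5)),
    list(el = "F4", f = 21, bw = 3, sd = 4, gain = NULL),
    list(el = "T7", f = 25, bw = 3, sd = 4, gain = NULL),
    list(el = "P3", f = 0, bw = 8, sd = 10, gain = NULL),
    list(el = "P4", f = 0, bw = 8, sd = 10, gain = NULL))
  labels <- montage$eeg_labels
  pos <- electrode_positions(labels)
  ar <- lapply(spec, function(s) ar_resonator(s$f, s$bw, fs, pink = if (s$f == 0) 0.95 else 0))
  mix <- t(vapply(spec, function(s) {
    centre <- electrode_positions(s$el)[1, ]
    d2 <- (pos[, 1] - centre[1])^2 + (pos[, 2] - centre[2])^2
    exp(-d2 / (2 * spread^2))
  }, numeric(length(labels))))
  colnames(mix) <- labels
  cm <- matrix(1, 4, length(spec), dimnames = list(mi_classes(), NULL))
  for (i in seq_along(spec))
    if (!is.null(spec[[i]]$gain)) cm[names(spec[[i]]$gain), i] <- spec[[i]]$gain
  source_model(ar, vapply(spec, `[[`, numeric(1), "sd"), cm, mix)
}

#' Simulate source signals under a trial schedule
#'
#' Draws Gaussian innovations, multiplies their scale by the class gain of
#' the active imagery epoch (gain 1 in idle intervals between trials), and
#' runs each source's AR recursion. A burn-in of `10 * model_order + 50`
#' samples precedes the returned segment so the processes are stationary at
#' onset.
#'
#' @param model A [source_model()].
#' @param schedule A [build_schedule()] result.
#' @param seed Integer seed; simulation is deterministic per seed.
#' @param fs Sampling rate in Hz.
#' @param duration_s Length of the simulated segment (default: the
#'   schedule's duration plus one trailing blank).
#' @return `M x T` numeric matrix of source signals; attribute `"fs"`.
#' @export
simulate_sources <- function(model, schedule, seed, fs,
                             duration_s = schedule_duration(schedule) + schedule$blank_s) {
  stopifnot(inherits(model, "source_model"), inherits(schedule, "trial_schedule"))
  fs <- check_number(fs, "fs", lower = .Machine$double.eps)
  M <- length(model$ar_coeffs)
  T <- round(duration_s * fs)
  if (any(schedule$entries$onset_s + schedule$mi_s > duration_s + 1e-9))
    mibci_stop("schedule extends beyond the simulated duration")
  burn <- 10 * model$model_order + 50
  with_seed(seed, {
    S <- matrix(0, M, T)
    for (i in seq_len(M)) {
      gain <- rep(1, T)
      for (r in seq_len(nrow(schedule$entries))) {
        cls <- schedule$entries$mi_class[r]
        g <- model$class_modulation[cls, i]
        if (g != 1) {
          i0 <- floor(schedule$entries$onset_s[r] * fs) + 1L
          i1 <- min(T, ceiling((schedule$entries$onset_s[r] + schedule$mi_s) * fs))
          gain[i0:i1] <- g
        }
      }
      innov <- rnorm(T + burn) * model$innovation_scale[i] * c(rep(1, burn), gain)
      a <- model$ar_coeffs[[i]]
      x <- if (all(a == 0)) innov
           else as.numeric(stats::filter(innov, a, method = "recursive"))
      S[i, ] <- x[burn + seq_len(T)]
    }
    attr(S, "fs") <- fs
    S
  })
}
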