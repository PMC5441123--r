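## Chebyshev type-I band-pass filters, designed in zero-pole-gain form and
## applied as a cascade of second-order sections. Narrow bands (2 Hz at
## 1 kHz) put poles within 1e-3 of the unit circle; a degree-20 transfer
## function is numerically meaningless there, while biquads are exact to
## double precision.

#' Design a Chebyshev type-I band-pass filter as second-order sections
#'
#' Analog prototype poles, low-pass-to-band-pass transform with bilinear
#' prewarping, conjugate pole pairing into biquads; each section carries one
#' zero at z = 1 and one at z = -1, with the gain distributed evenly across
#' sections. Passband gain peaks at 1 with `rp` dB ripple.
#'
#' @param order Filter order `n` (>= 2); the band-pass has `2n` poles.
#' @param rp Passband ripple in dB (default 0.5).
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `"sos_filter"`: list of biquads (`b`, `a`),
#'   plus `fs` and `band`.
#' @export
cheby1_bandpass <- function(order, rp = 0.5, low, high, fs) {
  order <- check_count(order, "order")
  if (order < 2) mibci_stop("order must be >= 2")
  low <- check_number(low, "low", lower = 0)
  high <- check_number(high, "high")
  if (!(low > 0 && low < high && high < fs / 2))
    mibci_stop(sprintf("band edges must satisfy 0 < low < high < fs/2 (got %g-%g at fs %g)",
                       low, high, fs))
  eps <- sqrt(10^(rp / 10) - 1)
  mu <- asinh(1 / eps) / order
  theta <- (2 * seq_len(order) - 1) * pi / (2 * order)
  p_lp <- complex(real = -sinh(mu) * sin(theta),
                  imaginary = cosh(mu) * cos(theta))
  W1 <- 2 * fs * tan(pi * low / fs)
  W2 <- 2 * fs * tan(pi * high / fs)
  B <- W2 - W1; W0 <- sqrt(W1 * W2)
  pb <- unlist(lapply(p_lp, function(p) {
    t1 <- p * B / 2; sq <- sqrt(t1 * t1 - W0^2); c(t1 + sq, t1 - sq)
  }))
  pz <- (2 * fs + pb) / (2 * fs - pb)
  if (any(Mod(pz) >= 1))
    mibci_stop(sprintf("unstable design for band %g-%g Hz at order %d; use a lower order or wider band",
                       low, high, order))
  up <- pz[Im(pz) > 0]
  if (length(up) != order) { # degenerate real poles: pair by modulus
    re <- sort(Re(pz[abs(Im(pz)) < 1e-12]))
    up <- c(up, complex(real = re[seq(1, length(re), by = 2)], imaginary = 0))
  }
  sos <- lapply(up, function(p)
    list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2)))
  f0 <- atan(W0 / (2 * fs)) * fs / pi
  z0 <- exp(2i * pi * f0 / fs)
  H <- prod(vapply(sos, function(s)
    (z0^2 * s$b[1] + z0 * s$b[2] + s$b[3]) /
      (z0^2 * s$a[1] + z0 * s$a[2] + s$a[3]), complex(1)))
  target <- if (order %% 2 == 0) 10^(-rp / 20) else 1
  g <- (target / Mod(H))^(1 / length(sos))
  for (i in seq_along(sos)) sos[[i]]$b <- sos[[i]]$b * g
  structure(list(sos = sos, fs = fs, band = c(low, high)), class = "sos_filter")
}

#' Magnitude response of a second-order-section filter
#' @param filt An `"sos_filter"`.
#' @param freqs Frequencies in Hz.
#' @return Numeric vector of |H(f)|.
#' @export
sos_response <- function(filt, freqs) {
  z <- exp(2i * pi * freqs / filt$fs)
  vapply(z, function(zz) Mod(prod(vapply(filt$sos, function(s)
    (zz^2 * s$b[1] + zz * s$b[2] + s$b[3]) /
      (zz^2 * s$a[1] + zz * s$a[2] + s$a[3]), complex(1)))), numeric(1))
}

## one biquad, causal, zero initial conditions; x is a matrix (columns =
## signals). MA part via shifts, AR part via the C recursion in stats::filter.
sos_filt1 <- function(x, s) {
  n <- nrow(x)
  sh1 <- rbind(0, x[-n, , drop = FALSE])
  sh2 <- rbind(0, 0, x[seq_len(max(n - 2, 0)), , drop = FALSE])
  xb <- s$b[1] * x + s$b[2] * sh1 + s$b[3] * sh2
  y <- stats::filter(xb, -s$a[2:3], method = "recursive")
  matrix(as.numeric(y), n)
}

#' Zero-phase filtering through second-order sections
#'
#' Forward-backward application (squared magnitude response, zero group
#' delay) with odd-reflection end padding long enough for the section's
#' ringing time.
#'
#' @param x Numeric vector or matrix (columns are independent signals).
#' @param filt An `"sos_filter"`.
#' @param pad Padding length in samples; default scales with the inverse
#'   bandwidth.
#' @return Filtered signal, same shape as `x`.
#' @export
sos_filtfilt <- function(x, filt, pad = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 4) mibci_stop("signal too short to filter")
  if (is.null(pad))
    pad <- min(n - 1, max(200, round(3 * filt$fs / max(diff(filt$band), 1e-9))))
  top <- 2 * matrix(x[1, ], pad, ncol(x), byrow = TRUE) - x[pad:1 + 1, , drop = FALSE]
  bot <- 2 * matrix(x[n, ], pad, ncol(x), byrow = TRUE) - x[n - (1:pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  for (s in filt$sos) xp <- sos_filt1(xp, s)
  xp <- xp[nrow(xp):1, , drop = FALSE]
  for (s in filt$sos) xp <- sos_filt1(xp, s)
  xp <- xp[nrow(xp):1, , drop = FALSE]
  out <- xp[pad + seq_len(n), , drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Notch out mains interference
#'
#' Constrained biquad notch (zeros on the unit circle at the target
#' frequency, poles just inside) applied forward-backward, so attenuation at
#' the centre is complete while the response is within 1 dB outside
#' `center_hz +/- 2` Hz for the default bandwidth.
#'
#' @param x A `"recording"` (all channels filtered) or numeric
#'   vector/matrix (columns = signals).
#' @param center_hz Notch centre frequency (default 50).
#' @param fs Sampling rate; taken from the recording when `x` is one.
#' @param bw Notch -3 dB bandwidth in Hz (default 1).
#' @return Same type as `x`.
#' @export
notch_filter <- function(x, center_hz = 50, fs = NULL, bw = 1) {
  if (inherits(x, "recording")) {
    fs <- x$montage$fs
    labs <- rownames(x$data)
    x$data <- t(notch_filter(t(x$data), center_hz, fs, bw))
    rownames(x$data) <- labs
    return(x)
  }
  if (is.null(fs)) mibci_stop("fs required when filtering raw signals")
  if (center_hz >= fs / 2)
    mibci_stop(sprintf("notch centre (%g Hz) must lie below the Nyquist frequency (%g Hz)",
                       center_hz, fs / 2))
  w0 <- 2 * pi * center_hz / fs
  r <- 1 - pi * bw / fs
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * sum(a) / sum(b)  # unit gain at DC
  filt <- structure(list(sos = list(list(b = b, a = a)), fs = fs,
                         band = c(center_hz - bw, center_hz + bw)),
                    class = "sos_filter")
  sos_filtfilt(x, filt, pad = min(if (is.null(dim(x))) length(x) - 1 else nrow(x) - 1,
                                  round(5 * fs / bw)))
}

## memoised band designs: the filterbank reuses identical biquads across
## epochs and channels
filter_cache <- new.env(parent = emptyenv())

cached_bandpass <- function(order, rp, low, high, fs) {
  key <- paste(order, rp, low, high, fs, sep = "|")
  f <- filter_cache[[key]]
  if (is.null(f)) {
    f <- cheby1_bandpass(order, rp, low, high, fs)
    filter_cache[[key]] <- f
  }
  f
}
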