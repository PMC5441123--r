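#' Remove ocular activity from the EEG by least-squares regression
#'
#' Each EEG channel's projection onto the EOG channels is estimated by
#' ordinary least squares over the whole recording and subtracted. The EOG
#' channels themselves are kept untouched so blink commands can still be
#' detected downstream.
#'
#' @param rec A `"recording"` with at least one EOG channel.
#' @return The corrected `"recording"`.
#' @export
regress_out_eog <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  eog_idx <- match(rec$montage$eog_labels, rownames(rec$data))
  eog_idx <- eog_idx[!is.na(eog_idx)]
  if (length(eog_idx) < 1) mibci_stop("no EOG channels present")
  eeg_idx <- match(rec$montage$eeg_labels, rownames(rec$data))
  E <- t(rec$data[eog_idx, , drop = FALSE])
  if (all(abs(E) < .Machine$double.eps)) {
    warning("all EOG channels are zero; nothing to regress out")
    return(rec)
  }
  E <- sweep(E, 2, colMeans(E))
  X <- t(rec$data[eeg_idx, , drop = FALSE])
  beta <- qr.solve(crossprod(E) + diag(1e-12, ncol(E)), crossprod(E, X))
  rec$data[eeg_idx, ] <- t(X - E %*% beta)
  rec
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across channels from each channel.
#' Applied to the EEG channels only (EOG excluded) when given an epoch that
#' knows its channel roles.
#'
#' @param epoch An `"epoch"` or a channels-by-samples matrix (>= 2 rows).
#' @return Same type as the input.
#' @export
car_filter <- function(epoch) {
  if (inherits(epoch, "epoch")) {
    epoch$data <- car_filter(epoch$data)
    return(epoch)
  }
  if (nrow(epoch) < 2) mibci_stop("CAR requires at least 2 channels")
  sweep(epoch, 2, colMeans(epoch))
}

new_epoch <- function(data, mi_class, window, fs, onset_s = NA_real_) {
  structure(list(data = data, mi_class = mi_class, window = window,
                 fs = fs, onset_s = onset_s),
            class = "epoch")
}

#' Cut imagery (and idle) epochs out of a recording
#'
#' One epoch per scheduled trial, spanning `window` seconds relative to the
#' cue onset (default the full 4 s imagery interval). Optionally cuts idle
#' epochs from the blank intervals between trials, labelled `"idle"` --
#' these are the no-command baseline the classifier's idle state is
#' validated against. Each epoch is baseline-corrected by subtracting the
#' per-channel mean of the `baseline_s` seconds preceding the cue. Only EEG
#' channels are retained.
#'
#' @param rec A `"recording"`.
#' @param window Numeric length-2, seconds relative to cue onset.
#' @param idle Also return idle epochs of length `idle_len_s` starting at
#'   each trial's blank onset (default `FALSE`).
#' @param idle_len_s Idle epoch length, seconds (default: blank length).
#' @param baseline_s Pre-cue baseline length for mean subtraction, seconds
#'   (default 0.5; 0 disables).
#' @return List of `"epoch"` objects.
#' @export
extract_epochs <- function(rec, window = c(0, 4), idle = FALSE,
                           idle_len_s = NULL, baseline_s = 0.5) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$montage$fs
  T <- ncol(rec$data)
  eeg_idx <- match(rec$montage$eeg_labels, rownames(rec$data))
  ent <- rec$schedule$entries
  out <- vector("list", 0)
  for (r in seq_len(nrow(ent))) {
    i0 <- round((ent$onset_s[r] + window[1]) * fs) + 1L
    i1 <- round((ent$onset_s[r] + window[2]) * fs)
    if (i0 < 1 || i1 > T)
      mibci_stop(sprintf("window [%g, %g] for trial %d (session %d run %d) exceeds the recording",
                         window[1], window[2], ent$trial_index[r],
                         ent$session[r], ent$run[r]))
    X <- rec$data[eeg_idx, i0:i1, drop = FALSE]
    if (baseline_s > 0) {
      b0 <- max(1L, round((ent$onset_s[r] - baseline_s) * fs) + 1L)
      b1 <- max(b0, round(ent$onset_s[r] * fs))
      X <- X - rowMeans(rec$data[eeg_idx, b0:b1, drop = FALSE])
    }
    out[[length(out) + 1L]] <-
      new_epoch(X, ent$mi_class[r], window, fs, ent$onset_s[r])
  }
  if (idle) {
    len <- idle_len_s %||% rec$schedule$blank_s
    for (r in seq_len(nrow(ent))) {
      start <- ent$onset_s[r] - rec$schedule$blank_s
      i0 <- round(start * fs) + 1L
      i1 <- round((start + len) * fs)
      if (i0 < 1 || i1 > T) next
      out[[length(out) + 1L]] <-
        new_epoch(rec$data[eeg_idx, i0:i1, drop = FALSE], "idle",
                  c(0, len), fs, start)
    }
  }
  out
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch> %s: %d channels x %d samples (%g Hz)\n",
              x$mi_class, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Decompose an epoch into narrowband (electrode, band) components
#'
#' Tiles `[low, high)` with contiguous bands of `width` Hz (the lowest edge
#' clamped to 0.5 Hz so the design stays realisable) and band-pass filters
#' every channel with a zero-phase Chebyshev type-I filter of the given
#' order. Each (electrode, band) pair yields one component -- the atom all
#' feature selection works on. 25 channels with 2 Hz bands over 0-60 Hz give
#' 750 components.
#'
#' @param epoch An `"epoch"`, or a channels-by-samples matrix with `fs`.
#' @param low,high Filterbank range in Hz (defaults 0 and 60).
#' @param width Band width in Hz (default 2); must divide `high - low`.
#' @param order Chebyshev type-I order (default 10).
#' @param rp Passband ripple in dB (default 0.5).
#' @param fs Sampling rate (taken from the epoch if absent).
#' @return List of `"band_component"` objects: `electrode`, `band`
#'   (length-2 Hz), `signal`.
#' @export
filterbank <- function(epoch, low = 0, high = 60, width = 2, order = 10,
                       rp = 0.5, fs = NULL) {
  if (inherits(epoch, "epoch")) {
    fs <- epoch$fs
    X <- epoch$data
  } else X <- as.matrix(epoch)
  if (is.null(fs)) mibci_stop("fs required")
  bands <- filterbank_bands(low, high, width, fs)
  labels <- rownames(X) %||% paste0("ch", seq_len(nrow(X)))
  out <- vector("list", nrow(X) * nrow(bands))
  k <- 0L
  for (b in seq_len(nrow(bands))) {
    filt <- cached_bandpass(order, rp, bands[b, 1], bands[b, 2], fs)
    Y <- sos_filtfilt(t(X), filt)
    for (ch in seq_len(nrow(X))) {
      k <- k + 1L
      out[[k]] <- structure(list(electrode = labels[ch],
                                 band = unname(c(bands[b, 3], bands[b, 4])),
                                 signal = Y[, ch]),
                            class = "band_component")
    }
  }
  out
}

## nominal band tiling; column 1-2 realisable edges, 3-4 nominal edges
filterbank_bands <- function(low, high, width, fs) {
  if (width <= 0 || abs((high - low) / width - round((high - low) / width)) > 1e-9)
    mibci_stop("width must divide high - low")
  if (high > fs / 2)
    mibci_stop("filterbank range exceeds the Nyquist frequency")
  lo <- seq(low, high - width, by = width)
  hi <- lo + width
  real_lo <- pmax(lo, 0.5)
  real_hi <- pmin(hi, fs / 2 - 0.5)
  cbind(real_lo, real_hi, lo, hi)
}

## band power per epoch/channel/band: power[epoch, channel, band].
## All epochs (equal length) of one band are filtered in a single matrix
## call; per-epoch padding keeps epochs independent.
band_power_epochs <- function(epochs, low = 0, high = 60, width = 2,
                              order = 10, rp = 0.5) {
  stopifnot(length(epochs) > 0)
  fs <- epochs[[1]]$fs
  n_ch <- nrow(epochs[[1]]$data)
  len <- ncol(epochs[[1]]$data)
  bands <- filterbank_bands(low, high, width, fs)
  X <- matrix(0, len, n_ch * length(epochs))
  for (e in seq_along(epochs)) {
    if (ncol(epochs[[e]]$data) != len || nrow(epochs[[e]]$data) != n_ch)
      mibci_stop("all epochs must share channel count and length")
    X[, (e - 1) * n_ch + seq_len(n_ch)] <- t(epochs[[e]]$data)
  }
  P <- array(0, dim = c(length(epochs), n_ch, nrow(bands)),
             dimnames = list(NULL, rownames(epochs[[1]]$data), NULL))
  for (b in seq_len(nrow(bands))) {
    filt <- cached_bandpass(order, rp, bands[b, 1], bands[b, 2], fs)
    Y <- sos_filtfilt(X, filt)
    P[, , b] <- t(matrix(colMeans(Y^2), n_ch))
  }
  attr(P, "bands") <- bands[, 3:4, drop = FALSE]
  P
}
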