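#' Detect single and double blinks on the vertical EOG
#'
#' Threshold detector: samples exceeding `threshold_mad` median absolute
#' deviations of the (median-centred) vertical EOG are grouped into events
#' separated by a refractory gap; two events whose peaks fall within
#' `double_window_s` merge into one double blink.
#'
#' @param eog A `"recording"` (uses its `VEOG-U` channel, falling back to
#'   the first EOG channel) or a numeric vector.
#' @param fs Sampling rate (taken from the recording if given one).
#' @param threshold_mad Threshold in MAD units (default 4).
#' @param refractory_s Minimum separation between peaks of one event
#'   (default 0.1 s; must stay below the inter-pulse gap of a double blink).
#' @param double_window_s Two events closer than this merge into a double
#'   blink (default 0.6 s).
#' @param min_width_s Minimum time the signal must spend above threshold for
#'   an event to count (default 0.02 s), rejecting single-sample noise
#'   exceedances.
#' @return Data frame `time_s`, `kind` (`"single"`/`"double"`), possibly
#'   empty.
#' @export
detect_blinks <- function(eog, fs = NULL, threshold_mad = 4,
                          refractory_s = 0.1, double_window_s = 0.6,
                          min_width_s = 0.02) {
  if (inherits(eog, "recording")) {
    fs <- eog$montage$fs
    ch <- intersect("VEOG-U", rownames(eog$data))
    if (!length(ch)) ch <- intersect(eog$montage$eog_labels, rownames(eog$data))[1]
    if (is.na(ch) || !length(ch)) mibci_stop("no vertical EOG channel present")
    eog <- eog$data[ch[1], ]
  }
  if (is.null(fs)) mibci_stop("fs required for raw signals")
  x <- eog - median(eog)
  s <- mad(x)
  empty <- data.frame(time_s = numeric(0), kind = character(0))
  if (s < .Machine$double.eps) return(empty)
  above <- which(abs(x) > threshold_mad * s)
  if (!length(above)) return(empty)
  ## group threshold crossings into events by the refractory gap
  gap <- diff(above) > refractory_s * fs
  grp <- cumsum(c(TRUE, gap))
  groups <- split(above, grp)
  groups <- groups[vapply(groups, length, integer(1)) >= min_width_s * fs]
  if (!length(groups)) return(empty)
  peaks <- vapply(groups, function(idx) idx[which.max(abs(x[idx]))], numeric(1))
  times <- peaks / fs
  ## merge into single/double events
  out <- empty
  i <- 1
  while (i <= length(times)) {
    if (i < length(times) && times[i + 1] - times[i] <= double_window_s) {
      out <- rbind(out, data.frame(time_s = times[i], kind = "double"))
      i <- i + 2
    } else {
      out <- rbind(out, data.frame(time_s = times[i], kind = "single"))
      i <- i + 1
    }
  }
  rownames(out) <- NULL
  out
}
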