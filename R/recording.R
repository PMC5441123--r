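#' @rdname render_recording
#' @param time_s Event time in seconds.
#' @param fs Sampling rate in Hz.
#' @param n Length of the target signal in samples.
#' @param amplitude Peak amplitude in microvolts.
#' @keywords internal
blink_template <- function(time_s, fs, n, amplitude = 150) {
  ## 300 ms biphasic pulse: dominant positive lobe, small negative rebound
  len <- round(0.3 * fs)
  t <- seq_len(len) / len
  shape <- sin(pi * t)^2 - 0.35 * sin(2 * pi * t)
  shape <- shape / max(shape) * amplitude
  out <- numeric(n)
  i0 <- round(time_s * fs)
  idx <- i0 + seq_len(len)
  keep <- idx >= 1 & idx <= n
  out[idx[keep]] <- shape[keep]
  out
}

#' Render a synthetic EEG/EOG recording
#'
#' Mixes the AR sources onto the scalp channels and adds, in order: mains
#' interference (a 50 Hz sinusoid), single/double eye blinks (a 300 ms
#' biphasic pulse on the vertical EOG pair with 30% leakage onto prefrontal
#' and 15% onto other frontal channels; a double blink is two pulses 400 ms
#' apart), white sensor noise, and subtraction of a simulated reference
#' channel so the stored data is already ear-referenced. Ground-truth blink
#' times are kept alongside the data.
#'
#' @param model A [source_model()] whose mixing matches the montage's EEG
#'   channels.
#' @param schedule A [build_schedule()] result.
#' @param montage A [montage_spec()].
#' @param line_noise_amp Mains sinusoid amplitude in microvolts (default 5).
#' @param line_noise_hz Mains frequency (default 50).
#' @param blink_rate_per_min Mean blink events per minute (default 6; 0
#'   disables blinks). About 30% of events are double blinks.
#' @param sensor_noise_sd White noise standard deviation in microvolts.
#' @param seed Integer seed.
#' @param duration_s Recording length (default: schedule duration plus one
#'   blank).
#'
#' @return An object of class `"recording"`: list with `data` (channels x
#'   samples, rownames = EEG then EOG labels), `montage`, `schedule`,
#'   `blink_truth` (data frame `time_s`, `kind`).
#' @export
render_recording <- function(model, schedule, montage = montage_spec(),
                             line_noise_amp = 5, line_noise_hz = 50,
                             blink_rate_per_min = 6, sensor_noise_sd = 1,
                             seed = 1,
                             duration_s = schedule_duration(schedule) + schedule$blank_s) {
  stopifnot(inherits(model, "source_model"), inherits(montage, "montage_spec"))
  if (ncol(model$mixing) != length(montage$eeg_labels))
    mibci_stop("mixing width (", ncol(model$mixing),
               ") does not match montage EEG channel count (",
               length(montage$eeg_labels), ")")
  fs <- montage$fs
  S <- simulate_sources(model, schedule, seed = seed, fs = fs,
                        duration_s = duration_s)
  T <- ncol(S)
  n_eeg <- length(montage$eeg_labels)
  n_eog <- length(montage$eog_labels)
  with_seed(seed + 1L, {
    eeg <- t(model$mixing) %*% S
    tt <- seq_len(T) / fs
    if (line_noise_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      line <- line_noise_amp * sin(2 * pi * line_noise_hz * tt + phase)
      eeg <- eeg + matrix(line, n_eeg, T, byrow = TRUE)
    }
    eog <- matrix(rnorm(n_eog * T, 0, max(sensor_noise_sd, 0.5)), n_eog, T)
    ## blink truth + waveforms
    blink_truth <- data.frame(time_s = numeric(0), kind = character(0))
    if (blink_rate_per_min > 0) {
      n_events <- max(0, round(blink_rate_per_min * duration_s / 60))
      times <- sort(runif(n_events, 1, duration_s - 1.5))
      ## enforce 1.5 s separation so events are unambiguous
      if (length(times) > 1) times <- times[c(TRUE, diff(times) > 1.5)]
      kinds <- sample(c("single", "double"), length(times), replace = TRUE,
                      prob = c(0.7, 0.3))
      blink_truth <- data.frame(time_s = times, kind = kinds,
                                stringsAsFactors = FALSE)
      wave <- numeric(T)
      for (i in seq_along(times)) {
        wave <- wave + blink_template(times[i], fs, T)
        if (kinds[i] == "double")
          wave <- wave + blink_template(times[i] + 0.4, fs, T)
      }
      labels <- montage$eeg_labels
      frontal <- grepl("^Fp", labels)
      frontal2 <- grepl("^F[0-9z78]", labels)
      veog_u <- match("VEOG-U", montage$eog_labels)
      veog_d <- match("VEOG-D", montage$eog_labels)
      if (!is.na(veog_u)) eog[veog_u, ] <- eog[veog_u, ] + wave
      if (!is.na(veog_d)) eog[veog_d, ] <- eog[veog_d, ] - 0.8 * wave
      eeg[frontal, ] <- eeg[frontal, ] + rep(0.30, sum(frontal)) %o% wave
      eeg[frontal2, ] <- eeg[frontal2, ] + rep(0.15, sum(frontal2)) %o% wave
    }
    if (sensor_noise_sd > 0)
      eeg <- eeg + matrix(rnorm(n_eeg * T, 0, sensor_noise_sd), n_eeg, T)
    ## simulated reference: weak pickup of the sources plus its own noise,
    ## subtracted from every EEG channel (data stored ear-referenced)
    ref <- as.numeric(crossprod(rep(0.05, nrow(S)), S)) +
      rnorm(T, 0, sensor_noise_sd * 0.5)
    eeg <- eeg - matrix(ref, n_eeg, T, byrow = TRUE)
    data <- rbind(eeg, eog)
    rownames(data) <- c(montage$eeg_labels, montage$eog_labels)
    structure(list(data = data, montage = montage, schedule = schedule,
                   blink_truth = blink_truth),
              class = "recording")
  })
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples (%.1f s at %g Hz), %d trials, %d blink events\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$montage$fs,
              x$montage$fs, nrow(x$schedule$entries), nrow(x$blink_truth)))
  invisible(x)
}

## ------------------------------------------------------------------------
## container I/O: 16-bit scaled integer CSV (EDF-like quantisation) + JSON
## sidecar carrying montage, schedule and blink truth.

#' Write / read a recording
#'
#' The signal container is a CSV of 16-bit integers (one column per channel)
#' with per-channel physical scaling recorded in comment headers, emulating
#' the quantisation of clinical EEG containers; montage, trial schedule and
#' blink ground truth travel in a JSON sidecar (`<path>.json`). The
#' quantisation step of channel `i` is `(pmax_i - pmin_i) / 65535`
#' microvolts; round-tripping is lossless up to that step.
#'
#' @param rec A `"recording"`.
#' @param path Base path; `write_recording` creates `<path>.csv` and
#'   `<path>.json`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `"recording"`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  X <- rec$data
  pmin <- apply(X, 1, min); pmax <- apply(X, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dig <- round(sweep(sweep(X, 1, pmin), 1, (pmax - pmin) / 65535, "/")) - 32768
  con <- file(paste0(path, ".csv"), "w")
  writeLines(c(sprintf("# fs: %.10g", rec$montage$fs),
               sprintf("# pmin: %s", paste(format(pmin, digits = 17), collapse = ",")),
               sprintf("# pmax: %s", paste(format(pmax, digits = 17), collapse = ","))),
             con)
  write.table(t(dig), con, sep = ",", row.names = FALSE,
              col.names = rownames(X), quote = FALSE)
  close(con)
  sidecar <- list(
    fs = rec$montage$fs,
    montage = list(eeg_labels = rec$montage$eeg_labels,
                   eog_labels = rec$montage$eog_labels,
                   reference_label = rec$montage$reference_label,
                   fs = rec$montage$fs),
    schedule = list(entries = rec$schedule$entries,
                    blank_s = rec$schedule$blank_s, mi_s = rec$schedule$mi_s),
    blink_truth = rec$blink_truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  csv <- paste0(path, ".csv"); sidecar <- paste0(path, ".json")
  if (!file.exists(csv)) mibci_stop("missing signal file: ", csv)
  if (!file.exists(sidecar)) mibci_stop("missing sidecar file: ", sidecar)
  hdr <- readLines(csv, n = 3)
  get_field <- function(name) {
    line <- grep(paste0("^# ", name, ":"), hdr, value = TRUE)
    if (length(line) != 1) mibci_stop("malformed header: field `", name, "`")
    as.numeric(strsplit(sub(paste0("^# ", name, ": *"), "", line), ",")[[1]])
  }
  fs_hdr <- get_field("fs"); pmin <- get_field("pmin"); pmax <- get_field("pmax")
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("fs", "montage", "schedule"))
    if (is.null(side[[f]])) mibci_stop("malformed sidecar: field `", f, "`")
  if (!isTRUE(all.equal(as.numeric(side$fs), fs_hdr)))
    mibci_stop("fs mismatch between signal header (", fs_hdr,
               ") and sidecar (", side$fs, ")")
  tab <- read.table(csv, sep = ",", header = TRUE, comment.char = "#",
                    check.names = FALSE)
  dig <- t(as.matrix(tab)) + 32768
  if (length(pmin) != nrow(dig)) mibci_stop("malformed header: pmin length")
  X <- sweep(sweep(dig, 1, (pmax - pmin) / 65535, "*"), 1, pmin, "+")
  rownames(X) <- colnames(tab)
  m <- side$montage
  montage <- montage_spec(m$eeg_labels, m$eog_labels, m$reference_label, m$fs)
  entries <- as.data.frame(side$schedule$entries, stringsAsFactors = FALSE)
  entries$session <- as.integer(entries$session)
  entries$run <- as.integer(entries$run)
  entries$trial_index <- as.integer(entries$trial_index)
  entries$mi_class <- as.character(entries$mi_class)
  entries$onset_s <- as.numeric(entries$onset_s)
  schedule <- structure(list(entries = entries,
                             blank_s = side$schedule$blank_s,
                             mi_s = side$schedule$mi_s,
                             classes = mi_classes()),
                        class = "trial_schedule")
  bt <- side$blink_truth
  blink_truth <- if (is.null(bt) || length(bt) == 0)
    data.frame(time_s = numeric(0), kind = character(0))
  else {
    bt <- as.data.frame(bt, stringsAsFactors = FALSE)
    bt$time_s <- as.numeric(bt$time_s)
    bt$kind <- as.character(bt$kind)
    bt
  }
  structure(list(data = X, montage = montage, schedule = schedule,
                 blink_truth = blink_truth),
            class = "recording")
}

#' Quantisation step of the stored container per channel
#'
#' @param rec A `"recording"` (uses its current data range).
#' @return Numeric vector, microvolts per digital unit.
#' @export
recording_resolution <- function(rec) {
  rng <- apply(rec$data, 1, function(x) diff(range(x)))
  rng[rng < .Machine$double.eps] <- 1
  rng / 65535
}
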