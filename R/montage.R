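#' Electrode montage specification
#'
#' Describes the recording setup: 25 scalp EEG electrodes (10-20 names over
#' the sensorimotor strip and surroundings), four periocular EOG electrodes,
#' an ear reference and the sampling rate. These defaults match a typical
#' 40-channel amplifier setup sampled at 1000 Hz with the left-ear electrode
#' (A1) as reference.
#'
#' @param eeg_labels Character vector of EEG channel names (default: 25
#'   standard 10-20 sites centred on the sensorimotor strip).
#' @param eog_labels Character vector of 4 EOG channel names: horizontal
#'   left/right and vertical up/down.
#' @param reference_label Name of the reference electrode (default `"A1"`).
#' @param fs Sampling rate in Hz (default 1000).
#'
#' @return An object of class `"montage_spec"`.
#' @export
#' @examples
#' m <- montage_spec()
#' length(m$eeg_labels)  # 25
montage_spec <- function(eeg_labels = default_eeg_labels(),
                         eog_labels = c("HEOG-L", "HEOG-R", "VEOG-U", "VEOG-D"),
                         reference_label = "A1",
                         fs = 1000) {
  fs <- check_number(fs, "fs", lower = .Machine$double.eps)
  eeg_labels <- as.character(eeg_labels)
  eog_labels <- as.character(eog_labels)
  all_labels <- c(eeg_labels, eog_labels, reference_label)
  if (anyDuplicated(all_labels))
    mibci_stop("channel labels must be unique; duplicated: ",
               paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  if (length(eeg_labels) < 1) mibci_stop("at least one EEG channel required")
  structure(list(eeg_labels = eeg_labels, eog_labels = eog_labels,
                 reference_label = reference_label, fs = fs),
            class = "montage_spec")
}

#' Default 25-channel 10-20 EEG label set
#'
#' Frontal, fronto-central, central, temporal, centro-parietal and parietal
#' sites; the exact physical layout of the original cap is known only
#' graphically, so this list is a configurable default rather than ground
#' truth.
#' @return Character vector of 25 labels.
#' @export
default_eeg_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P3", "Pz", "P4")
}

## crude 2-D head coordinates for spatial mixing (unit head radius);
## anterior = +y, left = -x
electrode_positions <- function(labels) {
  pos <- list(
    Fp1 = c(-0.3, 0.9), Fp2 = c(0.3, 0.9),
    F7 = c(-0.8, 0.55), F3 = c(-0.4, 0.55), Fz = c(0, 0.55),
    F4 = c(0.4, 0.55), F8 = c(0.8, 0.55),
    FT7 = c(-0.85, 0.28), FC3 = c(-0.42, 0.28), FCz = c(0, 0.28),
    FC4 = c(0.42, 0.28), FT8 = c(0.85, 0.28),
    T7 = c(-0.9, 0), C3 = c(-0.45, 0), Cz = c(0, 0), C4 = c(0.45, 0),
    T8 = c(0.9, 0),
    TP7 = c(-0.85, -0.28), CP3 = c(-0.42, -0.28), CPz = c(0, -0.28),
    CP4 = c(0.42, -0.28), TP8 = c(0.85, -0.28),
    P3 = c(-0.4, -0.55), Pz = c(0, -0.55), P4 = c(0.4, -0.55))
  out <- t(vapply(labels, function(l) pos[[l]] %||% c(0, 0), numeric(2)))
  rownames(out) <- labels
  colnames(out) <- c("x", "y")
  out
}

#' @export
print.montage_spec <- function(x, ...) {
  cat(sprintf("<montage_spec> %d EEG + %d EOG channels, ref %s, fs = %g Hz\n",
              length(x$eeg_labels), length(x$eog_labels),
              x$reference_label, x$fs))
  invisible(x)
}
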