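#' Band-limited spectral power of a component
#'
#' Mean squared amplitude of the narrowband signal, in microvolts squared.
#'
#' @param comp A `"band_component"` or numeric vector.
#' @return Scalar power.
#' @export
spectral_power <- function(comp) {
  x <- if (inherits(comp, "band_component")) comp$signal else comp
  if (length(x) == 0) mibci_stop("empty signal")
  mean(x^2)
}

#' Between-task R-squared of a power feature
#'
#' Squared point-biserial correlation between the pooled power values and
#' the binary task label: the fraction of power variance explained by which
#' of the two tasks was performed. Zero when the groups are identical, one
#' when they are perfectly separated.
#'
#' @param powers_a,powers_b Numeric vectors of per-trial powers (each >= 2
#'   values).
#' @return Scalar in \[0, 1\].
#' @export
r_squared <- function(powers_a, powers_b) {
  if (length(powers_a) < 2 || length(powers_b) < 2)
    mibci_stop("need at least 2 power values per task")
  pooled <- c(powers_a, powers_b)
  if (var(pooled) < .Machine$double.eps) return(0)
  lab <- rep(c(1, 0), c(length(powers_a), length(powers_b)))
  cor(pooled, lab)^2
}

#' Score all (electrode, band) components by between-class R-squared
#'
#' For every component the per-epoch band power is computed, the R-squared
#' of each of the 6 class pairs evaluated, and their arithmetic mean taken as
#' the component's score. Idle epochs, when present, do not enter the
#' scoring but their mean power per component is retained for the later
#' ERD/ERS screening.
#'
#' @param epochs List of `"epoch"` objects covering >= 2 imagery classes
#'   (idle epochs allowed and used only as baseline).
#' @param low,high,width,order Filterbank configuration (see
#'   [filterbank()]).
#' @return An object of class `"rsq_map"`: data frame `scores` (electrode,
#'   band_lo, band_hi, score, plus mean class/idle powers), array
#'   `per_pair`, and the filterbank configuration.
#' @export
rank_components <- function(epochs, low = 0, high = 60, width = 2, order = 10) {
  classes_present <- unique(vapply(epochs, `[[`, character(1), "mi_class"))
  classes <- intersect(mi_classes(), classes_present)
  if (length(classes) < 2)
    mibci_stop("need epochs from at least 2 imagery classes")
  labs <- vapply(epochs, `[[`, character(1), "mi_class")
  small <- classes[vapply(classes, function(cl) sum(labs == cl) < 2, logical(1))]
  if (length(small)) {
    warning("classes with < 2 epochs excluded from pairings: ",
            paste(small, collapse = ", "))
    classes <- setdiff(classes, small)
    if (length(classes) < 2) mibci_stop("not enough populated classes")
  }
  mi <- epochs[labs != "idle"]
  idle <- epochs[labs == "idle"]
  ## idle epochs may have a different length; compute power arrays separately
  P <- band_power_epochs(mi, low, high, width, order)
  bands <- attr(P, "bands")
  labs_mi <- vapply(mi, `[[`, character(1), "mi_class")
  n_ch <- dim(P)[2]; n_b <- dim(P)[3]
  pairs <- utils::combn(classes, 2)
  per_pair <- array(NA_real_, dim = c(n_ch, n_b, ncol(pairs)),
                    dimnames = list(dimnames(P)[[2]], NULL, apply(pairs, 2, paste, collapse = "|")))
  for (p in seq_len(ncol(pairs))) {
    ia <- labs_mi == pairs[1, p]; ib <- labs_mi == pairs[2, p]
    for (b in seq_len(n_b))
      per_pair[, b, p] <- vapply(seq_len(n_ch), function(ch)
        r_squared(P[ia, ch, b], P[ib, ch, b]), numeric(1))
  }
  score <- apply(per_pair, c(1, 2), mean)
  class_power <- lapply(classes, function(cl)
    apply(P[labs_mi == cl, , , drop = FALSE], c(2, 3), mean))
  names(class_power) <- classes
  idle_power <- NULL
  if (length(idle) > 0) {
    Pi <- band_power_epochs(idle, low, high, width, order)
    idle_power <- apply(Pi, c(2, 3), mean)
  }
  electrodes <- dimnames(P)[[2]]
  scores <- data.frame(
    electrode = rep(electrodes, n_b),
    band_lo = rep(bands[, 1], each = n_ch),
    band_hi = rep(bands[, 2], each = n_ch),
    score = as.vector(score),
    stringsAsFactors = FALSE)
  structure(list(scores = scores, per_pair = per_pair,
                 class_power = class_power, idle_power = idle_power,
                 config = list(low = low, high = high, width = width,
                               order = order)),
            class = "rsq_map")
}

#' Select the characteristic components
#'
#' Takes the `top_k` components by mean R-squared (ties broken by lower
#' band edge, then electrode name) and optionally screens them for
#' physiological plausibility: a component is kept if, relative to the idle
#' baseline, its mean epoch power moves in the expected direction for at
#' least one class -- a decrease (ERD) for either hand or foot imagery, or
#' an increase (ERS) for tongue imagery. Components failing the screen are
#' flagged in `screen_notes`; if screening would drop everything, the top-1
#' component is kept with a warning.
#'
#' @param map An `"rsq_map"` from [rank_components()].
#' @param top_k Number of components before screening (default 10).
#' @param screen Apply the ERD/ERS screen (default `TRUE`; requires idle
#'   epochs to have been present when ranking).
#' @return An object of class `"component_selection"`: data frame
#'   `selected` (`electrode`, `band_lo`, `band_hi`, `score`) and character
#'   vector `screen_notes`.
#' @export
select_components <- function(map, top_k = 10, screen = TRUE) {
  stopifnot(inherits(map, "rsq_map"))
  sc <- map$scores
  if (nrow(sc) == 0) mibci_stop("empty score map")
  ord <- order(-sc$score, sc$band_lo, sc$electrode)
  top <- sc[ord, ][seq_len(min(top_k, nrow(sc))), ]
  notes <- character(0)
  if (screen) {
    if (is.null(map$idle_power)) {
      warning("no idle baseline available; screening skipped")
    } else {
      keep <- logical(nrow(top))
      for (i in seq_len(nrow(top))) {
        ch <- match(top$electrode[i], rownames(map$idle_power))
        b <- which(abs(attr_bands(map) - top$band_lo[i]) < 1e-9)[1]
        base <- map$idle_power[ch, b]
        ok <- FALSE
        for (cl in names(map$class_power)) {
          mp <- map$class_power[[cl]][ch, b]
          if (cl %in% c("right_hand", "left_hand", "foot") && mp < base) ok <- TRUE
          if (cl == "tongue" && mp > base) ok <- TRUE
        }
        keep[i] <- ok
        if (!ok)
          notes <- c(notes, sprintf("%s %g-%g Hz: no ERD/ERS-consistent power shift",
                                    top$electrode[i], top$band_lo[i], top$band_hi[i]))
      }
      if (!any(keep)) {
        warning("screening removed every component; keeping the top-ranked one")
        keep[1] <- TRUE
      }
      top <- top[keep, ]
    }
  }
  rownames(top) <- NULL
  structure(list(selected = top, screen_notes = notes),
            class = "component_selection")
}

attr_bands <- function(map) {
  n_b <- dim(map$per_pair)[2]
  map$config$low + (seq_len(n_b) - 1) * map$config$width
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("<component_selection> %d components (%d screened out)\n",
              nrow(x$selected), length(x$screen_notes)))
  print(x$selected)
  invisible(x)
}

#' Extract the selected components of an epoch as a component matrix
#'
#' Filters the epoch once per selected band and stacks the selected
#' (electrode, band) signals as rows -- the multichannel object that the
#' temporal ICA and CSP stages consume.
#'
#' @param epoch An `"epoch"`.
#' @param selection A `"component_selection"`.
#' @param order,rp Filter design parameters (defaults 10, 0.5).
#' @return Numeric matrix, one row per selected component.
#' @export
component_signals <- function(epoch, selection, order = 10, rp = 0.5) {
  sel <- selection$selected
  fs <- epoch$fs
  out <- matrix(0, nrow(sel), ncol(epoch$data))
  ubands <- unique(sel[, c("band_lo", "band_hi")])
  for (b in seq_len(nrow(ubands))) {
    lo <- max(ubands$band_lo[b], 0.5); hi <- min(ubands$band_hi[b], fs / 2 - 0.5)
    filt <- cached_bandpass(order, rp, lo, hi, fs)
    rows <- which(sel$band_lo == ubands$band_lo[b])
    chans <- match(sel$electrode[rows], rownames(epoch$data))
    Y <- sos_filtfilt(t(epoch$data[chans, , drop = FALSE]), filt)
    out[rows, ] <- t(Y)
  }
  rownames(out) <- sprintf("%s_%g-%g", sel$electrode, sel$band_lo, sel$band_hi)
  out
}
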