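#' Trace-normalised class covariance
#'
#' Average over epochs of `X X' / trace(X X')`. Trace normalisation removes
#' per-trial amplitude so every epoch contributes equally to the spatial
#' structure.
#'
#' @param epochs List of channels-by-samples matrices (or `"epoch"`
#'   objects) of one class; >= 2 required.
#' @return `C x C` matrix with unit trace.
#' @export
class_covariance <- function(epochs) {
  if (length(epochs) < 2) mibci_stop("need at least 2 epochs per class")
  mats <- lapply(epochs, function(e) if (inherits(e, "epoch")) e$data else e)
  acc <- 0
  for (X in mats) {
    Cx <- tcrossprod(X)
    acc <- acc + Cx / sum(diag(Cx))
  }
  acc / length(mats)
}

#' One-versus-rest common spatial patterns
#'
#' For each class `c`, simultaneously diagonalises the class covariance and
#' the composite covariance `Sigma_c + Sigma_rest` (the unweighted mean of
#' the other classes' covariances serving as "rest"), so that each spatial
#' filter's eigenvalue for the class and for the rest sum to exactly one.
#' Filters are sorted by eigenvalue (descending) and the `n_pairs` filters
#' from each end are retained: the directions where the class's relative
#' variance is largest and smallest.
#'
#' @param epochs_by_class Named list (one entry per class in
#'   [mi_classes()]) of lists of epochs/matrices.
#' @param n_pairs Filters kept from each end per class (default 2).
#' @return An object of class `"csp_filter_set"`: `per_class` maps class to
#'   `filters` (`2*n_pairs x C`, rows are filters) and `eigenvalues`
#'   (full length-`C` descending vector in \[0, 1\]); plus `n_pairs`.
#' @export
fit_ovr_csp <- function(epochs_by_class, n_pairs = 2) {
  classes <- mi_classes()
  if (!all(classes %in% names(epochs_by_class)))
    mibci_stop("epochs_by_class must contain all of: ",
               paste(classes, collapse = ", "))
  covs <- lapply(epochs_by_class[classes], class_covariance)
  C <- nrow(covs[[1]])
  if (n_pairs * 2 > C) mibci_stop("n_pairs too large for ", C, " channels")
  per_class <- lapply(classes, function(cl) {
    Sc <- covs[[cl]]
    Sr <- Reduce(`+`, covs[setdiff(classes, cl)]) / (length(classes) - 1)
    St <- Sc + Sr
    eg <- eigen(St, symmetric = TRUE)
    if (min(eg$values) < 1e-10 * max(eg$values)) {
      warning("singular composite covariance; applying shrinkage")
      St <- St + diag(1e-6 * sum(diag(St)) / C, C)
      eg <- eigen(St, symmetric = TRUE)
    }
    Wh <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
    e2 <- eigen(Wh %*% Sc %*% Wh, symmetric = TRUE)
    filt <- t(e2$vectors) %*% Wh        # rows = filters, eigenvalue descending
    ## sign convention: largest-magnitude entry of each filter positive
    for (i in seq_len(nrow(filt))) {
      j <- which.max(abs(filt[i, ]))
      if (filt[i, j] < 0) filt[i, ] <- -filt[i, ]
    }
    keep <- c(seq_len(n_pairs), C - n_pairs + seq_len(n_pairs))
    list(filters = filt[keep, , drop = FALSE],
         eigenvalues = pmin(pmax(e2$values, 0), 1))
  })
  names(per_class) <- classes
  structure(list(per_class = per_class, n_pairs = n_pairs),
            class = "csp_filter_set")
}

#' Log-variance CSP feature vector of one epoch
#'
#' Projects the epoch onto every retained filter of every class model and
#' returns the log of each projection's variance normalised by the summed
#' variance within that class model. Feature length is
#' `4 * 2 * n_pairs`. Zero-variance projections are floored at
#' `log(1e-12)` and flagged via the `"floored"` attribute.
#'
#' @param filters A `"csp_filter_set"`.
#' @param epoch An `"epoch"` or channels-by-samples matrix.
#' @return Named numeric feature vector.
#' @export
extract_features <- function(filters, epoch) {
  stopifnot(inherits(filters, "csp_filter_set"))
  X <- if (inherits(epoch, "epoch")) epoch$data else as.matrix(epoch)
  floored <- FALSE
  out <- unlist(lapply(names(filters$per_class), function(cl) {
    P <- filters$per_class[[cl]]$filters %*% X
    v <- rowSums(P^2)
    tot <- sum(v)
    f <- if (tot < .Machine$double.eps) rep(log(1e-12), length(v))
         else log(pmax(v / tot, 1e-12))
    if (any(v / max(tot, .Machine$double.eps) <= 1e-12)) floored <<- TRUE
    names(f) <- sprintf("%s_f%d", cl, seq_along(f))
    f
  }))
  attr(out, "floored") <- floored
  out
}

#' Mean first-minus-last filter variance gap
#'
#' The separability summary used to compare the direct and ICA-preprocessed
#' CSP pathways: over the epochs of one class, the mean difference between
#' the variance captured by the class model's first (class-maximal) and last
#' (class-minimal) spatial filter. Epochs are trace-normalised before
#' projection so the statistic is comparable across representations of
#' different physical scale; the variances themselves are left unlogged.
#'
#' @param filters A `"csp_filter_set"`.
#' @param epochs List of epochs/matrices belonging to `class`.
#' @param class One of [mi_classes()].
#' @return Scalar gap.
#' @export
first_last_gap <- function(filters, epochs, class) {
  stopifnot(inherits(filters, "csp_filter_set"))
  if (length(epochs) < 1) mibci_stop("need at least one epoch")
  f <- filters$per_class[[class]]$filters
  mean(vapply(epochs, function(e) {
    X <- if (inherits(e, "epoch")) e$data else as.matrix(e)
    X <- X / sqrt(sum(X^2) / ncol(X))
    P <- f %*% X
    v <- rowMeans(P^2)
    v[1] - v[length(v)]
  }, numeric(1)))
}

#' @export
print.csp_filter_set <- function(x, ...) {
  C <- ncol(x$per_class[[1]]$filters)
  cat(sprintf("<csp_filter_set> %d class models, %d channels, %d filters each\n",
              length(x$per_class), C, 2 * x$n_pairs))
  for (cl in names(x$per_class))
    cat(sprintf("  %-10s top eigenvalue %.3f\n", cl,
                x$per_class[[cl]]$eigenvalues[1]))
  invisible(x)
}
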