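#' Dependence contrast of model residuals
#'
#' Measures how far a set of residual series is from "jointly Gaussian and
#' mutually uncorrelated": the Gaussian mutual information of the
#' correlation matrix, `-log det R / 2`, plus a marginal non-Gaussianity
#' surrogate per row, the squared deviation of `E[log cosh e]` from its
#' standard-normal value. Zero (up to sampling error) if and only if the
#' rows are uncorrelated with Gaussian marginals under the surrogate.
#'
#' @param residuals Numeric matrix, rows = residual series (>= 2 rows).
#' @return Non-negative scalar.
#' @export
residual_mutual_information <- function(residuals) {
  E <- as.matrix(residuals)
  if (nrow(E) < 2) mibci_stop("need at least 2 residual series")
  sds <- apply(E, 1, sd)
  if (any(sds < .Machine$double.eps))
    mibci_stop("degenerate (zero-variance) residual row: ",
               paste(which(sds < .Machine$double.eps), collapse = ", "))
  Z <- (E - rowMeans(E)) / sds
  R <- tcrossprod(Z) / ncol(Z)
  ev <- pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  gauss_mi <- -0.5 * sum(log(ev))
  marg <- sum((rowMeans(log_cosh(Z)) - LOGCOSH_GAUSS)^2)
  gauss_mi + marg
}

#' Permutation- and scale-invariant separation error (Amari index)
#'
#' For `P = W_total %*% A_true`, 0 when `P` is a scaled permutation matrix;
#' grows towards 1 as rows/columns mix.
#'
#' @param P Square mixing-recovery product.
#' @return Scalar in \[0, ~1\].
#' @export
amari_index <- function(P) {
  P <- abs(as.matrix(P)); M <- nrow(P)
  r <- sum(P / apply(P, 1, max)) - M
  c <- sum(t(P) / apply(P, 2, max)) - M
  (r + c) / (2 * M * (M - 1))
}

#' Temporal-structure-preserving independent component analysis
#'
#' Separates linearly mixed sources by modelling each estimated source as a
#' stationary autoregression and driving the *residuals* of that model
#' towards independence with a natural-gradient update, instead of applying
#' an independence criterion to the raw samples. Because the update sees the
#' prediction-error-filtered data, spectral diversity alone identifies the
#' sources: Gaussian AR sources with distinct spectra -- which defeat
#' ordinary sample-wise ICA -- are separated. Setting `order = 0` disables
#' the temporal model and recovers a plain Infomax-style ICA, useful as the
#' temporal-structure-blind baseline.
#'
#' The update pairs the score function `phi(e_i) = tanh(e_i)` of source
#' `i`'s residual with every source filtered by source `i`'s own
#' prediction-error polynomial (the exact quasi-maximum-likelihood
#' gradient); `source_model = "full"` instead fits one joint multivariate
#' autoregression and pairs scores with the joint residuals.
#'
#' @param x Numeric matrix `C x T` of mixed signals (C >= 2).
#' @param order AR model order per source (default 6; 0 = blind).
#' @param lr Initial natural-gradient step size (default 0.05).
#' @param max_iter Maximum outer iterations (default 500).
#' @param tol Relative objective change for convergence (default 1e-6).
#' @param seed Seed for the unmixing-matrix jitter (default 1).
#' @param source_model `"diagonal"` (default) or `"full"`.
#' @return An object of class `"unmixing_model"`: `whitener` (`M x C`),
#'   `unmixing` (`M x M`, rows unit-residual-variance, ordered by component
#'   power, sign-fixed), `center`, `mvar` (an `"mvar_fit"` on the final
#'   sources when `order > 0`), `history` (objective per accepted
#'   iteration), `order`.
#' @export
fit_unmixing <- function(x, order = 6, lr = 0.05, max_iter = 500, tol = 1e-6,
                         seed = 1, source_model = c("diagonal", "full")) {
  source_model <- match.arg(source_model)
  X <- as.matrix(x)
  M <- nrow(X); T <- ncol(X)
  if (M < 2) mibci_stop("need at least 2 signals")
  if (T <= M * max(order, 1) * 4)
    mibci_stop("time series too short relative to dimension and order")
  center <- rowMeans(X)
  X <- X - center
  C0 <- tcrossprod(X) / T
  eg <- eigen(C0, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values))
    mibci_stop("input covariance numerically singular; remove redundant signals")
  whitener <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Z <- whitener %*% X
  W <- with_seed(seed, diag(M) + matrix(rnorm(M * M, 0, 0.01), M))
  ## residuals, scales and quasi-likelihood objective (density prop. to
  ## 1/cosh with per-source scale, plus the volume term) at a given W.
  ## The objective is invariant to row rescaling of W.
  evaluate <- function(W) {
    Y <- W %*% Z
    if (order == 0) {
      E <- Y
      Rlist <- NULL
    } else if (source_model == "diagonal") {
      A <- lapply(seq_len(M), function(i) fit_ar_scalar(Y[i, ], order))
      Rlist <- lapply(seq_len(M), function(i) {
        Yi <- pe_filter(t(Y), A[[i]])
        t(Yi[(order + 1):T, , drop = FALSE])
      })
      E <- do.call(rbind, lapply(seq_len(M), function(i) Rlist[[i]][i, ]))
    } else {
      E <- fit_mvar(Y, order)$residuals
      Rlist <- NULL
    }
    sd_e <- sqrt(rowMeans(E^2))
    if (any(sd_e < .Machine$double.eps))
      mibci_stop("degenerate component during unmixing")
    obj <- sum(rowMeans(log_cosh(E / sd_e))) + sum(log(sd_e)) -
      as.numeric(determinant(W)$modulus)
    list(obj = if (is.finite(obj)) obj else Inf, E = E, sd_e = sd_e,
         Rlist = Rlist)
  }
  lr0 <- lr
  r <- evaluate(W)
  history <- r$obj
  accepted <- 0L
  for (it in seq_len(max_iter)) {
    ## natural-gradient proposal from the current best, rows normalised to
    ## unit residual scale
    Wn <- W / r$sd_e
    En <- r$E / r$sd_e
    Te <- ncol(En)
    if (is.null(r$Rlist)) {
      G <- tanh(En) %*% t(En) / Te
    } else {
      G <- matrix(0, M, M)
      for (i in seq_len(M))
        G[i, ] <- tanh(En[i, , drop = FALSE]) %*% t(r$Rlist[[i]] / r$sd_e) / Te
    }
    Wp <- Wn + lr * (diag(M) - G) %*% Wn
    rp <- evaluate(Wp)
    if (rp$obj < r$obj - 1e-12 * abs(r$obj)) {
      imp <- r$obj - rp$obj
      W <- Wp; r <- rp
      history <- c(history, rp$obj)
      accepted <- accepted + 1L
      lr <- min(lr * 1.2, lr0 * 4)
      if (imp < tol * max(abs(rp$obj), 1)) break
    } else {
      lr <- lr / 2
      if (lr < lr0 / 2^20) {
        if (accepted == 0L)
          mibci_stop(paste0("unmixing diverged from the start; history: ",
                            paste(format(history, digits = 6), collapse = ", ")))
        break                                 # numerical optimum reached
      }
    }
  }
  ## final normalisation: unit residual variance, power order, sign fix
  Y <- W %*% Z
  if (order > 0) {
    res <- vapply(seq_len(M), function(i) {
      a <- fit_ar_scalar(Y[i, ], order)
      e <- pe_filter(Y[i, ], a)
      sd(e[(order + 1):T])
    }, numeric(1))
    W <- W / res
    Y <- W %*% Z
  }
  pow <- apply(Y, 1, var)
  ord <- order(pow, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  Wtot <- W %*% whitener
  mix_est <- MASS_ginv_like(Wtot)
  for (i in seq_len(M)) {
    j <- which.max(abs(mix_est[, i]))
    if (mix_est[j, i] < 0) W[i, ] <- -W[i, ]
  }
  kap <- kappa(W, exact = FALSE)
  if (kap > 1e8) warning("unmixing matrix badly conditioned (kappa = ",
                         format(kap, digits = 3), ")")
  Yf <- W %*% Z
  mv <- if (order > 0) fit_mvar(Yf, order) else NULL
  structure(list(whitener = whitener, unmixing = W, center = center,
                 mvar = mv, history = history, order = order,
                 source_model = if (order > 0) source_model else "none"),
            class = "unmixing_model")
}

## Moore-Penrose pseudo-inverse via SVD (estimated forward mixing = pinv of
## the total unmixing); avoids adding a MASS dependency for one call.
MASS_ginv_like <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Apply a fitted unmixing model
#'
#' @param model An `"unmixing_model"`.
#' @param data Numeric matrix `C x T` with the width the model was fitted
#'   on.
#' @param recenter Subtract the training channel means first (default
#'   `TRUE`).
#' @return Matrix `M x T` of independent components, ordered by training
#'   power.
#' @export
ica_transform <- function(model, data, recenter = TRUE) {
  stopifnot(inherits(model, "unmixing_model"))
  data <- as.matrix(data)
  if (nrow(data) != ncol(model$whitener))
    mibci_stop("data width (", nrow(data), ") does not match the model (",
               ncol(model$whitener), ")")
  if (recenter) data <- data - model$center
  model$unmixing %*% (model$whitener %*% data)
}

#' @export
print.unmixing_model <- function(x, ...) {
  cat(sprintf("<unmixing_model> %d components, AR order %d (%s), %d accepted steps, objective %.6g\n",
              nrow(x$unmixing), x$order, x$source_model, length(x$history),
              tail(x$history, 1)))
  invisible(x)
}
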