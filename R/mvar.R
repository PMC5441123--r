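#' Fit a multivariate autoregressive model by least squares
#'
#' Stacks the `P` previous sample vectors as regressors and solves the
#' multilinear regression `V_t = A U_t + E_t` for the coefficient matrices
#' `A_1 ... A_P` jointly by ordinary least squares. A rank-deficient
#' regressor matrix triggers a small ridge fallback with a warning.
#'
#' @param x Numeric matrix `M x T` of source signals.
#' @param order Model order `P` (>= 1). `T` must exceed `M * P + M`.
#' @return An object of class `"mvar_fit"`: `coeffs` (array
#'   `M x M x P`), `order`, `residuals` (`M x (T - P)`), `residual_cov`.
#' @export
fit_mvar <- function(x, order) {
  x <- as.matrix(x)
  M <- nrow(x); T <- ncol(x)
  order <- check_count(order, "order")
  if (T <= M * order + M)
    mibci_stop("time series too short: need T > M*P + M = ", M * order + M)
  ## regressors: U[, t] = (x_{t-1}, ..., x_{t-P}); build as T-P rows
  idx <- (order + 1):T
  U <- matrix(0, length(idx), M * order)
  for (k in seq_len(order))
    U[, (k - 1) * M + seq_len(M)] <- t(x[, idx - k, drop = FALSE])
  V <- t(x[, idx, drop = FALSE])
  qrU <- qr(U)
  A_flat <- if (qrU$rank < ncol(U)) {
    warning("rank-deficient regressor matrix; using ridge fallback")
    G <- crossprod(U)
    lam <- 1e-8 * sum(diag(G))
    t(solve(G + diag(lam, ncol(U)), crossprod(U, V)))
  } else {
    t(qr.coef(qrU, V))
  }
  E <- t(V - U %*% t(A_flat))
  coeffs <- array(A_flat, dim = c(M, M, order))
  structure(list(coeffs = coeffs, order = order, residuals = E,
                 residual_cov = tcrossprod(E) / ncol(E)),
            class = "mvar_fit")
}

#' @export
print.mvar_fit <- function(x, ...) {
  cat(sprintf("<mvar_fit> M = %d, order = %d, residual sd = %s\n",
              dim(x$coeffs)[1], x$order,
              paste(format(sqrt(diag(x$residual_cov)), digits = 3),
                    collapse = ", ")))
  invisible(x)
}

## univariate AR fit by OLS (used per estimated source inside the ICA loop)
fit_ar_scalar <- function(y, order) {
  T <- length(y)
  X <- matrix(0, T - order, order)
  for (k in seq_len(order)) X[, k] <- y[(order - k + 1):(T - k)]
  qr.solve(X, y[(order + 1):T])
}

## prediction-error filter e(t) = y(t) - sum_k a_k y(t-k), column-wise on a
## matrix; first `order` samples dropped by the caller
pe_filter <- function(y, a) {
  out <- stats::filter(y, c(1, -a), method = "convolution", sides = 1)
  if (is.null(dim(y))) as.numeric(out) else matrix(as.numeric(out), nrow(y))
}
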