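## Small-world neural network classifier: a 10-hidden-layer (8 neurons each)
## feedforward perceptron whose connection topology is perturbed by random
## cut-and-rewire events, giving shortcut edges that may skip layers. The
## output layer carries 4 neurons; at inference they pass through a
## hard-limit (threshold) transfer function, producing a 4-bit code. Only 4
## codes name imagery classes; the remaining 12 decode as "idle".

#' Class-to-output-code map
#'
#' Right hand 0001, left hand 0010, foot 0100, tongue 1000; every other
#' 4-bit pattern is idle.
#' @return Named character vector of 4-bit strings.
#' @export
gray_codes <- function() {
  c(right_hand = "0001", left_hand = "0010", foot = "0100", tongue = "1000")
}

#' Decode a 4-bit output pattern
#'
#' @param bits Numeric/logical vector of 4 bits or a 4-character string.
#' @return Class name or `"idle"`.
#' @export
decode_bits <- function(bits) {
  if (is.character(bits)) bits <- as.integer(strsplit(bits, "")[[1]])
  code <- paste(as.integer(bits), collapse = "")
  hit <- names(gray_codes())[gray_codes() == code]
  if (length(hit)) hit else "idle"
}

#' Build a small-world feedforward topology
#'
#' Starts from a fully layer-connected multilayer perceptron
#' (`input -> 8 x n_hidden -> 4`) and independently rewires each edge with
#' probability `rewire_p` to a uniformly chosen forward neuron, possibly
#' skipping layers -- the construction that gives small characteristic path
#' length at nearly unchanged clustering. Rewires that would leave a neuron
#' without an inbound or outbound connection are retried and then skipped.
#'
#' @param input_dim Number of input neurons (>= 1).
#' @param rewire_p Rewiring probability in \[0, 1\] (default 0.1).
#' @param seed Integer seed; construction is deterministic per seed.
#' @param n_hidden Number of hidden layers (default 10).
#' @param hidden_size Neurons per hidden layer (default 8).
#' @param n_out Output neurons (default 4).
#' @return An object of class `"swnn_topology"`: `layer` (per-neuron layer
#'   index, 0 = input), `mask` (N x N logical, `mask[i, j]` = edge i -> j),
#'   `layer_sizes`, `rewire_p`, `seed`.
#' @export
build_topology <- function(input_dim, rewire_p = 0.1, seed = 1,
                           n_hidden = 10, hidden_size = 8, n_out = 4) {
  input_dim <- check_count(input_dim, "input_dim")
  rewire_p <- check_number(rewire_p, "rewire_p", 0, 1)
  sizes <- c(input_dim, rep(hidden_size, n_hidden), n_out)
  layer <- rep(seq_along(sizes) - 1L, sizes)
  N <- length(layer)
  mask <- matrix(FALSE, N, N)
  for (l in seq_len(length(sizes) - 1)) {
    from <- which(layer == l - 1); to <- which(layer == l)
    mask[from, to] <- TRUE
  }
  mask <- with_seed(seed, {
    edges <- which(mask, arr.ind = TRUE)
    flip <- runif(nrow(edges)) < rewire_p
    for (k in which(flip)) {
      i <- edges[k, 1]; j <- edges[k, 2]
      if (sum(mask[, j]) <= 1 || sum(mask[i, ]) <= 1) next
      cand <- which(layer > layer[i] & !mask[i, ])
      cand <- cand[cand != i]
      ok <- FALSE
      for (tries in seq_len(5)) {
        if (!length(cand)) break
        j2 <- cand[sample.int(length(cand), 1)]
        mask[i, j] <- FALSE
        mask[i, j2] <- TRUE
        ok <- TRUE
        break
      }
      if (!ok) next
    }
    mask
  })
  structure(list(layer = layer, mask = mask, layer_sizes = sizes,
                 rewire_p = rewire_p, seed = seed),
            class = "swnn_topology")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

swnn_init_weights <- function(topology) {
  N <- length(topology$layer)
  W <- matrix(0, N, N)
  fan_in <- pmax(colSums(topology$mask), 1)
  fan_out <- pmax(rowSums(topology$mask), 1)
  idx <- which(topology$mask, arr.ind = TRUE)
  r <- sqrt(6 / (fan_in[idx[, 2]] + fan_out[idx[, 1]]))
  W[idx] <- runif(nrow(idx), -1, 1) * r
  b <- numeric(N)
  list(W = W, b = b)
}

swnn_forward <- function(model, X) {
  ## X: B x input_dim; returns list(Z = N x B activations, out = B x 4)
  top <- model$topology
  N <- length(top$layer)
  B <- nrow(X)
  Z <- matrix(0, N, B)
  Z[top$layer == 0, ] <- t(X)
  n_layers <- max(top$layer)
  for (l in seq_len(n_layers)) {
    idx <- which(top$layer == l)
    net <- crossprod(model$W[, idx, drop = FALSE], Z) + model$b[idx]
    Z[idx, ] <- sigmoid(net)
  }
  list(Z = Z, out = t(Z[top$layer == n_layers, , drop = FALSE]))
}

#' Train the small-world network
#'
#' Full-batch backpropagation (with momentum) of the cross-entropy between
#' the sigmoid outputs and the 4-bit class codes, combined with periodic
#' cut-and-rewire events: every `rewire_every` epochs the fraction
#' `cut_frac` of active connections with the smallest absolute weight is
#' cut and rewired to random forward positions (degree floor preserved),
#' letting the topology adapt alongside the weights. The hard-limit output
#' nonlinearity is used only at prediction time; its zero gradient makes
#' the sigmoid surrogate necessary for training.
#'
#' @param topology A `"swnn_topology"`.
#' @param features Numeric matrix, rows = feature vectors (width =
#'   `input_dim`).
#' @param labels Character vector of class labels (>= 2 distinct).
#' @param epochs Training epochs (default 300).
#' @param lr Learning rate (default 1).
#' @param momentum Momentum coefficient (default 0.9).
#' @param rewire_every Epochs between rewire events; 0 disables (default 50).
#' @param cut_frac Fraction of active edges cut per event (default 0.05).
#' @param seed Seed for weight init and rewiring (default 1).
#' @return An object of class `"swnn_model"` with `W`, `b`, `topology`,
#'   `history` (loss per epoch).
#' @export
swnn_train <- function(topology, features, labels, epochs = 300, lr = 1,
                       momentum = 0.9, rewire_every = 50, cut_frac = 0.05,
                       seed = 1) {
  stopifnot(inherits(topology, "swnn_topology"))
  X <- as.matrix(features)
  if (ncol(X) != topology$layer_sizes[1])
    mibci_stop("feature width ", ncol(X), " != input_dim ",
               topology$layer_sizes[1])
  if (length(unique(labels)) < 2)
    mibci_stop("need at least 2 classes in the training data")
  codes <- gray_codes()
  if (!all(labels %in% names(codes)))
    mibci_stop("unknown labels: ",
               paste(setdiff(labels, names(codes)), collapse = ", "))
  Ymat <- t(vapply(labels, function(l)
    as.numeric(strsplit(codes[[l]], "")[[1]] == "1"), numeric(4)))
  B <- nrow(X)
  with_seed(seed, {
    model <- c(swnn_init_weights(topology), list(topology = topology))
    V <- model$W * 0; vb <- model$b * 0
    out_idx <- which(topology$layer == max(topology$layer))
    history <- numeric(0)
    ep <- 1; fails <- 0
    while (ep <= epochs) {
      fw <- swnn_forward(model, X)
      P <- fw$out
      loss <- -mean(Ymat * log(pmax(P, 1e-12)) +
                    (1 - Ymat) * log(pmax(1 - P, 1e-12)))
      if (!is.finite(loss)) {
        fails <- fails + 1
        lr <- lr / 2
        if (fails >= 3)
          mibci_stop("non-finite loss after lr reductions; history: ",
                     paste(format(history, digits = 5), collapse = ", "))
        next
      }
      history <- c(history, loss)
      ## backprop through the DAG
      N <- length(topology$layer)
      Delta <- matrix(0, N, B)
      Delta[out_idx, ] <- t(P - Ymat) / B
      for (l in seq(max(topology$layer) - 1, 1)) {
        idx <- which(topology$layer == l)
        d <- model$W[idx, , drop = FALSE] %*% Delta
        Delta[idx, ] <- d * fw$Z[idx, , drop = FALSE] *
          (1 - fw$Z[idx, , drop = FALSE])
      }
      gW <- (fw$Z %*% t(Delta)) * topology$mask
      gb <- rowSums(Delta)
      V <- momentum * V - lr * gW
      vb <- momentum * vb - lr * gb
      model$W <- model$W + V
      model$b <- model$b + vb
      if (rewire_every > 0 && ep %% rewire_every == 0 && ep < epochs) {
        model <- swnn_rewire(model, cut_frac)
        V <- V * model$topology$mask
        topology <- model$topology
      }
      ep <- ep + 1
    }
    structure(list(W = model$W, b = model$b, topology = topology,
                   history = history),
              class = "swnn_model")
  })
}

## cut the weakest active edges and rewire them to random forward slots
swnn_rewire <- function(model, cut_frac) {
  top <- model$topology
  act <- which(top$mask, arr.ind = TRUE)
  n_cut <- floor(nrow(act) * cut_frac)
  if (n_cut < 1) return(model)
  w <- abs(model$W[act])
  ord <- order(w)
  cut <- 0
  layer <- top$layer
  for (k in ord) {
    if (cut >= n_cut) break
    i <- act[k, 1]; j <- act[k, 2]
    if (sum(top$mask[, j]) <= 1 || sum(top$mask[i, ]) <= 1) next
    cand <- which(layer > layer[i] & !top$mask[i, ] & layer > 0)
    if (!length(cand)) next
    j2 <- cand[sample.int(length(cand), 1)]
    top$mask[i, j] <- FALSE
    model$W[i, j] <- 0
    top$mask[i, j2] <- TRUE
    model$W[i, j2] <- rnorm(1, 0, 0.01)
    cut <- cut + 1
  }
  model$topology <- top
  model
}

#' Predict with the hard-limit output
#'
#' Forward pass; the four output activations are thresholded at 0.5 to a
#' 4-bit pattern, which is matched against the class code map. Any
#' non-class pattern (including all-zero and multi-bit patterns) decodes as
#' `"idle"`.
#'
#' @param model A `"swnn_model"`.
#' @param features Feature vector or matrix (rows = cases).
#' @param rule `"hard_limit"` (default): threshold each output at 0.5 and
#'   decode the 4-bit pattern, non-class patterns giving `"idle"` -- the
#'   online-control behaviour. `"force_choice"`: the class of the most
#'   active output neuron, never idle -- the readout used for accuracy
#'   benchmarking, where every trial has a true class.
#' @return Character vector of class labels (and `"idle"` under
#'   `"hard_limit"`).
#' @export
swnn_predict <- function(model, features,
                         rule = c("hard_limit", "force_choice")) {
  rule <- match.arg(rule)
  X <- if (is.null(dim(features))) matrix(features, nrow = 1)
       else as.matrix(features)
  if (any(!is.finite(X))) mibci_stop("non-finite feature values")
  if (ncol(X) != model$topology$layer_sizes[1])
    mibci_stop("feature width mismatch")
  P <- swnn_forward(model, X)$out
  if (rule == "force_choice") {
    ## output neuron j is the set bit of one class code
    neuron_class <- vapply(seq_len(4), function(j) {
      code <- paste(as.integer(seq_len(4) == j), collapse = "")
      decode_bits(code)
    }, character(1))
    return(neuron_class[max.col(P)])
  }
  apply(P >= 0.5, 1, function(bits) decode_bits(as.numeric(bits)))
}

#' @export
print.swnn_topology <- function(x, ...) {
  e <- which(x$mask, arr.ind = TRUE)
  skip <- sum(x$layer[e[, 2]] - x$layer[e[, 1]] > 1)
  cat(sprintf("<swnn_topology> layers %s, %d edges (%d skip-layer), rewire_p = %g\n",
              paste(x$layer_sizes, collapse = "-"), nrow(e), skip, x$rewire_p))
  invisible(x)
}

#' @export
print.swnn_model <- function(x, ...) {
  cat(sprintf("<swnn_model> %s, final loss %.4g after %d epochs\n",
              paste(x$topology$layer_sizes, collapse = "-"),
              tail(x$history, 1), length(x$history)))
  invisible(x)
}
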