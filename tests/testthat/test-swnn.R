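test_that("exactly four output codes name classes, all others are idle", {
  codes <- gray_codes()
  expect_length(codes, 4)
  all_codes <- vapply(0:15, function(k)
    paste(rev(as.integer(intToBits(k))[1:4]), collapse = ""), character(1))
  decoded <- vapply(all_codes, decode_bits, character(1))
  expect_equal(sum(decoded != "idle"), 4)
  expect_equal(sum(decoded == "idle"), 12)
  expect_equal(decode_bits("0010"), "left_hand")
  expect_equal(decode_bits(c(0, 0, 0, 1)), "right_hand")
  expect_equal(decode_bits("0100"), "foot")
  expect_equal(decode_bits("1000"), "tongue")
  expect_equal(decode_bits("0000"), "idle")
  expect_equal(decode_bits("1101"), "idle")
})

test_that("zero rewiring reproduces a pure layered perceptron", {
  topo <- build_topology(16, rewire_p = 0, seed = 1)
  e <- which(topo$mask, arr.ind = TRUE)
  expect_true(all(topo$layer[e[, 2]] - topo$layer[e[, 1]] == 1))
  expect_equal(topo$layer_sizes, c(16, rep(8, 10), 4))
})

test_that("rewired topologies are deterministic and keep every neuron wired", {
  t1 <- build_topology(16, rewire_p = 1, seed = 5)
  t2 <- build_topology(16, rewire_p = 1, seed = 5)
  expect_identical(t1$mask, t2$mask)
  hidden <- which(t1$layer > 0 & t1$layer < max(t1$layer))
  expect_true(all(colSums(t1$mask)[hidden] >= 1))
  expect_true(all(rowSums(t1$mask)[hidden] >= 1))
})

test_that("rewiring shortens paths at little clustering cost", {
  skip_if_not_installed("igraph")
  metrics <- function(topo) {
    g <- igraph::graph_from_adjacency_matrix(topo$mask + t(topo$mask) > 0,
                                             mode = "undirected")
    c(L = igraph::mean_distance(g), C = igraph::transitivity(g))
  }
  res <- t(sapply(1:10, function(s) {
    m0 <- metrics(build_topology(16, rewire_p = 0, seed = s))
    m1 <- metrics(build_topology(16, rewire_p = 0.1, seed = s))
    c(m0, m1)
  }))
  ## shortcut edges reduce the characteristic path length in most draws
  expect_gt(mean(res[, 3] < res[, 1]), 0.8)
  ## layered graphs are triangle-free; rewiring adds at most a little closure
  expect_true(all(res[, 2] == 0))
  expect_lt(max(res[, 4]), 0.05)
})

sep_features <- function(seed, n = 40, spread = 2, noise = 0.5) {
  set.seed(seed)
  mu <- matrix(rnorm(4 * 16, 0, spread), 4)
  X <- do.call(rbind, lapply(1:4, function(c)
    sweep(matrix(rnorm(n * 16, 0, noise), n), 2, mu[c, ], "+")))
  list(X = X, y = rep(mi_classes(), each = n))
}

test_that("separable features are fit to high accuracy within 200 epochs", {
  d <- sep_features(42)
  topo <- build_topology(16, rewire_p = 0.1, seed = 1)
  m <- swnn_train(topo, d$X, d$y, epochs = 200, seed = 1)
  expect_gte(mean(swnn_predict(m, d$X) == d$y), 0.95)
  ## training is deterministic
  m2 <- swnn_train(topo, d$X, d$y, epochs = 200, seed = 1)
  expect_identical(m$W, m2$W)
  ## the loss history is recorded per epoch
  expect_length(m$history, 200)
})

test_that("an untrained network carries no class information", {
  d <- sep_features(43)
  topo <- build_topology(16, rewire_p = 0.1, seed = 2)
  m0 <- swnn_train(topo, d$X, d$y, epochs = 1, seed = 2)
  acc <- mean(swnn_predict(m0, d$X) == d$y)
  expect_lte(acc, 0.35)   # no better than chance on 4 balanced classes
})

test_that("cut-and-rewire events never strand a neuron", {
  d <- sep_features(44)
  topo <- build_topology(16, rewire_p = 0.1, seed = 3)
  m <- swnn_train(topo, d$X, d$y, epochs = 120, rewire_every = 20,
                  cut_frac = 0.1, seed = 3)
  hidden <- which(m$topology$layer > 0 &
                    m$topology$layer < max(m$topology$layer))
  expect_true(all(colSums(m$topology$mask)[hidden] >= 1))
  expect_true(all(rowSums(m$topology$mask)[hidden] >= 1))
  ## rewiring changed the topology relative to the start
  expect_false(identical(m$topology$mask, topo$mask))
  ## masked-out weights stay zero
  expect_true(all(m$W[!m$topology$mask] == 0))
})

test_that("predict rejects malformed features", {
  d <- sep_features(45, n = 5)
  topo <- build_topology(16, rewire_p = 0, seed = 1)
  m <- swnn_train(topo, d$X, d$y, epochs = 5, seed = 1)
  expect_error(swnn_predict(m, c(NA, rep(0, 15))), "finite")
  expect_error(swnn_predict(m, rep(0, 15)), "width")
})

test_that("the small-world classifier stays within reach of an equal MLP", {
  ## moderately overlapping classes; compare held-out accuracy
  set.seed(48)
  mu <- matrix(rnorm(4 * 16, 0, 1), 4)
  gen <- function(seed) {
    set.seed(seed)
    X <- do.call(rbind, lapply(1:4, function(c)
      sweep(matrix(rnorm(40 * 16), 40), 2, mu[c, ], "+")))
    list(X = X, y = rep(mi_classes(), each = 40))
  }
  tr <- gen(1); te <- gen(2)
  topo <- build_topology(16, rewire_p = 0.1, seed = 1)
  m <- swnn_train(topo, tr$X, tr$y, epochs = 300, seed = 1)
  acc_swnn <- mean(swnn_predict(m, te$X) == te$y)
  nn <- nnet::nnet(tr$X, nnet::class.ind(factor(tr$y, mi_classes())),
                   size = 8, softmax = TRUE, trace = FALSE, maxit = 300)
  acc_mlp <- mean(mi_classes()[max.col(predict(nn, te$X))] == te$y)
  expect_gte(acc_swnn, acc_mlp - 0.10)
})
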