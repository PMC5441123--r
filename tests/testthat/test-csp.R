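test_that("class covariance is a unit-trace epoch average", {
  set.seed(1)
  X <- matrix(rnorm(4 * 100), 4)
  C1 <- class_covariance(list(X, X, X))
  expect_equal(sum(diag(C1)), 1, tolerance = 1e-10)
  expect_equal(C1, tcrossprod(X) / sum(diag(tcrossprod(X))), tolerance = 1e-12)
  ## white noise: off-diagonals at sampling level
  eps <- lapply(1:200, function(i) matrix(rnorm(4 * 100), 4))
  Cw <- class_covariance(eps)
  expect_lt(max(abs(Cw[upper.tri(Cw)])), 0.05)
  expect_error(class_covariance(list(X)), "2 epochs")
})

test_that("identical class distributions give eigenvalues of one half", {
  set.seed(2)
  eps <- lapply(1:40, function(i) matrix(rnorm(4 * 400), 4))
  by_class <- split(eps, rep(mi_classes(), each = 10))
  fset <- fit_ovr_csp(by_class, n_pairs = 1)
  for (cl in mi_classes())
    expect_equal(fset$per_class[[cl]]$eigenvalues, rep(0.5, 4),
                 tolerance = 0.05)
})

test_that("planted two-channel problem matches the analytic eigenvalue", {
  ## class variance (4, 1), rest (1, 4): top eigenvalue = 4/5 on channel 1
  set.seed(3)
  mk <- function(sds, n = 300) lapply(1:n, function(i)
    matrix(rnorm(2 * 200), 2) * sds)
  by_class <- list(right_hand = mk(c(2, 1)), left_hand = mk(c(1, 2)),
                   foot = mk(c(1, 2)), tongue = mk(c(1, 2)))
  fset <- fit_ovr_csp(by_class, n_pairs = 1)
  rh <- fset$per_class$right_hand
  expect_equal(rh$eigenvalues[1], 4 / 5, tolerance = 0.02)
  expect_gt(abs(rh$filters[1, 1]), abs(rh$filters[1, 2]))
})

test_that("class and rest eigenvalues pair to exactly one", {
  d <- planted_epochs(4, n_per_class = 15, C = 5, boost = 2)
  by_class <- split(d$epochs, factor(d$labels, mi_classes()))
  fset <- fit_ovr_csp(by_class, n_pairs = 2)
  covs <- lapply(by_class, class_covariance)
  for (cl in mi_classes()) {
    Sc <- covs[[cl]]
    Sr <- Reduce(`+`, covs[setdiff(mi_classes(), cl)]) / 3
    F <- fset$per_class[[cl]]$filters
    lam_c <- diag(F %*% Sc %*% t(F))
    lam_r <- diag(F %*% Sr %*% t(F))
    expect_lt(max(abs(lam_c + lam_r - 1)), 1e-8)
  }
})

test_that("log-variance features separate the planted class", {
  d <- planted_epochs(5, n_per_class = 30, C = 4, boost = 2.5)
  by_class <- split(d$epochs, factor(d$labels, mi_classes()))
  fset <- fit_ovr_csp(by_class, n_pairs = 1)
  ## class epochs put more variance on their model's first filter than last
  rh_eps <- d$epochs[d$labels == "right_hand"]
  gaps <- vapply(rh_eps, function(X) {
    P <- fset$per_class$right_hand$filters %*% X
    v <- rowSums(P^2)
    v[1] - v[length(v)]
  }, numeric(1))
  expect_gt(mean(gaps > 0), 0.9)
  ## feature vector has the contracted length and is finite
  f <- extract_features(fset, rh_eps[[1]])
  expect_length(f, 4 * 2 * 1)
  expect_true(all(is.finite(f)))
})

test_that("identity unmixing yields identical features on both pathways", {
  d <- planted_epochs(6, n_per_class = 10, C = 3)
  by_class <- split(d$epochs, factor(d$labels, mi_classes()))
  fset <- fit_ovr_csp(by_class, n_pairs = 1)
  id_model <- structure(list(whitener = diag(3), unmixing = diag(3),
                             center = rep(0, 3), mvar = NULL,
                             history = 0, order = 0, source_model = "none"),
                        class = "unmixing_model")
  ep <- d$epochs[[1]]
  f_raw <- extract_features(fset, ep)
  f_ic <- extract_features(fset, ica_transform(id_model, ep, recenter = TRUE))
  expect_equal(f_raw, f_ic)
})

test_that("zero-variance projections are floored and flagged", {
  d <- planted_epochs(7, n_per_class = 5, C = 3)
  by_class <- split(d$epochs, factor(d$labels, mi_classes()))
  fset <- fit_ovr_csp(by_class, n_pairs = 1)
  f <- extract_features(fset, matrix(0, 3, 50))
  expect_true(all(f == log(1e-12)))
  expect_true(attr(f, "floored"))
})

test_that("first-last gap equals the eigenvalue spread for a self-defining epoch", {
  set.seed(8)
  X <- matrix(rnorm(3 * 400), 3) * c(3, 1, 0.5)
  others <- lapply(1:20, function(i) matrix(rnorm(3 * 400), 3))
  by_class <- list(right_hand = list(X, X), left_hand = others[1:6],
                   foot = others[7:13], tongue = others[14:20])
  fset <- fit_ovr_csp(by_class, n_pairs = 1)
  gap <- first_last_gap(fset, list(X), "right_hand")
  ev <- fset$per_class$right_hand$eigenvalues
  expect_equal(gap, ev[1] - ev[length(ev)], tolerance = 1e-10)
})

test_that("identical class covariances give a near-zero gap", {
  set.seed(9)
  eps <- lapply(1:60, function(i) matrix(rnorm(3 * 300), 3))
  by_class <- split(eps, rep(mi_classes(), each = 15))
  fset <- fit_ovr_csp(by_class, n_pairs = 1)
  g <- first_last_gap(fset, by_class$foot, "foot")
  expect_lt(abs(g), 0.1)
})

test_that("filters are invariant (up to sign) under joint channel rotation", {
  d <- planted_epochs(10, n_per_class = 20, C = 4, boost = 2)
  by_class <- split(d$epochs, factor(d$labels, mi_classes()))
  fset <- fit_ovr_csp(by_class, n_pairs = 1)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  by_rot <- lapply(by_class, function(l) lapply(l, function(X) Q %*% X))
  fset_rot <- fit_ovr_csp(by_rot, n_pairs = 1)
  for (cl in mi_classes()) {
    f1 <- fset$per_class[[cl]]$filters
    f2 <- fset_rot$per_class[[cl]]$filters %*% Q
    for (i in seq_len(nrow(f1))) {
      co <- abs(sum(f1[i, ] * f2[i, ])) /
        sqrt(sum(f1[i, ]^2) * sum(f2[i, ]^2))
      expect_gt(co, 0.999)
    }
  }
})
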