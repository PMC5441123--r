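#' Simulate selected-component epochs for pathway benchmarking
#'
#' Generates epochs of the multichannel object the CSP stage consumes: a
#' square mixture of independent AR sources -- four narrowband sources
#' whose innovation scale is modulated by one class each (ERD gains < 1,
#' ERS > 1), plus broadband background sources -- with additive sensor
#' noise. Defaults are calibrated to the single-trial regime of motor
#' imagery (cross-validated accuracies in the 70-85% range): 60 trials per
#' class, correlated mixing, noise of the same order as the sources.
#'
#' @param seed Integer seed.
#' @param n_per_class Trials per class (default 60).
#' @param len Samples per epoch (default 150).
#' @param noise_sd Additive white noise SD per component (default 2).
#' @param gains Length-4 innovation-scale gains of the four class sources
#'   during their class (default `c(0.65, 0.65, 0.72, 1.35)`).
#' @param n_background Broadband background sources (default 2).
#' @return List: `epochs` (list of `C x len` matrices), `labels`
#'   (class names), `mixing` (true forward matrix), `idle` (list of
#'   unmodulated epochs, same size as one class).
#' @export
simulate_component_epochs <- function(seed, n_per_class = 60, len = 150,
                                      noise_sd = 2,
                                      gains = c(0.65, 0.65, 0.72, 1.35),
                                      n_background = 2) {
  M <- 4 + n_background
  ars <- c(list(c(1.7, -0.92), c(1.2, -0.85), c(0.4, -0.7), c(-0.9, -0.5)),
           rep(list(c(0.95, 0)), n_background))[seq_len(M)]
  base_sd <- c(rep(1, 4), rep(2.5, n_background))
  with_seed(seed, {
    A <- matrix(rnorm(M * M), M) + 1.2
    labels <- sample(rep(mi_classes(), n_per_class))
    gen_epoch <- function(cls_idx) {
      S <- matrix(0, M, len)
      for (i in seq_len(M)) {
        g <- if (!is.na(cls_idx) && i <= 4 && i == cls_idx) gains[i] else 1
        innov <- rnorm(len + 60, 0, base_sd[i] * g)
        S[i, ] <- stats::filter(innov, ars[[i]],
                                method = "recursive")[60 + seq_len(len)]
      }
      A %*% S + matrix(rnorm(M * len, 0, noise_sd), M)
    }
    epochs <- lapply(match(labels, mi_classes()), gen_epoch)
    idle <- lapply(seq_len(n_per_class), function(i) gen_epoch(NA))
    list(epochs = epochs, labels = labels, mixing = A, idle = idle)
  })
}

## classifier wrappers: fit on a feature matrix + labels, predict labels
fit_predict_classifier <- function(classifier, Xtr, ytr, Xte, seed = 1) {
  ytr <- factor(ytr, levels = mi_classes())
  switch(classifier,
    swnn = {
      topo <- build_topology(ncol(Xtr), rewire_p = 0.1, seed = seed)
      m <- swnn_train(topo, Xtr, as.character(ytr), seed = seed)
      swnn_predict(m, Xte, rule = "force_choice")
    },
    mlp = {
      m <- with_seed(seed, nnet::nnet(Xtr, nnet::class.ind(ytr), size = 8,
                                      softmax = TRUE, trace = FALSE,
                                      maxit = 300, MaxNWts = 5000))
      mi_classes()[max.col(predict(m, Xte))]
    },
    svm_rbf = {
      m <- e1071::svm(Xtr, ytr, kernel = "radial")
      as.character(predict(m, Xte))
    },
    lssvm = {
      m <- with_seed(seed, kernlab::lssvm(as.matrix(Xtr), ytr,
                                          kernel = "rbfdot"))
      as.character(kernlab::predict(m, as.matrix(Xte)))
    },
    mibci_stop("unknown classifier: ", classifier))
}

#' Cross-validated pathway/classifier comparison
#'
#' Stratified repeated k-fold cross-validation of the CSP feature pipeline.
#' CSP filters are refit on each fold's training epochs; the ICA transform
#' (when a pathway provides one) is considered part of the unsupervised
#' representation and applied as given. Fold assignment is reshuffled per
#' repeat under the given seed, and per-fold accuracies are retained for
#' paired comparisons.
#'
#' @param pathways Named list; each entry is `list(epochs = <list of C x T
#'   matrices>, labels = <character>)`.
#' @param classifiers Character vector from `"swnn"`, `"mlp"`,
#'   `"svm_rbf"`, `"lssvm"` (default `"swnn"`).
#' @param repeats,folds Cross-validation scheme (defaults 1 and 10). A
#'   class smaller than `folds` reduces the fold count with a warning.
#' @param n_pairs CSP filters per end (default 2).
#' @param seed Integer seed.
#' @return An object of class `"cv_report"`: data frame `summary`
#'   (pathway, classifier, mean and sd of accuracy in percent) and array
#'   `fold_acc`.
#' @export
cross_validate <- function(pathways, classifiers = "swnn", repeats = 1,
                           folds = 10, n_pairs = 2, seed = 1) {
  stopifnot(is.list(pathways), length(names(pathways)) == length(pathways))
  labels <- pathways[[1]]$labels
  min_class <- min(table(labels))
  if (min_class < folds) {
    warning("smallest class (", min_class, ") below fold count; using ",
            min_class, " folds")
    folds <- min_class
  }
  fold_acc <- array(NA_real_,
                    dim = c(length(pathways), length(classifiers),
                            repeats, folds),
                    dimnames = list(names(pathways), classifiers, NULL, NULL))
  for (rep_i in seq_len(repeats)) {
    fold_of <- with_seed(seed + rep_i * 131L, {
      f <- integer(length(labels))
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        f[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
      }
      f
    })
    for (p in seq_along(pathways)) {
      eps <- pathways[[p]]$epochs
      labs <- pathways[[p]]$labels
      for (k in seq_len(folds)) {
        tr <- fold_of != k
        fset <- fit_ovr_csp(split(eps[tr], factor(labs[tr], mi_classes())),
                            n_pairs)
        Xtr <- t(vapply(eps[tr], function(X) extract_features(fset, X),
                        numeric(8 * n_pairs)))
        Xte <- t(vapply(eps[!tr], function(X) extract_features(fset, X),
                        numeric(8 * n_pairs)))
        for (cf in seq_along(classifiers)) {
          pred <- fit_predict_classifier(classifiers[cf], Xtr, labs[tr], Xte,
                                         seed = seed + rep_i)
          fold_acc[p, cf, rep_i, k] <- 100 * mean(pred == labs[!tr])
        }
      }
    }
  }
  summary <- do.call(rbind, lapply(seq_along(pathways), function(p)
    do.call(rbind, lapply(seq_along(classifiers), function(cf)
      data.frame(pathway = names(pathways)[p], classifier = classifiers[cf],
                 mean_acc = mean(fold_acc[p, cf, , ]),
                 sd_acc = sd(as.vector(fold_acc[p, cf, , ])),
                 stringsAsFactors = FALSE)))))
  structure(list(summary = summary, fold_acc = fold_acc,
                 repeats = repeats, folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d x %d-fold CV\n", x$repeats, x$folds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' ERD/ERS index of a component against the idle baseline
#'
#' Relative band-power change of imagery epochs against idle epochs for one
#' (electrode, band) component: `(P_MI - P_idle) / P_idle`. Negative values
#' indicate desynchronisation (ERD), positive synchronisation (ERS).
#'
#' @param epochs Imagery epochs (list of `"epoch"`).
#' @param idle_epochs Idle epochs.
#' @param electrode Channel name.
#' @param band Length-2 numeric band in Hz.
#' @param order Filter order (default 10).
#' @return Scalar index.
#' @export
erds_index <- function(epochs, idle_epochs, electrode, band, order = 10) {
  if (!length(epochs) || !length(idle_epochs))
    mibci_stop("both epoch sets must be nonempty")
  bp <- function(eps) {
    fs <- eps[[1]]$fs
    filt <- cached_bandpass(order, 0.5, max(band[1], 0.5),
                            min(band[2], fs / 2 - 0.5), fs)
    mean(vapply(eps, function(e) {
      ch <- match(electrode, rownames(e$data))
      if (is.na(ch)) mibci_stop("electrode ", electrode, " not in epoch")
      mean(sos_filtfilt(e$data[ch, ], filt)^2)
    }, numeric(1)))
  }
  p_mi <- bp(epochs)
  p_idle <- bp(idle_epochs)
  if (p_idle < .Machine$double.eps) mibci_stop("zero idle-band power")
  (p_mi - p_idle) / p_idle
}
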