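#' Default pipeline configuration
#'
#' Nested list of tunables for the offline training pipeline; any entry can
#' be overridden through the `config` argument of [train_pipeline()].
#'
#' @return Named list.
#' @export
mibci_config <- function() {
  list(
    notch = list(center_hz = 50, bw = 1),
    epoch = list(window = c(0, 4), baseline_s = 0.5),
    filterbank = list(low = 0, high = 60, width = 2, order = 10),
    selection = list(top_k = 10, screen = TRUE),
    ica = list(order = 6, lr = 0.05, max_iter = 200, tol = 1e-6,
               source_model = "diagonal"),
    csp = list(n_pairs = 2),
    swnn = list(epochs = 300, lr = 1, rewire_p = 0.1, rewire_every = 50,
                cut_frac = 0.05))
}

merge_config <- function(config) {
  base <- mibci_config()
  if (is.null(config)) return(base)
  for (k in names(config)) base[[k]] <- modifyList(base[[k]], config[[k]])
  base
}

#' Train the full offline pipeline on a recording
#'
#' Runs the complete offline path: notch filtering, ocular regression,
#' epoch extraction (imagery and idle), common average reference,
#' characteristic-component ranking and selection, temporal ICA on the
#' concatenated selected-component signals, one-versus-rest CSP on both the
#' raw components (`csp_data`) and the independent components (`csp_ic`),
#' and small-world-network training on the ICA-pathway features.
#'
#' @param rec A `"recording"` containing all four classes.
#' @param config Optional overrides of [mibci_config()].
#' @param seed Integer seed controlling every stochastic stage.
#' @return An object of class `"pipeline_artifacts"`: `selection`, `ica`,
#'   `csp_data`, `csp_ic`, `classifier`, `config`, and the training
#'   feature matrices.
#' @export
train_pipeline <- function(rec, config = NULL, seed = 1) {
  cfg <- merge_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      mibci_stop("pipeline stage `", name, "` failed: ", conditionMessage(e)))
  }
  rec <- stage("notch", notch_filter(rec, cfg$notch$center_hz, bw = cfg$notch$bw))
  rec <- stage("eog", regress_out_eog(rec))
  epochs <- stage("epochs", extract_epochs(rec, cfg$epoch$window, idle = TRUE,
                                           baseline_s = cfg$epoch$baseline_s))
  epochs <- lapply(epochs, car_filter)
  labs <- vapply(epochs, `[[`, character(1), "mi_class")
  if (!all(mi_classes() %in% labs))
    mibci_stop("recording does not contain every imagery class")
  fb <- cfg$filterbank
  rsq <- stage("ranking", rank_components(epochs, fb$low, fb$high, fb$width, fb$order))
  sel <- stage("selection", select_components(rsq, cfg$selection$top_k,
                                              cfg$selection$screen))
  mi_epochs <- epochs[labs != "idle"]
  comp <- stage("components", lapply(mi_epochs, component_signals, selection = sel,
                                     order = fb$order))
  ica <- stage("ica", fit_unmixing(do.call(cbind, comp), order = cfg$ica$order,
                                   lr = cfg$ica$lr, max_iter = cfg$ica$max_iter,
                                   tol = cfg$ica$tol, seed = seed,
                                   source_model = cfg$ica$source_model))
  comp_ic <- lapply(comp, ica_transform, model = ica)
  mi_labs <- labs[labs != "idle"]
  by_class <- function(lst) split(lst, factor(mi_labs, levels = mi_classes()))
  csp_data <- stage("csp_data", fit_ovr_csp(by_class(comp), cfg$csp$n_pairs))
  csp_ic <- stage("csp_ic", fit_ovr_csp(by_class(comp_ic), cfg$csp$n_pairs))
  feats_ic <- t(vapply(comp_ic, function(X) extract_features(csp_ic, X),
                       numeric(8 * cfg$csp$n_pairs)))
  feats_data <- t(vapply(comp, function(X) extract_features(csp_data, X),
                         numeric(8 * cfg$csp$n_pairs)))
  topo <- build_topology(ncol(feats_ic), rewire_p = cfg$swnn$rewire_p,
                         seed = seed)
  clf <- stage("classifier",
               swnn_train(topo, feats_ic, mi_labs, epochs = cfg$swnn$epochs,
                          lr = cfg$swnn$lr, rewire_every = cfg$swnn$rewire_every,
                          cut_frac = cfg$swnn$cut_frac, seed = seed))
  structure(list(selection = sel, ica = ica, csp_data = csp_data,
                 csp_ic = csp_ic, classifier = clf, config = cfg,
                 features_ic = feats_ic, features_data = feats_data,
                 labels = mi_labs, seed = seed),
            class = "pipeline_artifacts")
}

#' Decode one epoch with trained artifacts
#'
#' @param artifacts A `"pipeline_artifacts"`.
#' @param epoch An `"epoch"` (EEG channels matching the training montage).
#' @return Decoded label: a class or `"idle"`.
#' @export
predict_pipeline <- function(artifacts, epoch) {
  comp <- component_signals(epoch, artifacts$selection,
                            order = artifacts$config$filterbank$order)
  ic <- ica_transform(artifacts$ica, comp)
  f <- extract_features(artifacts$csp_ic, ic)
  swnn_predict(artifacts$classifier, f)
}

#' Decoder backed by trained artifacts and a recording
#'
#' Cuts a 1-second window ending at the decode time out of the recording,
#' preprocesses it like a training epoch and classifies it; intended for
#' [run_session()].
#'
#' @param artifacts A `"pipeline_artifacts"`.
#' @param rec A `"recording"` (already notch/EOG cleaned or raw).
#' @param window_s Decoding window length (default 1 s).
#' @return Function `(t_s, state) -> label`.
#' @export
pipeline_decoder <- function(artifacts, rec, window_s = 1) {
  fs <- rec$montage$fs
  eeg_idx <- match(rec$montage$eeg_labels, rownames(rec$data))
  function(t, state) {
    i1 <- min(ncol(rec$data), max(round(t * fs), round(window_s * fs)))
    i0 <- i1 - round(window_s * fs) + 1L
    X <- car_filter(rec$data[eeg_idx, i0:i1, drop = FALSE])
    ep <- new_epoch(X, "unknown", c(0, window_s), fs)
    predict_pipeline(artifacts, ep)
  }
}

#' Save / load pipeline artifacts as JSON
#'
#' Serialises every matrix of the artifact bundle into a single JSON file;
#' reloading reproduces identical predictions.
#'
#' @param artifacts A `"pipeline_artifacts"`.
#' @param path File path.
#' @return `save_artifacts` returns `path` invisibly; `load_artifacts` the
#'   restored object.
#' @export
save_artifacts <- function(artifacts, path) {
  jsonlite::write_json(serialize_obj(unclass(artifacts)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_artifacts
#' @export
load_artifacts <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  art <- deserialize_obj(raw)
  class(art) <- "pipeline_artifacts"
  class(art$selection) <- "component_selection"
  class(art$ica) <- "unmixing_model"
  if (!is.null(art$ica$mvar)) class(art$ica$mvar) <- "mvar_fit"
  class(art$csp_data) <- class(art$csp_ic) <- "csp_filter_set"
  class(art$classifier) <- "swnn_model"
  class(art$classifier$topology) <- "swnn_topology"
  art$classifier$topology$mask <- matrix(as.logical(art$classifier$topology$mask),
                                         nrow = length(art$classifier$topology$layer))
  art
}

## JSON-safe encoding of nested lists of matrices/arrays/data frames
serialize_obj <- function(x) {
  if (is.matrix(x) || is.array(x))
    list(.mat = TRUE, dim = dim(x), dimnames = dimnames(x), data = as.vector(x))
  else if (is.data.frame(x)) list(.df = TRUE, data = x)
  else if (is.list(x)) lapply(x, serialize_obj)
  else x
}

deserialize_obj <- function(x) {
  if (is.list(x) && isTRUE(x$.mat)) {
    m <- array(x$data, dim = unlist(x$dim))
    if (!is.null(x$dimnames)) dimnames(m) <- x$dimnames
    m
  } else if (is.list(x) && isTRUE(x$.df)) as.data.frame(x$data)
  else if (is.list(x)) lapply(x, deserialize_obj)
  else x
}

#' @export
print.pipeline_artifacts <- function(x, ...) {
  cat(sprintf("<pipeline_artifacts> %d components selected, %d ICs, feature dim %d, %d training epochs\n",
              nrow(x$selection$selected), nrow(x$ica$unmixing),
              ncol(x$features_ic), nrow(x$features_ic)))
  invisible(x)
}
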