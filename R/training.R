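#' Construct a labeled training set
#'
#' @param features numeric matrix of feature vectors (rows = population
#'   pairs, columns in the fixed feature order).
#' @param labels integer vector of -1 (same species) / +1 (different
#'   species), one per row.
#' @param provenance `"general"` (coalescent-simulated) or `"custom"`
#'   (reference taxon).
#' @param cfg the [feature_config] the features were computed under.
#' @return an object of class `training_set`; its `scaling` element is the
#'   \[-1, 1\] transform fitted on these features.
#' @export
training_set <- function(features, labels,
                         provenance = c("general", "custom"),
                         cfg = feature_config()) {
  provenance <- match.arg(provenance)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels) || nrow(features) < 2L)
    stop("need >= 2 labeled feature vectors, one label per row")
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be -1 or +1")
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes (-1 and +1)")
  if (!all(is.finite(features))) stop("non-finite feature value in training set")
  colnames(features) <- feature_names(cfg)
  structure(list(features = features, labels = labels,
                 provenance = provenance, cfg = cfg,
                 scaling = fit_scaling(features)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set (%s): %d examples (%d same / %d different), %d features\n",
              x$provenance, length(x$labels), sum(x$labels == -1L),
              sum(x$labels == 1L), ncol(x$features)))
  invisible(x)
}

#' Build a "general" training set from a simulated scenario grid
#'
#' For every labeled grid cell and replicate, simulates a two-population
#' isolation-with-migration dataset, computes its feature vector, and
#' attaches the cell's label; unlabeled cells are skipped. Deterministic
#' given `seed`.
#'
#' @param grid list of [im_scenario] (e.g. [default_general_grid()]).
#' @param reps_per_cell replicates per labeled cell.
#' @param seed integer master seed.
#' @param cfg a [feature_config].
#' @return a `training_set` with provenance `"general"`.
#' @export
build_general_training_set <- function(grid, reps_per_cell = 20L, seed,
                                       cfg = feature_config()) {
  stopifnot(is.list(grid), reps_per_cell >= 1L)
  labs <- vapply(grid, function(s) s$label, integer(1))
  if (!any(labs == -1L, na.rm = TRUE) || !any(labs == 1L, na.rm = TRUE))
    stop("grid must contain labeled cells of both classes")
  cells <- which(!is.na(labs))
  rows <- list(); out_labs <- integer(0)
  k <- 0L
  for (ci in cells) {
    for (r in seq_len(reps_per_cell)) {
      k <- k + 1L
      ds <- simulate_im_pair(grid[[ci]], derive_seed(seed, k))
      rows[[k]] <- compute_feature_vector(ds, "pop1", "pop2", cfg)
      out_labs[k] <- labs[ci]
    }
  }
  training_set(do.call(rbind, rows), out_labs, "general", cfg)
}

#' Build a "custom" training set from a reference taxon
#'
#' One feature vector per unordered population pair of a reference dataset
#' whose sample map carries known species labels; a pair is labeled -1
#' (same species) when both populations share a species id, else +1. This
#' automates the relabeling of conspecific population pairs (+1 to -1) that
#' turns a naive all-pairs-different output into reference training data.
#'
#' @param ref a [multilocus_dataset] with a species column, complete-matrix
#'   filtered.
#' @param cfg a [feature_config].
#' @return a `training_set` with provenance `"custom"`.
#' @export
build_custom_training_set <- function(ref, cfg = feature_config()) {
  stopifnot(inherits(ref, "multilocus_dataset"))
  sm <- ref$sample_map
  if (!"species" %in% names(sm))
    stop("reference sample map must carry a species id for every population")
  if (!length(ref$loci)) stop("reference dataset has no loci")
  tb <- feature_table(ref, cfg)
  sp_of <- stats::setNames(sm$species, sm$population)[!duplicated(sm$population)]
  labs <- ifelse(sp_of[tb$popA] == sp_of[tb$popB], -1L, 1L)
  if (length(unique(labs)) < 2L)
    stop("reference populations are all ",
         if (labs[1] == -1L) "conspecific" else "heterospecific",
         "; both pair classes are required")
  training_set(as.matrix(tb[, feature_names(cfg)]), labs, "custom", cfg)
}

# Platt sigmoid fit: P(y = +1 | f) = 1 / (1 + exp(A f + B)), with the
# regularized targets of Platt (1999). Returns c(A, B).
fit_platt <- function(f, y) {
  np <- sum(y == 1L); nn <- sum(y == -1L)
  t <- ifelse(y == 1L, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # with p = 1/(1+e^z), NLL = sum[t z + log(1+e^{-z})], computed stably
    sum(t * z + ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z))))
  }
  init <- c(0, log((nn + 1) / (np + 1)))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  fit$par
}

platt_prob_plus <- function(platt, f) 1 / (1 + exp(platt[1] * f + platt[2]))

# decision values of an e1071 svm fit, oriented as returned by predict()
svm_decision <- function(fit, x) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  as.numeric(attr(p, "decision.values"))
}

svm_fit <- function(x, y, gamma, weights) {
  # LibSVM orients decision values by order of class appearance in the data;
  # sort rows by label so every fit (full and CV folds) has the same
  # orientation, keeping the Platt sigmoid consistent across folds.
  o <- order(y)
  e1071::svm(x[o, , drop = FALSE], y[o], type = "C-classification",
             kernel = "radial", cost = 1, gamma = gamma, scale = FALSE,
             class.weights = weights)
}

#' Train the probability-calibrated support-vector classifier
#'
#' Fits a soft-margin SVM with a radial-basis kernel at the LibSVM defaults
#' the method invokes (`C = 1`, `gamma = 1/n_features`) on \[-1, 1\]-scaled
#' features, with per-class weights inversely proportional to class counts
#' (reference sets are dominated by different-species pairs). Calibrated
#' same-species probabilities come from a Platt-style sigmoid fitted to
#' held-out decision values from seeded stratified cross-validation with
#' `min(5, smallest class size)` folds. Deterministic given `seed`.
#'
#' @param ts a `training_set`.
#' @param seed integer seed for the calibration folds.
#' @return an object of class `delim_model` carrying the SVM, the sigmoid
#'   parameters, the scaling transform, the feature order, and the
#'   feature-config fingerprint.
#' @export
train_classifier <- function(ts, seed) {
  stopifnot(inherits(ts, "training_set"))
  y <- factor(ts$labels, levels = c(-1L, 1L))
  counts <- table(y)
  if (any(counts < 2L))
    stop("need >= 2 examples per class for calibration folds; add training data")
  x <- apply_scaling(ts$scaling, ts$features)
  gamma <- 1 / ncol(x)
  weights <- stats::setNames(as.numeric(length(y) / (2 * counts)), names(counts))
  nfold <- min(5L, min(counts))
  # stratified folds, seeded
  set.seed(derive_seed(seed, 1L))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(nfold), length(idx)))
  }
  f_cv <- numeric(length(y))
  for (k in seq_len(nfold)) {
    tr <- fold != k
    fit_k <- svm_fit(x[tr, , drop = FALSE], y[tr], gamma, weights)
    f_cv[!tr] <- svm_decision(fit_k, x[!tr, , drop = FALSE])
  }
  platt <- fit_platt(f_cv, ts$labels)
  fit <- svm_fit(x, y, gamma, weights)
  structure(list(svm = fit, platt = platt, scaling = ts$scaling,
                 feature_names = colnames(ts$features),
                 fingerprint = config_fingerprint(ts$cfg),
                 provenance = ts$provenance, seed = as.integer(seed),
                 n_train = length(y)),
            class = "delim_model")
}

#' @export
print.delim_model <- function(x, ...) {
  cat(sprintf("delim_model (%s training, %d examples, %d features, fingerprint %s)\n",
              x$provenance, x$n_train, length(x$feature_names), x$fingerprint))
  invisible(x)
}

#' Predict labels and calibrated same-species probabilities
#'
#' @param model a `delim_model`.
#' @param features numeric matrix of raw (unscaled) feature vectors in the
#'   model's feature order.
#' @return data frame with columns `label` (-1 iff `p_same >= 0.5`) and
#'   `p_same`.
#' @export
predict_pairs <- function(model, features) {
  stopifnot(inherits(model, "delim_model"))
  m <- as.matrix(features)
  if (ncol(m) != length(model$feature_names))
    stop("feature count mismatch with model")
  x <- apply_scaling(model$scaling, m)
  f <- svm_decision(model$svm, x)
  p_same <- 1 - platt_prob_plus(model$platt, f)
  data.frame(label = ifelse(p_same >= 0.5, -1L, 1L), p_same = p_same)
}

#' Save / load a trained model
#'
#' The bundle holds the SVM state, calibration parameters, scaling
#' transform, feature order and configuration fingerprint; serialization is
#' deterministic, so identical training runs give byte-identical files.
#'
#' @param model a `delim_model`.
#' @param path file path.
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "delim_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "delim_model")) stop("not a delim_model file: ", path)
  m
}
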