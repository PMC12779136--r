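# Flux-feature assembly and the random-forest classification protocol.

#' Assemble the padded flux feature matrix
#'
#' Context-specific models retain different reaction sets, so their flux
#' profiles are not directly comparable. The feature space is the union
#' of active reaction ids across all models, in lexicographic order;
#' each sample contributes its flux where the reaction is in its active
#' set and a missing marker (`NA`) where it is not.
#'
#' @param models List of per-sample entries, each a list with `context`
#'   (a `context_model`) and `profile` (a `flux_profile`), as returned by
#'   [contextualize_sample()].
#' @param labels Named character vector mapping sample ids to class
#'   labels.
#' @param origin Optional named character vector (real/synthetic).
#' @return A `feature_matrix`: list with `values` (samples x features,
#'   `NA` marks an absent reaction), `samples` tibble, `feature_ids`.
#' @export
assemble_features <- function(models, labels, origin = NULL) {
  if (length(models) < 2L) {
    stop("need at least 2 samples to assemble features", call. = FALSE)
  }
  sids <- vapply(models, function(m) m$profile$sample_id, character(1))
  if (anyDuplicated(sids)) {
    stop("duplicate sample id: ", sids[duplicated(sids)][1], call. = FALSE)
  }
  feats <- sort(unique(unlist(lapply(models, function(m) m$context$active))))
  vals <- matrix(NA_real_, length(sids), length(feats),
                 dimnames = list(sids, feats))
  for (m in models) {
    sid <- m$profile$sample_id
    act <- intersect(m$context$active, feats)
    vals[sid, act] <- m$profile$fluxes[act]
  }
  lab <- labels[sids]
  if (anyNA(lab)) {
    stop("missing label for sample(s): ",
         paste(sids[is.na(lab)], collapse = ", "), call. = FALSE)
  }
  org <- if (is.null(origin)) {
    rep("real", length(sids))
  } else {
    unname(origin[sids])
  }
  structure(
    list(
      values = vals,
      samples = tibble::tibble(sample_id = sids, label = unname(lab),
                               origin = org),
      feature_ids = feats
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d reaction features (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Impute missing flux features
#'
#' `"zero"` (default) sets absent reactions to 0: a reaction not in a
#' sample's context model truly carries no flux there, keeping the
#' feature physical. `"sentinel"` sets them to `min - 1.5 * range` of
#' the observed fluxes — a value outside the observed range, letting
#' trees isolate absence as its own signal.
#'
#' @param fm A `feature_matrix`.
#' @param strategy `"zero"` or `"sentinel"`.
#' @return A `feature_matrix` without missing values.
#' @export
impute_missing <- function(fm, strategy = c("zero", "sentinel")) {
  strategy <- match.arg(strategy)
  vals <- fm$values
  if (anyNA(vals)) {
    if (strategy == "zero") {
      vals[is.na(vals)] <- 0
    } else {
      obs <- range(vals, na.rm = TRUE)
      vals[is.na(vals)] <- obs[1] - 1.5 * (obs[2] - obs[1])
    }
  }
  fm$values <- vals
  fm$imputed <- strategy
  fm
}

#' Random-forest configuration
#'
#' Mirrors the study protocol: 1000 trees, Gini impurity, balanced class
#' weights, a stratified 80/20 train/test split, 8-fold stratified
#' cross-validation on the training part, and an out-of-bag score.
#'
#' @param n_trees Number of trees (default 1000).
#' @param test_fraction Held-out fraction (default 0.2, stratified).
#' @param cv_folds Stratified CV folds on the training part (default 8).
#' @param missing_strategy Imputation for any remaining missing cells.
#' @param seed RNG seed for the split, CV folds, and forests.
#' @return List of class `rf_config`.
#' @export
rf_config <- function(n_trees = 1000, test_fraction = 0.2, cv_folds = 8,
                      missing_strategy = c("zero", "sentinel"),
                      seed = 1L) {
  stopifnot(n_trees >= 1, test_fraction > 0, test_fraction < 1,
            cv_folds >= 2)
  structure(
    list(n_trees = n_trees, test_fraction = test_fraction,
         cv_folds = cv_folds,
         missing_strategy = match.arg(missing_strategy), seed = seed),
    class = "rf_config"
  )
}

balanced_class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

stratified_split <- function(y, test_fraction) {
  test_idx <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- round(length(idx) * test_fraction)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  sort(test_idx)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_ranger <- function(x, y, cfg, seed) {
  ranger::ranger(
    x = x, y = y,
    num.trees = cfg$n_trees,
    splitrule = "gini",
    importance = "impurity",
    class.weights = balanced_class_weights(y)[levels(y)],
    oob.error = TRUE,
    seed = seed,
    num.threads = 1
  )
}

#' Train the flux random-forest classifier
#'
#' Imputes the feature matrix, performs a seeded stratified 80/20 split,
#' fits a 1000-tree Gini forest with balanced class weights on the
#' training part, evaluates accuracy / per-class precision, recall and
#' F1 / confusion matrix on the held-out part, runs stratified k-fold
#' cross-validation within the training part (refitting the forest per
#' fold), and records the out-of-bag score of the final forest. Fully
#' reproducible from `cfg$seed`.
#'
#' @param fm A `feature_matrix` (imputed or not).
#' @param cfg An [rf_config()].
#' @return A `flux_rf` fit: the forest, the report, split indices, and
#'   feature metadata.
#' @export
train_rf <- function(fm, cfg = rf_config()) {
  fm <- impute_missing(fm, cfg$missing_strategy)
  # canonical lexicographic feature order, so results do not depend on
  # the order in which context models were assembled
  ord <- order(fm$feature_ids)
  fm$feature_ids <- fm$feature_ids[ord]
  fm$values <- fm$values[, ord, drop = FALSE]
  y <- factor(fm$samples$label)
  if (nlevels(y) < 2L) {
    stop("need both classes present to train a classifier", call. = FALSE)
  }
  x <- as.data.frame(fm$values)
  colnames(x) <- make.names(fm$feature_ids)

  set.seed(cfg$seed)
  test_idx <- stratified_split(y, cfg$test_fraction)
  train_idx <- setdiff(seq_along(y), test_idx)

  forest <- fit_ranger(x[train_idx, , drop = FALSE], y[train_idx],
                       cfg, seed = cfg$seed)
  pred <- stats::predict(forest, x[test_idx, , drop = FALSE])$predictions
  truth <- y[test_idx]
  cm <- table(truth = truth, predicted = factor(pred, levels = levels(y)))
  acc <- sum(diag(cm)) / sum(cm)
  per_class <- lapply(levels(y), function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else NA_real_
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else {
      NA_real_
    }
    tibble::tibble(class = cl, precision = prec, recall = rec, f1 = f1,
                   n_test = sum(cm[cl, ]))
  })

  y_train <- y[train_idx]
  folds <- stratified_folds(y_train, cfg$cv_folds)
  cv_scores <- vapply(seq_len(cfg$cv_folds), function(k) {
    tr <- train_idx[folds != k]
    va <- train_idx[folds == k]
    if (length(va) == 0L) return(NA_real_)
    f <- fit_ranger(x[tr, , drop = FALSE], y[tr], cfg,
                    seed = cfg$seed + k)
    p <- stats::predict(f, x[va, , drop = FALSE])$predictions
    mean(p == y[va])
  }, numeric(1))

  mis <- fm$samples[test_idx, ][pred != truth, , drop = FALSE]

  structure(
    list(
      forest = forest,
      feature_ids = fm$feature_ids,
      classes = levels(y),
      report = list(
        accuracy = acc,
        per_class = dplyr::bind_rows(per_class),
        confusion = cm,
        cv_scores = cv_scores,
        cv_mean = mean(cv_scores, na.rm = TRUE),
        cv_sd = stats::sd(cv_scores[!is.na(cv_scores)]),
        oob_score = 1 - forest$prediction.error,
        misclassified = mis
      ),
      train_idx = train_idx,
      test_idx = test_idx,
      samples = fm$samples,
      config = cfg
    ),
    class = "flux_rf"
  )
}

#' @export
print.flux_rf <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<flux_rf> %d features; test accuracy %.4f, OOB %.4f, CV %.4f +/- %.4f\n",
    length(x$feature_ids), r$accuracy, r$oob_score, r$cv_mean, r$cv_sd
  ))
  print(r$confusion)
  invisible(x)
}

#' Per-class test metrics of a flux random forest
#'
#' @param x A `flux_rf`.
#' @param ... Unused.
#' @return Tibble: class, precision, recall, f1, n_test.
#' @export
tidy.flux_rf <- function(x, ...) x$report$per_class

#' One-row performance summary of a flux random forest
#'
#' @param x A `flux_rf`.
#' @param ... Unused.
#' @export
glance.flux_rf <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    accuracy = r$accuracy,
    oob_score = r$oob_score,
    cv_mean = r$cv_mean,
    cv_sd = r$cv_sd,
    cv_min = min(r$cv_scores, na.rm = TRUE),
    cv_max = max(r$cv_scores, na.rm = TRUE),
    n_features = length(x$feature_ids),
    n_train = length(x$train_idx),
    n_test = length(x$test_idx)
  )
}
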