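# Classification / ranking layer: stratified five-fold cross-validation over
# interchangeable model families, exhaustive feature-subset search, final
# random-forest classifier (binary ID) and regression ranker (real score).
# Model fits go through randomForest / e1071 / nnet / stats / xgboost; the CV
# harness, metrics and subset search are the package's own.

CLASSIFIER_FAMILIES <- c("rf_classifier", "svm_classifier", "gnb_classifier",
                         "mlp_classifier")
REGRESSOR_FAMILIES <- c("linear_regression", "logistic_regression",
                        "rf_regression", "gb_regression")

#' Model specification
#'
#' @param family One of `rf_classifier`, `svm_classifier`, `gnb_classifier`,
#'   `mlp_classifier`, `linear_regression`, `logistic_regression`,
#'   `rf_regression`, `gb_regression`.
#' @param features Non-empty character vector of feature column names.
#' @param hyperparameters Named list (e.g. `ntree`, `size`, `nrounds`).
#' @param seed Integer seed controlling fold assignment and stochastic fits.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family, features, hyperparameters = list(),
                       seed = 1L) {
  family <- match.arg(family, c(CLASSIFIER_FAMILIES, REGRESSOR_FAMILIES))
  if (!length(features)) stop("features must be non-empty", call. = FALSE)
  structure(list(family = family, features = as.character(features),
                 hyperparameters = hyperparameters, seed = as.integer(seed)),
            class = "model_spec")
}

is_classifier <- function(family) family %in% CLASSIFIER_FAMILIES

# --- metrics ---------------------------------------------------------------

#' Confusion-matrix classification metrics
#'
#' Accuracy, positive predictive value and true positive rate from binary
#' predictions against binary labels. PPV is `NA` when nothing was predicted
#' positive.
#'
#' @param pred,truth Vectors of 0/1.
#' @return Named list `accuracy`, `ppv`, `tpr`.
#' @export
classification_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  list(
    accuracy = (tp + tn) / length(truth),
    ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    tpr = if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  )
}

#' Area under the ROC curve
#'
#' Sweeps a decision threshold over every distinct score, plots true against
#' false positive rates and integrates by the trapezoidal rule; ties are
#' handled so the result equals the mid-rank Mann-Whitney statistic.
#'
#' @param score Numeric scores (higher = more positive).
#' @param truth Binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0) {
    stop("AUC undefined: need both classes present", call. = FALSE)
  }
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(score >= t & truth == 1) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & truth == 0) / nneg,
                numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# --- folds -----------------------------------------------------------------

#' Stratified k-fold assignment
#'
#' Shuffles each class under the given seed and deals indices round-robin, so
#' fold sizes differ by at most one and each fold preserves the class ratio
#' to within one sample.
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  folds <- integer(length(labels))
  set.seed(seed)
  offset <- 0L  # rotate the deal between classes so remainders spread out
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  folds
}

# --- model fitting ---------------------------------------------------------

.scale_fit <- function(x) {
  mu <- vapply(x, mean, numeric(1))
  sd <- vapply(x, stats::sd, numeric(1))
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}
.scale_apply <- function(x, sc) {
  as.data.frame(sweep(sweep(as.matrix(x), 2L, sc$mu), 2L, sc$sd, "/"))
}

fit_model <- function(spec, x, y) {
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  switch(spec$family,
    rf_classifier = list(
      fit = randomForest::randomForest(
        x, factor(y, levels = c(0, 1)),
        ntree = if (is.null(hp$ntree)) 100L else hp$ntree)),
    svm_classifier = list(
      fit = e1071::svm(x, factor(y, levels = c(0, 1)))),
    gnb_classifier = list(
      fit = e1071::naiveBayes(x, factor(y, levels = c(0, 1)))),
    mlp_classifier = {
      sc <- .scale_fit(x)
      fit <- nnet::nnet(as.matrix(.scale_apply(x, sc)), y,
                        size = if (is.null(hp$size)) 8L else hp$size,
                        decay = if (is.null(hp$decay)) 1e-3 else hp$decay,
                        maxit = if (is.null(hp$maxit)) 300L else hp$maxit,
                        entropy = TRUE, trace = FALSE)
      list(fit = fit, scale = sc)
    },
    linear_regression = {
      d <- cbind(x, .y = y)
      list(fit = stats::lm(.y ~ ., data = d))
    },
    logistic_regression = {
      d <- cbind(x, .y = y)
      list(fit = suppressWarnings(
        stats::glm(.y ~ ., data = d, family = stats::binomial())))
    },
    rf_regression = list(
      # regression on the binary label is deliberate (ROC over its
      # continuous predictions), so silence the five-unique-values warning
      fit = suppressWarnings(randomForest::randomForest(
        x, as.numeric(y),
        ntree = if (is.null(hp$ntree)) 100L else hp$ntree))),
    gb_regression = list(
      fit = xgboost::xgboost(
        x = as.matrix(x), y = as.numeric(y),
        nrounds = if (is.null(hp$nrounds)) 50L else hp$nrounds,
        max_depth = if (is.null(hp$max_depth)) 3L else hp$max_depth,
        tree_method = "exact",  # mid-gap splits matter on small tables
        objective = "reg:squarederror", verbosity = 0, nthreads = 1L))
  )
}

predict_model <- function(spec, model, x) {
  switch(spec$family,
    rf_classifier = ,
    svm_classifier = ,
    gnb_classifier =
      as.integer(as.character(stats::predict(model$fit, x))),
    mlp_classifier =
      as.integer(stats::predict(model$fit,
                                as.matrix(.scale_apply(x, model$scale)),
                                type = "raw") > 0.5),
    linear_regression = unname(stats::predict(model$fit, newdata = x)),
    logistic_regression =
      unname(suppressWarnings(
        stats::predict(model$fit, newdata = x, type = "response"))),
    rf_regression = unname(stats::predict(model$fit, x)),
    gb_regression = unname(stats::predict(model$fit, as.matrix(x)))
  )
}

# --- cross-validation ------------------------------------------------------

#' Five-fold cross-validation of one model specification
#'
#' Stratified folds from the spec's seed; each fold is held out once while
#' the remaining folds train the model. Classifier families report per-fold
#' and mean accuracy, PPV and TPR (a fold with no positive predictions
#' contributes no PPV, with a warning); regression families report per-fold
#' and mean AUC of the ROC of their continuous predictions against the
#' binary labels.
#'
#' @param data Data.frame with feature columns and a 0/1 `label` column.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5).
#' @return A list of class `cv_report` with `fold_metrics` (data.frame),
#'   `mean` (named list), `folds` (assignment vector), `spec`.
#' @export
five_fold_cv <- function(data, spec, k = 5L) {
  if (!"label" %in% names(data)) stop("data needs a 'label' column",
                                      call. = FALSE)
  y <- data$label
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (min(table(y)) < 2L * k) {
    stop("need at least ", 2L * k, " rows per class for ", k, "-fold CV",
         call. = FALSE)
  }
  missing <- setdiff(spec$features, names(data))
  if (length(missing)) {
    stop("feature(s) absent from data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- data[, spec$features, drop = FALSE]
  if (anyNA(x)) stop("NA feature values in training data", call. = FALSE)

  folds <- stratified_folds(y, k = k, seed = spec$seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    model <- fit_model(spec, x[tr, , drop = FALSE], y[tr])
    pred <- predict_model(spec, model, x[te, , drop = FALSE])
    if (is_classifier(spec$family)) {
      m <- classification_metrics(pred, y[te])
      rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy, ppv = m$ppv,
                              tpr = m$tpr)
    } else {
      rows[[f]] <- data.frame(fold = f, auc = auc_roc(pred, y[te]))
    }
  }
  fold_metrics <- do.call(rbind, rows)
  if (is_classifier(spec$family)) {
    if (anyNA(fold_metrics$ppv)) {
      warning("PPV undefined (no positive predictions) in ",
              sum(is.na(fold_metrics$ppv)),
              " fold(s); excluded from the fold mean", call. = FALSE)
    }
    mean_metrics <- list(accuracy = mean(fold_metrics$accuracy),
                         ppv = mean(fold_metrics$ppv, na.rm = TRUE),
                         tpr = mean(fold_metrics$tpr, na.rm = TRUE))
  } else {
    mean_metrics <- list(auc = mean(fold_metrics$auc))
  }
  structure(list(fold_metrics = fold_metrics, mean = mean_metrics,
                 folds = folds, spec = spec),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$spec$family, "on",
      paste(x$spec$features, collapse = "+"), "\n")
  for (nm in names(x$mean)) cat(" ", nm, "=", round(x$mean[[nm]], 4), "\n")
  invisible(x)
}

#' Exhaustive feature-combination search
#'
#' Runs [five_fold_cv()] for every non-empty subset of the candidate features
#' (or an explicit list of subsets) and selects the best specification:
#' highest mean accuracy for classifier families, highest mean AUC for
#' regression families, ties broken by fewer features then lexicographic
#' feature names.
#'
#' @param data Training data.frame with a `label` column.
#' @param family Model family name.
#' @param candidate_features Feature pool (7 features give 127 subsets).
#' @param seed CV seed shared by all subsets.
#' @param subsets Optional list of character vectors to restrict the search.
#' @param hyperparameters Passed to every [model_spec()].
#' @return List with `results` (one row per subset: features string, metric
#'   columns) and `best` (the winning `model_spec`).
#' @export
feature_combination_search <- function(data, family, candidate_features,
                                       seed = 1L, subsets = NULL,
                                       hyperparameters = list()) {
  if (is.null(subsets)) {
    n <- length(candidate_features)
    subsets <- unlist(lapply(seq_len(n), function(k) {
      asplit(utils::combn(sort(candidate_features), k), 2L)
    }), recursive = FALSE)
    subsets <- lapply(subsets, as.character)
  }
  reports <- lapply(subsets, function(fs) {
    five_fold_cv(data, model_spec(family, fs, hyperparameters, seed))
  })
  metric <- if (is_classifier(family)) "accuracy" else "auc"
  results <- data.frame(
    features = vapply(subsets, paste, character(1), collapse = "+"),
    n_features = lengths(subsets),
    stringsAsFactors = FALSE
  )
  for (nm in names(reports[[1]]$mean)) {
    results[[nm]] <- vapply(reports, function(r) r$mean[[nm]], numeric(1))
  }
  ord <- order(-results[[metric]], results$n_features, results$features)
  best_fs <- subsets[[ord[1]]]
  list(results = results[ord, , drop = FALSE],
       best = model_spec(family, best_fs, hyperparameters, seed),
       reports = reports[ord])
}

#' Train the final classifier and ranker
#'
#' Fits the classifier spec (binary ID model) and the ranker spec
#' (real-valued scoring model) on the full training table and extracts the
#' classifier's impurity-based feature importances, normalised to sum to 1
#' when available.
#'
#' @param data Training data.frame with a `label` column.
#' @param classifier_spec,ranker_spec [model_spec()]s; the defaults mirror
#'   the pipeline's random-forest classifier and linear-regression ranker.
#' @return List of class `epivax_models` with `classifier`, `ranker`,
#'   `importance` (named numeric or `NULL`), and both specs.
#' @export
train_final_models <- function(data, classifier_spec, ranker_spec) {
  stopifnot(is_classifier(classifier_spec$family),
            !is_classifier(ranker_spec$family))
  xc <- data[, classifier_spec$features, drop = FALSE]
  xr <- data[, ranker_spec$features, drop = FALSE]
  classifier <- fit_model(classifier_spec, xc, data$label)
  ranker <- fit_model(ranker_spec, xr, data$label)
  importance <- NULL
  if (classifier_spec$family == "rf_classifier") {
    imp <- randomForest::importance(classifier$fit)[, 1]
    importance <- imp / sum(imp)
  }
  structure(list(classifier = classifier, ranker = ranker,
                 importance = importance,
                 classifier_spec = classifier_spec,
                 ranker_spec = ranker_spec),
            class = "epivax_models")
}

#' Classify, score and sort EHLA pairs
#'
#' Assigns each pair a binary ID from the classifier and a real score from
#' the ranker, then sorts by ID (descending), score (descending) and
#' (epitope sequence, allele name) ascending as a deterministic tie-break.
#' Warns when more than half of the scores sit within 1e-6 of 0 or 1 - the
#' saturation failure mode of logistic rankers, whose scores are then too
#' close to compare.
#'
#' @param pairs Feature-populated pair data.frame ([collect_features()]).
#' @param models An `epivax_models` object.
#' @return `pairs` with `id_label` and `score` columns, sorted.
#' @export
classify_and_rank <- function(pairs, models) {
  if (!nrow(pairs)) {
    pairs$id_label <- integer(0); pairs$score <- numeric(0)
    return(pairs)
  }
  xc <- pairs[, models$classifier_spec$features, drop = FALSE]
  xr <- pairs[, models$ranker_spec$features, drop = FALSE]
  pairs$id_label <- predict_model(models$classifier_spec, models$classifier,
                                  xc)
  pairs$score <- predict_model(models$ranker_spec, models$ranker, xr)
  saturated <- abs(pairs$score) < 1e-6 | abs(pairs$score - 1) < 1e-6
  if (mean(saturated) > 0.5) {
    warning("more than 50% of ranker scores are within 1e-6 of 0 or 1; ",
            "scores are too close to compare - consider a non-saturating ",
            "ranker family", call. = FALSE)
  }
  ord <- order(-pairs$id_label, -pairs$score,
               pairs$mutant_sequence, pairs$allele)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Screen a plain epitope list for positive class-I pairs
#'
#' Expands each peptide against the class-I panel, populates the
#' classifier's features (the wild-type window of a bare peptide is taken as
#' the peptide itself, so the rank ratio is 1) and reports, per epitope,
#' whether any allele yields a positive ID, plus the aggregate fraction.
#'
#' @param epitopes Non-empty character vector of peptides.
#' @param panel Class-I allele panel.
#' @param models An `epivax_models` object.
#' @param registry Predictor registry from [build_registry()].
#' @return List with `per_epitope` (data.frame `epitope`, `any_positive`) and
#'   `fraction` (scalar).
#' @export
screen_epitope_list <- function(epitopes, panel, models, registry) {
  if (!length(epitopes)) {
    stop("cannot screen an empty epitope list: fraction undefined",
         call. = FALSE)
  }
  feats <- union(models$classifier_spec$features,
                 models$ranker_spec$features)
  pairs <- data.frame(
    mutation = NA_character_,
    mutant_sequence = rep(epitopes, each = nrow(panel)),
    wildtype_sequence = rep(epitopes, each = nrow(panel)),
    start = NA_integer_, length = nchar(rep(epitopes, each = nrow(panel))),
    mutation_offset = NA_integer_, mhc_class = "I",
    allele = rep(panel$allele, times = length(epitopes)),
    locus = rep(panel$locus, times = length(epitopes)),
    stringsAsFactors = FALSE
  )
  pairs <- collect_features(pairs, registry, feats)
  pairs <- classify_and_rank(pairs, models)
  any_pos <- tapply(pairs$id_label, pairs$mutant_sequence, function(v) {
    any(v == 1L)
  })
  per <- data.frame(epitope = epitopes,
                    any_positive = unname(any_pos[epitopes]))
  list(per_epitope = per, fraction = mean(per$any_positive))
}
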