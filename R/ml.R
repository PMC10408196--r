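#' Model configuration for the response classifier
#'
#' @param n_rfe_features features retained by recursive feature elimination
#'   (default 30).
#' @param n_repeats random train/test splits (default 100).
#' @param train_fraction training share per split (default 0.8, stratified).
#' @param grid data.frame over the boosting hyperparameters
#'   `interaction_depth`, `n_trees`, `shrinkage`, `min_node_size` (defaults
#'   span each axis at desk scale).
#' @param resampling `"auto"` (LOOCV up to `loocv_max` training samples,
#'   k-fold beyond), `"loocv"`, or `"kfold"`.
#' @param k_folds folds for the k-fold fallback (default 5).
#' @param loocv_max largest training size still tuned by LOOCV (default 60).
#' @param rfe_mode `"halve_step"` (halve until <= 2x target, then step by 1)
#'   or `"halve"` (halve straight to the target; used for large repeated
#'   runs).
#' @param threshold probability operating point for sensitivity/specificity
#'   (default 0.5).
#' @param seed master seed; all split/tuning randomness derives from it.
#' @return a `model_config` list.
#' @export
model_config <- function(n_rfe_features = 30, n_repeats = 100,
                         train_fraction = 0.8,
                         grid = expand.grid(interaction_depth = c(1, 2, 3),
                                            n_trees = c(50, 100, 150),
                                            shrinkage = c(0.01, 0.1),
                                            min_node_size = c(5, 10)),
                         resampling = c("auto", "loocv", "kfold"),
                         k_folds = 5, loocv_max = 60,
                         rfe_mode = c("halve_step", "halve"),
                         threshold = 0.5, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_rfe_features >= 1)
  structure(list(n_rfe_features = n_rfe_features, n_repeats = n_repeats,
                 train_fraction = train_fraction, grid = grid,
                 resampling = match.arg(resampling), k_folds = k_folds,
                 loocv_max = loocv_max, rfe_mode = match.arg(rfe_mode),
                 threshold = threshold, seed = seed),
            class = "model_config")
}

as_binary_labels <- function(labels, positive = "responder",
                             negative = "non_responder") {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c(positive, negative))
  if (length(bad))
    stop("labels other than the two classes present (exclude upstream): ",
         paste(bad, collapse = ", "))
  factor(labels, levels = c(negative, positive))
}

#' Preprocess a feature matrix for model training
#'
#' Removes near-zero-variance columns (caret convention: frequency ratio of
#' the two most common values > 95/5 and unique-value fraction < 10%), then
#' z-scores each column. When `stats` from a training fit is supplied, its
#' column set, means and SDs are reused verbatim — test data are never
#' re-centered on themselves.
#'
#' @param x samples x features numeric matrix.
#' @param stats result of a previous call (training statistics), or NULL to
#'   fit on `x`.
#' @return the design matrix with attribute `"stats"` (`keep`, `center`,
#'   `scale`).
#' @export
preprocess <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    nzv <- caret::nearZeroVar(x, freqCut = 95 / 5, uniqueCut = 10)
    keep <- setdiff(colnames(x), colnames(x)[nzv])
    # nearZeroVar misses exactly-constant doubles only in pathological cases;
    # drop zero-sd columns regardless since they cannot be scaled
    keep <- keep[apply(x[, keep, drop = FALSE], 2, stats::sd) > 0]
    if (length(keep) == 0) stop("all features removed by the variance filter")
    ctr <- colMeans(x[, keep, drop = FALSE])
    scl <- apply(x[, keep, drop = FALSE], 2, stats::sd)
    stats <- list(keep = keep, center = ctr, scale = scl)
  }
  miss <- setdiff(stats$keep, colnames(x))
  if (length(miss)) {
    x <- cbind(x, matrix(0, nrow(x), length(miss),
                         dimnames = list(rownames(x), miss)))
  }
  out <- sweep(sweep(x[, stats$keep, drop = FALSE], 2, stats$center),
               2, stats$scale, "/")
  attr(out, "stats") <- stats
  out
}

xgb_params <- function(depth, eta, min_node) {
  # min_node is a minimum observation count per terminal node; xgboost's
  # min_child_weight is a hessian sum, ~0.25 per observation under the
  # logistic loss, so rescale to keep the grid axis in observation units
  list(objective = "binary:logistic", max_depth = as.integer(depth),
       eta = eta, min_child_weight = 0.25 * min_node, nthread = 1)
}

fit_gbm <- function(x, y01, depth = 2, n_trees = 100, eta = 0.1,
                    min_node = 5) {
  dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y01)
  xgboost::xgb.train(params = xgb_params(depth, eta, min_node), data = dm,
                     nrounds = as.integer(n_trees), verbose = 0)
}

predict_gbm <- function(bst, x) {
  as.numeric(stats::predict(bst, xgboost::xgb.DMatrix(as.matrix(x))))
}

gbm_importance <- function(bst, feature_names) {
  imp <- xgboost::xgb.importance(model = bst)
  out <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  out
}

cv_fold_ids <- function(y, k) {
  ids <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    ids[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  ids
}

cv_auc <- function(x, y, depth, n_trees, eta, min_node, folds) {
  scores <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    bst <- fit_gbm(x[tr, , drop = FALSE], as.integer(y[tr]) - 1L,
                   depth, n_trees, eta, min_node)
    scores[!tr] <- predict_gbm(bst, x[!tr, , drop = FALSE])
  }
  rank_auc(scores[!is.na(scores)], (y == levels(y)[2])[!is.na(scores)])
}

#' Recursive feature elimination with a boosting base learner
#'
#' Iteratively fits the gradient-boosting learner, ranks features by gain
#' importance, and removes the least important: subset sizes are halved
#' until at most `2 * n_features` remain, then reduced one feature at a time
#' (`rfe_mode = "halve_step"`); `"halve"` goes straight down by halving. The
#' cross-validated AUC of each visited subset size is recorded and the
#' best-scoring subset of size `n_features` is returned.
#'
#' @param x samples x features design matrix (already preprocessed).
#' @param y binary factor (negative level first).
#' @param n_features target subset size.
#' @param config a [model_config()] (grid point for the base learner is its
#'   first row).
#' @param seed RNG seed.
#' @return list with `selected` (feature names), `ranking` (full elimination
#'   order, most important last), `path` (data.frame of size and CV AUC).
#' @export
rfe_select <- function(x, y, n_features = 30, config = model_config(),
                       seed = NULL) {
  stopifnot(ncol(x) >= n_features)
  gp <- config$grid[1, ]
  with_seed(seed, {
    current <- colnames(x)
    eliminated <- character(0)
    path <- list()
    folds <- cv_fold_ids(y, min(config$k_folds, min(table(y))))
    repeat {
      xs <- x[, current, drop = FALSE]
      bst <- fit_gbm(xs, as.integer(y) - 1L, gp$interaction_depth,
                     gp$n_trees, gp$shrinkage, gp$min_node_size)
      imp <- sort(gbm_importance(bst, current), decreasing = TRUE)
      path[[length(path) + 1L]] <- data.frame(
        size = length(current),
        cv_auc = cv_auc(xs, y, gp$interaction_depth, gp$n_trees,
                        gp$shrinkage, gp$min_node_size, folds))
      if (length(current) <= n_features) break
      target <- if (config$rfe_mode == "halve" ||
                    length(current) > 2 * n_features)
        max(n_features, floor(length(current) / 2))
      else length(current) - 1L
      drop_n <- length(current) - target
      dropped <- names(utils::tail(imp, drop_n))
      eliminated <- c(dropped, eliminated)
      current <- names(utils::head(imp, target))
    }
    sel_order <- names(sort(gbm_importance(
      fit_gbm(x[, current, drop = FALSE], as.integer(y) - 1L,
              gp$interaction_depth, gp$n_trees, gp$shrinkage,
              gp$min_node_size), current), decreasing = TRUE))
    list(selected = current, ranking = c(sel_order, eliminated),
         path = do.call(rbind, path))
  })
}

#' Train a grid-tuned gradient-boosting classifier
#'
#' Every grid point is scored by cross-validated AUC — leave-one-out when the
#' training set is small enough (`resampling = "auto"`), k-fold otherwise —
#' and the best point is refit on the full training set.
#'
#' @param x samples x features design matrix.
#' @param y binary factor (negative level first), >= 10 samples.
#' @param config a [model_config()].
#' @param seed RNG seed for fold assignment.
#' @return list with `booster`, `best` (grid row), `cv_auc`, `grid_results`.
#' @export
train_classifier <- function(x, y, config = model_config(), seed = NULL) {
  if (length(y) < 10) stop("need at least 10 training samples")
  if (nlevels(droplevels(y)) < 2) stop("single-class training set")
  with_seed(seed, {
    n <- length(y)
    use_loo <- config$resampling == "loocv" ||
      (config$resampling == "auto" && n <= config$loocv_max)
    folds <- if (use_loo) seq_len(n)
             else cv_fold_ids(y, min(config$k_folds, min(table(y))))
    res <- config$grid
    res$cv_auc <- vapply(seq_len(nrow(res)), function(i)
      cv_auc(x, y, res$interaction_depth[i], res$n_trees[i],
             res$shrinkage[i], res$min_node_size[i], folds), numeric(1))
    best <- res[which.max(res$cv_auc), ]
    bst <- fit_gbm(x, as.integer(y) - 1L, best$interaction_depth,
                   best$n_trees, best$shrinkage, best$min_node_size)
    list(booster = bst, best = best, cv_auc = best$cv_auc, grid_results = res)
  })
}

eval_metrics <- function(scores, y, threshold) {
  pos <- y == levels(y)[2]
  pred_pos <- scores >= threshold
  tp <- sum(pred_pos & pos); fn <- sum(!pred_pos & pos)
  tn <- sum(!pred_pos & !pos); fp <- sum(pred_pos & !pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(spec)) warning("no negatives present: specificity undefined")
  if (is.na(sens)) warning("no positives present: sensitivity undefined")
  list(auc = rank_auc(scores, pos), sensitivity = sens, specificity = spec,
       confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                          dimnames = list(predicted = c("neg", "pos"),
                                          actual = c("neg", "pos"))))
}

#' Repeated stratified train/test evaluation
#'
#' `n_repeats` stratified splits; per split: near-zero-variance filter and
#' scaling fit on the training part, recursive feature elimination, grid
#' tuning, final fit, and held-out evaluation (AUC, sensitivity and
#' specificity at the configured threshold). Reports per-split metrics,
#' mean +/- SD, and per-feature selection frequency.
#'
#' @param x samples x features matrix (rows named by sample, columns by
#'   feature), e.g. `t(table$values)`.
#' @param labels responder / non_responder per sample.
#' @param config a [model_config()].
#' @return a `model_report`: `splits` (per-split metrics), `mean_auc`,
#'   `sd_auc`, `mean_sensitivity`, `mean_specificity`,
#'   `selection_frequency`.
#' @export
repeated_split_eval <- function(x, labels, config = model_config()) {
  y <- as_binary_labels(labels)
  if (any(table(y) < 5)) stop("each class needs >= 5 samples for stratified splits")
  x <- as.matrix(x)
  splits <- vector("list", config$n_repeats)
  selected <- list()
  for (r in seq_len(config$n_repeats)) {
    seed_r <- derive_seed(config$seed, paste0("split", r))
    idx_tr <- with_seed(seed_r, {
      as.vector(caret::createDataPartition(y, p = config$train_fraction,
                                           list = FALSE))
    })
    xtr <- preprocess(x[idx_tr, , drop = FALSE])
    st <- attr(xtr, "stats")
    xte <- preprocess(x[-idx_tr, , drop = FALSE], stats = st)
    ytr <- y[idx_tr]; yte <- y[-idx_tr]
    nf <- min(config$n_rfe_features, ncol(xtr))
    rfe <- rfe_select(xtr, ytr, n_features = nf, config = config,
                      seed = derive_seed(seed_r, "rfe"))
    fit <- train_classifier(xtr[, rfe$selected, drop = FALSE], ytr, config,
                            seed = derive_seed(seed_r, "tune"))
    sc <- predict_gbm(fit$booster, xte[, rfe$selected, drop = FALSE])
    met <- suppressWarnings(eval_metrics(sc, yte, config$threshold))
    selected[[r]] <- rfe$selected
    splits[[r]] <- data.frame(split = r, auc = met$auc,
                              sensitivity = met$sensitivity,
                              specificity = met$specificity)
  }
  sp <- do.call(rbind, splits)
  freq_tab <- table(unlist(selected)) / config$n_repeats
  freq <- stats::setNames(rep(0, ncol(x)), colnames(x))
  freq[names(freq_tab)] <- as.numeric(freq_tab)
  structure(list(splits = sp, mean_auc = mean(sp$auc, na.rm = TRUE),
                 sd_auc = stats::sd(sp$auc, na.rm = TRUE),
                 mean_sensitivity = mean(sp$sensitivity, na.rm = TRUE),
                 mean_specificity = mean(sp$specificity, na.rm = TRUE),
                 selection_frequency = sort(freq, decreasing = TRUE),
                 config = config),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report: AUC %.3f +/- %.3f over %d splits\n",
              x$mean_auc, x$sd_auc, nrow(x$splits)))
  cat(sprintf("  sensitivity %.3f, specificity %.3f (threshold %.2f)\n",
              x$mean_sensitivity, x$mean_specificity, x$config$threshold))
  invisible(x)
}

#' Fit the final response classifier on all data
#'
#' Re-runs feature selection and tuning on the full dataset (the repeated
#' splits above estimate generalization; this model is the deployable one).
#'
#' @param x samples x features matrix.
#' @param labels responder / non_responder.
#' @param config a [model_config()].
#' @return a `response_model`: `booster`, `features` (selected ids),
#'   `preprocess_stats`, `best` grid row, `importance`, `levels`,
#'   `threshold`.
#' @export
finalize_model <- function(x, labels, config = model_config()) {
  y <- as_binary_labels(labels)
  x <- as.matrix(x)
  xd <- preprocess(x)
  st <- attr(xd, "stats")
  nf <- min(config$n_rfe_features, ncol(xd))
  rfe <- rfe_select(xd, y, n_features = nf, config = config,
                    seed = derive_seed(config$seed, "final_rfe"))
  fit <- train_classifier(xd[, rfe$selected, drop = FALSE], y, config,
                          seed = derive_seed(config$seed, "final_tune"))
  imp <- gbm_importance(fit$booster, rfe$selected)
  structure(list(booster = fit$booster, features = rfe$selected,
                 preprocess_stats = st, best = fit$best,
                 importance = sort(imp, decreasing = TRUE),
                 levels = levels(y), threshold = config$threshold),
            class = "response_model")
}

#' Predict response probabilities with a fitted model
#' @param object a `response_model`.
#' @param newdata samples x features matrix (full feature set; columns are
#'   matched by name, missing ones imputed as 0 before scaling).
#' @param ... unused.
#' @return numeric vector of responder probabilities.
#' @export
predict.response_model <- function(object, newdata, ...) {
  xd <- preprocess(as.matrix(newdata), stats = object$preprocess_stats)
  predict_gbm(object$booster, xd[, object$features, drop = FALSE])
}

#' Evaluate a fitted model on an external cohort
#'
#' External features are joined to the model's feature set by terminal clade
#' name; features absent from the external table are imputed as 0 before the
#' training scaling is applied.
#'
#' @param model a [finalize_model()] result.
#' @param external_x samples x features matrix of the external cohort
#'   (columns named by lineage or terminal clade).
#' @param external_labels responder / non_responder.
#' @return list with `auc`, `sensitivity`, `specificity`, `confusion`,
#'   `scores`.
#' @export
evaluate_external <- function(model, external_x, external_labels) {
  y <- as_binary_labels(external_labels)
  external_x <- as.matrix(external_x)
  train_feats <- model$preprocess_stats$keep
  term_train <- terminal_clade(train_feats)
  term_ext <- terminal_clade(colnames(external_x))
  hit <- match(term_train, term_ext)
  if (all(is.na(hit))) stop("no overlapping features with the external cohort")
  xd <- matrix(0, nrow(external_x), length(train_feats),
               dimnames = list(rownames(external_x), train_feats))
  ok <- !is.na(hit)
  xd[, ok] <- external_x[, hit[ok], drop = FALSE]
  sc <- predict.response_model(model, xd)
  met <- eval_metrics(sc, y, model$threshold)
  met$scores <- sc
  met
}
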