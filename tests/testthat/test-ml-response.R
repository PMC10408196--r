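# compact configuration for fast unit runs
fast_config <- function(...) {
  model_config(grid = expand.grid(interaction_depth = c(1, 3), n_trees = 60,
                                  shrinkage = 0.1, min_node_size = 5),
               resampling = "kfold", rfe_mode = "halve", ...)
}

# two gaussian clouds with informative leading features
toy_data <- function(n = 60, p = 40, n_info = 4, delta = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("non_responder", "responder"), each = n / 2),
                levels = c("non_responder", "responder"))
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n),
                                paste0("k__B|g__G|s__sp", 1:p)))
    x[y == "responder", seq_len(n_info)] <-
      x[y == "responder", seq_len(n_info)] + delta
    list(x = x, y = y)
  })
}

test_that("preprocessing filters, scales, and never leaks test statistics", {
  set.seed(81)
  x <- cbind(matrix(rnorm(200), 50, 4), const = 1,
             rare = c(rep(0, 49), 1))
  colnames(x)[1:4] <- paste0("f", 1:4)
  d <- preprocess(x)
  expect_false("const" %in% colnames(d))
  expect_false("rare" %in% colnames(d))   # near-zero variance
  expect_equal(unname(colMeans(d)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(d, 2, sd)), rep(1, 4), tolerance = 1e-10)
  # test-set scaling reuses the training statistics
  shifted <- x + 5
  d2 <- preprocess(shifted, stats = attr(d, "stats"))
  expect_equal(unname(colMeans(d2)), unname(5 / attr(d, "stats")$scale),
               tolerance = 1e-8)
  expect_gt(min(colMeans(d2)), 1)  # clearly not re-centered to zero
  expect_error(preprocess(matrix(1, 10, 3,
                                 dimnames = list(NULL, letters[1:3]))),
               "all features removed")
})

test_that("rfe keeps planted informative features and the identity case", {
  td <- toy_data(n = 80, p = 60, n_info = 5, delta = 2.5, seed = 3)
  d <- preprocess(td$x)
  sel <- rfe_select(d, td$y, n_features = 15, config = fast_config(),
                    seed = 11)
  expect_length(sel$selected, 15)
  expect_true(all(paste0("k__B|g__G|s__sp", 1:5) %in% sel$selected))
  # n_features = everything is the identity selection
  sel_all <- rfe_select(d, td$y, n_features = ncol(d),
                        config = fast_config(), seed = 11)
  expect_setequal(sel_all$selected, colnames(d))
  expect_error(rfe_select(d, td$y, n_features = ncol(d) + 1), "ncol")
})

test_that("tuned boosting separates separable data and not permuted labels", {
  td <- toy_data(n = 60, p = 10, n_info = 4, delta = 2.5, seed = 4)
  d <- preprocess(td$x)
  fit <- train_classifier(d, td$y, config = model_config(
    grid = expand.grid(interaction_depth = 2, n_trees = 80, shrinkage = 0.1,
                       min_node_size = 5), resampling = "loocv"), seed = 5)
  expect_gte(fit$cv_auc, 0.95)   # LOOCV AUC on a separable toy
  expect_equal(nrow(fit$grid_results), 1)  # single grid point: direct fit
  yperm <- withr::with_seed(6, sample(td$y))
  fitp <- train_classifier(d, yperm, config = fast_config(), seed = 5)
  expect_lt(abs(fitp$cv_auc - 0.5), 0.25)
  expect_error(train_classifier(d[1:5, ], td$y[1:5]), "at least 10")
  expect_error(train_classifier(d, factor(rep("responder", 60),
                                          levels = levels(td$y))),
               "single-class")
})

test_that("repeated splits report stable metrics deterministically", {
  td <- toy_data(n = 60, p = 30, n_info = 4, delta = 2.5, seed = 7)
  cfg <- fast_config(n_repeats = 6, n_rfe_features = 10, seed = 99)
  rep1 <- repeated_split_eval(td$x, td$y, cfg)
  rep2 <- repeated_split_eval(td$x, td$y, cfg)
  expect_identical(rep1$splits, rep2$splits)   # same master seed, same runs
  expect_gt(rep1$mean_auc, 0.8)
  expect_true(all(rep1$selection_frequency >= 0 &
                    rep1$selection_frequency <= 1))
  expect_true(all(rep1$splits$auc >= 0 & rep1$splits$auc <= 1))
  expect_error(repeated_split_eval(td$x[1:8, ], td$y[1:8], cfg), ">= 5")
})

test_that("external evaluation joins by terminal clade and flags degenerates", {
  td <- toy_data(n = 60, p = 20, n_info = 4, delta = 2.5, seed = 8)
  cfg <- fast_config(n_rfe_features = 8, seed = 13)
  model <- finalize_model(td$x, td$y, cfg)
  # identical external set reproduces resubstitution metrics
  res_self <- evaluate_external(model, td$x, td$y)
  self_scores <- predict(model, td$x)
  expect_equal(res_self$scores, self_scores)
  expect_gt(res_self$auc, 0.9)
  # lineage prefixes differ but terminal clades match
  x_ext <- td$x
  colnames(x_ext) <- sub("^k__B\\|g__G\\|", "k__Bacteria|g__Other|",
                         colnames(x_ext))
  res_term <- evaluate_external(model, x_ext, td$y)
  expect_equal(res_term$auc, res_self$auc)
  # permuted external labels give chance AUC
  yp <- withr::with_seed(9, sample(td$y))
  expect_lt(abs(evaluate_external(model, td$x, yp)$auc - 0.5), 0.2)
  # single-class external set: specificity undefined with warning
  xr <- td$x[td$y == "responder", ]
  expect_warning(res_r <- evaluate_external(model, xr,
                                            rep("responder", nrow(xr))),
                 "specificity undefined")
  expect_true(is.na(res_r$specificity))
  # no overlapping features at all
  x_none <- td$x; colnames(x_none) <- paste0("s__other", 1:20)
  expect_error(evaluate_external(model, x_none, td$y), "no overlapping")
})

test_that("AUC is invariant to monotone transforms of the scores", {
  set.seed(91)
  sc <- runif(40); y <- rbinom(40, 1, 0.5)
  a1 <- microresist:::rank_auc(sc, y)
  a2 <- microresist:::rank_auc(qlogis(sc), y)
  expect_equal(a1, a2)
  expect_equal(microresist:::rank_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # agrees with the ROC reference implementation
  a3 <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                       direction = "<")))
  expect_equal(a1, a3)
})
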