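#' SVM stage configuration
#'
#' @param kernel Kernel type (default `"radial"`).
#' @param cost Regularisation cost used when `tune = FALSE` (default 10).
#' @param gamma RBF kernel width; `NULL` (default) uses the scale
#'   heuristic `1 / (p * var)` computed on the standardised training data.
#' @param tune Grid-search cost/gamma by internal cross-validation?
#' @param cost_grid,gamma_mult Grid searched when `tune = TRUE`: every
#'   cost in `cost_grid` crossed with the scale-heuristic gamma times each
#'   multiplier in `gamma_mult`.
#' @param tune_folds Internal CV folds for tuning (default 3).
#' @return An `svm_config` list.
#' @export
svm_config <- function(kernel = "radial", cost = 10, gamma = NULL,
                       tune = FALSE, cost_grid = c(0.1, 1, 10, 100),
                       gamma_mult = c(0.1, 1, 10), tune_folds = 3) {
  structure(list(kernel = kernel, cost = cost, gamma = gamma, tune = tune,
                 cost_grid = cost_grid, gamma_mult = gamma_mult,
                 tune_folds = as.integer(tune_folds)),
            class = "svm_config")
}

#' Boosted-stage configuration
#'
#' @param max_depth,eta,nrounds Tree depth, learning rate and boosting
#'   rounds used when `tune = FALSE` (defaults 3, 0.1, 150).
#' @param tune Grid-search depth/eta by internal cross-validation?
#' @param depth_grid,eta_grid Grids searched when `tune = TRUE`.
#' @param tune_folds Internal CV folds for tuning (default 3).
#' @return An `xgb_config` list.
#' @export
xgb_config <- function(max_depth = 3, eta = 0.1, nrounds = 150,
                       tune = FALSE, depth_grid = c(2, 3, 4),
                       eta_grid = c(0.05, 0.1, 0.3), tune_folds = 3) {
  structure(list(max_depth = max_depth, eta = eta, nrounds = nrounds,
                 tune = tune, depth_grid = depth_grid, eta_grid = eta_grid,
                 tune_folds = as.integer(tune_folds)),
            class = "xgb_config")
}

scale_gamma_heuristic <- function(x) {
  v <- mean(apply(x, 2, stats::var))
  if (v <= 0) v <- 1
  1 / (ncol(x) * v)
}

simple_fold_accuracy <- function(x, y, folds, fit_fun, pred_fun) {
  n <- nrow(x)
  fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
  correct <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (length(unique(y[!test])) < 2) next
    m <- fit_fun(x[!test, , drop = FALSE], y[!test])
    correct <- correct + sum(pred_fun(m, x[test, , drop = FALSE]) == y[test])
  }
  correct / n
}

#' Train the SVM stage of the serial fusion
#'
#' Standardises the features (training statistics only), optionally
#' grid-searches cost and gamma by internal cross-validation, and fits a
#' kernel maximum-margin classifier.
#'
#' @param x Numeric matrix or data frame of features (rows = samples).
#' @param y Class labels (>= 2 classes, >= 2 samples per class advised).
#' @param cfg An [svm_config()].
#' @param seed Seed for the tuning fold assignment.
#' @return An `svm_stage` model: the fitted SVM, the scaler parameters,
#'   the class levels, support vectors and kernel parameters.
#' @export
train_svm_stage <- function(x, y, cfg = svm_config(), seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  assert_that(nlevels(y) >= 2, "need >= 2 classes to train")
  centre <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scl, "/")
  gamma0 <- scale_gamma_heuristic(xs)

  cost <- cfg$cost
  gamma <- cfg$gamma %||% gamma0
  if (cfg$tune) {
    grid <- expand.grid(cost = cfg$cost_grid,
                        gamma = gamma0 * cfg$gamma_mult)
    acc <- with_seed(seed, {
      apply(grid, 1, function(g) {
        simple_fold_accuracy(
          xs, y, cfg$tune_folds,
          function(xt, yt) e1071::svm(xt, yt, kernel = cfg$kernel,
                                      cost = g[["cost"]],
                                      gamma = g[["gamma"]], scale = FALSE),
          function(m, xt) predict(m, xt))
      })
    })
    best <- which.max(acc)
    cost <- grid$cost[best]
    gamma <- grid$gamma[best]
  }
  fit <- e1071::svm(xs, y, kernel = cfg$kernel, cost = cost, gamma = gamma,
                    scale = FALSE, decision.values = TRUE)
  structure(list(fit = fit, center = centre, scale = scl,
                 classes = levels(y), kernel = cfg$kernel,
                 cost = cost, gamma = gamma,
                 sv_x = fit$SV, sv_class = y[fit$index]),
            class = "svm_stage")
}

#' @export
predict.svm_stage <- function(object, newdata, ...) {
  xs <- scale_like(object, newdata)
  factor(as.character(predict(object$fit, xs)), levels = object$classes)
}

scale_like <- function(model, x) {
  x <- as.matrix(x)
  assert_that(ncol(x) == length(model$center),
              sprintf("feature width %d does not match the %d the model was trained on",
                      ncol(x), length(model$center)))
  sweep(sweep(x, 2, model$center), 2, model$scale, "/")
}

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# Per-class decision scores with a class-count-stable width: the pairwise
# decision values are averaged per class with the sign oriented so that a
# positive score favours that class.
decision_block <- function(model, xs) {
  dv <- attr(predict(model$fit, xs, decision.values = TRUE),
             "decision.values")
  classes <- model$classes
  out <- matrix(0, nrow(xs), length(classes),
                dimnames = list(NULL, paste0("svm_dec_", classes)))
  pairs <- strsplit(colnames(dv), "/")
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    acc <- numeric(nrow(xs))
    cnt <- 0L
    for (j in seq_along(pairs)) {
      if (pairs[[j]][1] == cl) {
        acc <- acc + dv[, j]
        cnt <- cnt + 1L
      } else if (pairs[[j]][2] == cl) {
        acc <- acc - dv[, j]
        cnt <- cnt + 1L
      }
    }
    out[, ci] <- if (cnt > 0) acc / cnt else 0
  }
  out
}

#' Append SVM-derived features to a feature matrix
#'
#' Implements the serial fusion's feature synthesis: the original
#' features are augmented with (a) one decision-function score per class
#' and (b) per class, the maximum and mean RBF-kernel similarity of the
#' sample to that class's support vectors. The layout is fixed by the
#' trained stage, so training and prediction always agree.
#'
#' @param model An `svm_stage` from [train_svm_stage()].
#' @param x Feature matrix with the training width.
#' @return Numeric matrix: `[x | decision block | similarity block]`.
#' @export
augment_features <- function(model, x) {
  assert_that(inherits(model, "svm_stage"), "`model` must be an svm_stage")
  xs <- scale_like(model, x)
  dec <- decision_block(model, xs)
  k <- rbf_kernel(xs, model$sv_x, model$gamma)
  sim <- do.call(cbind, lapply(model$classes, function(cl) {
    cols <- model$sv_class == cl
    if (!any(cols)) {
      m <- matrix(0, nrow(xs), 2)
    } else {
      kk <- k[, cols, drop = FALSE]
      m <- cbind(apply(kk, 1, max), rowMeans(kk))
    }
    colnames(m) <- paste0(c("svm_simmax_", "svm_simmean_"), cl)
    m
  }))
  out <- cbind(as.matrix(x), dec, sim)
  rownames(out) <- NULL
  out
}

xgb_params <- function(cfg, n_classes) {
  base <- list(max_depth = cfg$max_depth, eta = cfg$eta, nthread = 1)
  if (n_classes > 2) {
    c(base, list(objective = "multi:softprob", num_class = n_classes))
  } else {
    c(base, list(objective = "binary:logistic"))
  }
}

fit_xgb <- function(x, y_int, cfg, n_classes, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y_int)
  params <- c(xgb_params(cfg, n_classes), list(seed = seed))
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = cfg$nrounds, verbose = 0)
}

predict_xgb <- function(booster, x, classes) {
  pr <- predict(booster, xgboost::xgb.DMatrix(x))
  if (length(classes) > 2) {
    pm <- if (is.matrix(pr)) pr
          else matrix(pr, ncol = length(classes), byrow = TRUE)
    factor(classes[max.col(pm, ties.method = "first")], levels = classes)
  } else {
    factor(classes[1 + (pr > 0.5)], levels = classes)
  }
}

#' Train the serial SVM-to-XGBoost fusion
#'
#' Trains the SVM stage, augments every training row with the SVM's
#' decision scores and support-vector similarity summaries, then fits a
#' gradient-boosted-tree classifier on the augmented matrix. Training
#' rows are augmented out-of-fold by default (`oof_folds` inner folds):
#' each row's SVM-derived features come from a model that did not see it,
#' so their distribution matches what the boosted stage will encounter at
#' prediction time. Without this the decision-value feature separates the
#' training rows with an optimistically wide margin and the tree
#' thresholds land arbitrarily inside it. The final SVM stage is fitted
#' on all rows and is the one used to augment new samples. Before the
#' boosted stage the data are re-shuffled with a fresh seeded permutation
#' ("repartitioning"); when `xgb_cfg$tune` is on, depth and learning rate
#' are grid-searched by internal cross-validation on the augmented
#' training data.
#'
#' @param x Feature matrix (selected-band reflectances).
#' @param y Class labels.
#' @param svm_cfg An [svm_config()].
#' @param xgb_cfg An [xgb_config()].
#' @param oof_folds Inner folds for out-of-fold augmentation of the
#'   training rows (default 5); `0` augments with the final SVM stage
#'   directly.
#' @param seed Integer seed controlling tuning folds, repartitioning and
#'   the boosted stage.
#' @return A `fused_model`.
#' @export
train_fused <- function(x, y, svm_cfg = svm_config(),
                        xgb_cfg = xgb_config(), oof_folds = 5,
                        seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  assert_that(nlevels(y) >= 2, "need >= 2 classes to train")
  svm_stage <- train_svm_stage(x, y, svm_cfg, seed = child_seed(seed, 1L))
  aug <- augment_features(svm_stage, x)
  if (oof_folds >= 2 && nrow(x) >= 2 * oof_folds) {
    inner <- stratified_folds(y, k = oof_folds,
                              seed = child_seed(seed, 6L))
    for (g in sort(unique(inner))) {
      hold <- inner == g
      if (length(unique(y[!hold])) < 2) next  # keep full-model features
      m_g <- train_svm_stage(x[!hold, , drop = FALSE], y[!hold], svm_cfg,
                             seed = child_seed(seed, 7L))
      aug[hold, ] <- augment_features(m_g, x[hold, , drop = FALSE])
    }
  }
  classes <- levels(y)
  y_int <- as.integer(y) - 1L

  # repartition: fresh shuffle before the boosted stage
  perm <- with_seed(child_seed(seed, 2L), sample.int(nrow(aug)))
  aug_p <- aug[perm, , drop = FALSE]
  y_p <- y_int[perm]

  cfg <- xgb_cfg
  if (xgb_cfg$tune) {
    grid <- expand.grid(max_depth = xgb_cfg$depth_grid,
                        eta = xgb_cfg$eta_grid)
    acc <- with_seed(child_seed(seed, 3L), {
      apply(grid, 1, function(g) {
        cfg_g <- xgb_cfg
        cfg_g$max_depth <- g[["max_depth"]]
        cfg_g$eta <- g[["eta"]]
        simple_fold_accuracy(
          aug_p, y_p, xgb_cfg$tune_folds,
          function(xt, yt) fit_xgb(xt, yt, cfg_g, length(classes),
                                   seed = child_seed(seed, 4L)),
          function(m, xt) {
            as.integer(as.character(
              predict_xgb(m, xt, as.character(seq_along(classes) - 1L))))
          })
      })
    })
    best <- which.max(acc)
    cfg$max_depth <- grid$max_depth[best]
    cfg$eta <- grid$eta[best]
  }
  booster <- fit_xgb(aug_p, y_p, cfg, length(classes),
                     seed = child_seed(seed, 5L))
  structure(list(svm_stage = svm_stage, booster = booster,
                 classes = classes, xgb_cfg = cfg, seed = seed,
                 feature_width = ncol(x)),
            class = "fused_model")
}

#' @export
predict.fused_model <- function(object, newdata, ...) {
  aug <- augment_features(object$svm_stage, as.matrix(newdata))
  predict_xgb(object$booster, aug, object$classes)
}

#' @export
print.fused_model <- function(x, ...) {
  cat("<fused_model> SVM (", x$svm_stage$kernel, ", C=", x$svm_stage$cost,
      ") -> XGBoost (depth=", x$xgb_cfg$max_depth, ", eta=", x$xgb_cfg$eta,
      ", nrounds=", x$xgb_cfg$nrounds, "); classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# --- baselines ------------------------------------------------------------

#' Train a baseline classifier
#'
#' The four reference models the fusion is compared against: a standalone
#' RBF SVM, random forest, XGBoost on the raw band features, and AdaBoost
#' (multi-class SAMME over shallow CART trees).
#'
#' @param name One of `"svm"`, `"rf"`, `"xgboost"`, `"adaboost"`.
#' @param x Feature matrix.
#' @param y Class labels.
#' @param seed Integer seed.
#' @param ... Passed to the underlying fitters ([svm_config()] fields for
#'   `"svm"`, `ntree` for `"rf"`, [xgb_config()] fields for `"xgboost"`,
#'   `n_rounds`/`max_depth` for `"adaboost"`).
#' @return A `baseline_model`.
#' @export
train_baseline <- function(name, x, y, seed = 1L, ...) {
  assert_that(is.character(name) && length(name) == 1,
              "`name` must be a single string")
  assert_that(name %in% c("svm", "rf", "xgboost", "adaboost"),
              paste0("unknown model name: '", name, "'"))
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  dots <- list(...)
  fit <- switch(name,
    svm = train_svm_stage(x, y, do.call(svm_config, dots), seed = seed),
    rf = with_seed(seed,
      randomForest::randomForest(x, y, ntree = dots$ntree %||% 500)),
    xgboost = {
      cfg <- do.call(xgb_config, dots[setdiff(names(dots), "ntree")])
      list(booster = fit_xgb(x, as.integer(y) - 1L, cfg,
                             nlevels(y), seed = seed),
           classes = levels(y))
    },
    adaboost = adaboost_fit(x, y, n_rounds = dots$n_rounds %||% 50,
                            max_depth = dots$max_depth %||% 1, seed = seed)
  )
  structure(list(name = name, fit = fit, classes = levels(y)),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- switch(object$name,
    svm = predict(object$fit, newdata),
    rf = predict(object$fit, newdata),
    xgboost = predict_xgb(object$fit$booster, newdata, object$fit$classes),
    adaboost = adaboost_predict(object$fit, newdata)
  )
  factor(as.character(out), levels = object$classes)
}

# SAMME AdaBoost with shallow CART trees as weak learners.
adaboost_fit <- function(x, y, n_rounds = 50, max_depth = 1, seed = 1L) {
  k <- nlevels(y)
  n <- nrow(x)
  feat_names <- paste0("f", seq_len(ncol(x)))
  colnames(x) <- feat_names
  df <- data.frame(.y = y, x)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      tree <- rpart::rpart(
        .y ~ ., data = df, weights = w, method = "class",
        control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                       minsplit = 2, xval = 0))
      pred <- predict(tree, df, type = "class")
      err <- sum(w * (pred != y)) / sum(w)
      if (err >= 1 - 1 / k) break        # weaker than chance: stop
      err <- max(err, 1e-10)
      alpha <- log((1 - err) / err) + log(k - 1)
      learners[[length(learners) + 1]] <- tree
      alphas <- c(alphas, alpha)
      if (err <= 1e-10) break            # perfect learner: done
      w <- w * exp(alpha * (pred != y))
      w <- w / sum(w)
    }
  })
  assert_that(length(learners) > 0,
              "adaboost found no weak learner better than chance")
  list(learners = learners, alphas = alphas, classes = levels(y),
       feat_names = feat_names)
}

adaboost_predict <- function(fit, x) {
  x <- as.matrix(x)
  colnames(x) <- fit$feat_names
  df <- as.data.frame(x)
  votes <- matrix(0, nrow(df), length(fit$classes),
                  dimnames = list(NULL, fit$classes))
  for (m in seq_along(fit$learners)) {
    pred <- predict(fit$learners[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + fit$alphas[m]
  }
  factor(fit$classes[max.col(votes, ties.method = "first")],
         levels = fit$classes)
}
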