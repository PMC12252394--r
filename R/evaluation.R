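#' Stratified fold assignment
#'
#' Partitions samples into `k` folds, stratifying on the class label
#' nested within an optional treatment group (e.g. nitrogen level): within
#' each group x class cell the samples are shuffled and dealt round-robin
#' onto the folds, so per-fold class counts within each group deviate from
#' balance by at most one sample. Classes with fewer than `k` members are
#' simply spread as evenly as possible.
#'
#' @param labels Class labels (length n).
#' @param groups Optional treatment-group vector (length n).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, groups = NULL, k = 10, seed = 1L) {
  n <- length(labels)
  assert_that(is_count(k) && k >= 2, "`k` must be an integer >= 2")
  assert_that(k <= n, sprintf("k = %d exceeds the %d samples", k, n))
  if (is.null(groups)) groups <- rep(1L, n)
  assert_that(length(groups) == n, "`groups` must match `labels` length")
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (g in unique(groups)) {
      for (cl in unique(labels[groups == g])) {
        idx <- which(groups == g & labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        offset <- offset + length(idx)
      }
    }
  })
  fold
}

#' Confusion matrix from actual and predicted labels
#'
#' Rows are actual classes, columns predicted.
#'
#' @param actual,predicted Label vectors of equal length.
#' @param classes Class level set; defaults to the union of both vectors.
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(actual, predicted, classes = NULL) {
  if (is.null(classes)) {
    classes <- sort(unique(c(as.character(actual), as.character(predicted))))
  }
  a <- factor(as.character(actual), levels = classes)
  p <- factor(as.character(predicted), levels = classes)
  m <- table(actual = a, predicted = p)
  structure(matrix(as.integer(m), nrow = length(classes),
                   dimnames = dimnames(m)),
            class = c("confusion_matrix", "matrix"))
}

check_cm <- function(cm) {
  m <- unclass(as.matrix(cm))
  assert_that(nrow(m) == ncol(m), "confusion matrix must be square")
  assert_that(all(m >= 0), "confusion matrix counts must be >= 0")
  assert_that(sum(m) > 0, "confusion matrix is empty (N = 0)")
  m
}

#' Overall accuracy of a confusion matrix
#'
#' `OA = 100 * sum(diag) / N`, in percent.
#'
#' @param cm Square count matrix (rows actual, columns predicted).
#' @return Overall accuracy in percent.
#' @export
overall_accuracy <- function(cm) {
  m <- check_cm(cm)
  100 * sum(diag(m)) / sum(m)
}

#' Cohen's kappa of a confusion matrix
#'
#' `kappa = (N * sum(x_ii) - sum(x_i+ * x_+i)) / (N^2 - sum(x_i+ * x_+i))`
#' with row marginals `x_i+` and column marginals `x_+i`. When the
#' expected-agreement term equals `N^2` (all mass in one row and column)
#' the coefficient is undefined and `NA` is returned with a warning.
#'
#' @param cm Square count matrix (rows actual, columns predicted).
#' @return Kappa coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
kappa_coef <- function(cm) {
  m <- check_cm(cm)
  n <- sum(m)
  chance <- sum(rowSums(m) * colSums(m))
  if (chance == n^2) {
    warn("kappa undefined: expected agreement equals N^2")
    return(NA_real_)
  }
  (n * sum(diag(m)) - chance) / (n^2 - chance)
}

# Resolve a model spec into fit/predict closures. `model` is either one
# of the known names or a list(fit = function(x, y, seed),
# predict = function(fit, x)).
resolve_model <- function(model, ...) {
  if (is.list(model) && all(c("fit", "predict") %in% names(model))) {
    return(model)
  }
  assert_that(is.character(model) && length(model) == 1,
              "`model` must be a name or a list(fit =, predict =)")
  dots <- list(...)
  if (model %in% c("svm_xgboost", "fused")) {
    list(
      fit = function(x, y, seed) {
        train_fused(x, y,
                    svm_cfg = dots$svm_cfg %||% svm_config(),
                    xgb_cfg = dots$xgb_cfg %||% xgb_config(),
                    seed = seed)
      },
      predict = function(fit, x) predict(fit, x)
    )
  } else if (model %in% c("svm", "rf", "xgboost", "adaboost")) {
    list(
      fit = function(x, y, seed) {
        do.call(train_baseline, c(list(model, x, y, seed = seed), dots))
      },
      predict = function(fit, x) predict(fit, x)
    )
  } else {
    abort(paste0("unknown model name: '", model, "'"))
  }
}

#' Cross-validated evaluation of a classifier
#'
#' Stratified k-fold cross-validation: for each fold the model (including
#' its internal standardisation) is fitted on the remaining folds only and
#' evaluated on the held-out fold. Reports per-fold confusion matrices,
#' overall accuracy and kappa, their means over folds (the headline
#' numbers), and the pooled confusion matrix.
#'
#' @param x Feature matrix or spectra tibble (its `band_*` columns are
#'   used).
#' @param y Class labels.
#' @param model Model name (`"svm_xgboost"`, `"svm"`, `"rf"`,
#'   `"xgboost"`, `"adaboost"`) or a `list(fit =, predict =)` pair.
#' @param groups Optional treatment groups for stratification.
#' @param k Folds (default 10).
#' @param seed Integer seed (fold assignment and model fits).
#' @param folds Optional precomputed fold assignment (overrides
#'   `groups`/`k`/`seed` for partitioning); used to share folds across
#'   comparisons.
#' @param ... Extra arguments for the model builder (e.g. `svm_cfg`,
#'   `xgb_cfg`, `ntree`).
#' @return An `eval_report` object; see [tidy.eval_report()] and
#'   [glance.eval_report()].
#' @export
cross_validate <- function(x, y, model = "svm_xgboost", groups = NULL,
                           k = 10, seed = 1L, folds = NULL, ...) {
  if (is.data.frame(x) && length(band_cols(x)) > 0) x <- spectra_matrix(x)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  assert_that(nrow(x) == length(y), "`x` rows must match `y` length")
  if (is.null(folds)) {
    folds <- stratified_folds(y, groups, k = k, seed = seed)
  }
  assert_that(length(folds) == length(y),
              "`folds` must assign every sample")
  spec <- resolve_model(model, ...)
  classes <- levels(y)

  fold_ids <- sort(unique(folds))
  per_fold <- vector("list", length(fold_ids))
  skipped <- integer(0)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (fi in seq_along(fold_ids)) {
    f <- fold_ids[fi]
    test <- folds == f
    if (length(unique(y[!test])) < 2) {
      warn(sprintf("fold %d skipped: training data has a single class", f))
      skipped <- c(skipped, f)
      next
    }
    fit <- spec$fit(x[!test, , drop = FALSE], y[!test],
                    seed = child_seed(seed, 100L + f))
    pred <- spec$predict(fit, x[test, , drop = FALSE])
    cm <- confusion_matrix(y[test], pred, classes = classes)
    pooled <- pooled + unclass(cm)
    per_fold[[fi]] <- tibble(
      fold = f, n_test = sum(test),
      oa = overall_accuracy(cm),
      kappa = suppressWarnings(kappa_coef(cm)),
      confusion = list(cm)
    )
  }
  fold_tbl <- bind_rows(per_fold)
  assert_that(nrow(fold_tbl) > 0, "every fold was skipped")
  pooled <- structure(pooled, class = c("confusion_matrix", "matrix"))
  structure(list(
    folds = fold_tbl,
    mean_oa = mean(fold_tbl$oa),
    mean_kappa = mean(fold_tbl$kappa, na.rm = TRUE),
    pooled = pooled,
    pooled_oa = overall_accuracy(pooled),
    pooled_kappa = suppressWarnings(kappa_coef(pooled)),
    fold_assignment = folds,
    skipped_folds = skipped,
    model = if (is.character(model)) model else "custom",
    k = length(fold_ids), seed = seed, classes = classes
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$model, "-", x$k, "folds\n")
  cat(sprintf("  mean OA: %.1f%%  mean kappa: %.3f\n",
              x$mean_oa, x$mean_kappa))
  cat(sprintf("  pooled OA: %.1f%%  pooled kappa: %.3f\n",
              x$pooled_oa, x$pooled_kappa))
  invisible(x)
}

#' Tidy per-fold results of an evaluation
#'
#' @param x An `eval_report` from [cross_validate()].
#' @param ... Unused.
#' @return A tibble with one row per evaluated fold (`fold`, `n_test`,
#'   `oa`, `kappa`).
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::select(x$folds, "fold", "n_test", "oa", "kappa")
}

#' One-row summary of an evaluation
#'
#' @param x An `eval_report` from [cross_validate()].
#' @param ... Unused.
#' @return A one-row tibble: `model`, `k`, `mean_oa`, `mean_kappa`,
#'   `pooled_oa`, `pooled_kappa`, `seed`.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(model = x$model, k = x$k, mean_oa = x$mean_oa,
         mean_kappa = x$mean_kappa, pooled_oa = x$pooled_oa,
         pooled_kappa = x$pooled_kappa, seed = x$seed)
}

fold_hash <- function(folds) {
  paste0("f", paste(folds, collapse = ""))
}

#' Compare classifiers on shared folds
#'
#' Runs [cross_validate()] for each named model with an identical fold
#' assignment, so rows differ only in the classifier.
#'
#' @param x Feature matrix or spectra tibble.
#' @param y Class labels.
#' @param models Character vector of model names (default: the fusion and
#'   the four baselines).
#' @param groups,k,seed As in [cross_validate()].
#' @param ... Extra model-builder arguments shared by all models.
#' @return A tibble with one row per model (`model`, `mean_oa`,
#'   `mean_kappa`, `pooled_oa`, `pooled_kappa`); the full reports are in
#'   attribute `reports` and the shared fold hash in `fold_hash`.
#' @export
compare_models <- function(x, y, models = c("svm_xgboost", "svm", "rf",
                                            "xgboost", "adaboost"),
                           groups = NULL, k = 10, seed = 1L, ...) {
  if (is.data.frame(x) && length(band_cols(x)) > 0) x <- spectra_matrix(x)
  y <- droplevels(as.factor(y))
  folds <- stratified_folds(y, groups, k = k, seed = seed)
  reports <- purrr::map(models, function(m) {
    cross_validate(x, y, model = m, folds = folds, seed = seed, ...)
  })
  names(reports) <- models
  out <- purrr::map_dfr(reports, glance) |>
    dplyr::select(-"seed", -"k")
  attr(out, "reports") <- reports
  attr(out, "fold_hash") <- fold_hash(folds)
  attr(out, "seed") <- seed
  out
}

#' Compare band subsets as classifier inputs on shared folds
#'
#' Evaluates one classifier on several band subsets of the same spectra
#' with an identical fold assignment. A `"full"` (all bands) row is added
#' if not supplied.
#'
#' @param spectra Spectra tibble.
#' @param labels Class labels aligned with `spectra` rows.
#' @param subsets Named list of `band_subset` objects (or numeric
#'   wavelength vectors, or the string `"full"`).
#' @param model Model name (default the serial fusion).
#' @param groups,k,seed As in [cross_validate()].
#' @param ... Extra model-builder arguments.
#' @return A tibble with one row per input (`input`, `n_bands`,
#'   `mean_oa`, `mean_kappa`, `pooled_oa`, `pooled_kappa`); reports and
#'   fold hash in attributes as in [compare_models()].
#' @export
compare_band_inputs <- function(spectra, labels, subsets,
                                model = "svm_xgboost", groups = NULL,
                                k = 10, seed = 1L, ...) {
  assert_that(is.list(subsets) && !is.null(names(subsets)),
              "`subsets` must be a named list")
  if (!any(names(subsets) == "full")) {
    subsets <- c(list(full = "full"), subsets)
  }
  y <- droplevels(as.factor(labels))
  folds <- stratified_folds(y, groups, k = k, seed = seed)
  reports <- purrr::imap(subsets, function(s, nm) {
    sub_spectra <- if (identical(s, "full")) spectra
                   else select_bands(spectra, s)
    nb <- length(band_cols(sub_spectra))
    assert_that(nb > 0, paste0("subset '", nm, "' selects no bands"))
    cross_validate(sub_spectra, y, model = model, folds = folds,
                   seed = seed, ...)
  })
  out <- purrr::imap_dfr(reports, function(r, nm) {
    bind_cols(tibble(input = nm),
              dplyr::select(glance(r), -"model", -"seed", -"k"))
  })
  out$n_bands <- purrr::map_int(unname(subsets), function(s) {
    if (identical(s, "full")) length(band_cols(spectra))
    else if (inherits(s, "band_subset")) length(s$indices)
    else length(s)
  })
  out <- dplyr::relocate(out, "n_bands", .after = "input")
  attr(out, "reports") <- reports
  attr(out, "fold_hash") <- fold_hash(folds)
  attr(out, "seed") <- seed
  out
}
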