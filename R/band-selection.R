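#' Configuration for the Lasso band screen
#'
#' @param alpha_grid Positive, log-spaced penalty grid searched by
#'   cross-validation (glmnet's lambda). Default `10^seq(0, -4,
#'   length.out = 60)`.
#' @param cv_folds Cross-validation folds (>= 2, default 5).
#' @param target_encoding How the two classes are encoded for the
#'   regression-based selector: `"binary_01"` (default) or `"pm1"`.
#' @param max_iter,tol Optimiser limits passed to glmnet.
#' @param seed Integer seed for the CV fold assignment.
#' @return A `lasso_config` list.
#' @export
lasso_config <- function(alpha_grid = 10^seq(0, -4, length.out = 60),
                         cv_folds = 5,
                         target_encoding = c("binary_01", "pm1"),
                         max_iter = 1e6, tol = 1e-10, seed = 1L) {
  target_encoding <- match.arg(target_encoding)
  assert_that(length(alpha_grid) > 0 && all(alpha_grid > 0),
              "`alpha_grid` must be non-empty and positive")
  assert_that(is_count(cv_folds) && cv_folds >= 2, "`cv_folds` must be >= 2")
  structure(list(alpha_grid = sort(alpha_grid, decreasing = TRUE),
                 cv_folds = as.integer(cv_folds),
                 target_encoding = target_encoding,
                 max_iter = max_iter, tol = tol, seed = as.integer(seed)),
            class = "lasso_config")
}

#' Configuration for CARS refinement
#'
#' @param n_runs Number of Monte Carlo iterations N (>= 2, default 50).
#' @param sample_fraction Fraction of samples drawn without replacement
#'   per run (default 0.8).
#' @param pls_components Latent components A of the inner PLS models
#'   (default 5; clipped with a warning when it exceeds what the retained
#'   set supports).
#' @param ars_draws Draws of the adaptive reweighted sampling step;
#'   `NULL` (default) uses the initial subset size p.
#' @param rmsecv_folds Folds of the RMSECV criterion (default 5).
#' @param ars Enable the adaptive reweighted sampling step (default TRUE);
#'   with `FALSE` only the exponential forced reduction prunes bands.
#' @param seed Integer seed; the whole refinement is deterministic given it.
#' @return A `cars_config` list.
#' @export
cars_config <- function(n_runs = 50, sample_fraction = 0.8,
                        pls_components = 5, ars_draws = NULL,
                        rmsecv_folds = 5, ars = TRUE, seed = 1L) {
  assert_that(is_count(n_runs) && n_runs >= 2, "`n_runs` must be >= 2")
  assert_that(sample_fraction > 0 && sample_fraction <= 1,
              "`sample_fraction` must be in (0, 1]")
  assert_that(is_count(pls_components), "`pls_components` must be >= 1")
  structure(list(n_runs = as.integer(n_runs),
                 sample_fraction = sample_fraction,
                 pls_components = as.integer(pls_components),
                 ars_draws = ars_draws,
                 rmsecv_folds = as.integer(rmsecv_folds),
                 ars = isTRUE(ars), seed = as.integer(seed)),
            class = "cars_config")
}

new_band_subset <- function(indices, wavelengths, stage, trace = NULL,
                            chosen_run = NA_integer_) {
  ord <- order(wavelengths)
  structure(list(indices = indices[ord], wavelengths = wavelengths[ord],
                 stage = stage, trace = trace, chosen_run = chosen_run),
            class = "band_subset")
}

#' @export
print.band_subset <- function(x, ...) {
  cat("<band_subset> stage:", x$stage, "-", length(x$indices), "bands\n")
  cat(" ", paste(sprintf("%.2f", x$wavelengths), collapse = ", "), "nm\n")
  if (!is.na(x$chosen_run)) cat("  chosen CARS run:", x$chosen_run, "\n")
  invisible(x)
}

#' Restrict a spectra tibble to a band subset
#'
#' @param spectra Spectra tibble.
#' @param subset A `band_subset` (or numeric wavelengths to keep).
#' @return The spectra tibble with only the subset's band columns.
#' @export
select_bands <- function(spectra, subset) {
  wl <- if (inherits(subset, "band_subset")) subset$wavelengths
        else as.numeric(subset)
  keep <- band_col_names(wl)
  missing <- setdiff(keep, names(spectra))
  assert_that(length(missing) == 0,
              paste("bands not present in `spectra`:",
                    paste(missing, collapse = ", ")))
  spectra[, c(setdiff(names(spectra), band_cols(spectra)), keep)]
}

encode_target <- function(labels, encoding) {
  labels <- as.factor(labels)
  lev <- levels(labels)
  assert_that(length(lev) == 2,
              paste0("the regression-based selectors need exactly 2 ",
                     "classes, got ", length(lev)))
  if (encoding == "binary_01") {
    as.numeric(labels == lev[2])
  } else {
    ifelse(labels == lev[2], 1, -1)
  }
}

#' Lasso screen for characteristic bands
#'
#' Standardises the bands, encodes the two-class label numerically and
#' fits an L1-penalised linear model over the penalty grid, choosing the
#' penalty that minimises mean cross-validated squared error. Bands with
#' non-zero coefficients at that penalty form the screened subset. If the
#' optimum shrinks every coefficient to zero, the largest penalty with a
#' non-empty selection is used instead, with a warning.
#'
#' @param spectra Spectra tibble (samples x bands).
#' @param labels Two-class labels aligned with the rows of `spectra`.
#' @param cfg A [lasso_config()].
#' @return A `band_subset` with `stage = "lasso"`.
#' @export
lasso_screen <- function(spectra, labels, cfg = lasso_config()) {
  x <- standardize(spectra_matrix(spectra))
  wl <- band_wavelengths(spectra)
  y <- encode_target(labels, cfg$target_encoding)
  n <- nrow(x)
  assert_that(length(labels) == n, "`labels` must match rows of `spectra`")

  fold_id <- with_seed(cfg$seed,
                       sample(rep_len(seq_len(cfg$cv_folds), n)))
  cvfit <- glmnet::cv.glmnet(
    x, y, family = "gaussian", alpha = 1, lambda = cfg$alpha_grid,
    foldid = fold_id, standardize = FALSE,
    maxit = cfg$max_iter, thresh = cfg$tol
  )
  beta <- coef(cvfit, s = "lambda.min")[-1]
  idx <- which(abs(beta) > 0)
  if (length(idx) == 0) {
    # walk the path towards weaker penalties until something survives
    full <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                           lambda = cfg$alpha_grid, standardize = FALSE,
                           maxit = cfg$max_iter, thresh = cfg$tol)
    nz <- full$df
    pos <- which(nz > 0)
    assert_that(length(pos) > 0,
                "lasso selected no bands at any penalty in the grid")
    warn("CV-optimal penalty selected no bands; using the largest penalty with a non-empty selection")
    beta <- as.matrix(full$beta)[, pos[1]]
    idx <- which(abs(beta) > 0)
  }
  new_band_subset(idx, wl[idx], stage = "lasso")
}

# Exponential forced-reduction schedule with r_1 = 1 and r_N = 2/p.
cars_ratio_schedule <- function(p, n_runs) {
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * seq_len(n_runs))
}

#' CARS refinement of a band subset
#'
#' Competitive adaptive reweighted sampling: over `n_runs` Monte Carlo
#' iterations, a random sample of plots is drawn, a PLS model is fitted on
#' the currently retained bands, and each band is weighted by its share of
#' the absolute PLS coefficients. An exponentially decreasing forced
#' reduction keeps the top `ceiling(r_i * p)` bands by weight (ties broken
#' by ascending wavelength), after which adaptive reweighted sampling
#' draws bands with replacement proportionally to their weights and
#' retains the union. Each run's retained set is scored by the
#' cross-validated RMSE of a PLS model on all samples; the run minimising
#' RMSECV supplies the returned subset.
#'
#' @param spectra Spectra tibble.
#' @param labels Two-class labels aligned with `spectra` rows.
#' @param cfg A [cars_config()].
#' @param subset Optional `band_subset` restricting the candidate bands
#'   (e.g. a Lasso screen); default all bands.
#' @return A `band_subset` with `stage = "cars"`, a `trace` tibble
#'   (`run`, `ratio`, `n_retained`, `rmsecv`, `retained` list-column) and
#'   `chosen_run`.
#' @export
cars_refine <- function(spectra, labels, cfg = cars_config(),
                        subset = NULL) {
  if (!is.null(subset)) spectra <- select_bands(spectra, subset)
  x_all <- standardize(spectra_matrix(spectra))
  wl <- band_wavelengths(spectra)
  y <- encode_target(labels, "binary_01")
  n <- nrow(x_all)
  p <- ncol(x_all)
  assert_that(p >= 2, "CARS needs an input subset of >= 2 bands")

  ratios <- cars_ratio_schedule(p, cfg$n_runs)
  n_draw <- max(2L, ceiling(cfg$sample_fraction * n))
  ars_draws <- cfg$ars_draws %||% p

  with_seed(cfg$seed, {
    retained <- seq_len(p)
    trace <- vector("list", cfg$n_runs)
    clip_warned <- FALSE
    for (i in seq_len(cfg$n_runs)) {
      samp <- sample.int(n, n_draw)
      a_i <- min(cfg$pls_components, length(retained), n_draw - 1)
      if (a_i < cfg$pls_components && !clip_warned) {
        warn(sprintf(
          "PLS components clipped from %d to %d to fit the retained set",
          cfg$pls_components, a_i))
        clip_warned <- TRUE
      }
      fit <- pls_fit(x_all[samp, retained, drop = FALSE], y[samp], a_i)
      b <- abs(fit$coefficients)
      if (sum(b) == 0) b[] <- 1  # uninformative fit: uniform weights
      w <- b / sum(b)

      # forced reduction: top ceiling(r_i * p) by weight, ties by wavelength
      keep_n <- min(ceiling(ratios[i] * p), length(retained))
      ord <- order(-w, wl[retained])
      keep_pos <- ord[seq_len(keep_n)]
      o <- order(retained[keep_pos])
      retained <- retained[keep_pos][o]
      w <- w[keep_pos][o]
      w <- w / sum(w)

      if (cfg$ars && length(retained) > 1) {
        drawn <- sample(retained, size = ars_draws, replace = TRUE,
                        prob = w)
        retained <- sort(unique(drawn))
      }
      if (length(retained) < 1) {
        warn(sprintf("run %d retained no bands; skipped", i))
        trace[[i]] <- tibble(run = i, ratio = ratios[i], n_retained = 0L,
                             rmsecv = NA_real_, retained = list(integer()))
        next
      }
      rmsecv <- pls_rmsecv(x_all[, retained, drop = FALSE], y,
                           a = min(cfg$pls_components, length(retained)),
                           folds = cfg$rmsecv_folds,
                           seed = sample.int(2^31 - 1, 1))
      trace[[i]] <- tibble(run = i, ratio = ratios[i],
                           n_retained = length(retained),
                           rmsecv = rmsecv, retained = list(retained))
    }
    trace <- bind_rows(trace)
    ok <- which(!is.na(trace$rmsecv))
    assert_that(length(ok) > 0, "every CARS run collapsed; nothing to return")
    chosen <- ok[which.min(trace$rmsecv[ok])]
    idx <- trace$retained[[chosen]]
    new_band_subset(idx, wl[idx], stage = "cars", trace = trace,
                    chosen_run = chosen)
  })
}

#' Lasso screen followed by CARS refinement
#'
#' The two-stage characteristic-band extractor: an L1 screen removes the
#' bulk of the collinear, uninformative bands, then CARS competitively
#' prunes the survivors to a compact subset. A single-band Lasso result is
#' passed through unchanged (CARS needs at least two candidates).
#'
#' @param spectra Spectra tibble.
#' @param labels Two-class labels aligned with `spectra` rows.
#' @param lasso_cfg A [lasso_config()].
#' @param cars_cfg A [cars_config()].
#' @return A `band_subset` with `stage = "lasso_cars"`; its `trace` and
#'   `chosen_run` come from the CARS stage, and the attribute
#'   `lasso_subset` records the screened stage.
#' @export
lasso_cars <- function(spectra, labels, lasso_cfg = lasso_config(),
                       cars_cfg = cars_config()) {
  screened <- lasso_screen(spectra, labels, lasso_cfg)
  if (length(screened$indices) == 1) {
    out <- new_band_subset(screened$indices, screened$wavelengths,
                           stage = "lasso_cars")
  } else {
    refined <- cars_refine(spectra, labels, cars_cfg, subset = screened)
    # map indices back to the parent spectra's band positions
    parent_idx <- screened$indices[match(refined$wavelengths,
                                         screened$wavelengths)]
    out <- new_band_subset(parent_idx, refined$wavelengths,
                           stage = "lasso_cars", trace = refined$trace,
                           chosen_run = refined$chosen_run)
  }
  attr(out, "lasso_subset") <- screened
  out
}
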