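test_that("stratified folds partition samples with balanced classes", {
  y <- rep(c("a", "b"), each = 10)
  f <- stratified_folds(y, k = 10, seed = 1)
  expect_setequal(f, 1:10)
  for (k in 1:10) {
    expect_identical(sort(y[f == k]), c("a", "b"))
  }

  # partition law and counting oracle under grouping
  withr::with_seed(4, {
    y2 <- sample(c("a", "b", "c"), 83, replace = TRUE)
    g2 <- sample(c("N0", "N2"), 83, replace = TRUE)
  })
  f2 <- stratified_folds(y2, g2, k = 10, seed = 2)
  expect_length(f2, 83)
  expect_true(all(f2 %in% 1:10))
  for (gg in unique(g2)) {
    for (cc in unique(y2)) {
      counts <- table(factor(f2[g2 == gg & y2 == cc], levels = 1:10))
      expect_lte(max(counts) - min(counts), 1)
    }
  }
  expect_error(stratified_folds(y, k = 25), "exceeds")
  expect_error(stratified_folds(y, k = 1), ">= 2")
})

test_that("OA and kappa match the definitional formulas", {
  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "a", "b", "b"))
  expect_equal(overall_accuracy(cm), 100)
  expect_equal(kappa_coef(cm), 1)

  m <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(overall_accuracy(m), 75)

  balanced <- matrix(c(25, 25, 25, 25), 2)
  expect_equal(kappa_coef(balanced), 0)

  hand <- matrix(c(40, 10, 20, 30), 2, byrow = TRUE)
  expect_equal(overall_accuracy(hand), 70)
  expect_equal(kappa_coef(hand), 0.4)

  withr::with_seed(1, {
    for (i in 1:200) {
      k <- sample(2:5, 1)
      m <- matrix(rpois(k * k, 8), k, k)
      if (sum(m) == 0) next
      expect_lt(abs(overall_accuracy(m) - brute_oa(m)), 1e-12)
      if (sum(rowSums(m) * colSums(m)) != sum(m)^2) {
        expect_lt(abs(kappa_coef(m) - brute_kappa(m)), 1e-12)
      }
    }
  })
})

test_that("kappa edge laws hold", {
  # kappa = 1 iff no off-diagonal mass
  d <- diag(c(5L, 9L, 2L))
  expect_equal(kappa_coef(d), 1)
  d[1, 2] <- 1L
  expect_lt(kappa_coef(d), 1)
  # kappa = 0 whenever cells equal the product of the marginals / N
  p <- outer(c(0.6, 0.4), c(0.3, 0.7)) * 100
  expect_equal(kappa_coef(p), 0, tolerance = 1e-12)
  # undefined case is flagged
  one <- matrix(c(7, 0, 0, 0), 2)
  expect_warning(k <- kappa_coef(one), "undefined")
  expect_true(is.na(k))
  expect_error(overall_accuracy(matrix(0, 2, 2)), "N = 0")
})

oracle_model <- function() {
  # stub that memorises the training rows' labels and predicts by lookup
  list(
    fit = function(x, y, seed) list(x = x, y = y),
    predict = function(fit, x) {
      idx <- apply(x, 1, function(r) {
        which.min(colSums((t(fit$x) - r)^2))
      })
      fit$y[idx]
    }
  )
}

test_that("cross-validation reports the expected extremes", {
  fx <- make_separable(n_per = 20, d = 3, gap = 8, seed = 6)
  rep1 <- cross_validate(fx$x, fx$y, model = oracle_model(), k = 10,
                         seed = 1)
  expect_equal(rep1$mean_oa, 100)
  expect_equal(rep1$mean_kappa, 1)
  expect_equal(sum(tidy(rep1)$n_test), 40)

  const_model <- list(fit = function(x, y, seed) levels(y)[1],
                      predict = function(fit, x) {
                        factor(rep(fit, nrow(x)))
                      })
  rep2 <- cross_validate(fx$x, fx$y, model = const_model, k = 10, seed = 1)
  expect_true(all(tidy(rep2)$kappa == 0))
  expect_equal(rep2$mean_oa, 50)

  rep3 <- cross_validate(fx$x, fx$y, model = oracle_model(), k = 10,
                         seed = 1)
  expect_identical(glance(rep1), glance(rep3))
  expect_identical(rep1$fold_assignment, rep3$fold_assignment)
})

test_that("fold bookkeeping is consistent", {
  fx <- make_separable(n_per = 15, seed = 7)
  rep1 <- cross_validate(fx$x, fx$y, model = oracle_model(), k = 5,
                         seed = 3)
  expect_equal(rep1$mean_oa, mean(tidy(rep1)$oa))
  expect_equal(sum(unclass(rep1$pooled)), 30)
  # pooled matrix equals the sum of the per-fold matrices
  acc <- Reduce(`+`, lapply(rep1$folds$confusion, unclass))
  expect_equal(unclass(rep1$pooled), acc, ignore_attr = TRUE)
})

test_that("model comparison shares folds and validates names", {
  fx <- make_rings(n_per = 25, seed = 8)
  out <- compare_models(fx$x, fx$y, models = c("rf", "xgboost"), k = 5,
                        seed = 2, ntree = 100)
  expect_identical(out$model, c("rf", "xgboost"))
  reports <- attr(out, "reports")
  expect_identical(reports$rf$fold_assignment,
                   reports$xgboost$fold_assignment)
  expect_type(attr(out, "fold_hash"), "character")
  expect_error(
    compare_models(fx$x, fx$y, models = "mlp", k = 5, seed = 2),
    "unknown model")
})

test_that("band-input comparison adds a full row and repeats identically", {
  sp <- generate_spectra(synthetic_design(seed = 9,
                                          include_reference = FALSE),
                         n_bands = 24)
  sp0 <- sp[sp$n_level == "N0", ]
  y <- ifelse(sp0$class == "low_N_efficient", "eff", "ineff")
  wl <- band_wavelengths(sp0)
  out <- compare_band_inputs(sp0, y,
                             subsets = list(w1 = wl[3:6], w2 = wl[3:6]),
                             model = "rf", k = 5, seed = 4, ntree = 100)
  expect_identical(out$input, c("full", "w1", "w2"))
  expect_equal(out$n_bands, c(24L, 4L, 4L))
  # identical subsets give identical rows
  expect_equal(out[out$input == "w1", -1], out[out$input == "w2", -1])
  expect_error(
    compare_band_inputs(sp0, y, subsets = list(bad = numeric(0)),
                        model = "rf", k = 5, seed = 4),
    "no bands|not present")
})

test_that("folds whose training data collapse to one class are skipped", {
  x <- matrix(rnorm(20), 10, 2)
  # the only minority sample sits in fold 2, so fold 2's training data
  # (folds 1 and 3) hold a single class and that fold must be skipped
  y2 <- factor(c("b", rep("a", 9)))
  f2 <- c(2, rep(c(1, 2, 3), 3))
  expect_warning(
    r <- cross_validate(x, y2, model = oracle_model(), folds = f2,
                        seed = 1),
    "single class")
  expect_identical(r$skipped_folds, 2)
  expect_equal(nrow(tidy(r)), 2)
})
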