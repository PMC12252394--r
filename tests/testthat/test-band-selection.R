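test_that("PLS1 reduces to known regressions at the extremes", {
  withr::with_seed(1, {
    x1 <- matrix(rnorm(30), 30, 1)
    y1 <- 2 + 3 * x1[, 1] + rnorm(30, 0, 0.1)
  })
  f1 <- pls_fit(x1, y1, a = 1)
  ols1 <- lm(y1 ~ x1[, 1])
  expect_equal(f1$coefficients, unname(coef(ols1)[2]), tolerance = 1e-10)
  expect_equal(f1$intercept, unname(coef(ols1)[1]), tolerance = 1e-10)

  withr::with_seed(2, {
    x <- matrix(rnorm(20 * 4), 20, 4)
    y <- x %*% c(1, -2, 0.5, 3) + rnorm(20, 0, 0.2)
  })
  f <- pls_fit(x, y, a = 4)
  expect_equal(predict(f, x), unname(fitted(lm(y ~ x))), tolerance = 1e-8)

  fc <- pls_fit(x, rep(5, 20), a = 2)
  expect_equal(fc$coefficients, rep(0, 4))
  expect_equal(predict(fc, x), rep(5, 20))

  expect_error(pls_fit(matrix(1, 10, 2), rnorm(10), a = 1),
               "zero variance")
  expect_error(pls_fit(x, y, a = 25), "min")
})

test_that("forced-reduction schedule hits its boundary values exactly", {
  for (p in c(2, 7, 50, 224)) {
    for (n in c(2, 10, 50)) {
      r <- nitrospec:::cars_ratio_schedule(p, n)
      expect_equal(r[1], 1, tolerance = 1e-12)
      expect_equal(r[n], 2 / p, tolerance = 1e-12)
      expect_true(all(diff(r) <= 1e-12))
    }
  }
  expect_equal(nitrospec:::cars_ratio_schedule(2, 2), c(1, 1))
})

# study-sized two-class spectra fixture
selection_fixture <- function(seed = 1, n_bands = 224, noise_sd = 0.01) {
  d <- synthetic_design(seed = seed, noise_sd = noise_sd,
                        include_reference = FALSE)
  sp <- generate_spectra(d, n_bands = n_bands)
  sp0 <- sp[sp$n_level == "N0", ]
  list(spectra = sp0,
       labels = ifelse(sp0$class == "low_N_efficient",
                       "efficient", "inefficient"),
       windows = d$signature_bands)
}

test_that("lasso screen finds a planted exact linear signal", {
  # independent bands so the planted band is identifiable, not aliased
  withr::with_seed(3, x <- matrix(rnorm(80 * 40, 0.3, 0.05), 80, 40))
  sp <- tibble::as_tibble(x, .name_repair = ~ band_col_names(
    seq(400, 1000, length.out = 40)))
  j <- 17
  target <- as.numeric(x[, j] > median(x[, j]))
  sub <- lasso_screen(sp, target, lasso_config(seed = 1))
  expect_true(j %in% sub$indices)
  expect_identical(sub$stage, "lasso")
  expect_true(all(diff(sub$wavelengths) > 0))
})

test_that("lasso screen handles degenerate penalty grids and targets", {
  fx <- selection_fixture(seed = 4, n_bands = 30)
  # only enormous penalties: full shrinkage everywhere -> nothing to return
  expect_error(
    lasso_screen(fx$spectra, fx$labels,
                 lasso_config(alpha_grid = c(1e6, 1e7))),
    "no bands")
  # constant target: every coefficient is zero at every penalty
  expect_error(
    lasso_screen(fx$spectra, rep(1, nrow(fx$spectra)),
                 lasso_config(seed = 1)),
    "2 classes|no bands")
  expect_error(lasso_screen(fx$spectra, fx$labels,
                            lasso_config(alpha_grid = numeric(0))),
               "alpha_grid")
})

test_that("lasso selection is invariant to band column order", {
  fx <- selection_fixture(seed = 5, n_bands = 40)
  sub1 <- lasso_screen(fx$spectra, fx$labels, lasso_config(seed = 2))
  meta <- setdiff(names(fx$spectra), band_cols(fx$spectra))
  perm <- withr::with_seed(9, sample(band_cols(fx$spectra)))
  sub2 <- lasso_screen(fx$spectra[, c(meta, perm)], fx$labels,
                       lasso_config(seed = 2))
  expect_equal(sort(sub1$wavelengths), sort(sub2$wavelengths))
})

test_that("CARS trace obeys its structural invariants and is reproducible", {
  fx <- selection_fixture(seed = 1)
  cfg <- cars_config(n_runs = 30, seed = 7)
  out <- cars_refine(fx$spectra, fx$labels, cfg)
  tr <- out$trace
  expect_true(all(diff(tr$n_retained) <= 0))
  expect_equal(tr$ratio[1], 1, tolerance = 1e-12)
  expect_equal(tr$ratio[nrow(tr)], 2 / 224, tolerance = 1e-12)
  expect_equal(tr$rmsecv[out$chosen_run], min(tr$rmsecv, na.rm = TRUE))
  expect_setequal(out$indices, tr$retained[[out$chosen_run]])

  out2 <- cars_refine(fx$spectra, fx$labels, cfg)
  expect_identical(out$trace, out2$trace)
  expect_identical(out$wavelengths, out2$wavelengths)
})

test_that("CARS keeps a strongly predictive band among pure noise", {
  withr::with_seed(11, {
    n <- 80
    x <- matrix(rnorm(n * 20, 0.3, 0.05), n, 20)
    y <- rep(c(0, 1), each = n / 2)
    x[, 7] <- 0.3 + 0.1 * y + rnorm(n, 0, 0.005)  # high-SNR signal band
  })
  sp <- tibble::as_tibble(x, .name_repair = ~ band_col_names(
    seq(400, 1000, length.out = 20)))
  sp <- dplyr::mutate(sp, sample_id = as.character(dplyr::row_number()),
                      .before = 1)
  out <- cars_refine(sp, y, cars_config(n_runs = 25, seed = 3))
  expect_true(7 %in% out$indices)
})

test_that("the p = 2 boundary keeps both bands through forced reduction", {
  withr::with_seed(12, {
    x <- matrix(rnorm(40), 20, 2)
    y <- as.numeric(x[, 1] + 0.5 * x[, 2] + rnorm(20, 0, 0.1) > 0)
  })
  sp <- tibble::as_tibble(x, .name_repair = ~ band_col_names(c(500, 700)))
  out <- cars_refine(sp, y, cars_config(n_runs = 2, ars = FALSE, seed = 1))
  expect_equal(out$trace$n_retained, c(2L, 2L))
})

test_that("lasso_cars composes the two stages with full provenance", {
  fx <- selection_fixture(seed = 2, n_bands = 120)
  sub <- lasso_cars(fx$spectra, fx$labels,
                    lasso_config(seed = 1),
                    cars_config(n_runs = 20, seed = 2))
  lasso_sub <- attr(sub, "lasso_subset")
  expect_identical(sub$stage, "lasso_cars")
  expect_identical(lasso_sub$stage, "lasso")
  expect_true(all(sub$indices %in% lasso_sub$indices))
  expect_true(all(sub$wavelengths %in% lasso_sub$wavelengths))
  expect_false(is.null(sub$trace))
})

test_that("a singleton lasso result passes through CARS unchanged", {
  fx <- selection_fixture(seed = 6, n_bands = 30)
  single <- nitrospec:::new_band_subset(5L, band_wavelengths(fx$spectra)[5],
                                        stage = "lasso")
  # emulate composition after a 1-band screen via select_bands + refine pre
  expect_error(cars_refine(fx$spectra, fx$labels, subset = single),
               ">= 2 bands")
})

test_that("select_bands restricts columns and validates membership", {
  fx <- selection_fixture(seed = 1, n_bands = 20)
  wl <- band_wavelengths(fx$spectra)[c(3, 9)]
  out <- select_bands(fx$spectra, wl)
  expect_equal(band_wavelengths(out), wl)
  expect_error(select_bands(fx$spectra, 123.45), "not present")
})
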