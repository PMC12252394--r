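#' Partial least squares regression (PLS1, NIPALS)
#'
#' Fits a single-response PLS regression on centred data by the NIPALS
#' algorithm. With `A = min(n - 1, p)` components on full-rank data the
#' fit reproduces ordinary least squares; with fewer components it is the
#' usual shrunken PLS solution whose coefficient magnitudes CARS uses as
#' variable-importance weights.
#'
#' @param x Numeric matrix (n x p).
#' @param y Numeric response of length n.
#' @param a Number of latent components, `1 <= a <= min(n - 1, p)`.
#' @return A `pls_fit` list with `coefficients` (length p), `intercept`,
#'   and `n_components` (components actually extracted; deflation stops
#'   early when the residual covariance vanishes, e.g. for constant y).
#' @export
pls_fit <- function(x, y, a) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  p <- ncol(x)
  assert_that(length(y) == n, "`y` length must match rows of `x`")
  assert_that(is_count(a) && a <= min(n - 1, p),
              "`a` must satisfy 1 <= a <= min(n - 1, p)")
  mx <- colMeans(x)
  my <- mean(y)
  xc <- sweep(x, 2, mx)
  yc <- y - my
  if (all(apply(xc, 2, function(col) all(abs(col) < 1e-12)))) {
    abort("all predictors have zero variance after centring")
  }

  w_mat <- matrix(0, p, a)
  p_mat <- matrix(0, p, a)
  q_vec <- numeric(a)
  n_comp <- 0L
  for (comp in seq_len(a)) {
    cv <- drop(crossprod(xc, yc))
    nrm <- sqrt(sum(cv^2))
    if (nrm < 1e-12) break  # nothing left to explain
    w <- cv / nrm
    t_score <- drop(xc %*% w)
    tt <- sum(t_score^2)
    if (tt < 1e-24) break
    p_load <- drop(crossprod(xc, t_score)) / tt
    q <- sum(yc * t_score) / tt
    xc <- xc - tcrossprod(t_score, p_load)
    yc <- yc - q * t_score
    w_mat[, comp] <- w
    p_mat[, comp] <- p_load
    q_vec[comp] <- q
    n_comp <- comp
  }
  if (n_comp == 0L) {
    b <- numeric(p)
  } else {
    w_mat <- w_mat[, seq_len(n_comp), drop = FALSE]
    p_mat <- p_mat[, seq_len(n_comp), drop = FALSE]
    q_vec <- q_vec[seq_len(n_comp)]
    b <- drop(w_mat %*% solve(crossprod(p_mat, w_mat), q_vec))
  }
  structure(list(coefficients = b, intercept = my - sum(mx * b),
                 n_components = n_comp),
            class = "pls_fit")
}

#' @rdname pls_fit
#' @param object A `pls_fit`.
#' @param newdata Numeric matrix with p columns.
#' @param ... Unused.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

# Cross-validated RMSE of a PLS model (the subset-quality criterion used
# inside CARS). Folds are contiguous over a seeded permutation.
pls_rmsecv <- function(x, y, a, folds = 5, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  folds <- min(folds, n)
  perm <- with_seed(seed, sample.int(n))
  fold_id <- rep_len(seq_len(folds), n)[order(perm)]
  press <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (all(test) || !any(test)) next
    a_f <- min(a, sum(!test) - 1, ncol(x))
    if (a_f < 1) next
    fit <- pls_fit(x[!test, , drop = FALSE], y[!test], a_f)
    pred <- predict(fit, x[test, , drop = FALSE])
    press <- press + sum((y[test] - pred)^2)
  }
  sqrt(press / n)
}
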