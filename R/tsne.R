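# Exact t-SNE, sized for the handful of variety points this workflow
# embeds (n is typically 12-13). Gaussian kernels with per-point precision
# calibrated to the target perplexity by bisection; Student-t similarities
# in the embedding; gradient descent with momentum and adaptive gains.

# Conditional -> joint similarity matrix P for a data matrix.
tsne_p_matrix <- function(x, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- d2[i, -i]
    for (tries in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) {
        h <- 0
        pr <- w
      } else {
        pr <- w / sw
        h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {   # entropy too high -> sharpen
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    p[i, -i] <- pr
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

tsne_impl <- function(x, dims, perplexity, n_iter, seed,
                      eta = 100, momentum_switch = 250,
                      exaggeration_stop = 100) {
  n <- nrow(x)
  p <- tsne_p_matrix(x, perplexity)
  with_seed(seed, {
    y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
    inc <- matrix(0, n, dims)
    gains <- matrix(1, n, dims)
    p_run <- p * 4  # early exaggeration
    for (iter in seq_len(n_iter)) {
      if (iter == exaggeration_stop + 1) p_run <- p
      ydist2 <- as.matrix(dist(y))^2
      num <- 1 / (1 + ydist2)
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      mult <- (p_run - q) * num
      grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
      mom <- if (iter <= momentum_switch) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains <- pmax(gains, 0.01)
      inc <- mom * inc - eta * gains * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    y
  })
}
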