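# Shared fixtures and independent oracles, built in code at test time.

# Two well-separated Gaussian blobs.
make_blobs <- function(n_per = 6, d = 4, sep = 10, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n_per * d, 0, sd), n_per, d),
      matrix(rnorm(n_per * d, sep, sd), n_per, d)
    )
    rownames(x) <- paste0("p", seq_len(2 * n_per))
    list(x = x, blob = rep(1:2, each = n_per))
  })
}

# Linearly separable two-class features.
make_separable <- function(n_per = 15, d = 5, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, gap), n_per, d))
    list(x = x, y = factor(rep(c("a", "b"), each = n_per)))
  })
}

# Nonlinear (concentric rings) two-class features: separable by an RBF
# machine, not by a linear boundary.
make_rings <- function(n_per = 30, noise = 0.08, seed = 1) {
  withr::with_seed(seed, {
    th <- runif(2 * n_per, 0, 2 * pi)
    r <- c(rep(1, n_per), rep(2.2, n_per)) + rnorm(2 * n_per, 0, noise)
    list(x = cbind(r * cos(th), r * sin(th)),
         y = factor(rep(c("inner", "outer"), each = n_per)))
  })
}

# Brute-force agglomerative clustering with complete linkage: keeps all
# clusters as index sets and rescans every pair distance at each step.
brute_complete_linkage <- function(x) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(j, i)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_d)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# Two-cluster assignment from the brute-force oracle (second-to-last
# partition), as a canonical membership vector.
brute_two_clusters <- function(x) {
  res <- brute_complete_linkage(x)
  part <- res$partitions[[length(res$partitions) - 1]]
  out <- integer(nrow(as.matrix(x)))
  for (k in seq_along(part)) out[part[[k]]] <- k
  out
}

# Canonical form of a two-group membership vector so that labellings can
# be compared up to cluster-id permutation.
canon_two <- function(v) {
  if (v[1] != 1) v <- 3 - v
  v
}

# Direct evaluation of overall accuracy and kappa from the definition,
# written independently of the package implementation.
brute_oa <- function(m) {
  100 * sum(diag(m)) / sum(m)
}
brute_kappa <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

# Two interleaved noisy spirals: a nonlinear two-class problem where a
# single fixed-hyperparameter RBF boundary underfits, so refining the
# margin structure helps.
make_spirals <- function(n_per = 40, noise = 0.5, seed = 31) {
  withr::with_seed(seed, {
    t <- seq(0.5, 3 * pi, length.out = n_per)
    x <- rbind(cbind(t * cos(t), t * sin(t)),
               cbind(t * cos(t + pi), t * sin(t + pi))) +
      matrix(rnorm(4 * n_per, 0, noise), 2 * n_per, 2)
    list(x = x, y = factor(rep(c("a", "b"), each = n_per)))
  })
}
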