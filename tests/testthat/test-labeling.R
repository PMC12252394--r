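test_that("standardize centres, scales and zeroes constant columns", {
  withr::with_seed(1, x <- matrix(rnorm(60, 5, 3), 15, 4))
  z <- standardize(x)
  expect_equal(colMeans(z), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 4), tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  xc <- cbind(x, 7)
  expect_equal(standardize(xc)[, 5], rep(0, 15))
})

test_that("t-SNE embedding is deterministic and respects structure", {
  b <- make_blobs(n_per = 6, seed = 2)
  cfg <- embedding_config(out_dims = 2, perplexity = 3, n_iter = 400,
                          seed = 9)
  y1 <- tsne_embed(b$x, cfg)
  y2 <- tsne_embed(b$x, cfg)
  expect_identical(y1, y2)

  # two planted blobs stay separated in the embedding
  d <- as.matrix(dist(y1))
  within <- c(d[1:6, 1:6][upper.tri(diag(6))],
              d[7:12, 7:12][upper.tri(diag(6))])
  between <- d[1:6, 7:12]
  expect_gt(min(between), max(within))

  # a duplicated row pair stays mutually nearest
  x <- rbind(b$x, b$x[1, , drop = FALSE])
  rownames(x) <- c(rownames(b$x), "dup")
  y <- tsne_embed(x, embedding_config(out_dims = 2, perplexity = 3,
                                      n_iter = 400, seed = 9))
  dd <- as.matrix(dist(y))
  diag(dd) <- Inf
  expect_equal(which.min(dd[13, ]), 1L, ignore_attr = TRUE)
  expect_equal(which.min(dd[1, ]), 13L, ignore_attr = TRUE)
})

test_that("over-large perplexity is rejected", {
  b <- make_blobs(n_per = 3, seed = 1)
  expect_error(
    tsne_embed(b$x, embedding_config(perplexity = 2, n_iter = 10)),
    "perplexity")
})

test_that("two-group clustering matches the brute-force oracle", {
  expect_setequal(hcluster_two(matrix(c(0, 0, 1, 1), 2, 2))$assignment,
                  1:2)
  for (s in 1:12) {
    n <- sample(4:8, 1)
    withr::with_seed(s, x <- matrix(rnorm(n * 3), n, 3))
    got <- hcluster_two(x)
    expect_equal(canon_two(unname(got$assignment)),
                 canon_two(brute_two_clusters(x)),
                 ignore_attr = TRUE, info = paste("seed", s))
    # full merge-height sequence agrees with the rescanning oracle
    expect_equal(sort(got$tree$height),
                 sort(brute_complete_linkage(x)$heights),
                 tolerance = 1e-12, info = paste("seed", s))
  }
  b <- make_blobs(n_per = 5, seed = 3)
  cl <- hcluster_two(b$x)$assignment
  expect_equal(canon_two(unname(cl)), canon_two(b$blob),
               ignore_attr = TRUE)
})

test_that("anchoring orients clusters and excludes the reference", {
  assignment <- c(ref = 1L, a = 1L, b = 2L, c = 2L, d = 1L)
  lab <- anchor_labels(assignment, "ref", condition = "low_N")
  expect_setequal(lab$variety, c("a", "b", "c", "d"))
  expect_identical(lab$class[lab$variety %in% c("a", "d")],
                   c("efficient", "efficient"))
  expect_identical(lab$class[lab$variety %in% c("b", "c")],
                   c("inefficient", "inefficient"))
  # swapping cluster ids changes nothing
  lab2 <- anchor_labels(3L - assignment, "ref", condition = "low_N")
  expect_equal(lab, lab2, ignore_attr = TRUE)
  # reference alone in its cluster -> everything else inefficient
  lab3 <- anchor_labels(c(ref = 1L, a = 2L, b = 2L), "ref")
  expect_true(all(lab3$class == "inefficient"))
  expect_error(anchor_labels(assignment, "zz"), "not present")
})

test_that("condition labels combine into three disjoint groups", {
  mk <- function(eff, all, cond) {
    tibble::tibble(variety = all, condition = cond,
                   class = ifelse(all %in% eff, "efficient",
                                  "inefficient"))
  }
  vars <- paste0("v", 1:4)
  grp <- combine_conditions(mk(c("v1", "v2"), vars, "low_N"),
                            mk("v3", vars, "high_N"))
  expect_identical(grp$group,
                   c("low_N_efficient", "low_N_efficient",
                     "high_N_efficient", "inefficient"))
  expect_error(
    combine_conditions(mk("v1", vars, "low_N"), mk("v1", vars, "high_N")),
    "both conditions")

  # the trial-sized partition: 6 + 2 + 4 varieties
  v12 <- sprintf("v%02d", 1:12)
  grp12 <- combine_conditions(
    mk(v12[c(1, 2, 3, 4, 8, 12)], v12, "low_N"),
    mk(v12[c(7, 10)], v12, "high_N"))
  expect_equal(as.integer(table(grp12$group)[c("low_N_efficient",
                                               "high_N_efficient",
                                               "inefficient")]),
               c(6L, 2L, 4L))
})

test_that("fertilization strategies are a fixed lookup", {
  expect_match(strategy_for("high_N_efficient"), "delay top-dressing")
  expect_match(strategy_for("inefficient"), "Maintain the standard")
  expect_match(strategy_for("low_N_efficient"), "basal nitrogen")
  expect_length(strategy_for(c("inefficient", "inefficient")), 2)
  expect_error(strategy_for("super_efficient"), "unknown")
})

test_that("labeling is invariant to variety row order", {
  d <- synthetic_design(seed = 6)
  ph <- generate_phenotypes(d)
  lab1 <- label_efficiency(ph, "low_N", cfg = embedding_config(seed = 4))
  ph_shuffled <- withr::with_seed(1, ph[sample.int(nrow(ph)), ])
  lab2 <- label_efficiency(ph_shuffled, "low_N",
                           cfg = embedding_config(seed = 4))
  expect_identical(
    dplyr::arrange(as.data.frame(lab1), variety),
    dplyr::arrange(as.data.frame(lab2), variety),
    ignore_attr = TRUE)
})

test_that("reflectance clustering scores agreement with truth labels", {
  # expression heterogeneity off: spectra are then a deterministic
  # function of the class alone, so clustering must recover it exactly
  d <- synthetic_design(seed = 11, noise_sd = 0, pheno_noise_cv = 0.02,
                        signature_expression_sd = 0)
  sp <- generate_spectra(d, n_bands = 40)
  ph <- generate_phenotypes(d)
  truth <- label_efficiency(ph, "low_N", cfg = embedding_config(seed = 2))
  sp_low <- sp[sp$n_level == "N0", ]
  res <- reflectance_cluster_baseline(
    sp_low, truth, reference_variety = "Jimai22",
    cfg = embedding_config(perplexity = 10, n_iter = 300, seed = 5))
  # noise-free spectra are a deterministic function of class, and the
  # noise-free-spectra classes match the planted phenotype classes here
  expect_equal(res$accuracy, 1)
  expect_equal(res$n_varieties, 12)

  # agreement fraction equals an independent recomputation
  joined <- dplyr::inner_join(res$labels, truth, by = "variety")
  expect_equal(res$accuracy, mean(joined$class.x == joined$class.y))
})
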