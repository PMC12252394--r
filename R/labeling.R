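#' t-SNE embedding configuration
#'
#' @param out_dims Embedding dimension, 2 or 3 (default 3, matching the
#'   three-dimensional embeddings the labelling procedure inspects).
#' @param perplexity Positive perplexity; must satisfy
#'   `perplexity < (n - 1) / 3` for `n` embedded points. The default 3.5
#'   suits the 12-13 variety points the procedure typically embeds.
#' @param n_iter Gradient-descent iterations (default 1000).
#' @param seed Integer seed controlling the random embedding initialisation.
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(out_dims = 3, perplexity = 3.5, n_iter = 1000,
                             seed = 1L) {
  assert_that(out_dims %in% c(2, 3), "`out_dims` must be 2 or 3")
  assert_that(is.numeric(perplexity) && perplexity > 0,
              "`perplexity` must be > 0")
  assert_that(is_count(n_iter), "`n_iter` must be a positive integer")
  structure(list(out_dims = as.integer(out_dims), perplexity = perplexity,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "embedding_config")
}

#' Column-wise standardisation
#'
#' Centres every column to mean zero and scales to unit sample standard
#' deviation; constant columns are mapped to all-zero columns rather than
#' NaN.
#'
#' @param x Numeric matrix or data frame with >= 2 rows.
#' @return Numeric matrix of the same shape.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "`x` needs >= 2 rows to standardise")
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- Inf  # constant columns -> zeros
  sweep(sweep(x, 2, mu), 2, s, "/")
}

#' Embed points with t-SNE
#'
#' Deterministic for a fixed `cfg$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param x Numeric matrix (rows = points). Row names are carried over.
#' @param cfg An [embedding_config()].
#' @return Numeric matrix `nrow(x)` x `cfg$out_dims`.
#' @export
tsne_embed <- function(x, cfg = embedding_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  assert_that(n >= 4, "need >= 4 points to embed")
  if (cfg$perplexity >= (n - 1) / 3) {
    abort(sprintf(
      "perplexity %.2f too large for %d points (needs < (n - 1) / 3 = %.2f)",
      cfg$perplexity, n, (n - 1) / 3))
  }
  y <- tsne_impl(x, dims = cfg$out_dims, perplexity = cfg$perplexity,
                 n_iter = cfg$n_iter, seed = cfg$seed)
  rownames(y) <- rownames(x)
  y
}

#' Agglomerative clustering into two groups
#'
#' Complete-linkage hierarchical clustering on Euclidean distances, cut at
#' k = 2. Starting from singletons, the two closest clusters are merged
#' repeatedly, with inter-cluster distance taken as the maximum pairwise
#' point distance (complete linkage).
#'
#' @param coords Numeric matrix of points (>= 2 rows); row names identify
#'   the points.
#' @return A list with `assignment` (named integer vector of cluster ids
#'   1/2) and `tree` (the full `stats::hclust` object, whose `merge` and
#'   `height` record the merge sequence).
#' @export
hcluster_two <- function(coords) {
  coords <- as.matrix(coords)
  assert_that(nrow(coords) >= 2, "need >= 2 points to cluster")
  tree <- hclust(dist(coords), method = "complete")
  assignment <- cutree(tree, k = 2)
  if (!is.null(rownames(coords))) names(assignment) <- rownames(coords)
  list(assignment = assignment, tree = tree)
}

#' Anchor cluster ids to efficiency classes via a reference variety
#'
#' The cluster containing the reference variety is labelled `efficient`,
#' the other `inefficient`. The reference itself is excluded from the
#' reported variety set (it is a control), but recorded in the attributes.
#'
#' @param assignment Named integer vector of cluster ids (from
#'   [hcluster_two()]); names are variety ids.
#' @param reference_variety Variety id anchoring the efficient cluster.
#' @param condition Condition tag stored in the output (e.g. `"low_N"`).
#' @return A tibble (`variety`, `condition`, `class`) for all
#'   non-reference varieties, with attributes `reference` and
#'   `reference_cluster`.
#' @export
anchor_labels <- function(assignment, reference_variety,
                          condition = "stress") {
  assert_that(!is.null(names(assignment)),
              "`assignment` must be named by variety")
  assert_that(reference_variety %in% names(assignment),
              paste0("reference variety '", reference_variety,
                     "' not present in the assignment"))
  ref_cluster <- assignment[[reference_variety]]
  keep <- setdiff(names(assignment), reference_variety)
  out <- tibble(
    variety = keep,
    condition = condition,
    class = unname(ifelse(assignment[keep] == ref_cluster,
                          "efficient", "inefficient"))
  )
  attr(out, "reference") <- reference_variety
  attr(out, "reference_cluster") <- unname(ref_cluster)
  out
}

#' Label varieties by nitrogen efficiency under one stress condition
#'
#' Runs the full labelling chain: the eight agronomic indices for the
#' stress contrast, column standardisation, t-SNE embedding (optional),
#' complete-linkage clustering into two groups, and anchoring on the
#' reference variety.
#'
#' @param pheno Phenotype tibble (see [index_table()]); must include the
#'   reference variety.
#' @param condition `"low_N"` (contrast N0 vs N1) or `"high_N"` (N2 vs N1).
#' @param reference_variety Reference variety id; defaults to `"Jimai22"`
#'   for low-N and `"Shannong28"` for high-N.
#' @param cfg An [embedding_config()].
#' @param skip_tsne If TRUE, cluster the standardised indices directly
#'   (fully deterministic); default FALSE.
#' @param n_denominator,nfue_mode Passed to [index_table()].
#' @return An efficiency-labels tibble as from [anchor_labels()], with the
#'   index table and embedding attached as attributes `indices` and
#'   `embedding`.
#' @export
label_efficiency <- function(pheno, condition = c("low_N", "high_N"),
                             reference_variety = NULL,
                             cfg = embedding_config(),
                             skip_tsne = FALSE,
                             n_denominator = 225,
                             nfue_mode = "centered") {
  condition <- match.arg(condition)
  contrast <- if (condition == "low_N") "N0_vs_N1" else "N2_vs_N1"
  if (is.null(reference_variety)) {
    reference_variety <- if (condition == "low_N") "Jimai22" else "Shannong28"
  }
  indices <- index_table(pheno, contrast = contrast,
                         n_denominator = n_denominator,
                         nfue_mode = nfue_mode)
  assert_that(reference_variety %in% indices$variety,
              paste0("reference variety '", reference_variety,
                     "' has no phenotypes for contrast ", contrast))
  m <- as.matrix(indices[, c("WY", "ANA", "WDMM", "TGW",
                             "NUE", "AENF", "NFUE", "NT")])
  rownames(m) <- indices$variety
  z <- standardize(m)
  emb <- if (skip_tsne) z else tsne_embed(z, cfg)
  cl <- hcluster_two(emb)
  out <- anchor_labels(cl$assignment, reference_variety,
                       condition = condition)
  attr(out, "indices") <- indices
  attr(out, "embedding") <- emb
  attr(out, "seed") <- cfg$seed
  out
}

#' Combine low-N and high-N efficiency labels into three groups
#'
#' Varieties efficient under low-N stress become `low_N_efficient`, those
#' efficient under high-N stress `high_N_efficient`, the rest
#' `inefficient`. A variety efficient under both conditions raises an
#' error listing the conflicting varieties (the grouping assumes the two
#' efficient sets are disjoint).
#'
#' @param labels_lowN,labels_highN Label tibbles from [label_efficiency()]
#'   (or [anchor_labels()]) over the same variety set.
#' @return A tibble (`variety`, `group`).
#' @export
combine_conditions <- function(labels_lowN, labels_highN) {
  assert_that(setequal(labels_lowN$variety, labels_highN$variety),
              "the two label sets must cover the same varieties")
  eff_low <- labels_lowN$variety[labels_lowN$class == "efficient"]
  eff_high <- labels_highN$variety[labels_highN$class == "efficient"]
  overlap <- intersect(eff_low, eff_high)
  if (length(overlap) > 0) {
    abort(paste0("varieties efficient under both conditions: ",
                 paste(sort(overlap), collapse = ", "),
                 " (the three-group partition assumes disjoint sets)"))
  }
  varieties <- sort(unique(labels_lowN$variety))
  group <- dplyr::case_when(
    varieties %in% eff_low ~ "low_N_efficient",
    varieties %in% eff_high ~ "high_N_efficient",
    TRUE ~ "inefficient"
  )
  tibble(variety = varieties, group = group)
}

#' Fertilization strategy for an efficiency group
#'
#' Static lookup mapping each of the three efficiency groups to the
#' recommended nitrogen fertilization strategy at normal nitrogen levels.
#'
#' @param group One of `"inefficient"`, `"low_N_efficient"`,
#'   `"high_N_efficient"` (vectorised).
#' @return Character vector of strategy descriptors.
#' @export
strategy_for <- function(group) {
  lookup <- c(
    inefficient = paste(
      "Maintain the standard nitrogen application; stable normal-level",
      "fertilization gives these varieties their best uptake efficiency."),
    low_N_efficient = paste(
      "Reduce basal nitrogen before planting and supplement small amounts",
      "of phosphorus/potassium foliar fertilizer to balance nutrients."),
    high_N_efficient = paste(
      "Increase nitrogen application and delay top-dressing to the",
      "critical growth stages (e.g. heading) to exploit high-N potential.")
  )
  bad <- setdiff(unique(group), names(lookup))
  assert_that(length(bad) == 0,
              paste("unknown efficiency group:", paste(bad, collapse = ", ")))
  unname(lookup[group])
}

#' Cluster raw reflectance and score agreement with phenotype-based labels
#'
#' The baseline experiment: run t-SNE + complete-linkage clustering
#' directly on canopy reflectance samples, assign each variety by majority
#' vote of its samples' clusters, anchor on the reference variety, and
#' report the agreement fraction with the phenotype-derived truth labels.
#'
#' @param spectra Spectra tibble restricted to a single stress condition
#'   (must contain `variety` and `band_*` columns, reference included).
#' @param truth Label tibble (`variety`, `class`) from
#'   [label_efficiency()] for the matching condition.
#' @param reference_variety Variety anchoring the efficient cluster.
#' @param cfg An [embedding_config()]; its perplexity applies at the
#'   sample level, so larger values than the variety-level default are
#'   appropriate.
#' @param skip_tsne Cluster standardised reflectance directly if TRUE.
#' @return A list with `accuracy` (fraction of non-reference varieties
#'   whose cluster label matches `truth`), `labels` (per-variety tibble)
#'   and `n_varieties`.
#' @export
reflectance_cluster_baseline <- function(spectra, truth,
                                         reference_variety,
                                         cfg = embedding_config(
                                           perplexity = 10),
                                         skip_tsne = FALSE) {
  assert_that("variety" %in% names(spectra),
              "`spectra` must have a `variety` column")
  assert_that(reference_variety %in% spectra$variety,
              "reference variety missing from `spectra`")
  missing <- setdiff(truth$variety, spectra$variety)
  assert_that(length(missing) == 0,
              paste("varieties in `truth` missing from `spectra`:",
                    paste(missing, collapse = ", ")))
  x <- standardize(spectra_matrix(spectra))
  emb <- if (skip_tsne) x else tsne_embed(x, cfg)
  cl <- hcluster_two(emb)$assignment
  # variety-level majority vote over its samples' clusters
  votes <- tibble(variety = spectra$variety, cluster = unname(cl)) |>
    group_by(.data$variety) |>
    summarise(cluster = {
      tb <- table(.data$cluster)
      as.integer(names(tb)[which.max(tb)])
    }, .groups = "drop")
  assignment <- setNames(votes$cluster, votes$variety)
  labels <- anchor_labels(assignment, reference_variety,
                          condition = "reflectance")
  joined <- dplyr::inner_join(labels,
                              dplyr::select(truth, "variety",
                                            truth_class = "class"),
                              by = "variety")
  list(
    accuracy = mean(joined$class == joined$truth_class),
    labels = labels,
    n_varieties = nrow(joined)
  )
}
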