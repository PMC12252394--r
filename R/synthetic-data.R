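#' Describe a synthetic nitrogen-response field trial
#'
#' Builds the design object consumed by [generate_spectra()] and
#' [generate_phenotypes()]. The defaults mirror the field trial the package
#' models: 12 candidate winter-wheat varieties plus two reference varieties,
#' three nitrogen applications (0, 225 and 450 kg/ha, i.e. low-N stress,
#' normal, high-N stress), two replicate plots per variety and level, and
#' five sampled canopy regions per plot, so each stress condition yields
#' 120 canopy-region spectra.
#'
#' Each variety carries exactly one nitrogen-efficiency class. The default
#' class map plants six low-N-efficient varieties (v01-v04, v08, v12), two
#' high-N-efficient ones (v07, v10) and four inefficient ones (v05, v06,
#' v09, v11). The reference varieties Jimai22 (low-N efficient, planted at
#' N0 and N1 only) and Shannong28 (high-N efficient, planted at N1 and N2
#' only) anchor the cluster labelling downstream.
#'
#' @param n_varieties Number of candidate varieties (default 12).
#' @param replicates_per_cell Replicate plots per variety x nitrogen level.
#' @param n_regions Canopy regions sampled per plot (default 5).
#' @param n_levels Named numeric vector of nitrogen applications in kg/ha.
#' @param class_map Named character vector mapping variety id to one of
#'   `"low_N_efficient"`, `"high_N_efficient"`, `"inefficient"`. `NULL` uses
#'   the default partition above (requires `n_varieties == 12`).
#' @param signature_bands List of length-2 numeric wavelength windows (nm)
#'   that carry the class signal in the spectra.
#' @param signature_expression_sd SD of the per-variety, per-window
#'   expression multiplier of the class signal (default 0.5). Distinct
#'   spectral windows reflect distinct biochemical mechanisms, and
#'   varieties express them with different strengths; without this
#'   heterogeneity all windows would be perfectly collinear copies of one
#'   another, which no real canopy shows.
#' @param effect_size Dimensionless reflectance shift planted inside the
#'   signature windows (default 0.05).
#' @param noise_sd Reflectance noise standard deviation (default 0.01).
#' @param pheno_noise_cv Coefficient of variation of the multiplicative
#'   phenotype noise (default 0.03).
#' @param collinearity_length Gaussian smoothing kernel width in nm applied
#'   to the spectral noise so adjacent bands are strongly correlated.
#' @param include_reference Plant the two reference varieties? Default TRUE.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `synthetic_design` object (a validated list).
#' @export
#' @examples
#' d <- synthetic_design(seed = 1)
#' spectra <- generate_spectra(d)
#' pheno <- generate_phenotypes(d)
synthetic_design <- function(n_varieties = 12,
                             replicates_per_cell = 2,
                             n_regions = 5,
                             n_levels = c(N0 = 0, N1 = 225, N2 = 450),
                             class_map = NULL,
                             signature_bands = list(c(400, 540),
                                                    c(600, 660),
                                                    c(850, 900)),
                             signature_expression_sd = 0.5,
                             effect_size = 0.05,
                             noise_sd = 0.01,
                             pheno_noise_cv = 0.03,
                             collinearity_length = 30,
                             include_reference = TRUE,
                             seed = 1L) {
  assert_that(is_count(n_varieties), "`n_varieties` must be a positive integer")
  assert_that(is_count(replicates_per_cell),
              "`replicates_per_cell` must be >= 1")
  assert_that(is_count(n_regions), "`n_regions` must be >= 1")
  assert_that(is.numeric(n_levels) && length(n_levels) >= 2,
              "`n_levels` needs at least two nitrogen applications")
  if (is.null(names(n_levels))) {
    names(n_levels) <- paste0("N", seq_along(n_levels) - 1L)
  }
  assert_that(signature_expression_sd >= 0,
              "`signature_expression_sd` must be >= 0")
  assert_that(effect_size >= 0, "`effect_size` must be >= 0")
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  assert_that(pheno_noise_cv >= 0, "`pheno_noise_cv` must be >= 0")
  assert_that(collinearity_length > 0, "`collinearity_length` must be > 0")

  varieties <- sprintf("v%02d", seq_len(n_varieties))
  if (is.null(class_map)) {
    if (n_varieties == 12) {
      class_map <- setNames(rep("inefficient", 12), varieties)
      class_map[varieties[c(1, 2, 3, 4, 8, 12)]] <- "low_N_efficient"
      class_map[varieties[c(7, 10)]] <- "high_N_efficient"
    } else {
      classes <- c("low_N_efficient", "high_N_efficient", "inefficient")
      class_map <- setNames(classes[(seq_len(n_varieties) - 1L) %% 3L + 1L],
                            varieties)
    }
  }
  assert_that(all(varieties %in% names(class_map)),
              "`class_map` must name every variety")
  class_map <- class_map[varieties]
  valid <- c("low_N_efficient", "high_N_efficient", "inefficient")
  assert_that(all(class_map %in% valid),
              paste("classes must be one of:", paste(valid, collapse = ", ")))
  assert_that(is.list(signature_bands) &&
                all(vapply(signature_bands, length, 1L) == 2),
              "`signature_bands` must be a list of length-2 windows")

  design <- structure(list(
    n_varieties = as.integer(n_varieties),
    replicates_per_cell = as.integer(replicates_per_cell),
    n_regions = as.integer(n_regions),
    n_levels = n_levels,
    varieties = varieties,
    class_map = class_map,
    signature_bands = lapply(signature_bands, sort),
    signature_expression_sd = signature_expression_sd,
    effect_size = effect_size,
    noise_sd = noise_sd,
    pheno_noise_cv = pheno_noise_cv,
    collinearity_length = collinearity_length,
    include_reference = isTRUE(include_reference),
    seed = as.integer(seed)
  ), class = "synthetic_design")
  design
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("<synthetic_design>\n")
  cat("  varieties:", x$n_varieties,
      if (x$include_reference) "(+ 2 reference)" else "", "\n")
  cat("  levels:", paste(sprintf("%s=%g", names(x$n_levels), x$n_levels),
                         collapse = ", "), "kg/ha\n")
  cat("  replicates x regions:", x$replicates_per_cell, "x", x$n_regions, "\n")
  cat("  effect_size:", x$effect_size, " noise_sd:", x$noise_sd,
      " seed:", x$seed, "\n")
  invisible(x)
}

# Reference varieties and the levels they are planted at.
reference_plan <- function(design) {
  if (!design$include_reference) {
    return(tibble(variety = character(), class = character(),
                  levels = list()))
  }
  lv <- names(design$n_levels)
  tibble(
    variety = c("Jimai22", "Shannong28"),
    class = c("low_N_efficient", "high_N_efficient"),
    levels = list(lv[c(1, 2)], lv[c(2, 3)])
  )
}

# Per-class signature-window activation by nitrogen level index (1 = low
# stress, 2 = normal, 3 = high stress). Low-N-efficient varieties express
# their signature most strongly under nitrogen deficit, high-N-efficient
# ones under nitrogen excess; inefficient varieties carry no signature.
class_level_coef <- function(class, level_idx) {
  lowc <- c(1, 0.5, 0)
  highc <- c(0, -0.5, 1)
  switch(class,
    low_N_efficient = lowc[level_idx],
    high_N_efficient = highc[level_idx],
    inefficient = 0,
    abort(paste("unknown class:", class))
  )
}

# Smooth vegetation reflectance template: low visible reflectance with a
# green peak near 550 nm, a logistic red-edge rise centred near 715 nm and
# a near-infrared plateau with a mild water-related dip near 970 nm.
vegetation_base_curve <- function(wl) {
  0.04 +
    0.05 * exp(-(wl - 550)^2 / (2 * 40^2)) +
    0.43 / (1 + exp(-(wl - 715) / 12)) -
    0.03 * exp(-(wl - 970)^2 / (2 * 25^2))
}

# Raised-cosine bump equal to 1 at the window centre, 0 at the edges.
window_bump <- function(wl, window) {
  inside <- wl >= window[1] & wl <= window[2]
  out <- numeric(length(wl))
  if (any(inside)) {
    centre <- mean(window)
    half <- (window[2] - window[1]) / 2
    out[inside] <- 0.5 * (1 + cos(pi * (wl[inside] - centre) / half))
  }
  out
}

# Gaussian smoothing matrix over the band grid (rows normalised).
smoothing_matrix <- function(wl, kernel_sd) {
  d <- outer(wl, wl, function(a, b) a - b)
  w <- exp(-d^2 / (2 * kernel_sd^2))
  sweep(w, 1, rowSums(w), "/")
}

#' Generate synthetic canopy reflectance spectra
#'
#' Emits one spectrum per variety x planted nitrogen level x replicate x
#' canopy region. Each spectrum is the vegetation base curve, plus a small
#' deterministic nitrogen-level effect in the visible range (more applied
#' nitrogen means more chlorophyll, hence lower visible reflectance), plus
#' a class- and level-dependent reflectance shift inside the design's
#' signature windows, plus spatially smoothed noise so that adjacent bands
#' are strongly collinear, as in real hyperspectral canopy data. All values
#' are clipped to \[0, 1\].
#'
#' @param design A [synthetic_design()].
#' @param n_bands Number of bands on an even grid (default 224).
#' @param wl_min,wl_max Wavelength range in nm (default 400-1000).
#' @return A tibble with columns `sample_id`, `variety`, `class`, `n_level`,
#'   `replicate`, `region` and one `band_<wavelength>` column per band.
#' @export
generate_spectra <- function(design, n_bands = 224, wl_min = 400,
                             wl_max = 1000) {
  assert_that(inherits(design, "synthetic_design"),
              "`design` must be a synthetic_design object")
  assert_that(is_count(n_bands) && n_bands >= 8, "`n_bands` must be >= 8")
  assert_that(wl_min < wl_max, "`wl_min` must be < `wl_max`")
  for (w in design$signature_bands) {
    if (w[1] < wl_min || w[2] > wl_max) {
      abort(sprintf(
        "signature window [%g, %g] nm lies outside the band range [%g, %g] nm",
        w[1], w[2], wl_min, wl_max))
    }
  }

  wl <- seq(wl_min, wl_max, length.out = n_bands)
  base <- vegetation_base_curve(wl)
  visible <- 1 / (1 + exp((wl - 700) / 10))  # smooth visible-range mask
  bumps <- lapply(design$signature_bands, function(w) window_bump(wl, w))
  smoother <- smoothing_matrix(wl, design$collinearity_length)

  lv_names <- names(design$n_levels)
  refs <- reference_plan(design)
  cells <- bind_rows(
    tidyr::expand_grid(variety = design$varieties, n_level = lv_names),
    if (nrow(refs) > 0) {
      tidyr::unnest(dplyr::transmute(refs, variety = .data$variety,
                                     n_level = .data$levels),
                    "n_level")
    }
  )
  class_of <- c(design$class_map,
                setNames(refs$class, refs$variety))
  cells <- tidyr::expand_grid(cells,
                              replicate = seq_len(design$replicates_per_cell),
                              region = seq_len(design$n_regions))
  cells$class <- unname(class_of[cells$variety])

  with_seed(child_seed(design$seed, 11L), {
    all_varieties <- unique(cells$variety)
    amp <- setNames(1 + design$noise_sd * rnorm(length(all_varieties)),
                    all_varieties)
    # variety x window expression of the class signature: different
    # windows reflect different mechanisms, expressed with
    # variety-specific strength (kept positive)
    expr <- matrix(pmax(1 + design$signature_expression_sd *
                          rnorm(length(all_varieties) * length(bumps)),
                        0.1),
                   nrow = length(all_varieties),
                   dimnames = list(all_varieties, NULL))
    refl <- matrix(0, nrow(cells), n_bands)
    for (i in seq_len(nrow(cells))) {
      lvl_idx <- match(cells$n_level[i], lv_names)
      n_applied <- design$n_levels[lvl_idx]
      mu <- base * amp[cells$variety[i]]
      # chlorophyll response to applied nitrogen in the visible range
      mu <- mu + 0.01 * (1 - n_applied / 225) * visible
      cc <- class_level_coef(cells$class[i], lvl_idx)
      if (cc != 0 && design$effect_size > 0) {
        for (w in seq_along(bumps)) {
          mu <- mu + design$effect_size * cc *
            expr[cells$variety[i], w] * bumps[[w]]
        }
      }
      if (design$noise_sd > 0) {
        eps <- drop(smoother %*% rnorm(n_bands))
        eps <- eps / stats::sd(eps) * design$noise_sd
        mu <- mu + eps
      }
      refl[i, ] <- pmin(pmax(mu, 0), 1)
    }
    colnames(refl) <- band_col_names(wl)
    out <- bind_cols(
      tibble(
        sample_id = sprintf("%s_%s_r%d_g%d", cells$variety, cells$n_level,
                            cells$replicate, cells$region),
        variety = cells$variety,
        class = cells$class,
        n_level = cells$n_level,
        replicate = cells$replicate,
        region = cells$region
      ),
      as_tibble(refl)
    )
    out
  })
}

# Expected phenotype multiplier for a class at a nitrogen level, relative
# to the normal-nitrogen (N1) value.
class_pheno_mult <- function(class, level_idx) {
  m <- switch(class,
    low_N_efficient = c(1.04, 1, 0.92),
    high_N_efficient = c(0.90, 1, 1.15),
    inefficient = c(0.85, 1, 0.88),
    abort(paste("unknown class:", class))
  )
  m[level_idx]
}

#' Generate synthetic wheat phenotypes
#'
#' Draws wheat yield (WY, kg/ha), above-ground nitrogen accumulation (ANA,
#' g/plant), dry matter mass (WDMM, g/plant) and thousand-grain weight
#' (TGW, g) per variety x planted nitrogen level x replicate. Expected
#' values are a variety base level times a class-dependent nitrogen
#' response: low-N-efficient varieties hold or improve their phenotypes
#' under nitrogen deficit, high-N-efficient ones gain markedly under
#' nitrogen excess, and inefficient ones decline under both stresses.
#' Noise is multiplicative with coefficient of variation
#' `design$pheno_noise_cv`.
#'
#' @param design A [synthetic_design()].
#' @return A tibble with columns `variety`, `class`, `n_level`, `replicate`,
#'   `WY_raw`, `ANA_raw`, `WDMM_raw`, `TGW_raw`; all values strictly
#'   positive.
#' @export
generate_phenotypes <- function(design) {
  assert_that(inherits(design, "synthetic_design"),
              "`design` must be a synthetic_design object")
  lv_names <- names(design$n_levels)
  refs <- reference_plan(design)
  cells <- bind_rows(
    tidyr::expand_grid(variety = design$varieties, n_level = lv_names),
    if (nrow(refs) > 0) {
      tidyr::unnest(dplyr::transmute(refs, variety = .data$variety,
                                     n_level = .data$levels),
                    "n_level")
    }
  )
  class_of <- c(design$class_map, setNames(refs$class, refs$variety))
  cells <- tidyr::expand_grid(cells,
                              replicate = seq_len(design$replicates_per_cell))
  cells$class <- unname(class_of[cells$variety])

  base_means <- c(WY_raw = 7500, ANA_raw = 2.0, WDMM_raw = 15, TGW_raw = 45)

  with_seed(child_seed(design$seed, 23L), {
    all_varieties <- unique(cells$variety)
    # variety-specific base levels (genetic variation, shared across levels)
    vbase <- matrix(1 + design$pheno_noise_cv *
                      rnorm(length(all_varieties) * 4),
                    nrow = length(all_varieties), ncol = 4,
                    dimnames = list(all_varieties, names(base_means)))
    vbase <- pmax(vbase, 0.5)
    draws <- matrix(1 + design$pheno_noise_cv * rnorm(nrow(cells) * 4),
                    nrow = nrow(cells))
    draws <- pmax(draws, 0.1)
    lvl_idx <- match(cells$n_level, lv_names)
    mult <- mapply(class_pheno_mult, cells$class, lvl_idx)
    vals <- sapply(seq_along(base_means), function(j) {
      base_means[j] * vbase[cells$variety, j] * mult * draws[, j]
    })
    colnames(vals) <- names(base_means)
    bind_cols(
      tibble(variety = cells$variety, class = cells$class,
             n_level = cells$n_level, replicate = cells$replicate),
      as_tibble(vals)
    )
  })
}

#' Write a synthetic design to YAML
#'
#' @param design A [synthetic_design()].
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_design_yaml <- function(design, path) {
  x <- unclass(design)
  x$n_levels <- as.list(x$n_levels)
  x$class_map <- as.list(x$class_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a synthetic design from YAML
#'
#' @param path File written by [write_design_yaml()].
#' @return A [synthetic_design()].
#' @export
read_design_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  synthetic_design(
    n_varieties = x$n_varieties,
    replicates_per_cell = x$replicates_per_cell,
    n_regions = x$n_regions,
    n_levels = unlist(x$n_levels),
    class_map = unlist(x$class_map),
    signature_bands = x$signature_bands,
    signature_expression_sd = x$signature_expression_sd,
    effect_size = x$effect_size,
    noise_sd = x$noise_sd,
    pheno_noise_cv = x$pheno_noise_cv,
    collinearity_length = x$collinearity_length,
    include_reference = x$include_reference,
    seed = x$seed
  )
}
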