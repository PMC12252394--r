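#' Agronomic nitrogen-efficiency indices
#'
#' Elementary index calculators used throughout the classification
#' workflow. All are vectorised over their arguments.
#'
#' * `change_rate(stress, control)` = (stress - control) / control, the
#'   relative change of a phenotype under nitrogen stress.
#' * `nue(yield_stress, yield_control, delta_n)` — nitrogen use efficiency:
#'   yield difference per kg of applied-nitrogen difference.
#' * `aenf(ana_stress, ana_control, delta_n)` — agronomic efficiency of
#'   nitrogen fertilizer: gain in above-ground nitrogen accumulation per kg
#'   of applied-nitrogen difference.
#' * `nfue(wdmm_stress, wdmm_control, mode)` — nitrogen fertilizer
#'   utilization efficiency, a dry-matter ratio statistic. The default
#'   `"centered"` mode returns ratio - 1 so that "no change" maps to 0;
#'   `"literal"` returns the bare ratio.
#' * `nt(yield_stress, yield_control)` — nitrogen tolerance coefficient,
#'   the yield ratio stress/control.
#'
#' @param stress,control,yield_stress,yield_control,ana_stress,ana_control,wdmm_stress,wdmm_control
#'   Strictly positive phenotype values (controls must be > 0).
#' @param delta_n Positive applied-nitrogen difference in kg/ha.
#' @param mode `"centered"` (default) or `"literal"` for `nfue()`.
#' @return Numeric vector of index values.
#' @name agronomic_indices
NULL

#' @rdname agronomic_indices
#' @export
change_rate <- function(stress, control) {
  assert_that(all(control > 0), "`control` phenotype values must be > 0")
  (stress - control) / control
}

#' @rdname agronomic_indices
#' @export
nue <- function(yield_stress, yield_control, delta_n) {
  assert_that(all(delta_n > 0), "`delta_n` must be > 0")
  (yield_stress - yield_control) / delta_n
}

#' @rdname agronomic_indices
#' @export
aenf <- function(ana_stress, ana_control, delta_n) {
  assert_that(all(delta_n > 0), "`delta_n` must be > 0")
  (ana_stress - ana_control) / delta_n
}

#' @rdname agronomic_indices
#' @export
nfue <- function(wdmm_stress, wdmm_control, mode = c("centered", "literal")) {
  mode <- match.arg(mode)
  assert_that(all(wdmm_control > 0), "`wdmm_control` must be > 0")
  r <- wdmm_stress / wdmm_control
  if (mode == "centered") r - 1 else r
}

#' @rdname agronomic_indices
#' @export
nt <- function(yield_stress, yield_control) {
  assert_that(all(yield_control > 0), "`yield_control` must be > 0")
  yield_stress / yield_control
}

validate_phenotypes <- function(pheno) {
  need <- c("variety", "n_level", "replicate",
            "WY_raw", "ANA_raw", "WDMM_raw", "TGW_raw")
  missing <- setdiff(need, names(pheno))
  assert_that(length(missing) == 0,
              paste("phenotype table is missing columns:",
                    paste(missing, collapse = ", ")))
  raw <- as.matrix(pheno[, c("WY_raw", "ANA_raw", "WDMM_raw", "TGW_raw")])
  assert_that(all(is.finite(raw)) && all(raw > 0),
              "all raw phenotype values must be finite and > 0")
  invisible(pheno)
}

#' Compute the eight agronomic indices per variety for a stress contrast
#'
#' Replicate measurements are first averaged per variety x nitrogen level
#' (the field protocol takes replicate means as the variety measurement),
#' then the eight indices are computed from the level means: the change
#' rates of wheat yield (WY), above-ground nitrogen accumulation (ANA),
#' dry matter mass (WDMM) and thousand-grain weight (TGW), plus NUE, AENF,
#' NFUE and NT. Varieties lacking the stress level of the requested
#' contrast (for example a reference variety planted at only two levels)
#' are dropped from that contrast; a variety with stress-level data but no
#' control (N1) data raises an error naming the variety.
#'
#' @param pheno Phenotype tibble with columns `variety`, `n_level`,
#'   `replicate`, `WY_raw`, `ANA_raw`, `WDMM_raw`, `TGW_raw`.
#' @param contrast `"N0_vs_N1"` (low-N stress vs normal) or `"N2_vs_N1"`
#'   (high-N stress vs normal).
#' @param n_denominator Applied-nitrogen difference (kg/ha) used for NUE
#'   and AENF; defaults to 225, the absolute difference between each
#'   stress level and the normal application in the trial design.
#' @param nfue_mode `"centered"` (default) or `"literal"`; see [nfue()].
#' @return A tibble with one row per variety having both contrast levels:
#'   `variety`, `contrast`, `WY`, `ANA`, `WDMM`, `TGW`, `NUE`, `AENF`,
#'   `NFUE`, `NT`.
#' @export
index_table <- function(pheno, contrast = c("N0_vs_N1", "N2_vs_N1"),
                        n_denominator = 225,
                        nfue_mode = c("centered", "literal")) {
  contrast <- match.arg(contrast)
  nfue_mode <- match.arg(nfue_mode)
  validate_phenotypes(pheno)
  assert_that(n_denominator > 0, "`n_denominator` must be > 0")
  stress_level <- if (contrast == "N0_vs_N1") "N0" else "N2"

  means <- pheno |>
    group_by(.data$variety, .data$n_level) |>
    summarise(across(c("WY_raw", "ANA_raw", "WDMM_raw", "TGW_raw"), mean),
              .groups = "drop")

  has_control <- means |> filter(.data$n_level == "N1") |> pull("variety")
  has_stress <- means |>
    filter(.data$n_level == stress_level) |>
    pull("variety")
  no_control <- setdiff(has_stress, has_control)
  if (length(no_control) > 0) {
    abort(paste0("missing control (N1) phenotypes for variety: ",
                 paste(no_control, collapse = ", ")))
  }
  keep <- intersect(has_stress, has_control)
  assert_that(length(keep) > 0,
              paste0("no variety has both levels of contrast ", contrast))

  wide <- means |>
    filter(.data$variety %in% keep,
           .data$n_level %in% c("N1", stress_level)) |>
    tidyr::pivot_wider(names_from = "n_level",
                       values_from = c("WY_raw", "ANA_raw", "WDMM_raw",
                                       "TGW_raw"))
  s <- function(col) wide[[paste0(col, "_", stress_level)]]
  ctl <- function(col) wide[[paste0(col, "_N1")]]

  tibble(
    variety = wide$variety,
    contrast = contrast,
    WY = change_rate(s("WY_raw"), ctl("WY_raw")),
    ANA = change_rate(s("ANA_raw"), ctl("ANA_raw")),
    WDMM = change_rate(s("WDMM_raw"), ctl("WDMM_raw")),
    TGW = change_rate(s("TGW_raw"), ctl("TGW_raw")),
    NUE = nue(s("WY_raw"), ctl("WY_raw"), n_denominator),
    AENF = aenf(s("ANA_raw"), ctl("ANA_raw"), n_denominator),
    NFUE = nfue(s("WDMM_raw"), ctl("WDMM_raw"), mode = nfue_mode),
    NT = nt(s("WY_raw"), ctl("WY_raw"))
  ) |>
    arrange(.data$variety)
}

#' Summary statistics of the agronomic indices across varieties
#'
#' Per index: maximum, minimum, sample standard deviation (n - 1
#' denominator), mean, and the coefficient of variation CV = SD / |mean|,
#' reported both as a fraction and as a percentage. A zero mean leaves the
#' CV undefined (`NA` with `cv_defined = FALSE`).
#'
#' @param indices Output of [index_table()] (>= 2 varieties).
#' @return A tibble with one row per index: `index`, `max`, `min`, `sd`,
#'   `mean`, `cv`, `cv_pct`, `cv_defined`.
#' @export
summarize_indices <- function(indices) {
  cols <- c("WY", "ANA", "WDMM", "TGW", "NUE", "AENF", "NFUE", "NT")
  missing <- setdiff(cols, names(indices))
  assert_that(length(missing) == 0,
              paste("index table is missing columns:",
                    paste(missing, collapse = ", ")))
  assert_that(nrow(indices) >= 2, "need >= 2 varieties to summarise")
  purrr::map_dfr(cols, function(cl) {
    v <- indices[[cl]]
    m <- mean(v)
    s <- stats::sd(v)
    defined <- !isTRUE(all.equal(m, 0)) && m != 0
    cv <- if (defined) s / abs(m) else NA_real_
    tibble(index = cl, max = max(v), min = min(v), sd = s, mean = m,
           cv = cv, cv_pct = 100 * cv, cv_defined = defined)
  })
}
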