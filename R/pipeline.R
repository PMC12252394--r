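#' Pipeline configuration
#'
#' Collects every stage configuration of the end-to-end workflow. Input
#' data come either from a [synthetic_design()] (default) or from CSV
#' paths (`spectra_csv`, `phenotype_csv`).
#'
#' @param out_dir Output directory for stage artifacts.
#' @param design A [synthetic_design()] used when no CSV paths are given.
#' @param spectra_csv,phenotype_csv Optional input CSV paths.
#' @param embedding An [embedding_config()].
#' @param skip_tsne Cluster standardised indices directly (deterministic).
#' @param lasso A [lasso_config()].
#' @param cars A [cars_config()].
#' @param svm An [svm_config()].
#' @param xgb An [xgb_config()].
#' @param k Cross-validation folds (default 10).
#' @param models Model names compared in the model-comparison stage.
#' @param sample_unit `"region"` keeps the five canopy-region spectra per
#'   plot as separate samples (default); `"plot"` averages them first.
#' @param nfue_mode,n_denominator Index options, see [index_table()].
#' @param run_normal_n Also run the three-group comparison at normal
#'   nitrogen (default TRUE).
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("nitrospec_run_"),
                            design = synthetic_design(),
                            spectra_csv = NULL, phenotype_csv = NULL,
                            embedding = embedding_config(),
                            skip_tsne = FALSE,
                            lasso = lasso_config(),
                            cars = cars_config(),
                            svm = svm_config(),
                            xgb = xgb_config(),
                            k = 10,
                            models = c("svm_xgboost", "svm", "rf",
                                       "xgboost", "adaboost"),
                            sample_unit = c("region", "plot"),
                            nfue_mode = "centered",
                            n_denominator = 225,
                            run_normal_n = TRUE,
                            seed = 1L) {
  sample_unit <- match.arg(sample_unit)
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage_csv <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  readr::write_csv(x, path)
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

band_subset_tibble <- function(subset) {
  tibble(index = subset$indices,
         wavelength = subset$wavelengths,
         stage = subset$stage)
}

#' Run the full classification pipeline
#'
#' Executes the end-to-end workflow: phenotype indices, efficiency
#' labelling under both stress conditions, Lasso-CARS band selection per
#' condition, serial SVM-XGBoost training with baseline and band-subset
#' comparisons under stratified ten-fold cross-validation, and the
#' three-group comparison at normal nitrogen. Every stage writes its
#' artifact as CSV into `cfg$out_dir`, and a JSON manifest records the
#' config hash, seed and artifact list.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  assert_that(inherits(cfg, "pipeline_config"),
              "`cfg` must be a pipeline_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- new.env(parent = emptyenv())
  art$paths <- character(0)
  add_artifact <- function(...) art$paths <- c(art$paths, ...)
  log_stage <- function(stage, t0) {
    message(sprintf("[nitrospec] %-16s %.1fs", stage,
                    as.numeric(Sys.time()) - t0))
  }

  # -- data ----------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  dat <- run_stage("data", {
    if (!is.null(cfg$spectra_csv)) {
      assert_that(!is.null(cfg$phenotype_csv),
                  "`phenotype_csv` is required alongside `spectra_csv`")
      assert_that(file.exists(cfg$phenotype_csv),
                  paste0("no such file: ", cfg$phenotype_csv))
      list(spectra = read_spectra_csv(cfg$spectra_csv),
           pheno = readr::read_csv(cfg$phenotype_csv,
                                   show_col_types = FALSE))
    } else {
      list(spectra = generate_spectra(cfg$design),
           pheno = generate_phenotypes(cfg$design))
    }
  })
  if (cfg$sample_unit == "plot" && "plot" %in% names(dat$spectra)) {
    dat$spectra <- aggregate_plot_spectra(dat$spectra)
  }
  log_stage("data", t0)

  # -- indices -------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  indices <- run_stage("indices", {
    low <- index_table(dat$pheno, "N0_vs_N1",
                       n_denominator = cfg$n_denominator,
                       nfue_mode = cfg$nfue_mode)
    high <- index_table(dat$pheno, "N2_vs_N1",
                        n_denominator = cfg$n_denominator,
                        nfue_mode = cfg$nfue_mode)
    add_artifact(write_stage_csv(low, cfg$out_dir, "indices_low"),
                 write_stage_csv(high, cfg$out_dir, "indices_high"),
                 write_stage_csv(summarize_indices(low), cfg$out_dir,
                                 "index_summary_low"),
                 write_stage_csv(summarize_indices(high), cfg$out_dir,
                                 "index_summary_high"))
    list(low = low, high = high)
  })
  log_stage("indices", t0)

  # -- labeling ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  labels <- run_stage("labeling", {
    emb <- cfg$embedding
    emb$seed <- child_seed(cfg$seed, 31L)
    low <- label_efficiency(dat$pheno, "low_N", cfg = emb,
                            skip_tsne = cfg$skip_tsne,
                            n_denominator = cfg$n_denominator,
                            nfue_mode = cfg$nfue_mode)
    emb$seed <- child_seed(cfg$seed, 32L)
    high <- label_efficiency(dat$pheno, "high_N", cfg = emb,
                             skip_tsne = cfg$skip_tsne,
                             n_denominator = cfg$n_denominator,
                             nfue_mode = cfg$nfue_mode)
    groups <- combine_conditions(low, high)
    strat <- mutate(groups, strategy = strategy_for(.data$group))
    add_artifact(write_stage_csv(bind_rows(low, high), cfg$out_dir,
                                 "efficiency_labels"),
                 write_stage_csv(strat, cfg$out_dir,
                                 "groups_and_strategies"))
    list(low = low, high = high, groups = groups)
  })
  log_stage("labeling", t0)

  # -- band selection (per stress condition) -------------------------------
  t0 <- as.numeric(Sys.time())
  condition_data <- function(level, label_tbl) {
    sp <- dat$spectra |>
      filter(.data$n_level == level,
             .data$variety %in% label_tbl$variety)
    cls <- setNames(label_tbl$class, label_tbl$variety)
    list(spectra = sp, labels = unname(cls[sp$variety]))
  }
  bands <- run_stage("band_selection", {
    sel <- purrr::imap(list(low = "N0", high = "N2"), function(level, nm) {
      cd <- condition_data(level, labels[[nm]])
      lasso_cfg <- cfg$lasso
      lasso_cfg$seed <- child_seed(cfg$seed, 41L)
      cars_cfg <- cfg$cars
      cars_cfg$seed <- child_seed(cfg$seed, 42L)
      lc <- lasso_cars(cd$spectra, cd$labels, lasso_cfg, cars_cfg)
      cars_only <- cars_refine(cd$spectra, cd$labels, cars_cfg)
      list(data = cd, lasso = attr(lc, "lasso_subset"),
           cars = cars_only, lasso_cars = lc)
    })
    for (nm in names(sel)) {
      add_artifact(write_stage_csv(
        bind_rows(band_subset_tibble(sel[[nm]]$lasso),
                  band_subset_tibble(sel[[nm]]$cars),
                  band_subset_tibble(sel[[nm]]$lasso_cars)),
        cfg$out_dir, paste0("bands_", nm)))
      tr <- sel[[nm]]$lasso_cars$trace
      if (!is.null(tr)) {
        add_artifact(write_stage_csv(dplyr::select(tr, -"retained"),
                                     cfg$out_dir,
                                     paste0("cars_trace_", nm)))
      }
    }
    sel
  })
  log_stage("band_selection", t0)

  # -- training + evaluation -----------------------------------------------
  t0 <- as.numeric(Sys.time())
  evaluation <- run_stage("evaluation", {
    out <- purrr::imap(bands, function(sel, nm) {
      cd <- sel$data
      sub_spectra <- select_bands(cd$spectra, sel$lasso_cars)
      comp_models <- compare_models(
        sub_spectra, cd$labels, models = cfg$models,
        k = cfg$k, seed = child_seed(cfg$seed, 51L),
        svm_cfg = cfg$svm, xgb_cfg = cfg$xgb)
      comp_bands <- compare_band_inputs(
        cd$spectra, cd$labels,
        subsets = list(lasso = sel$lasso, cars = sel$cars,
                       lasso_cars = sel$lasso_cars),
        model = "svm_xgboost", k = cfg$k,
        seed = child_seed(cfg$seed, 52L),
        svm_cfg = cfg$svm, xgb_cfg = cfg$xgb)
      add_artifact(write_stage_csv(comp_models, cfg$out_dir,
                                   paste0("model_comparison_", nm)),
                   write_stage_csv(comp_bands, cfg$out_dir,
                                   paste0("band_input_comparison_", nm)))
      list(models = comp_models, band_inputs = comp_bands)
    })
    out
  })
  log_stage("evaluation", t0)

  # -- three-group task at normal nitrogen ---------------------------------
  normal_n <- NULL
  if (isTRUE(cfg$run_normal_n)) {
    t0 <- as.numeric(Sys.time())
    normal_n <- run_stage("normal_n", {
      sp1 <- dat$spectra |>
        filter(.data$n_level == "N1",
               .data$variety %in% labels$groups$variety)
      grp <- setNames(labels$groups$group, labels$groups$variety)
      y3 <- unname(grp[sp1$variety])
      low_wl <- bands$low$lasso_cars$wavelengths
      high_wl <- bands$high$lasso_cars$wavelengths
      comp <- compare_band_inputs(
        sp1, y3,
        subsets = list(lowN_bands = low_wl, highN_bands = high_wl,
                       union = sort(union(low_wl, high_wl))),
        model = "svm_xgboost", k = cfg$k,
        seed = child_seed(cfg$seed, 61L),
        svm_cfg = cfg$svm, xgb_cfg = cfg$xgb)
      add_artifact(write_stage_csv(comp, cfg$out_dir,
                                   "normal_n_comparison"))
      comp
    })
    log_stage("normal_n", t0)
  }

  manifest <- list(
    package = "nitrospec",
    version = as.character(utils::packageVersion("nitrospec")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    sample_unit = cfg$sample_unit,
    artifacts = basename(art$paths),
    stages = c("data", "indices", "labeling", "band_selection",
               "evaluation", if (!is.null(normal_n)) "normal_n")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(out_dir = cfg$out_dir, data = dat, indices = indices,
                 labels = labels, bands = bands, evaluation = evaluation,
                 normal_n = normal_n, manifest = manifest))
}
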