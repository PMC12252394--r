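#' Plot selected bands on the mean reflectance curve
#'
#' @param object A `band_subset`.
#' @param spectra Optional spectra tibble supplying the mean reflectance
#'   curve; without it only the selected wavelengths are shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot band_subset
#' @export
autoplot.band_subset <- function(object, spectra = NULL, ...) {
  sel <- tidy(object)
  p <- ggplot2::ggplot()
  if (!is.null(spectra)) {
    curve <- tibble(wavelength = band_wavelengths(spectra),
                    reflectance = colMeans(spectra_matrix(spectra)))
    p <- p +
      ggplot2::geom_line(data = curve,
                         ggplot2::aes(.data$wavelength,
                                      .data$reflectance)) +
      ggplot2::geom_point(
        data = dplyr::semi_join(
          mutate(curve, wavelength = round(.data$wavelength, 6)),
          mutate(sel, wavelength = round(.data$wavelength, 6)),
          by = "wavelength"),
        ggplot2::aes(.data$wavelength, .data$reflectance),
        colour = "firebrick", size = 2)
  } else {
    p <- p +
      ggplot2::geom_vline(data = sel,
                          ggplot2::aes(xintercept = .data$wavelength),
                          colour = "firebrick")
  }
  p +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance",
                  title = paste0("Selected bands (", object$stage, ", n = ",
                                 nrow(sel), ")")) +
    ggplot2::theme_minimal()
}

#' Plot the CARS refinement trace
#'
#' Retained-set size and RMSECV per Monte Carlo run, with the chosen run
#' marked.
#'
#' @param subset A `band_subset` carrying a CARS `trace`.
#' @return A ggplot object.
#' @export
plot_cars_trace <- function(subset) {
  assert_that(inherits(subset, "band_subset") && !is.null(subset$trace),
              "`subset` must carry a CARS trace")
  tr <- dplyr::select(subset$trace, "run", "n_retained", "rmsecv") |>
    tidyr::pivot_longer(-"run", names_to = "metric")
  ggplot2::ggplot(tr, ggplot2::aes(.data$run, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = subset$chosen_run,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Monte Carlo run", y = NULL,
                  title = "CARS refinement trace") +
    ggplot2::theme_minimal()
}

#' Plot per-fold evaluation results
#'
#' @param object An `eval_report` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("oa", "kappa"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("%s: mean OA %.1f%%, mean kappa %.2f",
                                  object$model, object$mean_oa,
                                  object$mean_kappa)) +
    ggplot2::theme_minimal()
}

#' Plot the labelling embedding
#'
#' Scatter of the first two embedding dimensions used for clustering,
#' coloured by the assigned efficiency class.
#'
#' @param labels Output of [label_efficiency()].
#' @return A ggplot object.
#' @export
plot_embedding <- function(labels) {
  emb <- attr(labels, "embedding")
  assert_that(!is.null(emb), "`labels` carries no embedding attribute")
  ref <- attr(labels, "reference")
  df <- tibble(variety = rownames(emb), d1 = emb[, 1], d2 = emb[, 2]) |>
    left_join(dplyr::select(labels, "variety", "class"), by = "variety") |>
    mutate(class = ifelse(.data$variety == ref, "reference", .data$class))
  ggplot2::ggplot(df, ggplot2::aes(.data$d1, .data$d2,
                                   colour = .data$class,
                                   label = .data$variety)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "dim 1", y = "dim 2",
                  title = "Variety embedding and efficiency classes") +
    ggplot2::theme_minimal()
}
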