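#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a band subset
#'
#' @param x A `band_subset`.
#' @param ... Unused.
#' @return A tibble (`index`, `wavelength`, `stage`).
#' @method tidy band_subset
#' @export
tidy.band_subset <- function(x, ...) {
  tibble(index = x$indices, wavelength = x$wavelengths, stage = x$stage)
}

#' @rdname tidy.band_subset
#' @method glance band_subset
#' @export
glance.band_subset <- function(x, ...) {
  tibble(stage = x$stage, n_bands = length(x$indices),
         wl_min = min(x$wavelengths), wl_max = max(x$wavelengths),
         chosen_run = x$chosen_run,
         min_rmsecv = if (is.null(x$trace)) NA_real_
                      else min(x$trace$rmsecv, na.rm = TRUE))
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble (`actual`, `predicted`, `n`).
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  m <- unclass(as.matrix(x))
  out <- as_tibble(as.table(m), .name_repair = "minimal")
  names(out) <- c("actual", "predicted", "n")
  mutate(out, n = as.integer(.data$n))
}
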