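#' Read and write spectra tables
#'
#' The on-disk schema is a plain CSV with metadata columns (`sample_id`
#' and any of `variety`, `class`, `n_level`, `replicate`, `plot`,
#' `region`) followed by one `band_<wavelength>` column per band.
#' `read_spectra_csv()` re-sorts band columns by ascending wavelength if
#' needed and validates the values.
#'
#' @param path CSV file path.
#' @param min_reflectance,max_reflectance Validation bounds; slightly wider
#'   than \[0, 1\] to tolerate calibration slack.
#' @return A spectra tibble.
#' @export
read_spectra_csv <- function(path, min_reflectance = -0.05,
                             max_reflectance = 1.5) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- grep("^band_", names(df), value = TRUE)
  assert_that(length(cols) >= 1,
              paste0("no band_<wavelength> columns found in ", path))
  wl <- suppressWarnings(as.numeric(sub("^band_", "", cols)))
  if (anyNA(wl)) {
    abort(paste0("malformed band column names: ",
                 paste(cols[is.na(wl)], collapse = ", ")))
  }
  if (anyDuplicated(wl)) {
    abort("duplicated wavelengths in band columns")
  }
  if (is.unsorted(wl)) {
    ord <- order(wl)
    df <- df[, c(setdiff(names(df), cols), cols[ord])]
    cols <- cols[ord]
  }
  m <- as.matrix(df[, cols])
  bad_row <- which(rowSums(!is.finite(m)) > 0)
  if (length(bad_row) > 0) {
    abort(paste0("missing or non-numeric reflectance in data row(s): ",
                 paste(head(bad_row, 5), collapse = ", ")))
  }
  out_of_range <- which(rowSums(m < min_reflectance |
                                  m > max_reflectance) > 0)
  if (length(out_of_range) > 0) {
    abort(paste0("reflectance outside [", min_reflectance, ", ",
                 max_reflectance, "] in data row(s): ",
                 paste(head(out_of_range, 5), collapse = ", ")))
  }
  as_tibble(df)
}

#' @rdname read_spectra_csv
#' @param spectra A spectra tibble.
#' @export
write_spectra_csv <- function(spectra, path) {
  readr::write_csv(spectra, path)
  invisible(path)
}

#' Per-band coefficient of variation screen
#'
#' Computes the coefficient of variation (sample SD / mean, across
#' samples) of every band and the fraction of bands whose CV exceeds a
#' threshold. The screen is diagnostic: it quantifies how much inter-plot
#' variability each wavelength carries but removes nothing.
#'
#' @param spectra Spectra tibble (>= 2 samples).
#' @param threshold CV threshold as a fraction (default 0.10).
#' @return A list with `band_cv` (tibble: `wavelength`, `mean`, `sd`,
#'   `cv`, `cv_defined`), `fraction_above` (share of defined-CV bands with
#'   CV > threshold) and `threshold`.
#' @export
band_cv_screen <- function(spectra, threshold = 0.10) {
  m <- spectra_matrix(spectra)
  assert_that(nrow(m) >= 2, "need >= 2 samples for a CV screen")
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  defined <- mu != 0
  cv <- ifelse(defined, s / abs(mu), NA_real_)
  band_cv <- tibble(
    wavelength = band_wavelengths(spectra),
    mean = unname(mu), sd = unname(s), cv = unname(cv),
    cv_defined = unname(defined)
  )
  list(
    band_cv = band_cv,
    fraction_above = mean(cv[defined] > threshold),
    threshold = threshold
  )
}

#' Plot geometry for raster extraction
#'
#' @param plot_id Identifier.
#' @param vertices Numeric 4 x 2 matrix of quadrilateral corners in
#'   raster pixel coordinates (columns `x` = raster column, `y` = raster
#'   row; 0-based pixel centres).
#' @return A `plot_geometry` object.
#' @export
plot_geometry <- function(plot_id, vertices) {
  vertices <- as.matrix(vertices)
  assert_that(nrow(vertices) >= 3 && ncol(vertices) == 2,
              "`vertices` must be an n x 2 matrix with n >= 3")
  area <- polygon_area(vertices)
  assert_that(area > 0, paste0("degenerate polygon for plot ", plot_id))
  structure(list(plot_id = plot_id, vertices = vertices,
                 center = colMeans(vertices)),
            class = "plot_geometry")
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Read plot geometries from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with a `plot_id`
#' property and coordinates already in raster pixel coordinates. The
#' closing vertex (equal to the first) is dropped if present.
#'
#' @param path GeoJSON file path.
#' @return List of [plot_geometry()] objects.
#' @export
read_plot_geometries <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  assert_that(identical(gj$type, "FeatureCollection"),
              "expected a GeoJSON FeatureCollection")
  purrr::imap(gj$features, function(f, i) {
    assert_that(identical(f$geometry$type, "Polygon"),
                paste0("feature ", i, " is not a Polygon"))
    ring <- f$geometry$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), ]
    id <- f$properties$plot_id %||% paste0("plot_", i)
    plot_geometry(id, v)
  })
}

#' Read a multi-band reflectance raster from TIFF
#'
#' Reads all directories of a (Geo)TIFF into a rows x cols x bands array.
#' Geo-referencing tags are not interpreted; plot geometries must be in
#' pixel coordinates.
#'
#' @param path TIFF file path.
#' @return 3-D numeric array.
#' @export
read_reflectance_tiff <- function(path) {
  assert_that(requireNamespace("tiff", quietly = TRUE),
              "the 'tiff' package is required to read TIFF rasters")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

# Block mean of one band over a window x window pixel block anchored at a
# point. Pixels are 0-based; for an even window the point's pixel sits at
# the lower-left of the central 2 x 2 block.
block_indices <- function(coord, window, n_pixels) {
  px <- round(coord)
  lo <- px - (ceiling(window / 2) - 1)
  hi <- lo + window - 1
  if (lo < 0 || hi > n_pixels - 1) {
    abort(sprintf(
      "sampling window [%d, %d] falls outside the raster (0..%d)",
      lo, hi, n_pixels - 1))
  }
  seq(lo, hi) + 1L  # to 1-based array indices
}

#' Extract per-plot canopy spectra from a reflectance raster
#'
#' For each quadrilateral plot, five sampling points are used: the plot
#' centre and, for each vertex, the point one fifth of the way along the
#' vertex-to-centre segment (measured from the vertex by default). At
#' each point the reflectance of every band is averaged over a
#' `window` x `window` pixel block, yielding one spectrum per
#' (plot, point).
#'
#' @param cube Numeric rows x cols x bands array of reflectance.
#' @param geoms List of [plot_geometry()] objects (4 vertices each).
#' @param wavelengths Numeric band wavelengths (nm); defaults to band
#'   indices.
#' @param window Block side length in pixels (default 20).
#' @param offset_from Where the one-fifth offset starts: `"vertex"`
#'   (default; point = vertex + 0.2 * (centre - vertex)) or `"center"`
#'   (point = centre + 0.2 * (vertex - centre)).
#' @param meta Optional tibble with a `plot_id` column to join onto the
#'   result.
#' @return A spectra tibble with columns `sample_id`, `plot`, `region`
#'   (1 = centre, 2-5 = vertex points) and `band_*` columns.
#' @export
extract_plot_spectra <- function(cube, geoms, wavelengths = NULL,
                                 window = 20,
                                 offset_from = c("vertex", "center"),
                                 meta = NULL) {
  offset_from <- match.arg(offset_from)
  assert_that(length(dim(cube)) == 3, "`cube` must be a 3-D array")
  assert_that(is_count(window), "`window` must be a positive integer")
  if (inherits(geoms, "plot_geometry")) geoms <- list(geoms)
  n_bands <- dim(cube)[3]
  if (is.null(wavelengths)) wavelengths <- seq_len(n_bands)
  assert_that(length(wavelengths) == n_bands,
              "`wavelengths` length must match the cube's band count")

  rows <- purrr::map_dfr(geoms, function(g) {
    assert_that(inherits(g, "plot_geometry"),
                "`geoms` must contain plot_geometry objects")
    assert_that(nrow(g$vertices) == 4,
                paste0("plot ", g$plot_id,
                       " must be a quadrilateral (4 vertices)"))
    ctr <- g$center
    pts <- rbind(
      ctr,
      t(apply(g$vertices, 1, function(v) {
        if (offset_from == "vertex") v + 0.2 * (ctr - v)
        else ctr + 0.2 * (v - ctr)
      }))
    )
    purrr::map_dfr(seq_len(nrow(pts)), function(k) {
      ci <- block_indices(pts[k, 1], window, dim(cube)[2])  # x -> columns
      ri <- block_indices(pts[k, 2], window, dim(cube)[1])  # y -> rows
      refl <- vapply(seq_len(n_bands),
                     function(b) mean(cube[ri, ci, b]), numeric(1))
      out <- tibble(sample_id = sprintf("%s_g%d", g$plot_id, k),
                    plot = g$plot_id, region = k)
      out[band_col_names(wavelengths)] <- as.list(refl)
      out
    })
  })
  if (!is.null(meta)) {
    rows <- dplyr::left_join(rows, meta, by = c(plot = "plot_id"))
    rows <- rows[, c("sample_id", "plot",
                     setdiff(names(rows), c("sample_id", "plot")))]
  }
  rows
}

#' Average region spectra to one spectrum per plot
#'
#' @param spectra Output of [extract_plot_spectra()] (or any spectra
#'   tibble with a `plot` column).
#' @return One-row-per-plot spectra tibble (band columns averaged).
#' @export
aggregate_plot_spectra <- function(spectra) {
  assert_that("plot" %in% names(spectra), "`spectra` needs a `plot` column")
  spectra |>
    group_by(.data$plot) |>
    summarise(across(dplyr::starts_with("band_"), mean), .groups = "drop") |>
    mutate(sample_id = paste0(.data$plot, "_mean"), .before = 1)
}
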