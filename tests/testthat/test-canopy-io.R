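test_that("spectra CSV round-trips losslessly", {
  sp <- generate_spectra(synthetic_design(seed = 1), n_bands = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(sp, path)
  back <- read_spectra_csv(path)
  expect_identical(names(back), names(sp))
  expect_equal(spectra_matrix(back), spectra_matrix(sp), tolerance = 1e-9)
})

test_that("shuffled band columns are re-sorted consistently", {
  sp <- generate_spectra(synthetic_design(seed = 1), n_bands = 8)
  shuffled <- sp[, c(setdiff(names(sp), band_cols(sp)),
                     withr::with_seed(3, sample(band_cols(sp))))]
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuffled, path)
  back <- read_spectra_csv(path)
  expect_false(is.unsorted(band_wavelengths(back)))
  expect_equal(spectra_matrix(back), spectra_matrix(sp), tolerance = 1e-9)
})

test_that("malformed spectra files raise descriptive errors", {
  sp <- generate_spectra(synthetic_design(seed = 1), n_bands = 8)
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- sp
  bad[[band_cols(sp)[2]]][3] <- 2.7  # outside calibration slack
  readr::write_csv(bad, path)
  expect_error(read_spectra_csv(path), "outside")

  bad2 <- sp
  bad2[[band_cols(sp)[1]]][5] <- NA
  readr::write_csv(bad2, path)
  expect_error(read_spectra_csv(path), "row")

  nob <- dplyr::select(sp, -dplyr::starts_with("band_"))
  readr::write_csv(nob, path)
  expect_error(read_spectra_csv(path), "band_")

  expect_error(read_spectra_csv(file.path(tempdir(), "nope.csv")),
               "no such file")
})

test_that("band CV screen matches hand and brute-force computation", {
  sp <- tibble::tibble(sample_id = c("a", "b"),
                       band_500.00 = c(0.2, 0.2),
                       band_600.00 = c(0.1, 0.3))
  scr <- band_cv_screen(sp, threshold = 0.10)
  expect_equal(scr$band_cv$cv[1], 0)
  expect_equal(scr$band_cv$cv[2], sd(c(0.1, 0.3)) / 0.2)
  expect_equal(round(scr$band_cv$cv[2], 4), 0.7071)
  expect_equal(scr$fraction_above, 0.5)

  big <- generate_spectra(synthetic_design(seed = 2), n_bands = 30)
  scr2 <- band_cv_screen(big, threshold = 0.02)
  m <- spectra_matrix(big)
  brute <- apply(m, 2, sd) / abs(colMeans(m))
  expect_equal(scr2$band_cv$cv, unname(brute), tolerance = 1e-12)
  expect_equal(scr2$fraction_above, mean(brute > 0.02))
})

test_that("zero-mean bands are flagged undefined in the screen", {
  sp <- tibble::tibble(sample_id = c("a", "b"),
                       band_500.00 = c(-0.04, 0.04),
                       band_600.00 = c(0.2, 0.4))
  scr <- band_cv_screen(sp)
  expect_false(scr$band_cv$cv_defined[1])
  expect_true(is.na(scr$band_cv$cv[1]))
  expect_equal(scr$fraction_above, 1)  # over defined bands only
})

# A raster whose band b value at (row r, col c) is a_b + g_r * r + g_c * c.
gradient_cube <- function(nr, nc, nb, a = 0.1 * seq_len(nb),
                          g_r = 0.001, g_c = 0.002) {
  cube <- array(0, c(nr, nc, nb))
  r <- matrix(0:(nr - 1), nr, nc)
  cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  for (b in seq_len(nb)) cube[, , b] <- a[b] + g_r * r + g_c * cc
  cube
}

square_geom <- function(id = "p1", x0 = 30, y0 = 30, side = 40) {
  plot_geometry(id, rbind(c(x0, y0), c(x0 + side, y0),
                          c(x0 + side, y0 + side), c(x0, y0 + side)))
}

test_that("constant rasters extract constant spectra", {
  cube <- array(0.37, c(100, 100, 3))
  out <- extract_plot_spectra(cube, square_geom(), window = 10)
  expect_equal(nrow(out), 5)
  expect_true(all(abs(spectra_matrix(out) - 0.37) < 1e-12))
})

test_that("block means of a linear gradient match the closed form", {
  g_r <- 0.001
  g_c <- 0.002
  a <- c(0.05, 0.20, 0.35)
  cube <- gradient_cube(120, 120, 3, a, g_r, g_c)
  g <- square_geom(x0 = 40, y0 = 40, side = 40)
  w <- 20
  out <- extract_plot_spectra(cube, g, window = w)
  ctr <- g$center
  pts <- rbind(ctr, t(apply(g$vertices, 1,
                            function(v) v + 0.2 * (ctr - v))))
  for (k in 1:5) {
    # analytic mean of a linear field over the anchored pixel block
    px <- round(pts[k, 1]); py <- round(pts[k, 2])
    cols <- (px - (w / 2 - 1)):(px + w / 2)
    rows <- (py - (w / 2 - 1)):(py + w / 2)
    expected <- a + g_r * mean(rows) + g_c * mean(cols)
    got <- as.numeric(spectra_matrix(out)[k, ])
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("extraction is translation-equivariant", {
  cube <- gradient_cube(150, 150, 2)
  base <- extract_plot_spectra(cube, square_geom(x0 = 30, y0 = 30),
                               window = 8)
  # shift geometry by (dr, dc) and build the raster shifted the same way
  dr <- 15; dc <- 22
  cube2 <- gradient_cube(150, 150, 2,
                         a = 0.1 * 1:2 - 0.001 * dr - 0.002 * dc)
  shifted <- extract_plot_spectra(cube2,
                                  square_geom(x0 = 30 + dc, y0 = 30 + dr),
                                  window = 8)
  expect_equal(spectra_matrix(shifted), spectra_matrix(base),
               tolerance = 1e-12)
})

test_that("offset direction flag moves the vertex sampling points", {
  cube <- gradient_cube(200, 200, 1)
  g <- square_geom(x0 = 60, y0 = 60, side = 60)
  from_vertex <- extract_plot_spectra(cube, g, window = 4)
  from_center <- extract_plot_spectra(cube, g, window = 4,
                                      offset_from = "center")
  # centre point identical, vertex points differ
  expect_equal(spectra_matrix(from_vertex)[1, ],
               spectra_matrix(from_center)[1, ])
  expect_false(isTRUE(all.equal(spectra_matrix(from_vertex)[2, ],
                                spectra_matrix(from_center)[2, ])))
})

test_that("bad geometries and windows are rejected", {
  cube <- array(0.5, c(50, 50, 2))
  expect_error(plot_geometry("d", rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
  tri <- plot_geometry("t", rbind(c(10, 10), c(30, 10), c(20, 30)))
  expect_error(extract_plot_spectra(cube, tri), "quadrilateral")
  near_edge <- square_geom(x0 = 0, y0 = 0, side = 10)
  expect_error(extract_plot_spectra(cube, near_edge, window = 20),
               "outside")
})

test_that("GeoJSON geometries round-trip through the reader", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         properties = list(plot_id = "plotA"),
         geometry = list(type = "Polygon",
                         coordinates = list(list(
                           list(10, 10), list(50, 10), list(50, 30),
                           list(10, 30), list(10, 10)))))
  ))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  geoms <- read_plot_geometries(path)
  expect_length(geoms, 1)
  expect_identical(geoms[[1]]$plot_id, "plotA")
  expect_equal(nrow(geoms[[1]]$vertices), 4)  # closing vertex dropped
  expect_equal(geoms[[1]]$center, c(30, 20))
})

test_that("plot aggregation averages the five region spectra", {
  cube <- gradient_cube(120, 120, 2)
  out <- extract_plot_spectra(cube, square_geom(x0 = 40, y0 = 40),
                              window = 6)
  agg <- aggregate_plot_spectra(out)
  expect_equal(nrow(agg), 1)
  expect_equal(as.numeric(spectra_matrix(agg)),
               unname(colMeans(spectra_matrix(out))))
})
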