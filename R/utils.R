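#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate select filter arrange group_by ungroup summarise
#'   across left_join bind_rows bind_cols pull rename n distinct
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2 imap pmap walk
#' @importFrom stats sd cor dist hclust cutree predict rnorm runif coef
#'   quantile var aggregate setNames
#' @importFrom utils head tail
NULL

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All package randomness funnels through this so
# no function mutates the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a parent seed, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647L)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

#' Column names holding reflectance bands
#'
#' Spectra travel as tibbles with metadata columns followed by one
#' `band_<wavelength>` column per band. These helpers recover the band
#' columns, their wavelengths (nm) and the bare reflectance matrix.
#'
#' @param spectra A spectra tibble with `band_*` columns.
#' @return `band_cols()`: character vector of band column names;
#'   `band_wavelengths()`: numeric wavelengths in nm;
#'   `spectra_matrix()`: numeric samples-by-bands matrix.
#' @export
band_cols <- function(spectra) {
  grep("^band_", names(spectra), value = TRUE)
}

#' @rdname band_cols
#' @export
band_wavelengths <- function(spectra) {
  as.numeric(sub("^band_", "", band_cols(spectra)))
}

#' @rdname band_cols
#' @export
spectra_matrix <- function(spectra) {
  cols <- band_cols(spectra)
  assert_that(length(cols) > 0, "no band_* columns found in `spectra`")
  m <- as.matrix(spectra[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

band_col_names <- function(wavelengths) {
  sprintf("band_%.2f", wavelengths)
}
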