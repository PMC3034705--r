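the_conversion <- new.env(parent = emptyenv())

#' EU/UK/US shoe-size conversion table
#'
#' The regional conversion table used by shoe shops, expanded so every EU
#' half-size a range label covers (e.g. `"38.5 - 39"`) has its own row. Two
#' adjacent range labels overlap at EU 39 and EU 44; those sizes are assigned
#' to the later row (`"39 - 39.5"`, `"44 - 44.5"`). US male sizes below EU 38
#' and US female sizes above EU 42.5 do not exist in the table and are `NA`,
#' never 0. EU 45.5 appears in no row of the source table and is therefore
#' absent here.
#'
#' @return A tibble with columns `eu_size`, `eu_label`, `uk`, `us_male`,
#'   `us_female`, one row per mapped EU half-size (36.0--46.5).
#' @export
size_conversion_table <- function() {
  if (is.null(the_conversion$table)) {
    path <- system.file("extdata", "size_conversion.csv", package = "footspurt",
                        mustWork = TRUE)
    the_conversion$table <- readr::read_csv(
      path,
      col_types = readr::cols(
        eu_size = readr::col_double(), eu_label = readr::col_character(),
        uk = readr::col_double(), us_male = readr::col_double(),
        us_female = readr::col_double()
      ),
      progress = FALSE
    )
  }
  the_conversion$table
}

#' Convert EU shoe sizes to UK and US sizes
#'
#' Looks each EU half-size up in [size_conversion_table()]. Sizes outside the
#' table's range (or EU 45.5, absent from it) yield a row of `NA`s rather
#' than an error, so the lookup can be used inside pipelines.
#'
#' @param eu numeric vector of EU sizes on the 0.5 grid.
#' @return A tibble with one row per input: `eu_size`, `eu_label`, `uk`,
#'   `us_male`, `us_female`.
#' @examples
#' convert_eu(c(36, 40, 45))
#' @export
convert_eu <- function(eu) {
  if (!all(on_grid(eu))) {
    abort("EU sizes must lie on the half-size (0.5) grid.")
  }
  tab <- size_conversion_table()
  idx <- match(eu, tab$eu_size)
  out <- tab[idx, ]
  out$eu_size <- eu
  out
}

#' Convert a count of EU shoe sizes to millimetres of foot length
#'
#' One EU size is one Paris point, 2/3 cm of last length (the "approximately
#' 7 mm" rule of thumb).
#'
#' @param n_sizes non-negative numeric count of EU sizes.
#' @return Length in millimetres: `n_sizes * 20/3`.
#' @examples
#' sizes_to_mm(3) # three Paris points = 2 cm
#' @export
sizes_to_mm <- function(n_sizes) {
  if (any(n_sizes < 0)) {
    abort("`n_sizes` must be non-negative.")
  }
  n_sizes * 20 / 3
}
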