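#' @importFrom rlang .data
#' @importFrom stats approx runif setNames
#' @importFrom utils head tail
NULL

#' Recognised panel units
#'
#' Areas are carried in kha (thousand hectares), N quantities in Gg N/yr
#' (1 Gg = 10^6 kg = thousand tonnes), application and deposition rates in
#' kg N/ha/yr, nutrient contents in % N of DM, and yields in t DM/ha.
#' @return Character vector of unit strings accepted by [as_panel()].
#' @export
panel_units <- function() {
  c("kha", "Gg N/yr", "kg N/ha/yr", "% N of DM", "t DM/ha", "dimensionless")
}

#' Default year grid
#'
#' The canonical coverage period of the budget panels, 1961--2019. Countries
#' with shorter statistical records (e.g. states independent since 1992) can
#' use a per-country grid via the `grids` argument of [as_panel()].
#' @param start,end First and last year (inclusive).
#' @return Integer vector of years.
#' @export
default_grid <- function(start = 1961, end = 2019) seq.int(start, end)

#' Convert a quantity/area pair to an average rate
#'
#' Centralizes the unit convention: a quantity of 1 Gg spread over 1 kha is
#' 1000 kg/ha. Returns `NA` where the area is zero or missing.
#'
#' @param quantity_gg Quantity in Gg (N)/yr.
#' @param area_kha Area in kha.
#' @return Rate in kg (N)/ha/yr.
#' @examples
#' kg_per_ha(1, 1)   # 1000
#' kg_per_ha(20, 2000) # 10
#' @export
kg_per_ha <- function(quantity_gg, area_kha) {
  ifelse(!is.na(area_kha) & area_kha > 0, quantity_gg * 1000 / area_kha, NA_real_)
}

#' Composite regions and their constituents
#'
#' Some statistical series report merged regions for part of the period
#' (Belgium--Luxembourg up to 1999, former Czechoslovakia up to 1992). These
#' are first-class region codes with a declared constituent list so that
#' area- or quantity-weighted merges can be computed.
#' @return Named list mapping composite code to character vector of
#'   constituent codes.
#' @export
composite_regions <- function() {
  list(
    "BEL-LUX" = c("BEL", "LUX"),
    "CSK" = c("CZE", "SVK")
  )
}

panel_columns <- c("country", "year", "variable", "unit", "value")

#' Validate and grid-complete a tidy panel
#'
#' A panel is a tibble with columns `country, year, variable, unit, value`:
#' one row per country-year-variable, value possibly `NA` (explicit missing).
#' `as_panel()` checks the schema, rejects unknown units, duplicate keys and
#' negative values, and completes the year grid per (country, variable) so
#' that every grid year is present.
#'
#' @param x A data frame with the five panel columns.
#' @param grid Integer vector of years; the default grid for all countries.
#' @param grids Optional named list country -> year vector overriding `grid`
#'   for specific countries.
#' @return A tibble panel, grid-complete, ordered by country, variable, year.
#' @export
as_panel <- function(x, grid = default_grid(), grids = NULL) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(panel_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- dplyr::select(x, dplyr::all_of(panel_columns))
  bad_unit <- setdiff(unique(x$unit), panel_units())
  if (length(bad_unit) > 0) {
    stop("unknown unit(s): ", paste(bad_unit, collapse = ", "))
  }
  dup <- x |>
    dplyr::count(.data$country, .data$year, .data$variable) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(
      "duplicate (country, year, variable) rows, e.g. ",
      dup$country[1], "/", dup$year[1], "/", dup$variable[1]
    )
  }
  neg <- x |> dplyr::filter(!is.na(.data$value) & .data$value < 0)
  if (nrow(neg) > 0) {
    stop(
      "negative value for ", neg$country[1], "/", neg$year[1], "/",
      neg$variable[1], ": ", neg$value[1]
    )
  }
  grid_for <- function(country) {
    if (!is.null(grids) && country %in% names(grids)) grids[[country]] else grid
  }
  if (nrow(x) == 0) {
    return(dplyr::arrange(x, .data$country, .data$variable, .data$year))
  }
  out_of_grid <- x |>
    dplyr::group_by(.data$country) |>
    dplyr::filter(!.data$year %in% grid_for(.data$country[1])) |>
    dplyr::ungroup()
  if (nrow(out_of_grid) > 0) {
    stop(
      "year outside the grid: ", out_of_grid$country[1], "/",
      out_of_grid$year[1], "/", out_of_grid$variable[1]
    )
  }
  # complete the grid per (country, variable), carrying the unit
  x |>
    dplyr::group_by(.data$country, .data$variable, .data$unit) |>
    dplyr::group_modify(function(d, key) {
      yrs <- grid_for(key$country)
      tibble::tibble(year = as.integer(yrs)) |>
        dplyr::left_join(d, by = "year")
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(panel_columns)) |>
    dplyr::arrange(.data$country, .data$variable, .data$year)
}

#' Read a tidy panel CSV
#'
#' Expects UTF-8 CSV with header `country,year,variable,unit,value`, '.'
#' decimal separator, and empty fields for missing values (never 0 or a
#' sentinel). The result is validated and grid-completed via [as_panel()].
#'
#' @inheritParams as_panel
#' @param path File path.
#' @return A tibble panel.
#' @export
read_panel <- function(path, grid = default_grid(), grids = NULL) {
  x <- read_tidy_csv(path)
  as_panel(x, grid = grid, grids = grids)
}

#' Read a tidy CSV with exact numeric parsing
#'
#' Columns are read as text and converted: a column whose non-empty entries
#' all parse as numbers becomes double (via the C library parser, which is
#' correctly rounded, so values written by [write_tidy_csv()] round-trip bit
#' for bit); a `year` column becomes integer. Empty fields are missing.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_tidy_csv <- function(path) {
  d <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE
  )
  num_re <- "^[+-]?([0-9]*\\.?[0-9]+)([eE][+-]?[0-9]+)?$"
  for (nm in names(d)) {
    x <- d[[nm]]
    obs <- !is.na(x)
    if (all(grepl(num_re, x[obs]))) { # all-empty columns default to double
      d[[nm]] <- as.numeric(x)
    }
  }
  if ("year" %in% names(d)) d$year <- as.integer(d$year)
  tibble::as_tibble(as.data.frame(d, stringsAsFactors = FALSE))
}

#' Write a tidy panel CSV
#'
#' Missing values are written as empty fields. Doubles are serialized in
#' shortest round-trippable form, so `read_panel(write_panel(x))` is the
#' identity on the value grid, bit for bit.
#'
#' @param panel A panel tibble (see [as_panel()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- tibble::as_tibble(panel)[, panel_columns]
  write_tidy_csv(panel, path)
  invisible(path)
}

#' Write a tibble as tidy CSV with round-trippable doubles
#'
#' Serializes double columns with 17 significant digits so that reading the
#' file back reproduces every value bit for bit; missing values become empty
#' fields.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(df, path) {
  df <- tibble::as_tibble(df)
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.double(x)) {
      s <- rep(NA_character_, length(x))
      obs <- !is.na(x)
      s[obs] <- sprintf("%.17g", x[obs])
      # trim to the shortest representation that still round-trips
      short <- sprintf("%.15g", x[obs])
      ok <- as.numeric(short) == x[obs]
      s[obs][ok] <- short[ok]
      df[[nm]] <- s
    }
  }
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Extract one (country, variable) series from a panel
#'
#' @param panel A panel tibble.
#' @param country,variable Keys selecting the series.
#' @return Tibble with columns `year`, `value` ordered by year.
#' @export
panel_series <- function(panel, country, variable) {
  panel |>
    dplyr::filter(.data$country == !!country, .data$variable == !!variable) |>
    dplyr::arrange(.data$year) |>
    dplyr::select("year", "value")
}

# ---- crop code registry ------------------------------------------------------

#' Crop-code registry
#'
#' Maps every registered crop code to exactly one of the output crop
#' categories. Fodder crops follow the statistical hierarchy of green-harvest
#' and root-crop codes (G1000 temporary grassland; G2100 lucerne and G2900
#' other green legumes, both mapping to the single category "Forage legumes";
#' G3000 green maize; G9000 = G9100 + G9900 other green-harvested plants;
#' R9000 fodder roots, the residual of root crops R0000 after potatoes R1000
#' and sugar beet R2000). The non-fodder side ships as a reduced mock
#' registry of named crops; the full 121-crop categorization belongs to the
#' source databases, not to this package.
#'
#' @return Tibble with columns `code`, `source`
#'   (`"eurostat-like"`/`"faostat-like"`), `category` (one of the output
#'   categories, or `NA` for codes that are inputs to derivations only).
#' @export
crop_code_registry <- function() {
  fodder <- tibble::tribble(
    ~code, ~category,
    "G1000", "Temporary grassland",
    "G2100", "Forage legumes",
    "G2900", "Forage legumes",
    "G3000", "Green maize",
    "G9000", "Other forage crops",
    "G9100", NA_character_, # merged into G9000
    "G9900", NA_character_, # merged into G9000
    "R0000", NA_character_, # parent of the R9000 residual
    "R1000", NA_character_,
    "R2000", NA_character_,
    "R9000", "Fodder roots"
  )
  fodder$source <- "eurostat-like"
  fao <- tibble::tribble(
    ~code, ~category,
    "wheat", "Wheat",
    "barley", "Barley",
    "grain_maize", "Grain maize",
    "oats", "Other cereals",
    "rye", "Other cereals",
    "rapeseed", "Oilseeds",
    "sunflower", "Oilseeds",
    "potatoes", "Potatoes",
    "sugar_beet", "Sugar beet",
    "field_peas", "Pulses",
    "faba_beans", "Pulses",
    "carrots", "Vegetables and other",
    "olives", "Olives",
    "grapes", "Grapes",
    "apples", "Other permanent crops"
  )
  fao$source <- "faostat-like"
  dplyr::bind_rows(fodder, fao)[, c("code", "source", "category")]
}

#' Category of a crop code
#'
#' Total on registered codes: every code maps to exactly one category or is
#' explicitly uncategorized (`NA`); unregistered codes are an error.
#' @param code Character vector of crop codes.
#' @return Character vector of categories (may be `NA`).
#' @export
crop_category <- function(code) {
  reg <- crop_code_registry()
  unknown <- setdiff(code, reg$code)
  if (length(unknown) > 0) {
    stop("unregistered crop code(s): ", paste(unknown, collapse = ", "))
  }
  reg$category[match(code, reg$code)]
}

# ---- N contents --------------------------------------------------------------

#' N contents of the fodder crops (% N of dry matter)
#'
#' The assumed crop N contents, constant over countries and years. The
#' grass/legume mixtures are weighted means of component contents: temporary
#' grassland 75% grass (2.0% N) + 25% clover (3.3% N); other green legumes
#' 90% clover + 10% grass; other green-harvested plants 75% cereal forage
#' (1.6% N) + 25% legumes (3.0% N). Mixture values are carried at the one
#' decimal used in the source tables.
#'
#' @return Tibble with columns `code`, `n_content` (% N of DM).
#' @export
fodder_n_contents <- function() {
  tibble::tribble(
    ~code, ~n_content,
    "G1000", 2.3,
    "G2100", 3.0,
    "G2900", 3.2,
    "G3000", 1.2,
    "G9000", 2.0,
    "R9000", 1.3
  )
}

#' Mixture components behind the fodder N contents
#'
#' Component contents and dry-matter shares for the three mixed crops.
#' @return Tibble with columns `code`, `component`, `share`, `n_content`.
#' @export
fodder_mixtures <- function() {
  tibble::tribble(
    ~code, ~component, ~share, ~n_content,
    "G1000", "grass", 0.75, 2.0,
    "G1000", "clover", 0.25, 3.3,
    "G2900", "clover", 0.90, 3.3,
    "G2900", "grass", 0.10, 2.0,
    "G9000", "cereal_forage", 0.75, 1.6,
    "G9000", "legumes", 0.25, 3.0
  )
}

#' Weighted-mean N content of a mixture
#'
#' @param n_contents Component N contents (% N of DM).
#' @param shares Dry-matter shares, summing to 1 within 1e-9.
#' @param digits Round the result to this many decimals (the source tables
#'   carry one decimal); `NULL` to skip rounding.
#' @return Mixture N content (% N of DM).
#' @examples
#' mixture_n_content(c(2.0, 3.3), c(0.75, 0.25)) # 2.3
#' @export
mixture_n_content <- function(n_contents, shares, digits = 1) {
  stopifnot(length(n_contents) == length(shares))
  if (any(shares < 0)) stop("negative mixture share")
  if (abs(sum(shares) - 1) > 1e-9) stop("mixture shares must sum to 1")
  if (any(n_contents <= 0 | n_contents > 10)) {
    stop("N contents must lie in (0, 10] % of DM")
  }
  out <- sum(n_contents * shares)
  if (!is.null(digits)) out <- round(out, digits)
  out
}
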