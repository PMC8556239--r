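# Aggregation of individual (FAOSTAT-side) crops into output categories with
# consistent area/harvest estimators. Crop N contents are fresh-basis factors
# applied uniformly across countries and years.

#' Crop N harvest from fresh production
#'
#' @param production Production in Gg (fresh basis).
#' @param n_content N content in % of the reported (fresh) mass.
#' @return N harvest in Gg N.
#' @examples
#' n_harvest(100, 2) # 2 Gg N
#' @export
n_harvest <- function(production, n_content) {
  stopifnot(all(production >= 0 | is.na(production)), all(n_content >= 0))
  production * n_content / 100
}

#' Category-level area/harvest estimators
#'
#' For each country-year-category: `A_sum` is the sum of available crop
#' areas, `H_sum` the sum of available crop N harvests, and `Y_est` the
#' ratio-of-sums N yield over the crops where both area and harvest are
#' available (equal to the area-weighted mean of crop yields). The estimated
#' category area is `A_est = H_sum / Y_est`, which amounts to assuming that
#' crops with missing areas yield like the observed remainder of the
#' category. When no crop has both (Y undefined), `A_est` falls back to
#' `A_sum` and the row is flagged.
#'
#' @param records Tibble of crop records with columns `country`, `year`,
#'   `category`, `crop`, `area` (kha or NA), `n_harvest` (Gg N or NA).
#' @return Tibble with one row per country-year-category: `A_sum`, `H_sum`,
#'   `Y_est`, `A_est`, `flag` (NA when clean).
#' @export
aggregate_categories <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("country", "year", "category", "crop", "area", "n_harvest")
  %in% names(records)))
  records |>
    dplyr::arrange(.data$country, .data$category, .data$year, .data$crop) |>
    dplyr::group_by(.data$country, .data$year, .data$category) |>
    dplyr::summarise(
      A_sum = sum(.data$area, na.rm = TRUE),
      H_sum = sum(.data$n_harvest, na.rm = TRUE),
      .a_both = sum(.data$area[!is.na(.data$area) & !is.na(.data$n_harvest)]),
      .h_both = sum(.data$n_harvest[!is.na(.data$area) & !is.na(.data$n_harvest)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      Y_est = ifelse(.data$.a_both > 0, .data$.h_both / .data$.a_both, NA_real_),
      A_est = ifelse(!is.na(.data$Y_est) & .data$Y_est > 0,
        .data$H_sum / .data$Y_est, .data$A_sum
      ),
      flag = ifelse(is.na(.data$Y_est) | .data$Y_est <= 0,
        "yield undefined; A_est = A_sum", NA_character_
      )
    ) |>
    dplyr::select(-".a_both", -".h_both")
}

#' Category aggregates as a tidy panel
#'
#' Reshapes the output of [aggregate_categories()] into panel form with
#' variables `area:<category>` (the `A_est` estimate) and
#' `n_harvest:<category>` (`H_sum`), the defaults used downstream.
#'
#' @param agg Output of [aggregate_categories()].
#' @return Panel tibble.
#' @export
category_panel <- function(agg) {
  dplyr::bind_rows(
    agg |>
      dplyr::transmute(.data$country, .data$year,
        variable = paste0("area:", .data$category),
        unit = "kha", value = .data$A_est
      ),
    agg |>
      dplyr::transmute(.data$country, .data$year,
        variable = paste0("n_harvest:", .data$category),
        unit = "Gg N/yr", value = .data$H_sum
      )
  ) |>
    dplyr::arrange(.data$country, .data$variable, .data$year)
}

#' Apply override rules to category-level estimates
#'
#' The default estimates (`H_sum`, `A_est`) pass through untouched without
#' rules. Overrides are ordinary edit rules on the category panel (replace an
#' area series by an external one, extrapolate a minor gap, assign zero where
#' a category is absent, ...). Rules must reference categories present in the
#' panel.
#'
#' @param cat_panel Panel from [category_panel()].
#' @param rules Edit rule list (see [apply_edit_rules()]).
#' @return Edited panel (with `edit_log` attribute).
#' @export
apply_category_overrides <- function(cat_panel, rules) {
  if (length(rules) == 0) {
    return(cat_panel)
  }
  vars <- unique(cat_panel$variable)
  for (rule in rules) {
    if (!is.null(rule$variable) && !rule$variable %in% vars) {
      stop("override rule targets unknown category variable: ", rule$variable)
    }
  }
  apply_edit_rules(cat_panel, rules)
}
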