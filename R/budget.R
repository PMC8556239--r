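# Assembly of the cropland N budget per country-year.

#' Assemble the cropland N budget
#'
#' Joins the five budget terms per country-year and derives the totals:
#' `input_total = fert_c + manure_c + bnf + deposition_c` (computed as that
#' sum, so the identity is exact), `surplus = input_total - harvest_n`, and
#' per-hectare rates `quantity * 1000 / cropland_in_use`. Nitrogen use
#' efficiency (`harvest_n / input_total`) is emitted as a convenience
#' column; divisions by zero yield missing. Missing terms are flagged, not
#' zero-filled.
#'
#' @param terms Tibble with columns `country`, `year`, `harvest_n`,
#'   `fert_c`, `manure_c`, `bnf`, `deposition_c` (Gg N/yr), and
#'   `cropland_in_use` (kha).
#' @return Budget tibble with the derived columns `input_total`, `surplus`,
#'   `input_rate`, `harvest_rate` (kg N/ha/yr), `nue`, and `flag`.
#' @export
assemble_budget <- function(terms) {
  terms <- tibble::as_tibble(terms)
  needed <- c(
    "country", "year", "harvest_n", "fert_c", "manure_c", "bnf",
    "deposition_c", "cropland_in_use"
  )
  missing_cols <- setdiff(needed, names(terms))
  if (length(missing_cols) > 0) {
    stop("budget terms missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  term_cols <- c("harvest_n", "fert_c", "manure_c", "bnf", "deposition_c")
  any_missing <- Reduce(`|`, lapply(term_cols, function(cl) is.na(terms[[cl]])))
  terms |>
    dplyr::mutate(
      input_total = .data$fert_c + .data$manure_c + .data$bnf + .data$deposition_c,
      surplus = .data$input_total - .data$harvest_n,
      input_rate = kg_per_ha(.data$input_total, .data$cropland_in_use),
      harvest_rate = kg_per_ha(.data$harvest_n, .data$cropland_in_use),
      nue = ifelse(!is.na(.data$input_total) & .data$input_total > 0,
        .data$harvest_n / .data$input_total, NA_real_
      ),
      flag = dplyr::case_when(
        any_missing ~ "missing budget term",
        (is.na(.data$cropland_in_use) | .data$cropland_in_use == 0) &
          .data$input_total != 0 ~ "no area: rates undefined",
        .default = NA_character_
      )
    )
}

#' Budget tibble in long (tidy) form
#'
#' @param budget Output of [assemble_budget()].
#' @return Long tibble `country`, `year`, `term`, `value` over the five
#'   budget terms plus `input_total` and `surplus`.
#' @export
budget_long <- function(budget) {
  budget |>
    dplyr::select(
      "country", "year", "harvest_n", "fert_c", "manure_c", "bnf",
      "deposition_c", "input_total", "surplus"
    ) |>
    tidyr::pivot_longer(-c("country", "year"), names_to = "term", values_to = "value")
}
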