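# S3 methods for the pipeline result: print, tidy/glance, autoplot.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.nbudget_build <- function(x, ...) {
  b <- x$budget
  cat("<nbudget_build>\n")
  cat(
    "  countries: ", paste(sort(unique(b$country)), collapse = ", "),
    "\n  years:     ", min(b$year), "-", max(b$year),
    "\n  budget rows:", nrow(b), "\n",
    sep = ""
  )
  v <- nb_validate(x)
  cat("  validation: ", sum(v$pass), "/", nrow(v), " checks pass\n", sep = "")
  invisible(x)
}

#' Tidy a pipeline result
#'
#' Returns the assembled budget in long form: one row per country-year-term
#' (the five budget terms plus `input_total` and `surplus`), values in
#' Gg N/yr.
#'
#' @param x An `nbudget_build`.
#' @param ... Unused.
#' @return A long tibble `country`, `year`, `term`, `value`.
#' @export
tidy.nbudget_build <- function(x, ...) {
  budget_long(x$budget)
}

#' One-row-per-country summary of a pipeline result
#'
#' @param x An `nbudget_build`.
#' @param ... Unused.
#' @return Tibble with per-country means over the covered years: harvest,
#'   total input, surplus (Gg N/yr), mean input rate and nitrogen use
#'   efficiency, and the number of years covered.
#' @export
glance.nbudget_build <- function(x, ...) {
  x$budget |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      harvest_n = mean(.data$harvest_n),
      input_total = mean(.data$input_total),
      surplus = mean(.data$surplus),
      input_rate = mean(.data$input_rate, na.rm = TRUE),
      nue = mean(.data$nue, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Plot the cropland N budget per country
#'
#' Stacked areas of the four N inputs (synthetic fertilizer, manure,
#' symbiotic fixation, deposition) with the N harvest overlaid as a line,
#' facetted by country.
#'
#' @param object An `nbudget_build`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbudget_build <- function(object, ...) {
  inputs <- object$budget |>
    dplyr::select(
      "country", "year",
      `Synthetic fertilizer` = "fert_c", Manure = "manure_c",
      `Symbiotic fixation` = "bnf", Deposition = "deposition_c"
    ) |>
    tidyr::pivot_longer(-c("country", "year"), names_to = "input", values_to = "value")
  ggplot2::ggplot(inputs, ggplot2::aes(.data$year, .data$value)) +
    ggplot2::geom_area(ggplot2::aes(fill = .data$input), position = "stack") +
    ggplot2::geom_line(
      data = object$budget,
      ggplot2::aes(.data$year, .data$harvest_n, linetype = "N harvest")
    ) +
    ggplot2::facet_wrap(~country, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "Gg N/yr", fill = "N input",
      linetype = NULL, title = "Cropland N budget"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fertilizer allocation shares
#'
#' Share of synthetic N applied to cropland over time, per country, with
#' survey-derived points distinguished from interpolated/extrapolated years.
#'
#' @param x An `nbudget_build`.
#' @return A ggplot object.
#' @export
plot_fert_share <- function(x) {
  stopifnot(inherits(x, "nbudget_build"))
  ggplot2::ggplot(x$fert, ggplot2::aes(.data$year, .data$share_c)) +
    ggplot2::geom_line(ggplot2::aes(color = .data$country)) +
    ggplot2::geom_point(
      data = dplyr::filter(x$fert, .data$provenance == "observed"),
      ggplot2::aes(color = .data$country), size = 0.8
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "share of synthetic N to cropland",
      title = "Fertilizer allocation"
    ) +
    ggplot2::theme_minimal()
}
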