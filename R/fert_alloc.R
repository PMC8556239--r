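# Allocation of synthetic N fertilizer between cropland (C) and permanent
# grassland (PG). The central quantity is the rate ratio R_PG/R_C, which
# together with the area ratio A_PG/A_C determines the share of total
# consumption applied to cropland without reference to consumption totals.

#' Area-weighted average fertilizer rate
#'
#' Aggregates individual crop rates into a land-category rate:
#' `sum(R * A) / sum(A)`.
#'
#' @param rates Rates (kg N/ha/yr).
#' @param areas Corresponding areas (kha), positive.
#' @return Weighted rate (kg N/ha/yr).
#' @examples
#' area_weighted_rate(c(100, 50), c(10, 10)) # 75
#' @export
area_weighted_rate <- function(rates, areas) {
  if (length(rates) == 0) stop("empty rate list")
  stopifnot(length(rates) == length(areas), all(areas > 0))
  sum(rates * areas) / sum(areas)
}

#' Renormalize a fertilized-subset rate to the whole category
#'
#' Surveys sometimes report the rate on the fertilized portion of grassland
#' only; the average rate over the whole category is `R_f * A_f / A_total`,
#' which conserves the implied quantity.
#'
#' @param r_f Rate on the fertilized subset (kg N/ha/yr).
#' @param a_f Fertilized area (kha).
#' @param a_total Total category area (kha), positive, `>= a_f`.
#' @return Average rate on the whole category.
#' @export
renormalize_fertilized <- function(r_f, a_f, a_total) {
  stopifnot(all(a_total > 0))
  if (any(a_f > a_total)) stop("fertilized area exceeds the category area")
  r_f * a_f / a_total
}

#' Share of synthetic N applied to cropland
#'
#' With all fertilizer going to agricultural land,
#' `Q_C / (Q_C + Q_PG) = (1 + (R_PG/R_C) * (A_PG/A_C))^-1`,
#' depending only on the rate ratio and the area ratio, not on consumption
#' totals. Strictly decreasing in both ratios; always in \[0, 1\].
#'
#' @param rate_ratio `R_PG / R_C` (>= 0), vectorized.
#' @param a_pg Permanent grassland area (kha).
#' @param a_c Cropland area (kha), positive.
#' @return Share in \[0, 1\].
#' @examples
#' share_to_cropland(0, 4000, 14000) # 1
#' share_to_cropland(1, 100, 100) # 0.5
#' @export
share_to_cropland <- function(rate_ratio, a_pg, a_c) {
  if (any(a_c <= 0)) stop("cropland area must be positive")
  if (any(rate_ratio < 0)) stop("rate ratio must be nonnegative")
  1 / (1 + rate_ratio * a_pg / a_c)
}

#' Rate ratio from total-grassland and non-grass-cropland rates
#'
#' Several sources distinguish only total grassland (PG + TG) from non-grass
#' cropland (C - TG). If the temporary-grassland rate is `k` times the
#' permanent-grassland rate, then with
#' `m = A_PG+TG / (A_PG + k * A_TG)` and `R_PG = m * R_PG+TG`:
#' `R_PG / R_C = (R_C-TG / (m * R_PG+TG) * A_C-TG / A_C + k * A_TG / A_C)^-1`.
#' Reduces to `R_PG+TG / R_C-TG` when `k = 1` and `A_TG = 0`.
#'
#' @param r_pg_tg Average rate on total grassland.
#' @param r_c_tg Average rate on non-grass cropland.
#' @param a_pg,a_tg,a_c Areas (kha); `a_c` includes temporary grassland.
#' @param a_c_minus_tg Non-grass cropland area; default `a_c - a_tg`.
#' @param a_pg_plus_tg Total grassland area; default `a_pg + a_tg`.
#' @param k Temporary/permanent rate multiplier (> 0), default 1.
#' @return Estimated `R_PG / R_C`.
#' @export
rate_ratio_from_total_grass <- function(r_pg_tg, r_c_tg, a_pg, a_tg, a_c,
                                        a_c_minus_tg = a_c - a_tg,
                                        a_pg_plus_tg = a_pg + a_tg,
                                        k = 1) {
  stopifnot(k > 0)
  if (any(a_pg + k * a_tg <= 0) || any(a_c <= 0)) stop("zero denominator in rate-ratio algebra")
  m <- a_pg_plus_tg / (a_pg + k * a_tg)
  if (any(m * r_pg_tg <= 0)) stop("zero denominator in rate-ratio algebra")
  1 / (r_c_tg / (m * r_pg_tg) * a_c_minus_tg / a_c + k * a_tg / a_c)
}

#' Rate ratio from one rate and the consumption total (last resort)
#'
#' When only the rate on one land category `x` is known, the ratio between
#' that rate and the implied rate on the complement of `x` (the remainder of
#' the agricultural area) is
#' `R_x / R_complement = R_x * (A_tot - A_x) / (Q_tot - R_x * A_x)`.
#' Used only when the ratio cannot be formed from two observed rates, since
#' it inherits the noise of the consumption total.
#'
#' @param r_x Rate on category x (kg N/ha/yr).
#' @param a_x Area of category x (kha).
#' @param a_tot Total agricultural area (kha), `> a_x`.
#' @param q_tot Total consumption (Gg N/yr); must exceed `r_x * a_x / 1000`.
#' @return `R_x / R_complement`.
#' @export
rate_ratio_last_resort <- function(r_x, a_x, a_tot, q_tot) {
  if (any(a_tot <= a_x)) stop("total area must exceed the category area")
  q_x <- r_x * a_x / 1000
  denom <- q_tot - q_x
  if (any(denom <= 0)) stop("implied complement rate is not positive")
  # convert the complement quantity to a rate on the complement area
  r_comp <- denom * 1000 / (a_tot - a_x)
  r_x / r_comp
}

#' Build a gap-filled rate-ratio series
#'
#' Multiple estimates in the same year are averaged first (averaging of
#' ratios, as the estimates are ratios); interior gaps are filled by linear
#' interpolation and the edges by constant extrapolation. Provenance is
#' recorded per year.
#'
#' @param points Tibble with columns `year`, `ratio` (may repeat years).
#' @param grid Year grid for the output.
#' @param zero_pg Logical: country applies no synthetic N to permanent
#'   grassland; returns an all-zero ratio series (allowed with no points).
#' @return Tibble `year`, `ratio`, `provenance` (`"observed"`,
#'   `"interpolated"`, `"extrapolated"`, `"zero-PG"`).
#' @export
build_rate_ratio_series <- function(points, grid = default_grid(), zero_pg = FALSE) {
  if (zero_pg) {
    return(tibble::tibble(year = as.integer(grid), ratio = 0, provenance = "zero-PG"))
  }
  points <- tibble::as_tibble(points)
  if (nrow(points) == 0) {
    stop("no rate-ratio points and country is not in the zero-PG list")
  }
  if (any(points$ratio < 0)) stop("negative rate ratio")
  if (!all(points$year %in% grid)) stop("rate-ratio point outside the year grid")
  pts <- points |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(ratio = mean(.data$ratio), .groups = "drop") |>
    dplyr::arrange(.data$year)
  s <- tibble::tibble(year = as.integer(grid)) |>
    dplyr::left_join(pts, by = "year") |>
    dplyr::rename(value = "ratio")
  observed <- !is.na(s$value)
  s <- interpolate_linear(s)
  interpolated <- !observed & !is.na(s$value)
  s <- extrapolate_const(s, "both")
  tibble::tibble(
    year = s$year, ratio = s$value,
    provenance = dplyr::case_when(
      observed ~ "observed",
      interpolated ~ "interpolated",
      .default = "extrapolated"
    )
  )
}

#' Allocate total consumption to cropland and permanent grassland
#'
#' `Q_C = share * Q_tot`; `Q_PG` is the complement `Q_tot - Q_C`, so the two
#' conserve the total exactly.
#'
#' @param q_tot Total consumption (Gg N/yr), vectorized.
#' @param share_c Share to cropland in \[0, 1\].
#' @return Tibble with `q_c`, `q_pg`.
#' @export
allocate_quantities <- function(q_tot, share_c) {
  stopifnot(all(share_c >= 0 & share_c <= 1, na.rm = TRUE))
  q_c <- q_tot * share_c
  tibble::tibble(q_c = q_c, q_pg = q_tot - q_c)
}

#' Check fertilizer survey observations for internal consistency
#'
#' An observation carrying all of rate `R` (kg N/ha/yr), quantity `Q`
#' (Gg N/yr) and area `A` (kha) must satisfy `Q = R * A / 1000` within a
#' relative tolerance (default 0.5%); inconsistent rows are flagged for
#' exclusion, with the reason recorded.
#'
#' @param obs Tibble with columns `country`, `year`, `land_category`, `R`,
#'   `Q`, `A` (any of the last three may be NA), `source`.
#' @param tol Relative tolerance.
#' @return `obs` with logical column `excluded` and character `reason`.
#' @export
check_fert_obs <- function(obs, tol = 0.005) {
  obs <- tibble::as_tibble(obs)
  complete <- !is.na(obs$R) & !is.na(obs$Q) & !is.na(obs$A)
  implied <- obs$R * obs$A / 1000
  bad <- complete & obs$Q > 0 & abs(obs$Q - implied) / obs$Q > tol
  obs$excluded <- bad
  obs$reason <- ifelse(bad, sprintf(
    "Q = %.4g inconsistent with R*A/1000 = %.4g", obs$Q, implied
  ), NA_character_)
  obs
}
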