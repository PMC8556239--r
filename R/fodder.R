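# Fodder-crop stage: humidity/dry-matter harmonization, reference-year yield
# estimation, the linear yield trend with grazing inflation, and N harvest.

#' Dry-matter fraction implied by a humidity basis
#'
#' Harvests of crops cut green are reported on varying water bases:
#' `national_percent` carries an explicit water percentage (0--88%),
#' `eu_standard` is the standard 65% water content for plants harvested
#' green, `dry_matter` is 0% water, `hay` assumes 85% dry matter, and
#' `fodder_root_default` assumes 16% dry matter (fodder roots are reported
#' without humidity values).
#'
#' @param basis One of `"national_percent"`, `"eu_standard"`, `"dry_matter"`,
#'   `"hay"`, `"fodder_root_default"` (vectorized).
#' @param water_pct Water content in percent, required for
#'   `national_percent`.
#' @return Dry-matter fraction in (0, 1].
#' @export
dm_fraction <- function(basis, water_pct = NA_real_) {
  basis <- as.character(basis)
  known <- c("national_percent", "eu_standard", "dry_matter", "hay", "fodder_root_default")
  if (!all(basis %in% known)) {
    stop("unknown humidity basis: ", paste(setdiff(basis, known), collapse = ", "))
  }
  water_pct <- rep_len(water_pct, length(basis))
  out <- dplyr::case_when(
    basis == "dry_matter" ~ 1,
    basis == "eu_standard" ~ 0.35,
    basis == "hay" ~ 0.85,
    basis == "fodder_root_default" ~ 0.16,
    .default = 1 - water_pct / 100
  )
  if (any(is.na(out))) stop("national_percent basis requires water_pct")
  if (any(out <= 0 | out > 1)) stop("implied dry-matter fraction outside (0, 1]")
  out
}

#' Convert a yield or production value to dry matter
#'
#' @param value Yield or production on the given basis.
#' @param basis Humidity basis (see [dm_fraction()]).
#' @param water_pct Water content for `national_percent`.
#' @return Dry-matter value (`value * dm_fraction`).
#' @examples
#' to_dry_matter(40, "eu_standard") # 14
#' to_dry_matter(50, "fodder_root_default") # 8
#' @export
to_dry_matter <- function(value, basis, water_pct = NA_real_) {
  value * dm_fraction(basis, water_pct)
}

#' Flag suspect yield reports across humidity bases
#'
#' Advisory screening of candidate yield series for the reporting errors
#' typical of mixed-humidity harvest statistics: (a) identical yields in
#' national and standard humidity although the humidity values differ (at
#' most one of the implied dry-matter yields can be right); (b) year-to-year
#' jumps where the old value on one basis roughly equals the new value on
#' another, i.e. the ratio of consecutive values matches the implied
#' dry-matter factor; (c) dry-matter yields outside plausible bounds. Flags
#' are advisory only; the final selection of yield observations is
#' config-driven.
#'
#' @param obs Tibble of yield observations for one country/crop: columns
#'   `year`, `value`, `basis`, `water_pct`.
#' @param jump_tol Relative tolerance for the basis-factor jump test.
#' @param dm_bounds Plausible dry-matter yield range (t DM/ha).
#' @return Tibble of flags: `year`, `type` (`"equal_across_bases"`,
#'   `"basis_jump"`, `"implausible_dm"`), `detail`.
#' @export
flag_yield_anomalies <- function(obs, jump_tol = 0.02, dm_bounds = c(0.5, 25)) {
  obs <- dplyr::arrange(tibble::as_tibble(obs), .data$year)
  flags <- list()
  # (a) equal value in national and EU-standard humidity with differing water
  nat <- obs[obs$basis == "national_percent", c("year", "value", "water_pct")]
  eu <- obs[obs$basis == "eu_standard", c("year", "value")]
  both <- dplyr::inner_join(nat, eu, by = "year", suffix = c("_nat", "_eu"))
  if (nrow(both) > 0) {
    a <- both[abs(both$value_nat - both$value_eu) < 1e-9 &
      abs(both$water_pct - 65) > 1e-9, ]
    if (nrow(a) > 0) {
      flags <- c(flags, list(tibble::tibble(
        year = a$year, type = "equal_across_bases",
        detail = "identical value in national and standard humidity"
      )))
    }
  }
  # (b) consecutive-year ratio equals an implied DM factor
  per_basis <- split(obs, obs$basis)
  for (b in names(per_basis)) {
    d <- per_basis[[b]]
    if (nrow(d) < 2) next
    f <- dm_fraction(d$basis, d$water_pct)
    r <- d$value[-1] / d$value[-nrow(d)]
    fac <- f[-1]
    hit <- !is.na(r) & (abs(r / fac - 1) < jump_tol | abs(r * fac - 1) < jump_tol) &
      abs(r - 1) > 0.2
    if (any(hit)) {
      flags <- c(flags, list(tibble::tibble(
        year = d$year[-1][hit], type = "basis_jump",
        detail = "year-to-year step matches the dry-matter factor"
      )))
    }
  }
  # (c) implausible dry-matter level
  dm <- to_dry_matter(obs$value, obs$basis, obs$water_pct)
  bad <- !is.na(dm) & (dm < dm_bounds[1] | dm > dm_bounds[2])
  if (any(bad)) {
    flags <- c(flags, list(tibble::tibble(
      year = obs$year[bad], type = "implausible_dm",
      detail = sprintf("dry-matter yield %.2f t/ha outside [%g, %g]", dm[bad], dm_bounds[1], dm_bounds[2])
    )))
  }
  if (length(flags) == 0) {
    return(tibble::tibble(year = integer(), type = character(), detail = character()))
  }
  dplyr::distinct(dplyr::bind_rows(flags))
}

#' Reference-yield model for a fodder crop
#'
#' Dry-matter yields are modeled as a line anchored at a reference year: the
#' 1961 yield is `anchor` (default 75%) of the 2010 reference yield, with the
#' same slope continued past 2010. For temporary grassland (G1000) the yield
#' is additionally inflated (default +20%) to account for grazing intake on
#' top of the mechanical harvest recorded in statistics.
#'
#' @param crop Crop code.
#' @param country Country code.
#' @param y2010 Reference dry-matter yield in 2010 (t DM/ha).
#' @param anchor Fraction of the 2010 yield attained in 1961, in (0, 1].
#' @param inflation Multiplicative grazing correction (>= 1), applied to
#'   G1000 only.
#' @param inflate Logical switch for the grazing correction (uniformly on by
#'   default).
#' @return A `yield_model` list.
#' @export
yield_model <- function(crop, country, y2010, anchor = 0.75, inflation = 1.2,
                        inflate = TRUE) {
  stopifnot(y2010 > 0, anchor > 0, anchor <= 1, inflation >= 1)
  structure(
    list(
      crop = crop, country = country, y2010 = y2010, anchor = anchor,
      inflation = inflation, inflate = inflate
    ),
    class = "yield_model"
  )
}

#' Evaluate a yield model at given years
#'
#' `y(t) = y2010 * (anchor + (1 - anchor) * (t - 1961) / (2010 - 1961))`,
#' times the grazing inflation factor for G1000. The line interpolates
#' exactly `(1961, anchor * y2010)` and `(2010, y2010)` and continues with
#' the same slope to 2019.
#'
#' @param model A [yield_model()].
#' @param year Integer vector of years.
#' @return Dry-matter yields (t DM/ha).
#' @export
yield_at <- function(model, year) {
  stopifnot(inherits(model, "yield_model"))
  f <- model$anchor + (1 - model$anchor) * (year - 1961) / (2010 - 1961)
  y <- model$y2010 * f
  if (identical(model$crop, "G1000") && isTRUE(model$inflate)) {
    y <- y * model$inflation
  }
  y
}

#' Estimate the 2010 reference yield from selected observations
#'
#' The reference yield is the unweighted mean of the config-selected yield
#' observations, each converted to dry matter. Selection (which years and
#' bases to trust) is a config list, mirroring the hand-picking a careful
#' analyst performs on mixed-humidity harvest statistics; the default picks
#' the dry-matter observations of 2010.
#'
#' @param obs Yield observation tibble: `country`, `crop`, `year`, `value`,
#'   `basis`, `water_pct`.
#' @param selection Tibble `country`, `crop`, `year`, `basis` naming the
#'   picked observations; `NULL` selects `year == 2010, basis ==
#'   "dry_matter"` rows for every country/crop present.
#' @return Tibble `country`, `crop`, `y2010` (t DM/ha); country/crop pairs
#'   with no selected observation are absent (fill via [donor_yield()]).
#' @export
estimate_reference_yield <- function(obs, selection = NULL) {
  obs <- tibble::as_tibble(obs)
  if (is.null(selection)) {
    picked <- dplyr::filter(obs, .data$year == 2010, .data$basis == "dry_matter")
  } else {
    picked <- dplyr::inner_join(
      obs, tibble::as_tibble(selection),
      by = c("country", "crop", "year", "basis")
    )
  }
  picked |>
    dplyr::mutate(dm = to_dry_matter(.data$value, .data$basis, .data$water_pct)) |>
    dplyr::group_by(.data$country, .data$crop) |>
    dplyr::summarise(y2010 = mean(.data$dm), .groups = "drop")
}

#' Production-weighted average yield of merged crop codes
#'
#' When a merged code's components report yields separately, the combined
#' yield is their production-weighted mean.
#'
#' @param yields Component yields.
#' @param production Component production weights (same length, nonnegative,
#'   positive sum).
#' @return Weighted mean yield.
#' @export
production_weighted_yield <- function(yields, production) {
  stopifnot(length(yields) == length(production), all(production >= 0))
  if (sum(production) <= 0) stop("production weights sum to zero")
  sum(yields * production) / sum(production)
}

#' Fill a missing reference yield from donor countries
#'
#' Copies (single donor) or averages (unweighted mean over donors) the 2010
#' reference yields of neighboring countries with similar climate and
#' productivity.
#'
#' @param ref Reference-yield tibble (`country`, `crop`, `y2010`).
#' @param target Country to fill.
#' @param crop Crop code to fill.
#' @param donors Character vector of donor countries (nonempty).
#' @return `ref` with the target row added.
#' @export
donor_yield <- function(ref, target, crop, donors) {
  if (length(donors) == 0) stop("empty donor list")
  d <- ref[ref$country %in% donors & ref$crop == crop, ]
  if (nrow(d) < length(donors)) {
    stop(
      "missing donor yield for crop ", crop, ": ",
      paste(setdiff(donors, d$country), collapse = ", ")
    )
  }
  dplyr::bind_rows(ref, tibble::tibble(
    country = target, crop = crop, y2010 = mean(d$y2010)
  ))
}

#' Fodder N harvest
#'
#' `area (kha) * dry-matter yield (t DM/ha) * N content (% N of DM) / 100`;
#' kha times t/ha is a kilotonne, i.e. a Gg, so the result is Gg N.
#'
#' @param area_kha Harvested area (kha).
#' @param dm_yield Dry-matter yield (t DM/ha).
#' @param n_content N content (% N of DM).
#' @return N harvest (Gg N).
#' @examples
#' fodder_n_harvest(100, 5, 2.3) # 11.5
#' @export
fodder_n_harvest <- function(area_kha, dm_yield, n_content) {
  stopifnot(all(area_kha >= 0 | is.na(area_kha)), all(dm_yield >= 0 | is.na(dm_yield)))
  area_kha * dm_yield * n_content / 100
}
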