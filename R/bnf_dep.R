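# Symbiotic N fixation (linear in harvested legume N) and atmospheric N
# deposition input to cropland.

#' Default symbiotic-fixation parameter table (synthetic placeholders)
#'
#' Per-category fixation parameters: Ndfa (fraction of plant N derived from
#' the atmosphere), BGN (total-to-aboveground plant N ratio, >= 1), NHI
#' (harvested-to-aboveground N ratio), the legume dry-matter share of the
#' harvest, and the N content of the legume fraction (% N of DM). The legume
#' DM shares follow the standard assumptions for the green-harvest crop
#' codes (temporary grassland 25%, other green legumes 90%, lucerne 100%,
#' other green-harvested plants 25%, pulses 100%). The Ndfa/BGN/NHI values
#' here are plausible placeholders for testing, NOT a published parameter
#' set; real analyses must supply their own table.
#'
#' @return Tibble `code`, `ndfa`, `bgn`, `nhi`, `legume_dm_share`,
#'   `legume_n_content`.
#' @export
bnf_params_default <- function() {
  tibble::tribble(
    ~code, ~ndfa, ~bgn, ~nhi, ~legume_dm_share, ~legume_n_content,
    "G1000", 0.80, 1.40, 0.80, 0.25, 3.3,
    "G2100", 0.80, 1.40, 0.80, 1.00, 3.0,
    "G2900", 0.80, 1.40, 0.80, 0.90, 3.3,
    "G9000", 0.70, 1.40, 0.80, 0.25, 3.0,
    "Pulses", 0.65, 1.30, 0.75, 1.00, NA
  )
}

#' Harvested legume N of a mixed stand
#'
#' `dm_harvest * legume_dm_share * legume_n_content / 100`: the N removed in
#' the legume fraction of the harvest, the `Y` entering the fixation model.
#'
#' @param dm_harvest Dry-matter harvest (Gg DM), vectorized.
#' @param legume_dm_share Legume fraction of the DM harvest, in \[0, 1\].
#' @param legume_n_content N content of the legume fraction (% N of DM).
#' @return Legume N harvest (Gg N).
#' @examples
#' legume_n_harvest(100, 0.25, 3.3) # 0.825
#' @export
legume_n_harvest <- function(dm_harvest, legume_dm_share, legume_n_content) {
  stopifnot(
    all(dm_harvest >= 0 | is.na(dm_harvest)),
    all(legume_dm_share >= 0 & legume_dm_share <= 1)
  )
  dm_harvest * legume_dm_share * legume_n_content / 100
}

#' Symbiotic N fixation from harvested legume N
#'
#' Fixation is assumed linear in the harvested legume N yield:
#' `BNF = Y * Ndfa * BGN / NHI`. Since `BGN >= 1` and `NHI <= 1`,
#' `BNF >= Y * Ndfa` always.
#'
#' @param y_legume Harvested legume N (Gg N), vectorized.
#' @param ndfa Fraction of plant N from the atmosphere, in \[0, 1\].
#' @param bgn Total-to-aboveground plant N ratio (>= 1).
#' @param nhi N harvest index in (0, 1].
#' @return Fixed N (Gg N).
#' @examples
#' bnf(1, 0.8, 1.5, 0.6) # 2
#' @export
bnf <- function(y_legume, ndfa, bgn, nhi) {
  stopifnot(all(ndfa >= 0 & ndfa <= 1), all(bgn >= 1))
  if (any(nhi <= 0)) stop("N harvest index must be positive")
  y_legume * ndfa * bgn / nhi
}

#' Atmospheric N deposition input to cropland
#'
#' Multiplies the deposition rate by the cropland area in use
#' (`Gg = kg/ha * kha / 1000`). Rate series that end early are extrapolated
#' constant forward to the end of the grid (e.g. rates ending in 2013 are
#' held constant through 2019).
#'
#' @param rates Series tibble `year`, `value` (kg N/ha/yr) for one country;
#'   may end before the grid does.
#' @param area Series tibble `year`, `value` (kha), cropland in use.
#' @return Series tibble `year`, `value` (Gg N/yr).
#' @export
deposition_to_cropland <- function(rates, area) {
  area <- dplyr::arrange(tibble::as_tibble(area), .data$year)
  r <- tibble::tibble(year = area$year) |>
    dplyr::left_join(dplyr::arrange(tibble::as_tibble(rates), .data$year), by = "year")
  if (any(!is.na(r$value) & r$value < 0)) stop("negative deposition rate")
  r <- extrapolate_const(r, "forward")
  tibble::tibble(year = area$year, value = r$value * area$value / 1000)
}
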