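# Manure N flow chain: excretion totals per livestock class, allocation to
# manure management systems, housing/storage losses, land allocation, and
# the split between cropland and permanent grassland. Every partition is
# computed as product + residual complement, so the conservation identities
# hold at machine precision in telescoped form (see the methods vignette).

#' Manure-management-system aggregation map
#'
#' Collapses the detailed inventory systems into four simplified classes:
#' grazing (pasture, range and paddock), solid (composting, daily spread,
#' solid storage and dry lot), liquid (anaerobic lagoon, digesters, liquid
#' system), and other.
#' @return Tibble `system`, `simplified`.
#' @export
mms_system_map <- function() {
  tibble::tribble(
    ~system, ~simplified,
    "Pasture range and paddock", "grazing",
    "Composting", "solid",
    "Daily spread", "solid",
    "Solid storage and dry lot", "solid",
    "Anaerobic lagoon", "liquid",
    "Digesters", "liquid",
    "Liquid system", "liquid",
    "Other", "other"
  )
}

#' Livestock-class aggregation map
#'
#' Collapses detailed inventory livestock classes into three:
#' ruminants and equines, pigs, and poultry and rabbits.
#' @return Tibble `class`, `simplified`.
#' @export
mms_class_map <- function() {
  tibble::tribble(
    ~class, ~simplified,
    "Cattle", "ruminants_equines",
    "Sheep", "ruminants_equines",
    "Buffalo", "ruminants_equines",
    "Goats", "ruminants_equines",
    "Horses", "ruminants_equines",
    "Mules and Asses", "ruminants_equines",
    "Swine", "pigs",
    "Poultry", "poultry_rabbits",
    "Rabbit", "poultry_rabbits"
  )
}

#' Aggregate detailed MMS excretion data to simplified shares
#'
#' Takes N quantities excreted per detailed system and livestock class and
#' returns, per country-year and simplified class, the share excreted in
#' each simplified system. Aggregation over livestock classes is
#' excretion-weighted by construction (quantities are summed before the
#' shares are formed). The last share per group is computed as the
#' complement so shares sum to 1 exactly.
#'
#' @param raw Tibble `country`, `year`, `class` (detailed), `system`
#'   (detailed), `value` (Gg N/yr excreted in that system).
#' @return Tibble `country`, `year`, `class` (simplified), `system`
#'   (simplified), `share`.
#' @export
aggregate_mms <- function(raw) {
  raw <- tibble::as_tibble(raw)
  smap <- mms_system_map()
  cmap <- mms_class_map()
  if (!all(raw$system %in% smap$system)) {
    stop(
      "unmapped manure management system: ",
      paste(setdiff(raw$system, smap$system), collapse = ", ")
    )
  }
  if (!all(raw$class %in% cmap$class)) {
    stop(
      "unmapped livestock class: ",
      paste(setdiff(raw$class, cmap$class), collapse = ", ")
    )
  }
  systems <- c("grazing", "solid", "liquid", "other")
  agg <- raw |>
    dplyr::mutate(
      class = cmap$simplified[match(.data$class, cmap$class)],
      system = smap$simplified[match(.data$system, smap$system)]
    ) |>
    dplyr::group_by(.data$country, .data$year, .data$class, .data$system) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("country"), !!rlang::sym("year"), !!rlang::sym("class")),
      system = systems, fill = list(value = 0)
    )
  agg |>
    dplyr::group_by(.data$country, .data$year, .data$class) |>
    dplyr::mutate(share = .data$value / sum(.data$value)) |>
    dplyr::group_modify(function(d, key) {
      # complement in the last listed system for an exact unit sum
      ord <- match(systems, d$system)
      d <- d[ord, ]
      d$share[length(systems)] <- 1 - sum(d$share[-length(systems)])
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::select("country", "year", "class", "system", "share")
}

#' Extend MMS shares over the full year grid
#'
#' Inventory time series typically start around 1990; shares are
#' extrapolated constant backward to the start of the grid and forward to
#' its end (e.g. 2019 takes the 2018 shares). Extrapolated years keep the
#' exact unit sum of the year they copy.
#'
#' @param shares Output of [aggregate_mms()].
#' @param grid Year grid.
#' @return Shares over the full grid.
#' @export
backfill_shares <- function(shares, grid = default_grid()) {
  shares |>
    dplyr::group_by(.data$country, .data$class, .data$system) |>
    dplyr::group_modify(function(d, key) {
      s <- tibble::tibble(year = as.integer(grid)) |>
        dplyr::left_join(d[, c("year", "share")], by = "year") |>
        dplyr::rename(value = "share")
      s <- extrapolate_const(s, "both")
      tibble::tibble(year = s$year, share = s$value)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("country", "year", "class", "system", "share")
}

#' Split excretion into grazing and housed
#'
#' `grazing = total * share`; housed is the exact complement.
#' @param excreted_total Total excretion (Gg N/yr), vectorized.
#' @param grazing_share Share excreted on pasture, in \[0, 1\].
#' @return Tibble `grazing`, `housed`.
#' @export
split_grazing_housed <- function(excreted_total, grazing_share) {
  stopifnot(all(grazing_share >= 0 & grazing_share <= 1))
  grazing <- excreted_total * grazing_share
  tibble::tibble(grazing = grazing, housed = excreted_total - grazing)
}

#' Housing and storage N losses
#'
#' `lost = housed * loss_share`; the quantity reaching the field is the
#' exact complement. A generic 30% loss share is a common fallback where no
#' country-specific estimate exists.
#'
#' @param housed In-house excretion (Gg N/yr), vectorized.
#' @param loss_share Loss fraction in \[0, 1).
#' @return Tibble `lost`, `applied`.
#' @export
apply_storage_losses <- function(housed, loss_share) {
  if (any(loss_share >= 1 | loss_share < 0)) stop("loss share must lie in [0, 1)")
  lost <- housed * loss_share
  tibble::tibble(lost = lost, applied = housed - lost)
}

#' Liquid/solid division of stored manure
#'
#' Land-allocation data assume a binary liquid/solid division, while
#' inventories sometimes report an "other" system. When the "other" share of
#' in-house excretion is at most `threshold` (default 20%), the mismatch is
#' ignored and liquid/solid are renormalized to sum to 1; above the
#' threshold, exogenous liquid/solid shares must be supplied (an error names
#' the offender otherwise).
#'
#' @param solid,liquid,other Shares of in-house (non-grazing) excretion.
#' @param threshold Maximum tolerated "other" share.
#' @param override Optional numeric `c(liquid =, solid =)` replacing the
#'   renormalization.
#' @param label Country/class label used in error messages.
#' @return Tibble `liquid`, `solid` (fractions summing to 1 exactly).
#' @export
liquid_solid_shares <- function(solid, liquid, other = 0, threshold = 0.2,
                                override = NULL, label = "") {
  if (!is.null(override)) {
    stopifnot(all(c("liquid", "solid") %in% names(override)))
    l <- unname(override["liquid"] / (override["liquid"] + override["solid"]))
    return(tibble::tibble(liquid = l, solid = 1 - l))
  }
  inhouse <- solid + liquid + other
  if (inhouse <= 0) stop("no in-house excretion to divide", if (nzchar(label)) paste0(" (", label, ")"))
  if (other / inhouse > threshold) {
    stop(
      "'other' manure system share ", sprintf("%.0f%%", 100 * other / inhouse),
      " exceeds ", sprintf("%.0f%%", 100 * threshold),
      "; exogenous liquid/solid data required",
      if (nzchar(label)) paste0(" (", label, ")")
    )
  }
  if (solid + liquid <= 0) stop("liquid + solid share is zero", if (nzchar(label)) paste0(" (", label, ")"))
  l <- liquid / (liquid + solid)
  tibble::tibble(liquid = l, solid = 1 - l)
}

#' Effective grass share of applied manure for a livestock class
#'
#' Ruminants/equines and pigs have separate grass/non-grass allocation
#' shares for liquid and solid manure; the effective share is their mean
#' weighted by the liquid/solid division averaged over a reference window
#' (default 1997--2001, matching the vintage of the allocation surveys).
#' Poultry and rabbits use a single share. The resulting grass share is held
#' constant over the whole period, on the assumption that the grass/non-grass
#' destination has remained stable even though management systems varied.
#'
#' @param liquid_weight Mean liquid fraction of stored manure over the
#'   window.
#' @param grass_alloc_liquid,grass_alloc_solid Grass shares for liquid and
#'   solid manure, in \[0, 1\].
#' @return Effective grass share.
#' @examples
#' effective_grass_share(0.6, 0.8, 0.5) # 0.68
#' @export
effective_grass_share <- function(liquid_weight, grass_alloc_liquid, grass_alloc_solid) {
  stopifnot(
    all(liquid_weight >= 0 & liquid_weight <= 1),
    all(grass_alloc_liquid >= 0 & grass_alloc_liquid <= 1),
    all(grass_alloc_solid >= 0 & grass_alloc_solid <= 1)
  )
  liquid_weight * grass_alloc_liquid + (1 - liquid_weight) * grass_alloc_solid
}

#' Split grass-destined manure N between permanent and temporary grassland
#'
#' Grassland-destined N (field-applied grass share plus all grazing
#' excretion) is divided between permanent and temporary grassland in
#' proportion to their areas; the temporary-grassland portion belongs to
#' cropland, so `to_cropland = applied_nongrass + TG portion` and
#' `to_permanent_grassland` is the exact remainder of the grass-destined N.
#'
#' @param applied_grass Field-applied manure N destined to grassland (Gg).
#' @param excreted_grazing Grazing excretion (Gg), all on grassland.
#' @param applied_nongrass Field-applied manure N on non-grass cropland (Gg).
#' @param a_pg,a_tg Grassland areas (kha).
#' @return Tibble `to_cropland`, `to_permanent_grassland`.
#' @export
split_to_land <- function(applied_grass, excreted_grazing, applied_nongrass,
                          a_pg, a_tg) {
  grass_destined <- applied_grass + excreted_grazing
  w <- grassland_weights(a_pg, a_tg)
  if (any(grass_destined > 0 & !is.na(w$flag))) {
    stop("grass-destined manure N with zero grassland area")
  }
  to_tg <- grass_destined * w$w_tg
  tibble::tibble(
    to_temporary_grassland = to_tg,
    to_cropland = applied_nongrass + to_tg,
    to_permanent_grassland = grass_destined - to_tg
  )
}

#' Full manure N flow table
#'
#' Chains the flow per country-year-class: excretion split into grazing and
#' housed by the (backfilled) management-system shares; housing/storage
#' losses; land allocation of the applied remainder via the effective grass
#' share; and the final split of grassland-destined N between permanent and
#' temporary grassland by area. Conservation holds at machine precision:
#' each partition is a product plus its exact complement
#' (`excreted_total - excreted_grazing == excreted_housed`, etc.).
#'
#' @param excretion Tibble `country`, `year`, `class` (simplified), `value`
#'   (Gg N/yr excreted).
#' @param mms_shares Backfilled shares from [backfill_shares()].
#' @param loss_shares Tibble `country`, `class`, `loss_share`.
#' @param grass_shares Tibble `country`, `class`, `grass_share` (effective,
#'   from [land_allocation_shares()] or supplied directly).
#' @param areas Tibble `country`, `year`, `a_pg`, `a_tg` (kha).
#' @return Flow tibble per country-year-class with columns `excreted_total`,
#'   `excreted_grazing`, `excreted_housed`, `lost_housing_storage`,
#'   `applied_total`, `applied_grass`, `applied_nongrass`, `to_cropland`,
#'   `to_permanent_grassland` (all Gg N/yr).
#' @export
manure_flows <- function(excretion, mms_shares, loss_shares, grass_shares, areas) {
  grazing <- mms_shares |>
    dplyr::filter(.data$system == "grazing") |>
    dplyr::select("country", "year", "class", grazing_share = "share")
  d <- excretion |>
    dplyr::inner_join(grazing, by = c("country", "year", "class")) |>
    dplyr::inner_join(loss_shares, by = c("country", "class")) |>
    dplyr::inner_join(grass_shares, by = c("country", "class")) |>
    dplyr::inner_join(areas, by = c("country", "year"))
  gh <- split_grazing_housed(d$value, d$grazing_share)
  la <- apply_storage_losses(gh$housed, d$loss_share)
  applied_grass <- la$applied * d$grass_share
  applied_nongrass <- la$applied - applied_grass
  land <- split_to_land(applied_grass, gh$grazing, applied_nongrass, d$a_pg, d$a_tg)
  tibble::tibble(
    country = d$country, year = d$year, class = d$class,
    excreted_total = d$value,
    excreted_grazing = gh$grazing,
    excreted_housed = gh$housed,
    lost_housing_storage = la$lost,
    applied_total = la$applied,
    applied_grass = applied_grass,
    applied_nongrass = applied_nongrass,
    to_temporary_grassland = land$to_temporary_grassland,
    to_cropland = land$to_cropland,
    to_permanent_grassland = land$to_permanent_grassland
  )
}

#' Effective land-allocation (grass) shares per country and class
#'
#' Combines the liquid/solid allocation survey with the mean
#' management-system division over a reference window. For ruminants/equines
#' and pigs the allocation table carries rows `manure_type` in
#' `{"liquid", "solid"}`; poultry and rabbits carry a single row
#' `manure_type == "all"`. Donor-country mappings fill countries absent from
#' the survey.
#'
#' @param alloc Tibble `country`, `class`, `manure_type`, `grass_share`.
#' @param mms_shares Backfilled shares from [backfill_shares()].
#' @param window Two-year vector, the averaging window for the liquid/solid
#'   weights (default `c(1997, 2001)`).
#' @param other_threshold Maximum tolerated "other" system share (see
#'   [liquid_solid_shares()]).
#' @param donors Optional named character vector `target = donor` copying a
#'   donor country's allocation rows.
#' @return Tibble `country`, `class`, `grass_share`.
#' @export
land_allocation_shares <- function(alloc, mms_shares, window = c(1997, 2001),
                                   other_threshold = 0.2, donors = NULL) {
  alloc <- tibble::as_tibble(alloc)
  if (!is.null(donors)) {
    extra <- purrr::imap(donors, function(donor, target) {
      d <- alloc[alloc$country == donor, ]
      if (nrow(d) == 0) stop("donor country absent from allocation table: ", donor)
      d$country <- target
      d
    })
    alloc <- dplyr::bind_rows(alloc, dplyr::bind_rows(extra))
  }
  # mean liquid/solid division over the window, per country-class
  win <- mms_shares |>
    dplyr::filter(.data$year >= window[1], .data$year <= window[2]) |>
    tidyr::pivot_wider(names_from = "system", values_from = "share") |>
    dplyr::group_by(.data$country, .data$class) |>
    dplyr::summarise(
      solid = mean(.data$solid), liquid = mean(.data$liquid),
      other = mean(.data$other), .groups = "drop"
    )
  weights <- win |>
    dplyr::rowwise() |>
    dplyr::mutate(liquid_weight = liquid_solid_shares(
      .data$solid, .data$liquid, .data$other,
      threshold = other_threshold,
      label = paste(.data$country, .data$class)
    )$liquid) |>
    dplyr::ungroup() |>
    dplyr::select("country", "class", "liquid_weight")
  split_types <- alloc |>
    dplyr::filter(.data$manure_type %in% c("liquid", "solid")) |>
    tidyr::pivot_wider(names_from = "manure_type", values_from = "grass_share") |>
    dplyr::inner_join(weights, by = c("country", "class")) |>
    dplyr::mutate(grass_share = effective_grass_share(
      .data$liquid_weight, .data$liquid, .data$solid
    )) |>
    dplyr::select("country", "class", "grass_share")
  single <- alloc |>
    dplyr::filter(.data$manure_type == "all") |>
    dplyr::select("country", "class", grass_share = "grass_share")
  dplyr::bind_rows(split_types, single) |>
    dplyr::arrange(.data$country, .data$class)
}
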