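# Pipeline orchestration: run the stages in order (crops -> fodder -> land
# -> fertilizer -> manure -> fixation/deposition -> budget), collect stage
# outputs, the edit log, and validation flags.

fodder_category_map <- function() {
  tibble::tibble(
    code = c("G1000", "G2100", "G2900", "G3000", "G9000", "R9000"),
    category = c(
      "Temporary grassland", "Forage legumes", "Forage legumes",
      "Green maize", "Other forage crops", "Fodder roots"
    )
  )
}

stage_crops <- function(obs, config) {
  records <- obs$crops |>
    dplyr::inner_join(obs$crop_meta, by = "crop") |>
    dplyr::mutate(n_harvest = n_harvest(.data$production, .data$n_content))
  agg <- aggregate_categories(records)
  panel <- category_panel(agg)
  panel <- apply_category_overrides(panel, config$category_overrides %||% list())
  list(aggregates = agg, panel = panel)
}

stage_fodder <- function(obs, config) {
  areas <- apply_edit_rules(obs$fodder_area, config$fodder_rules %||% list())
  edit_log <- attr(areas, "edit_log")
  ref <- estimate_reference_yield(obs$fodder_yield_obs, config$yield_selection)
  for (d in config$yield_donors %||% list()) {
    ref <- donor_yield(ref, d$target, d$crop, d$donors)
  }
  ncont <- fodder_n_contents()
  codes <- fodder_category_map()$code
  countries <- unique(areas$country)
  per_code <- purrr::map_dfr(countries, function(co) {
    purrr::map_dfr(codes, function(code) {
      a <- panel_series(areas, co, code)
      y2010 <- ref$y2010[ref$country == co & ref$crop == code]
      if (length(y2010) != 1) {
        stop("no reference yield for ", co, "/", code, " (supply a donor rule)")
      }
      model <- yield_model(code, co, y2010,
        anchor = config$anchor %||% 0.75,
        inflation = config$inflation %||% 1.2,
        inflate = config$inflate_grazing %||% TRUE
      )
      dm_yield <- yield_at(model, a$year)
      nc <- ncont$n_content[ncont$code == code]
      tibble::tibble(
        country = co, year = a$year, crop = code,
        area = a$value, dm_yield = dm_yield,
        dm_harvest = a$value * dm_yield, # kha * t/ha = Gg DM
        n_harvest = fodder_n_harvest(a$value, dm_yield, nc)
      )
    })
  })
  by_category <- per_code |>
    dplyr::inner_join(fodder_category_map(), by = c(crop = "code")) |>
    dplyr::arrange(.data$country, .data$category, .data$year, .data$crop) |>
    dplyr::group_by(.data$country, .data$year, .data$category) |>
    dplyr::summarise(
      area = sum(.data$area), n_harvest = sum(.data$n_harvest),
      .groups = "drop"
    )
  list(
    areas = areas, reference_yields = ref, per_code = per_code,
    by_category = by_category, edit_log = edit_log
  )
}

stage_land <- function(obs, crops_stage, fodder_stage) {
  cat_areas <- dplyr::bind_rows(
    crops_stage$panel |>
      dplyr::filter(startsWith(.data$variable, "area:")) |>
      dplyr::transmute(.data$country, .data$year,
        category = sub("^area:", "", .data$variable), area = .data$value
      ),
    fodder_stage$by_category |>
      dplyr::select("country", "year", "category", "area")
  )
  a_sum <- cat_areas |>
    dplyr::arrange(.data$country, .data$year, .data$category) |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(a_crop_sum = sum(.data$area), .groups = "drop")
  reported <- obs$land |>
    dplyr::filter(.data$variable == "cropland_reported") |>
    dplyr::select("country", "year", a_reported = "value")
  pg <- obs$land |>
    dplyr::filter(.data$variable == "permanent_grassland") |>
    dplyr::select("country", "year", a_pg = "value")
  tg <- fodder_stage$per_code |>
    dplyr::filter(.data$crop == "G1000") |>
    dplyr::select("country", "year", a_tg = "area")
  a_sum |>
    dplyr::left_join(reported, by = c("country", "year")) |>
    dplyr::left_join(pg, by = c("country", "year")) |>
    dplyr::left_join(tg, by = c("country", "year")) |>
    dplyr::mutate(a_c_in_use = cropland_in_use(.data$a_crop_sum, .data$a_reported))
}

stage_fert <- function(obs, config, land) {
  obs_checked <- check_fert_obs(obs$fert_obs, tol = config$fert_obs_tol %||% 0.005)
  usable <- dplyr::filter(obs_checked, !.data$excluded)
  countries <- unique(land$country)
  fert <- purrr::map_dfr(countries, function(co) {
    la <- dplyr::filter(land, .data$country == co)
    zero_pg <- co %in% (config$zero_pg %||% character())
    if (zero_pg) {
      rr <- build_rate_ratio_series(NULL, grid = la$year, zero_pg = TRUE)
    } else {
      d <- dplyr::filter(usable, .data$country == co)
      pts <- d |>
        dplyr::group_by(.data$year, .data$source) |>
        dplyr::group_modify(function(g, key) {
          has <- function(cat) any(g$land_category == cat)
          rate <- function(cat) g$R[g$land_category == cat][1]
          yr <- key$year
          ar <- la[la$year == yr, ]
          if (has("C") && has("PG")) {
            tibble::tibble(ratio = rate("PG") / rate("C"), route = "eq2-direct")
          } else if (has("C_minus_TG") && has("PG_plus_TG")) {
            k <- (config$k %||% list())[[co]] %||% 1
            tibble::tibble(
              ratio = rate_ratio_from_total_grass(
                rate("PG_plus_TG"), rate("C_minus_TG"),
                a_pg = ar$a_pg, a_tg = ar$a_tg, a_c = ar$a_reported, k = k
              ),
              route = "eq5"
            )
          } else if (has("PG") && !has("C")) {
            q_tot <- obs$fert_total$value[
              obs$fert_total$country == co & obs$fert_total$year == yr
            ]
            tibble::tibble(
              ratio = rate_ratio_last_resort(
                rate("PG"), ar$a_pg, ar$a_pg + ar$a_reported, q_tot
              ),
              route = "eq6"
            )
          } else {
            tibble::tibble(ratio = numeric(), route = character())
          }
        }) |>
        dplyr::ungroup()
      rr <- build_rate_ratio_series(pts[, c("year", "ratio")], grid = la$year)
    }
    share <- share_to_cropland(rr$ratio, la$a_pg, la$a_reported)
    ft <- dplyr::arrange(dplyr::filter(obs$fert_total, .data$country == co), .data$year)
    q_tot <- ft$value[match(la$year, ft$year)]
    q <- allocate_quantities(q_tot, share)
    tibble::tibble(
      country = co, year = la$year,
      rate_ratio = rr$ratio, provenance = rr$provenance,
      share_c = share, q_tot = q_tot, q_c = q$q_c, q_pg = q$q_pg,
      r_c = kg_per_ha(q$q_c, la$a_c_in_use),
      r_pg = kg_per_ha(q$q_pg, la$a_pg)
    )
  })
  list(fert = fert, excluded = dplyr::filter(obs_checked, .data$excluded))
}

stage_manure <- function(obs, config, land) {
  cmap <- mms_class_map()
  excretion <- obs$excretion_raw |>
    dplyr::mutate(class = cmap$simplified[match(.data$class, cmap$class)]) |>
    dplyr::group_by(.data$country, .data$year, .data$class) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  shares <- aggregate_mms(obs$mms_raw) |>
    backfill_shares(grid = sort(unique(land$year)))
  grass <- land_allocation_shares(
    obs$alloc_shares, shares,
    window = config$mms_window %||% c(1997, 2001),
    other_threshold = config$mms_other_threshold %||% 0.2,
    donors = config$alloc_donors
  )
  areas <- land |> dplyr::select("country", "year", "a_pg", "a_tg")
  flows <- manure_flows(excretion, shares, obs$loss_shares, grass, areas)
  totals <- flows |>
    dplyr::arrange(.data$country, .data$year, .data$class) |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(
      to_cropland = sum(.data$to_cropland),
      to_permanent_grassland = sum(.data$to_permanent_grassland),
      lost = sum(.data$lost_housing_storage),
      excreted_total = sum(.data$excreted_total),
      .groups = "drop"
    )
  list(flows = flows, totals = totals, mms_shares = shares, grass_shares = grass)
}

stage_bnf <- function(obs, crops_stage, fodder_stage) {
  params <- obs$bnf_params
  fodder_bnf <- fodder_stage$per_code |>
    dplyr::inner_join(params, by = c(crop = "code")) |>
    dplyr::mutate(
      y_legume = legume_n_harvest(
        .data$dm_harvest, .data$legume_dm_share, .data$legume_n_content
      ),
      bnf = bnf(.data$y_legume, .data$ndfa, .data$bgn, .data$nhi)
    ) |>
    dplyr::select("country", "year", category = "crop", "y_legume", "bnf")
  pulses <- crops_stage$panel |>
    dplyr::filter(.data$variable == "n_harvest:Pulses") |>
    dplyr::cross_join(params[params$code == "Pulses", ]) |>
    dplyr::mutate(
      y_legume = .data$value * .data$legume_dm_share,
      bnf = bnf(.data$y_legume, .data$ndfa, .data$bgn, .data$nhi)
    ) |>
    dplyr::select("country", "year", "y_legume", "bnf") |>
    dplyr::mutate(category = "Pulses", .after = "year")
  by_cat <- dplyr::bind_rows(fodder_bnf, pulses) |>
    dplyr::arrange(.data$country, .data$year, .data$category)
  total <- by_cat |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(bnf = sum(.data$bnf), .groups = "drop")
  list(by_category = by_cat, total = total)
}

stage_deposition <- function(obs, land) {
  purrr::map_dfr(unique(land$country), function(co) {
    la <- dplyr::filter(land, .data$country == co) |> dplyr::arrange(.data$year)
    rates <- obs$deposition_rates |>
      dplyr::filter(.data$country == co) |>
      dplyr::select("year", "value")
    dep <- deposition_to_cropland(rates, tibble::tibble(
      year = la$year, value = la$a_c_in_use
    ))
    tibble::tibble(country = co, year = dep$year, deposition_c = dep$value)
  })
}

#' Run the full budget pipeline
#'
#' Executes the stages in order -- crop-category aggregation, fodder area
#' gap-filling and harvest estimation, land bookkeeping, fertilizer
#' allocation, manure flows, symbiotic fixation and deposition -- and
#' assembles the cropland N budget per country-year.
#'
#' @param observables List of input tibbles (see [nb_generate()] for the
#'   components, or [read_observables()] to load them from CSVs).
#' @param config Pipeline configuration list: `fodder_rules`,
#'   `yield_selection`, `yield_donors`, `zero_pg`, `k`, `mms_window`,
#'   `mms_other_threshold`, `alloc_donors`, `category_overrides`, and the
#'   yield-trend parameters `anchor` (default 0.75), `inflation` (1.2),
#'   `inflate_grazing` (TRUE).
#' @return An `nbudget_build` list: stage outputs (`categories`,
#'   `crop_panel`, `fodder`, `land`, `fert`, `manure`, `bnf`,
#'   `deposition`), the final `budget` tibble, `edit_log`, and
#'   `excluded_obs`.
#' @export
nb_build <- function(observables, config = list()) {
  crops_stage <- stage_crops(observables, config)
  fodder_stage <- stage_fodder(observables, config)
  land <- stage_land(observables, crops_stage, fodder_stage)
  fert_stage <- stage_fert(observables, config, land)
  manure_stage <- stage_manure(observables, config, land)
  bnf_stage <- stage_bnf(observables, crops_stage, fodder_stage)
  deposition <- stage_deposition(observables, land)

  harvest <- dplyr::bind_rows(
    crops_stage$panel |>
      dplyr::filter(startsWith(.data$variable, "n_harvest:")) |>
      dplyr::transmute(.data$country, .data$year,
        category = sub("^n_harvest:", "", .data$variable), n_harvest = .data$value
      ),
    fodder_stage$by_category |>
      dplyr::select("country", "year", "category", "n_harvest")
  ) |>
    dplyr::arrange(.data$country, .data$year, .data$category) |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(harvest_n = sum(.data$n_harvest), .groups = "drop")

  terms <- harvest |>
    dplyr::left_join(
      fert_stage$fert |> dplyr::select("country", "year", fert_c = "q_c"),
      by = c("country", "year")
    ) |>
    dplyr::left_join(
      manure_stage$totals |> dplyr::select("country", "year", manure_c = "to_cropland"),
      by = c("country", "year")
    ) |>
    dplyr::left_join(bnf_stage$total, by = c("country", "year")) |>
    dplyr::left_join(deposition, by = c("country", "year")) |>
    dplyr::left_join(
      land |> dplyr::select("country", "year", cropland_in_use = "a_c_in_use"),
      by = c("country", "year")
    )
  budget <- assemble_budget(terms)

  structure(
    list(
      categories = crops_stage$aggregates,
      crop_panel = crops_stage$panel,
      fodder = fodder_stage,
      land = land,
      fert = fert_stage$fert,
      manure = manure_stage,
      bnf = bnf_stage,
      deposition = deposition,
      budget = budget,
      edit_log = fodder_stage$edit_log,
      excluded_obs = fert_stage$excluded
    ),
    class = "nbudget_build"
  )
}

#' Validate a pipeline result
#'
#' Recomputes every internal-consistency identity on the assembled result:
#' the budget summation and surplus identities, rate/quantity consistency,
#' the three manure conservation identities (in the exact telescoped form
#' they are constructed in), share and weight bounds, and the
#' quantity-conservation of the fertilizer allocation. Returns one row per
#' check with a pass/fail count.
#'
#' @param x An `nbudget_build`.
#' @param tol Relative tolerance for the rate/quantity cross-checks.
#' @return Tibble `check`, `n`, `failed`, `pass`.
#' @export
nb_validate <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "nbudget_build"))
  b <- x$budget
  m <- x$manure$flows
  f <- x$fert
  rel_ok <- function(a, bb) {
    ok <- is.na(a) | is.na(bb) | abs(a - bb) <= tol * pmax(1, abs(a), abs(bb))
    ok
  }
  checks <- list(
    "budget: input_total = fert + manure + bnf + deposition" =
      b$input_total == b$fert_c + b$manure_c + b$bnf + b$deposition_c,
    "budget: surplus = input_total - harvest" =
      b$surplus == b$input_total - b$harvest_n,
    "budget: input_rate consistent with quantities" =
      rel_ok(b$input_rate, b$input_total * 1000 / b$cropland_in_use),
    "fert: Q_C + Q_PG conserves Q_tot" =
      f$q_tot - f$q_c == f$q_pg,
    "fert: share within [0, 1]" =
      f$share_c >= 0 & f$share_c <= 1,
    "manure: grazing + housed = excreted (exact complement)" =
      m$excreted_total - m$excreted_grazing == m$excreted_housed,
    "manure: lost + applied = housed (exact complement)" =
      m$excreted_housed - m$lost_housing_storage == m$applied_total,
    "manure: grass + nongrass = applied (exact complement)" =
      m$applied_total - m$applied_grass == m$applied_nongrass,
    "manure: TG + PG = grass-destined (exact remainder)" =
      (m$applied_grass + m$excreted_grazing) - m$to_temporary_grassland ==
        m$to_permanent_grassland,
    "manure: to_cropland = nongrass + TG portion" =
      m$to_cropland == m$applied_nongrass + m$to_temporary_grassland,
    "manure: cropland + PG + lost = excreted (1e-9 relative)" =
      rel_ok(
        m$to_cropland + m$to_permanent_grassland + m$lost_housing_storage,
        m$excreted_total
      ),
    "land: cropland in use <= both inputs" =
      with(x$land, a_c_in_use <= pmax(a_crop_sum, a_reported) + 0)
  )
  purrr::imap_dfr(checks, function(ok, nm) {
    tibble::tibble(
      check = nm, n = length(ok),
      failed = sum(!ok, na.rm = TRUE),
      pass = all(ok, na.rm = TRUE)
    )
  })
}

#' Write the main pipeline outputs as tidy CSVs
#'
#' @param x An `nbudget_build`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
nb_write <- function(x, dir) {
  stopifnot(inherits(x, "nbudget_build"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- list(
    budget = x$budget,
    crop_categories = x$categories,
    fodder_crops = x$fodder$per_code,
    land_areas = x$land,
    fertilizer_allocation = x$fert,
    manure_flows = x$manure$flows,
    bnf_by_category = x$bnf$by_category,
    deposition = x$deposition
  )
  for (nm in names(out)) {
    write_tidy_csv(out[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}
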