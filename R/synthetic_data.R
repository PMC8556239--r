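# Seeded generator of ground-truth country panels and their degraded
# observable counterparts. The generator emulates the statistical structure
# of the international crop/livestock/fertilizer sources: smooth area and
# yield trends, management-system series starting in 1990, deposition rates
# ending in 2013, sparse fertilizer surveys, value masking, and the lumping
# of green-harvested fodder crops into a single historical "hay" aggregate
# before 1987 (as in the statistical yearbooks of the planned economies).
#
# Truth is defined as the pipeline output on the fully observed inputs, so
# it is internally conservation-consistent by construction; degradation
# never alters retained values, only removes or lumps them.

#' Synthetic-scenario configuration
#'
#' Four countries exercise the different code paths: `"AA"` fertilizes
#' permanent grassland with a smoothly decaying rate ratio; `"BB"` applies
#' no synthetic N to permanent grassland; `"CC"` has its green-fodder area
#' lumped into a single "hay" aggregate before 1987 (when lumping is on) and
#' borrows its manure land-allocation shares from `"AA"`; `"DD"` reports
#' fertilizer surveys for total grassland vs non-grass cropland, requiring
#' the temporary-grassland rate multiplier `k`.
#'
#' @param seed Integer seed; the same seed and config give bit-identical
#'   output.
#' @param countries Country codes (the four roles above are assigned in
#'   order; fewer countries drop roles from the end).
#' @param years Year grid.
#' @param degrade `NULL` for fully observed output, or a list with elements
#'   `area_missingness` (masking probability for area values, default 0.3),
#'   `hay_lumping` (logical), `survey_every` (years between fertilizer
#'   surveys, default 5), `survey_noise_sd` (sdlog of multiplicative
#'   lognormal noise on survey rates, default 0), `humidity_mixing`
#'   (emit extra unselected yield observations on other humidity bases).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         countries = c("AA", "BB", "CC", "DD"),
                         years = default_grid(),
                         degrade = list(
                           area_missingness = 0.3,
                           hay_lumping = TRUE,
                           survey_every = 5,
                           survey_noise_sd = 0,
                           humidity_mixing = TRUE
                         )) {
  if (length(countries) == 0 || length(years) == 0) {
    stop("degenerate config: need at least one country and one year")
  }
  if (!is.null(degrade)) {
    degrade <- utils::modifyList(
      list(
        area_missingness = 0.3, hay_lumping = TRUE, survey_every = 5,
        survey_noise_sd = 0, humidity_mixing = TRUE
      ),
      degrade
    )
  }
  structure(
    list(seed = as.integer(seed), countries = countries, years = as.integer(years), degrade = degrade),
    class = "synth_config"
  )
}

synth_crop_meta <- function() {
  tibble::tribble(
    ~crop, ~category, ~n_content,
    "wheat", "Wheat", 1.9,
    "oats", "Other cereals", 1.7,
    "rye", "Other cereals", 1.5,
    "field_peas", "Pulses", 3.6,
    "carrots", "Vegetables and other", 0.2
  )
}

fodder_codes <- c("G1000", "G2100", "G2900", "G3000", "G9000", "R9000")

# deterministic per-country role helpers
role_of <- function(country, countries) {
  roles <- c("pg_decay", "zero_pg", "hay_lumped", "total_grass")
  roles[match(country, countries)]
}

#' Generate a synthetic scenario
#'
#' Draws smooth country trajectories for crop areas and yields, fodder
#' reference yields, land areas, fertilizer consumption and rates, livestock
#' excretion and manure-management shares, and deposition rates; assembles
#' the observable input tables; computes the ground truth by running the
#' full pipeline on the undegraded observables; and finally applies the
#' configured degradations.
#'
#' @param config A [synth_config()].
#' @return List with elements `truth` (an `nbudget_build`, see
#'   [nb_build()]), `observables` (list of input tibbles), `build_config`
#'   (the pipeline configuration matching the observables), and `config`.
#' @export
nb_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cs <- config$countries
  yrs <- config$years
  u <- (yrs - min(yrs)) / max(1, diff(range(yrs)))
  ny <- length(yrs)

  # --- FAOSTAT-side crops -----------------------------------------------------
  meta <- synth_crop_meta()
  crops <- purrr::map_dfr(cs, function(co) {
    purrr::map_dfr(meta$crop, function(cr) {
      a0 <- round(runif(1, 100, 900), 1)
      atrend <- runif(1, -0.3, 0.4)
      y0 <- round(runif(1, 2, 6), 2)
      ytrend <- runif(1, 0.5, 1.2)
      area <- a0 * (1 + atrend * u)
      fresh_yield <- y0 * (1 + ytrend * u)
      tibble::tibble(
        country = co, year = yrs, crop = cr,
        area = area, production = area * fresh_yield
      )
    })
  })

  # --- fodder areas -----------------------------------------------------------
  # R9000 is observed only through the root-crop family R0000/R1000/R2000.
  fodder_area <- purrr::map_dfr(cs, function(co) {
    base <- c(
      G1000 = runif(1, 150, 600), G2100 = runif(1, 30, 120),
      G2900 = runif(1, 60, 250), G3000 = runif(1, 80, 300),
      G9000 = runif(1, 50, 200), R9000 = runif(1, 30, 120),
      R1000 = runif(1, 100, 400), R2000 = runif(1, 50, 200)
    )
    trend <- c(
      G1000 = runif(1, -0.2, 0.3), G2100 = runif(1, -0.3, 0.2),
      G2900 = runif(1, -0.3, 0.2), G3000 = runif(1, 0.1, 0.8),
      G9000 = runif(1, -0.4, 0.1), R9000 = runif(1, -0.8, -0.5),
      R1000 = runif(1, -0.4, 0), R2000 = runif(1, -0.2, 0.2)
    )
    g9100_w <- runif(1, 0.4, 0.7)
    series <- function(code) round(base[code] * (1 + trend[code] * u), 3)
    flat_pre87 <- function(v, code) {
      # the hay-lumped country reports flat component areas before 1987
      if (identical(role_of(co, cs), "hay_lumped") && code %in% c("G1000", "G2100", "G2900", "G9000")) {
        v[yrs < 1987] <- v[yrs == 1987]
      }
      v
    }
    g9000 <- flat_pre87(series("G9000"), "G9000")
    g9100 <- round(g9000 * g9100_w, 3)
    g9900 <- g9000 - g9100
    r9000 <- series("R9000")
    r1000 <- series("R1000")
    r2000 <- series("R2000")
    r0000 <- r1000 + r2000 + r9000
    vals <- list(
      G1000 = flat_pre87(series("G1000"), "G1000"),
      G2100 = flat_pre87(series("G2100"), "G2100"),
      G2900 = flat_pre87(series("G2900"), "G2900"),
      G3000 = series("G3000"),
      G9100 = g9100, G9900 = g9900,
      R0000 = r0000, R1000 = r1000, R2000 = r2000
    )
    purrr::imap_dfr(vals, function(v, code) {
      tibble::tibble(
        country = co, year = yrs, variable = code, unit = "kha", value = v
      )
    })
  })

  # --- fodder yield observations ---------------------------------------------
  ranges <- list(
    G1000 = c(5, 8), G2100 = c(6, 9), G2900 = c(5.5, 8.5),
    G3000 = c(9, 14), G9000 = c(4, 7)
  )
  yield_bits <- purrr::map(cs, function(co) {
    obs <- list()
    sel <- list()
    for (code in fodder_codes) {
      if (identical(role_of(co, cs), "total_grass") && code == "G2900") next # donor-filled
      if (code == "R9000") {
        fresh <- round(runif(1, 40, 70), 1)
        obs <- c(obs, list(tibble::tibble(
          country = co, crop = code, year = 2010, value = fresh,
          basis = "fodder_root_default", water_pct = NA_real_
        )))
        sel <- c(sel, list(tibble::tibble(
          country = co, crop = code, year = 2010, basis = "fodder_root_default"
        )))
      } else {
        v <- round(runif(1, ranges[[code]][1], ranges[[code]][2]), 2)
        obs <- c(obs, list(tibble::tibble(
          country = co, crop = code, year = 2010, value = v,
          basis = "dry_matter", water_pct = NA_real_
        )))
        sel <- c(sel, list(tibble::tibble(
          country = co, crop = code, year = 2010, basis = "dry_matter"
        )))
      }
    }
    list(obs = dplyr::bind_rows(obs), sel = dplyr::bind_rows(sel))
  })
  fodder_yield_obs <- dplyr::bind_rows(purrr::map(yield_bits, "obs"))
  yield_selection <- dplyr::bind_rows(purrr::map(yield_bits, "sel"))

  # --- land areas -------------------------------------------------------------
  land_bits <- purrr::map_dfr(cs, function(co) {
    a_pg0 <- round(runif(1, 500, 3000), 1)
    pg_trend <- runif(1, -0.3, 0.2)
    tibble::tibble(
      country = co, year = yrs,
      a_pg = round(a_pg0 * (1 + pg_trend * u), 3)
    )
  })
  # reported cropland: above the crop-area sum for most countries, below for
  # the total-grass country so both branches of the minimum rule are exercised
  crop_area_totals <- dplyr::bind_rows(
    crops |> dplyr::group_by(.data$country, .data$year) |>
      dplyr::summarise(a = sum(.data$area), .groups = "drop"),
    fodder_area |>
      dplyr::mutate(value = ifelse(
        .data$variable %in% c("R1000", "R2000"), -.data$value,
        ifelse(.data$variable %in% c(
          "G1000", "G2100", "G2900", "G3000", "G9100", "G9900", "R0000"
        ), .data$value, 0)
      )) |>
      dplyr::group_by(.data$country, .data$year) |>
      dplyr::summarise(a = sum(.data$value), .groups = "drop")
  ) |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(a = sum(.data$a), .groups = "drop")
  reported <- crop_area_totals |>
    dplyr::mutate(factor = ifelse(
      role_of(.data$country, cs) %in% "total_grass", 0.97, 1.04
    ), value = round(.data$a * .data$factor, 3))
  land <- dplyr::bind_rows(
    reported |> dplyr::transmute(.data$country, .data$year,
      variable = "cropland_reported", unit = "kha", value = .data$value
    ),
    land_bits |> dplyr::transmute(.data$country, .data$year,
      variable = "permanent_grassland", unit = "kha", value = .data$a_pg
    )
  )

  # --- synthetic fertilizer ---------------------------------------------------
  fert_total <- purrr::map_dfr(cs, function(co) {
    q0 <- runif(1, 100, 600)
    tibble::tibble(
      country = co, year = yrs,
      value = round(q0 * (0.3 + 1.7 * u - 1.0 * u^2), 3)
    )
  })
  fert_obs <- purrr::map_dfr(cs, function(co) {
    role <- role_of(co, cs)
    if (identical(role, "zero_pg")) {
      return(tibble::tibble())
    }
    rc0 <- runif(1, 20, 40)
    r_c <- round(rc0 * (1 + 2.5 * u), 2)
    if (identical(role, "total_grass")) {
      ratio_like <- 0.9 - 0.8 * u # declining grass/non-grass rate ratio
      r_g <- round(r_c * ratio_like, 2)
      tibble::tibble(
        country = co,
        year = rep(yrs, 2),
        land_category = rep(c("C_minus_TG", "PG_plus_TG"), each = ny),
        R = c(r_c, r_g), Q = NA_real_, A = NA_real_, source = "synthetic-survey"
      )
    } else {
      ratio <- if (identical(role, "pg_decay")) {
        0.2 + 0.6 * exp(-(yrs - min(yrs)) / 30)
      } else {
        rep(0.5, ny)
      }
      r_pg <- round(r_c * ratio, 2)
      tibble::tibble(
        country = co,
        year = rep(yrs, 2),
        land_category = rep(c("C", "PG"), each = ny),
        R = c(r_c, r_pg), Q = NA_real_, A = NA_real_, source = "synthetic-survey"
      )
    }
  })

  # --- manure -----------------------------------------------------------------
  detailed_classes <- c("Cattle", "Sheep", "Swine", "Poultry")
  excretion_raw <- purrr::map_dfr(cs, function(co) {
    purrr::map_dfr(detailed_classes, function(cl) {
      e0 <- runif(1, 20, 150)
      tr <- runif(1, -0.3, 0.5)
      tibble::tibble(
        country = co, year = yrs, class = cl,
        value = round(e0 * (1 + tr * u), 4)
      )
    })
  })
  mms_years <- yrs[yrs >= 1990 & yrs <= 2018]
  mms_raw <- purrr::map_dfr(cs, function(co) {
    purrr::map_dfr(detailed_classes, function(cl) {
      graz0 <- if (cl == "Poultry") runif(1, 0, 0.05) else runif(1, 0.2, 0.45)
      liq0 <- runif(1, 0.2, 0.5)
      oth <- runif(1, 0.02, 0.08)
      drift <- runif(1, -0.1, 0.1)
      uu <- (mms_years - 1990) / (2018 - 1990)
      graz <- graz0 * (1 + drift * uu)
      liq <- liq0 * (1 - drift * uu)
      sol <- 1 - graz - liq - oth
      exc <- excretion_raw$value[
        excretion_raw$country == co & excretion_raw$class == cl
      ][match(mms_years, yrs)]
      tibble::tibble(
        country = co,
        year = rep(mms_years, 5),
        class = cl,
        system = rep(c(
          "Pasture range and paddock", "Solid storage and dry lot",
          "Composting", "Liquid system", "Other"
        ), each = length(mms_years)),
        value = round(c(
          exc * graz, exc * sol * 0.7, exc * sol * 0.3, exc * liq, exc * oth
        ), 5)
      )
    })
  })
  simplified <- c("ruminants_equines", "pigs", "poultry_rabbits")
  loss_shares <- purrr::map_dfr(cs, function(co) {
    tibble::tibble(
      country = co, class = simplified,
      loss_share = round(runif(3, 0.15, 0.35), 3)
    )
  })
  alloc_cs <- setdiff(cs, cs[role_of(cs, cs) == "hay_lumped"]) # CC borrows from AA
  alloc_shares <- purrr::map_dfr(alloc_cs, function(co) {
    dplyr::bind_rows(
      tibble::tibble(
        country = co, class = "ruminants_equines",
        manure_type = c("liquid", "solid"),
        grass_share = round(runif(2, c(0.5, 0.3), c(0.8, 0.6)), 3)
      ),
      tibble::tibble(
        country = co, class = "pigs", manure_type = c("liquid", "solid"),
        grass_share = round(runif(2, c(0.1, 0.05), c(0.3, 0.2)), 3)
      ),
      tibble::tibble(
        country = co, class = "poultry_rabbits", manure_type = "all",
        grass_share = round(runif(1, 0.05, 0.2), 3)
      )
    )
  })
  alloc_donors <- if (any(role_of(cs, cs) == "hay_lumped")) {
    setNames(cs[1], cs[role_of(cs, cs) == "hay_lumped"])
  } else {
    NULL
  }

  # --- deposition (rates end in 2013, as deposition datasets do) --------------
  dep_years <- yrs[yrs <= 2013]
  deposition_rates <- purrr::map_dfr(cs, function(co) {
    d0 <- runif(1, 5, 15)
    uu <- (dep_years - min(yrs)) / max(1, diff(range(yrs)))
    tibble::tibble(
      country = co, year = dep_years,
      value = round(d0 * (1 + 0.8 * uu - 0.5 * uu^2), 4)
    )
  })

  observables <- list(
    crops = crops,
    crop_meta = meta,
    fodder_area = as_panel(fodder_area, grid = yrs),
    fodder_yield_obs = fodder_yield_obs,
    land = as_panel(land, grid = yrs),
    fert_total = fert_total,
    fert_obs = fert_obs,
    excretion_raw = excretion_raw,
    mms_raw = mms_raw,
    loss_shares = loss_shares,
    alloc_shares = alloc_shares,
    deposition_rates = deposition_rates,
    bnf_params = bnf_params_default()
  )

  clean_config <- list(
    years = yrs,
    fodder_rules = default_fodder_rules(cs, hay_lumping = FALSE),
    yield_selection = yield_selection,
    yield_donors = if (any(role_of(cs, cs) == "total_grass")) {
      list(list(
        target = cs[role_of(cs, cs) == "total_grass"], crop = "G2900",
        donors = cs[role_of(cs, cs) %in% c("pg_decay", "hay_lumped")]
      ))
    } else {
      list()
    },
    zero_pg = cs[role_of(cs, cs) == "zero_pg"],
    k = setNames(
      as.list(rep(1.5, sum(role_of(cs, cs) == "total_grass"))),
      cs[role_of(cs, cs) == "total_grass"]
    ),
    mms_window = c(1997, 2001),
    mms_other_threshold = 0.2,
    alloc_donors = alloc_donors,
    category_overrides = list()
  )

  truth <- nb_build(observables, clean_config)

  if (is.null(config$degrade)) {
    return(list(
      truth = truth, observables = observables,
      build_config = clean_config, config = config
    ))
  }
  degraded <- degrade(observables, config$degrade, seed = config$seed + 1L, countries = cs)
  build_config <- clean_config
  build_config$fodder_rules <- default_fodder_rules(
    cs,
    hay_lumping = isTRUE(config$degrade$hay_lumping)
  )
  list(
    truth = truth, observables = degraded,
    build_config = build_config, config = config
  )
}

#' Default fodder edit-rule list for the synthetic scenario
#'
#' Per country, in order: fill the detailed root/green codes, merge the two
#' detailed green-harvest codes into their parent, derive fodder roots as
#' the root-crop residual, split the lumped historical hay area (hay-lumped
#' country only) using 1987 reference shares, then interpolate interior gaps
#' and extrapolate the edges of every fodder code.
#'
#' @param countries Country codes.
#' @param hay_lumping Whether a pre-1987 "hay" aggregate must be split.
#' @return Edit rule list for [apply_edit_rules()].
#' @export
default_fodder_rules <- function(countries, hay_lumping = FALSE) {
  rules <- list()
  for (co in countries) {
    lumped <- hay_lumping && identical(role_of(co, countries), "hay_lumped")
    for (v in c("G9100", "G9900", "R0000", "R1000", "R2000")) {
      # in the hay-lumped country the detailed green codes must stay missing
      # before 1987 so that the merged parent is filled by the hay split
      dir <- if (lumped && v %in% c("G9100", "G9900")) "forward" else "both"
      rules <- c(rules, list(
        list(kind = "interpolate_linear", country = co, variable = v),
        list(kind = "extrapolate_const", country = co, variable = v, direction = dir)
      ))
    }
    rules <- c(rules, list(
      list(kind = "merge_sum", country = co, variable = "G9000", a = "G9100", b = "G9900"),
      list(
        kind = "residual", country = co, variable = "R9000",
        parent = "R0000", children = list("R1000", "R2000")
      )
    ))
    if (hay_lumping && identical(role_of(co, countries), "hay_lumped")) {
      rules <- c(rules, list(list(
        kind = "proportional_split", country = co, variable = "hay",
        components = list("G1000", "G2100", "G2900", "G9000"),
        reference_year = 1987
      )))
    }
    for (v in fodder_codes) {
      rules <- c(rules, list(
        list(kind = "interpolate_linear", country = co, variable = v),
        list(kind = "extrapolate_const", country = co, variable = v)
      ))
    }
  }
  rules
}

#' Degrade observables into their realistic, gappy counterparts
#'
#' Deterministic under the seed; masking never alters retained values. Area
#' values are masked at the configured rate (1987 is kept as the reference
#' anchor); the hay-lumped country's green-fodder components are replaced
#' before 1987 by their lumped sum under the variable `"hay"`; fertilizer
#' surveys are thinned to every n-th year, with optional multiplicative
#' lognormal noise on the rates.
#'
#' @param observables Observable list from [nb_generate()].
#' @param spec Degradation list (see [synth_config()]).
#' @param seed Integer seed for the masking stream.
#' @param countries Country codes (for role assignment).
#' @return Degraded observable list.
#' @export
degrade <- function(observables, spec, seed, countries) {
  set.seed(seed)
  obs <- observables
  protect_years <- c(1987L)

  mask_rate <- spec$area_missingness %||% 0
  if (mask_rate > 0) {
    fa <- obs$fodder_area
    maskable <- !is.na(fa$value) & !fa$year %in% protect_years
    drop <- maskable & runif(nrow(fa)) < mask_rate
    fa$value[drop] <- NA_real_
    obs$fodder_area <- fa
    cr <- obs$crops
    maskable <- !is.na(cr$area)
    drop <- maskable & runif(nrow(cr)) < mask_rate
    cr$area[drop] <- NA_real_
    obs$crops <- cr
  }

  if (isTRUE(spec$hay_lumping)) {
    co <- countries[role_of(countries, countries) == "hay_lumped"]
    if (length(co) == 1) {
      fa <- observables$fodder_area # lump from the clean values
      comp <- c("G1000", "G2100", "G2900", "G9100", "G9900")
      pre <- fa$country == co & fa$year < 1987
      hay <- fa |>
        dplyr::filter(.data$country == co, .data$year < 1987, .data$variable %in% comp) |>
        dplyr::group_by(.data$year) |>
        dplyr::summarise(value = sum(.data$value), .groups = "drop")
      fa2 <- obs$fodder_area
      fa2$value[fa2$country == co & fa2$year < 1987 & fa2$variable %in% comp] <- NA_real_
      hay_panel <- tibble::tibble(
        country = co, year = fa2$year[fa2$country == co & fa2$variable == "G1000"],
        variable = "hay", unit = "kha", value = NA_real_
      )
      hay_panel$value[match(hay$year, hay_panel$year)] <- hay$value
      obs$fodder_area <- dplyr::bind_rows(fa2, hay_panel) |>
        dplyr::arrange(.data$country, .data$variable, .data$year)
    }
  }

  every <- spec$survey_every %||% 1
  if (every > 1 && nrow(obs$fert_obs) > 0) {
    keep_years <- seq(min(obs$fert_obs$year), max(obs$fert_obs$year), by = every)
    obs$fert_obs <- dplyr::filter(obs$fert_obs, .data$year %in% keep_years)
  }
  sdlog <- spec$survey_noise_sd %||% 0
  if (sdlog > 0 && nrow(obs$fert_obs) > 0) {
    obs$fert_obs$R <- obs$fert_obs$R * exp(stats::rnorm(nrow(obs$fert_obs), 0, sdlog))
  }

  if (isTRUE(spec$humidity_mixing)) {
    extra <- obs$fodder_yield_obs |>
      dplyr::filter(.data$basis == "dry_matter") |>
      dplyr::mutate(
        year = 2008L,
        value = round(.data$value / 0.35, 2), # same yield re-expressed at 65% water
        basis = "eu_standard"
      )
    obs$fodder_yield_obs <- dplyr::bind_rows(obs$fodder_yield_obs, extra)
  }
  obs
}

#' Write an observable set to a directory of tidy CSVs
#'
#' @param observables Observable list from [nb_generate()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_observables <- function(observables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(observables)) {
    write_tidy_csv(observables[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read an observable set written by [write_observables()]
#'
#' @param dir Directory containing the CSVs.
#' @param years Year grid for the panel tables.
#' @return Observable list.
#' @export
read_observables <- function(dir, years = default_grid()) {
  rd <- function(nm) read_tidy_csv(file.path(dir, paste0(nm, ".csv")))
  list(
    crops = rd("crops"),
    crop_meta = rd("crop_meta"),
    fodder_area = as_panel(rd("fodder_area"), grid = years),
    fodder_yield_obs = rd("fodder_yield_obs"),
    land = as_panel(rd("land"), grid = years),
    fert_total = rd("fert_total"),
    fert_obs = rd("fert_obs") |>
      dplyr::mutate(dplyr::across(dplyr::any_of(c("R", "Q", "A")), as.numeric)),
    excretion_raw = rd("excretion_raw"),
    mms_raw = rd("mms_raw"),
    loss_shares = rd("loss_shares"),
    alloc_shares = rd("alloc_shares"),
    deposition_rates = rd("deposition_rates"),
    bnf_params = rd("bnf_params")
  )
}
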