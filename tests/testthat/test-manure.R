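test_that("detailed systems and classes aggregate to the simplified nomenclature", {
  raw <- tibble::tibble(
    country = "AA", year = 2000L, class = "Cattle",
    system = c("Pasture range and paddock", "Solid storage and dry lot", "Liquid system"),
    value = c(30, 40, 30)
  )
  out <- aggregate_mms(raw)
  expect_identical(out$share[out$system == "grazing"], 0.3)
  expect_identical(out$share[out$system == "solid"], 0.4)
  expect_identical(out$share[out$system == "liquid"], 0.3)
  expect_identical(out$share[out$system == "other"], 0)

  # composting and daily spread both count as solid
  raw2 <- tibble::tibble(
    country = "AA", year = 2000L, class = "Swine",
    system = c("Composting", "Daily spread", "Liquid system"),
    value = c(10, 10, 80)
  )
  out2 <- aggregate_mms(raw2)
  expect_identical(out2$share[out2$system == "solid"], 0.2)

  expect_error(
    aggregate_mms(dplyr::mutate(raw, system = "Compost heap")),
    "unmapped manure management system"
  )
  expect_error(
    aggregate_mms(dplyr::mutate(raw, class = "Llamas")),
    "unmapped livestock class"
  )
})

test_that("livestock classes merge with excretion weighting", {
  raw <- tibble::tibble(
    country = "AA", year = 2000L,
    class = c("Cattle", "Cattle", "Sheep", "Sheep"),
    system = rep(c("Pasture range and paddock", "Liquid system"), 2),
    value = c(20, 80, 30, 10) # cattle 20% grazing, sheep 75% grazing
  )
  out <- aggregate_mms(raw)
  rum <- out[out$class == "ruminants_equines", ]
  expect_equal(rum$share[rum$system == "grazing"], 50 / 140, tolerance = 1e-12)
  expect_identical(sum(rum$share), 1)
})

test_that("management-system shares extend over the grid by constant extrapolation", {
  shares <- aggregate_mms(tibble::tibble(
    country = "AA", year = rep(1990:2018, each = 2), class = "Cattle",
    system = rep(c("Pasture range and paddock", "Liquid system"), 29),
    value = rep(c(30, 70), 29) + rep(seq(0, 28), each = 2) * c(0.1, -0.1)
  ))
  full <- backfill_shares(shares, grid = 1961:2019)
  g <- full[full$system == "grazing", ]
  expect_identical(g$share[g$year == 1961], g$share[g$year == 1990])
  expect_identical(g$share[g$year == 2019], g$share[g$year == 2018])
  sums <- full |>
    dplyr::group_by(year) |>
    dplyr::summarise(s = sum(share), .groups = "drop")
  expect_identical(unique(sums$s), 1)
})

test_that("grazing/housed and loss partitions are exact complements", {
  gh <- split_grazing_housed(100, 0.3)
  expect_identical(gh$grazing, 30)
  expect_identical(gh$housed, 70)
  expect_identical(split_grazing_housed(100, 0)$housed, 100)
  la <- apply_storage_losses(70, 0.2)
  expect_identical(la$lost, 14)
  expect_identical(la$applied, 56)
  expect_identical(apply_storage_losses(70, 0)$lost, 0)
  expect_equal(apply_storage_losses(50, 0.3)$lost, 15, tolerance = 1e-12)
  expect_error(apply_storage_losses(70, 1), "\\[0, 1\\)")
  set.seed(31)
  tot <- runif(1000, 0, 500)
  sh <- runif(1000)
  gh <- split_grazing_housed(tot, sh)
  expect_identical(tot - gh$grazing, gh$housed) # exact complement
  expect_identical(gh$grazing + gh$housed, tot) # bit-exact on these instances
  la <- apply_storage_losses(gh$housed, runif(1000, 0, 0.99))
  expect_identical(gh$housed - la$lost, la$applied)
})

test_that("liquid/solid division renormalizes or demands exogenous data", {
  out <- liquid_solid_shares(solid = 0.3, liquid = 0.5, other = 0.2)
  expect_identical(out$liquid, 0.625)
  expect_identical(out$solid, 0.375)
  out <- liquid_solid_shares(solid = 0.4, liquid = 0.6, other = 0)
  expect_identical(out$liquid, 0.6)
  expect_error(
    liquid_solid_shares(solid = 0.33, liquid = 0.34, other = 0.33, label = "ES ruminants"),
    "exceeds 20%.*ES ruminants"
  )
  out <- liquid_solid_shares(
    solid = 0.33, liquid = 0.34, other = 0.33,
    override = c(liquid = 0.55, solid = 0.45)
  )
  expect_equal(out$liquid, 0.55, tolerance = 1e-12)
})

test_that("effective grass shares weight liquid and solid allocations", {
  expect_equal(effective_grass_share(0.6, 0.8, 0.5), 0.68, tolerance = 1e-12)
  expect_identical(effective_grass_share(1, 0.8, 0.5), 0.8)
  expect_identical(effective_grass_share(0, 0.8, 0.5), 0.5)
})

test_that("grassland-destined N splits by area with the TG part going to cropland", {
  out <- split_to_land(
    applied_grass = 60, excreted_grazing = 40, applied_nongrass = 10,
    a_pg = 300, a_tg = 100
  )
  expect_identical(out$to_permanent_grassland, 75)
  expect_identical(out$to_cropland, 35)
  out <- split_to_land(50, 10, 5, a_pg = 200, a_tg = 0)
  expect_identical(out$to_permanent_grassland, 60)
  expect_identical(out$to_cropland, 5)
  expect_error(split_to_land(10, 0, 0, a_pg = 0, a_tg = 0), "zero grassland")
  set.seed(32)
  ag <- runif(500, 0, 100)
  gz <- runif(500, 0, 100)
  ang <- runif(500, 0, 100)
  apg <- runif(500, 1, 3000)
  atg <- runif(500, 0, 1500)
  out <- split_to_land(ag, gz, ang, apg, atg)
  expect_identical(
    (ag + gz) - out$to_temporary_grassland, out$to_permanent_grassland
  )
  expect_identical(out$to_cropland, ang + out$to_temporary_grassland)
})

test_that("donor mappings copy allocation rows and the weighting window is honoured", {
  alloc <- tibble::tibble(
    country = "AA",
    class = c("ruminants_equines", "ruminants_equines", "poultry_rabbits"),
    manure_type = c("liquid", "solid", "all"),
    grass_share = c(0.8, 0.5, 0.1)
  )
  shares <- backfill_shares(aggregate_mms(tibble::tibble(
    country = rep(c("AA", "CC"), each = 3),
    year = 1999L,
    class = rep(c("Cattle", "Cattle", "Poultry"), 2),
    system = rep(c("Liquid system", "Solid storage and dry lot", "Solid storage and dry lot"), 2),
    value = rep(c(60, 40, 10), 2)
  )), grid = 1995:2005)
  out <- land_allocation_shares(alloc, shares, donors = c(CC = "AA"))
  expect_identical(sort(unique(out$country)), c("AA", "CC"))
  rum <- out[out$class == "ruminants_equines", ]
  expect_equal(rum$grass_share, rep(0.6 * 0.8 + 0.4 * 0.5, 2), tolerance = 1e-12)
  poul <- out[out$class == "poultry_rabbits", ]
  expect_identical(poul$grass_share, c(0.1, 0.1))
  expect_error(
    land_allocation_shares(alloc, shares, donors = c(CC = "XX")),
    "donor country absent"
  )
})

test_that("the full flow chain conserves N at machine precision and responds to losses monotonically", {
  g <- get_synth("clean")
  m <- g$truth$manure$flows
  # the three conservation identities, in the exact telescoped form
  expect_identical(m$excreted_total - m$excreted_grazing, m$excreted_housed)
  expect_identical(m$excreted_housed - m$lost_housing_storage, m$applied_total)
  expect_identical(m$applied_total - m$applied_grass, m$applied_nongrass)
  expect_identical(
    (m$applied_grass + m$excreted_grazing) - m$to_temporary_grassland,
    m$to_permanent_grassland
  )
  expect_identical(m$to_cropland, m$applied_nongrass + m$to_temporary_grassland)
  # and in plain sum form to 1e-12 relative
  lhs <- m$to_cropland + m$to_permanent_grassland + m$lost_housing_storage
  expect_equal(lhs, m$excreted_total, tolerance = 1e-12)

  # higher losses strictly decrease what reaches the land
  la1 <- apply_storage_losses(100, 0.2)
  la2 <- apply_storage_losses(100, 0.3)
  expect_lt(la2$applied, la1$applied)
})
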