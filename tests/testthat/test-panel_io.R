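test_that("a complete file round-trips through panel validation unchanged", {
  x <- tibble::tibble(
    country = "AA", year = 1961:1963, variable = "area", unit = "kha",
    value = c(1, 2, 3)
  )
  p <- as_panel(x, grid = 1961:1963)
  expect_identical(p$value, c(1, 2, 3))
  expect_identical(nrow(p), 3L)
})

test_that("missing grid years are completed as explicit missing", {
  x <- tibble::tibble(
    country = "AA", year = c(1961L, 1963L), variable = "area", unit = "kha",
    value = c(1, 3)
  )
  p <- as_panel(x, grid = 1961:1963)
  expect_identical(p$year, 1961:1963)
  expect_identical(p$value, c(1, NA, 3))
})

test_that("invalid panels are rejected with informative errors", {
  base <- tibble::tibble(
    country = "AA", year = 1961L, variable = "area", unit = "kha", value = 1
  )
  expect_error(
    as_panel(dplyr::mutate(base, value = -1), grid = 1961),
    "negative value"
  )
  expect_error(
    as_panel(dplyr::bind_rows(base, base), grid = 1961),
    "duplicate"
  )
  expect_error(
    as_panel(dplyr::mutate(base, unit = "bushels"), grid = 1961),
    "unknown unit"
  )
  expect_error(
    as_panel(dplyr::mutate(base, year = 1900L), grid = 1961),
    "outside the grid"
  )
})

test_that("read/write round-trip is the identity on randomized panels", {
  set.seed(7)
  for (rep in 1:5) {
    vals <- runif(59, 0, 5000) * sample(c(1, 1e-3, 1e3), 59, replace = TRUE)
    vals[sample(59, 15)] <- NA
    p <- as_panel(tibble::tibble(
      country = "ZZ", year = 1961:2019, variable = "area", unit = "kha",
      value = vals
    ))
    f <- withr::local_tempfile(fileext = ".csv")
    write_panel(p, f)
    p2 <- read_panel(f)
    expect_identical(p2$value, p$value)
    expect_identical(p2$year, p$year)
  }
})

test_that("an empty panel writes a header-only file", {
  p <- as_panel(tibble::tibble(
    country = character(), year = integer(), variable = character(),
    unit = character(), value = double()
  ), grid = 1961:1963)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  expect_identical(
    readLines(f),
    "country,year,variable,unit,value"
  )
})

test_that("the crop-code registry maps each code to exactly one category", {
  reg <- crop_code_registry()
  expect_identical(anyDuplicated(reg$code), 0L)
  expect_identical(crop_category(c("G2100", "G2900")), rep("Forage legumes", 2))
  expect_identical(crop_category("G1000"), "Temporary grassland")
  expect_identical(crop_category("R9000"), "Fodder roots")
  expect_true(is.na(crop_category("G9100"))) # input to the merged parent
  expect_error(crop_category("X9999"), "unregistered")
})

test_that("per-country year grids override the default grid", {
  x <- tibble::tibble(
    country = c("AA", "HR"), year = c(1961L, 1992L), variable = "area",
    unit = "kha", value = c(1, 2)
  )
  p <- as_panel(x, grid = 1961:1993, grids = list(HR = 1992:1993))
  expect_identical(sum(p$country == "HR"), 2L)
  expect_identical(sum(p$country == "AA"), 33L)
  expect_error(
    as_panel(
      tibble::tibble(
        country = "HR", year = 1961L, variable = "area", unit = "kha", value = 1
      ),
      grid = 1961:1993, grids = list(HR = 1992:1993)
    ),
    "outside the grid"
  )
})

test_that("quantity/area pairs convert to rates with the 1 Gg / 1 kha = 1000 kg/ha rule", {
  expect_identical(kg_per_ha(1, 1), 1000)
  expect_identical(kg_per_ha(20, 2000), 10)
  expect_true(is.na(kg_per_ha(5, 0)))
})

test_that("mixture N contents are share-weighted means of component contents", {
  expect_identical(mixture_n_content(c(2.0, 3.3), c(0.75, 0.25)), 2.3)
  expect_equal(mixture_n_content(c(2.0, 3.3), c(0.75, 0.25), digits = NULL),
    2.325,
    tolerance = 1e-12
  )
  expect_error(mixture_n_content(c(2, 3), c(0.6, 0.3)), "sum to 1")
  expect_error(mixture_n_content(c(2, 3), c(1.2, -0.2)), "negative")
})
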