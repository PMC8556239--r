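test_that("dry-matter conversion applies the declared water bases", {
  expect_equal(to_dry_matter(40, "eu_standard"), 14, tolerance = 1e-12)
  expect_equal(to_dry_matter(8, "hay"), 6.8, tolerance = 1e-12)
  expect_equal(to_dry_matter(50, "fodder_root_default"), 8, tolerance = 1e-12)
  expect_identical(to_dry_matter(5.5, "dry_matter"), 5.5)
  expect_equal(to_dry_matter(100, "national_percent", water_pct = 88), 12,
    tolerance = 1e-12
  )
  expect_error(to_dry_matter(10, "national_percent", water_pct = 100), "\\(0, 1\\]")
  expect_error(to_dry_matter(10, "sauna"), "unknown humidity basis")
})

test_that("the yield trend is affine and interpolates both anchor points", {
  m <- yield_model("G3000", "AA", y2010 = 10)
  expect_identical(yield_at(m, 2010), 10)
  expect_identical(yield_at(m, 1961), 7.5)
  expect_equal(yield_at(m, 2019), 10 * (0.75 + 0.25 * 58 / 49), tolerance = 1e-12)
  # affine: second differences vanish
  y <- yield_at(m, 1961:2019)
  expect_equal(diff(y, differences = 2), rep(0, 57), tolerance = 1e-12)
})

test_that("the grazing correction inflates temporary-grassland yields by the configured factor", {
  g <- yield_model("G1000", "AA", y2010 = 6)
  base <- yield_model("G1000", "AA", y2010 = 6, inflate = FALSE)
  expect_equal(yield_at(g, 1985) / yield_at(base, 1985), 1.2, tolerance = 1e-12)
  other <- yield_model("G2100", "AA", y2010 = 6)
  expect_identical(yield_at(other, 2010), 6)
})

test_that("fodder N harvest is the product of area, DM yield, and N content", {
  expect_equal(fodder_n_harvest(100, 5, 2.3), 11.5, tolerance = 1e-12)
  expect_identical(fodder_n_harvest(0, 5, 2.3), 0)
  set.seed(4)
  a <- runif(300, 0, 2000)
  y <- runif(300, 1, 15)
  nc <- runif(300, 1, 3.5)
  expect_equal(fodder_n_harvest(a, y, nc), a * y * nc / 100, tolerance = 1e-12)
})

test_that("reference yields average the selected dry-matter observations", {
  obs <- tibble::tibble(
    country = "AA", crop = "G3000",
    year = c(2009, 2010, 2010, 2011),
    value = c(11, 12, 36, 13),
    basis = c("dry_matter", "dry_matter", "national_percent", "dry_matter"),
    water_pct = c(NA, NA, 70, NA)
  )
  sel <- tibble::tibble(
    country = "AA", crop = "G3000",
    year = c(2010, 2010), basis = c("dry_matter", "national_percent")
  )
  ref <- estimate_reference_yield(obs, sel)
  expect_equal(ref$y2010, mean(c(12, 36 * 0.3)), tolerance = 1e-12)
  # default selection: dry-matter rows of 2010
  ref2 <- estimate_reference_yield(obs)
  expect_identical(ref2$y2010, 12)
})

test_that("donor countries fill missing reference yields by copy or mean", {
  ref <- tibble::tibble(
    country = c("AA", "CC"), crop = "G1000", y2010 = c(4, 6)
  )
  out <- donor_yield(ref, "DD", "G1000", c("AA", "CC"))
  expect_identical(out$y2010[out$country == "DD"], 5)
  out1 <- donor_yield(ref, "EE", "G1000", "AA")
  expect_identical(out1$y2010[out1$country == "EE"], 4)
  expect_error(donor_yield(ref, "DD", "G1000", character()), "empty donor")
  expect_error(donor_yield(ref, "DD", "G1000", c("AA", "XX")), "missing donor")
})

test_that("production-weighted merged yields follow the component weights", {
  expect_equal(production_weighted_yield(c(4, 6), c(30, 10)), 4.5, tolerance = 1e-12)
  expect_identical(production_weighted_yield(5, 10), 5)
})

test_that("yield anomaly screening flags the classic reporting errors", {
  # (a) same value in national and standard humidity, different water content
  obs <- tibble::tibble(
    year = c(2005, 2005),
    value = c(30, 30),
    basis = c("national_percent", "eu_standard"),
    water_pct = c(20, NA)
  )
  fl <- flag_yield_anomalies(obs)
  expect_true("equal_across_bases" %in% fl$type)

  # (b) a step exactly matching the dry-matter factor between years
  obs <- tibble::tibble(
    year = 2004:2006,
    value = c(40, 40, 14), # 14 = 40 * 0.35: basis confusion
    basis = "eu_standard",
    water_pct = NA
  )
  fl <- flag_yield_anomalies(obs)
  expect_true("basis_jump" %in% fl$type)

  # clean, consistent series: no flags
  obs <- tibble::tibble(
    year = 2004:2008,
    value = c(10, 10.4, 10.6, 11, 11.2),
    basis = "dry_matter",
    water_pct = NA
  )
  expect_identical(nrow(flag_yield_anomalies(obs)), 0L)
})
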