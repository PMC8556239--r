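test_that("area-weighted rates aggregate crop rates correctly", {
  expect_identical(area_weighted_rate(c(100, 50), c(10, 10)), 75)
  expect_identical(area_weighted_rate(60, 5), 60)
  expect_error(area_weighted_rate(numeric(), numeric()), "empty")
  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:10, 1)
    r <- runif(n, 0, 300)
    a <- runif(n, 0.1, 500)
    expect_equal(area_weighted_rate(r, a), sum(r * a) / sum(a), tolerance = 1e-12)
  }
})

test_that("fertilized-subset rates renormalize to the category and conserve quantity", {
  expect_identical(renormalize_fertilized(100, 50, 200), 25)
  expect_identical(renormalize_fertilized(80, 120, 120), 80)
  expect_error(renormalize_fertilized(80, 130, 120), "exceeds")
  set.seed(22)
  rf <- runif(200, 0, 300)
  af <- runif(200, 0, 100)
  at <- af + runif(200, 0, 100)
  out <- renormalize_fertilized(rf, af, at)
  expect_equal(out * at, rf * af, tolerance = 1e-12)
})

test_that("the cropland share formula matches a direct quantity-ratio oracle", {
  expect_identical(share_to_cropland(0, 4000, 14000), 1)
  expect_identical(share_to_cropland(1, 100, 100), 0.5)
  # forward construction: pick rates, compute quantities, take the ratio
  r_c <- 100
  r_pg <- 60
  a_c <- 14000
  a_pg <- 4000
  oracle <- (r_c * a_c) / (r_c * a_c + r_pg * a_pg)
  expect_equal(share_to_cropland(r_pg / r_c, a_pg, a_c), oracle, tolerance = 1e-12)
  expect_equal(share_to_cropland(0.6, 4000, 14000), 1 / (1 + 0.6 * 4 / 14),
    tolerance = 1e-12
  )
  set.seed(23)
  for (i in 1:200) {
    rr <- runif(1, 0, 3)
    a_pg <- runif(1, 0, 5000)
    a_c <- runif(1, 100, 20000)
    s <- share_to_cropland(rr, a_pg, a_c)
    expect_true(s >= 0 && s <= 1)
    # strictly decreasing in the rate ratio and the area ratio
    expect_true(share_to_cropland(rr + 0.1, a_pg, a_c) < s || a_pg == 0)
    expect_true(share_to_cropland(rr, a_pg + 10, a_c) < s || rr == 0)
  }
  expect_error(share_to_cropland(0.5, 100, 0), "positive")
})

test_that("the total-grassland disaggregation inverts its own forward construction", {
  # limit: no temporary grassland, k = 1 -> plain ratio of the two rates
  expect_equal(
    rate_ratio_from_total_grass(80, 100, a_pg = 500, a_tg = 0, a_c = 1000),
    0.8,
    tolerance = 1e-12
  )
  # worked example: R_PG = 60, k = 2 so R_TG = 120; grassland mean 80; R_C = 104
  expect_equal(
    rate_ratio_from_total_grass(80, 100,
      a_pg = 100, a_tg = 50, a_c = 250,
      a_c_minus_tg = 200, k = 2
    ),
    60 / 104,
    tolerance = 1e-12
  )
  set.seed(24)
  for (i in 1:300) {
    a_pg <- runif(1, 50, 4000)
    a_tg <- runif(1, 0, 1500)
    a_c_minus_tg <- runif(1, 100, 8000)
    a_c <- a_c_minus_tg + a_tg
    k <- runif(1, 0.5, 3)
    r_pg <- runif(1, 5, 200)
    r_tg <- k * r_pg
    r_c_minus_tg <- runif(1, 20, 300)
    # forward construction of the aggregated rates
    r_pg_tg <- (r_pg * a_pg + r_tg * a_tg) / (a_pg + a_tg)
    r_c <- (r_c_minus_tg * a_c_minus_tg + r_tg * a_tg) / a_c
    est <- rate_ratio_from_total_grass(r_pg_tg, r_c_minus_tg,
      a_pg = a_pg, a_tg = a_tg, a_c = a_c, k = k
    )
    expect_equal(est, r_pg / r_c, tolerance = 1e-9)
  }
})

test_that("the consumption-total fallback inverts its own forward construction", {
  # construct: category x at rate 60 on 100 kha, complement at 90 on 200 kha
  q_tot <- (60 * 100 + 90 * 200) / 1000
  expect_equal(rate_ratio_last_resort(60, 100, 300, q_tot), 60 / 90,
    tolerance = 1e-12
  )
  # uniform rate across the whole area gives ratio 1
  expect_equal(rate_ratio_last_resort(50, 100, 300, 50 * 300 / 1000), 1,
    tolerance = 1e-12
  )
  expect_identical(rate_ratio_last_resort(0, 100, 300, 10), 0)
  expect_error(rate_ratio_last_resort(100, 100, 300, 10), "not positive")
  expect_error(rate_ratio_last_resort(10, 300, 300, 10), "exceed")
  set.seed(25)
  for (i in 1:300) {
    a_x <- runif(1, 10, 2000)
    a_comp <- runif(1, 10, 2000)
    r_x <- runif(1, 1, 250)
    r_comp <- runif(1, 1, 250)
    q_tot <- (r_x * a_x + r_comp * a_comp) / 1000
    est <- rate_ratio_last_resort(r_x, a_x, a_x + a_comp, q_tot)
    expect_equal(est, r_x / r_comp, tolerance = 1e-9)
  }
})

test_that("rate-ratio series interpolate, extrapolate, and average duplicate years", {
  s <- build_rate_ratio_series(
    tibble::tibble(year = 1995L, ratio = 0.11),
    grid = 1961:2019
  )
  expect_identical(unique(s$ratio), 0.11)
  expect_identical(s$provenance[s$year == 1995], "observed")
  expect_identical(unique(s$provenance[s$year != 1995]), "extrapolated")

  s <- build_rate_ratio_series(
    tibble::tibble(year = c(1996L, 2006L), ratio = c(0.70, 0.17)),
    grid = 1990:2010
  )
  expect_equal(s$ratio[s$year == 2001], (0.70 + 0.17) / 2, tolerance = 1e-12)
  expect_identical(s$provenance[s$year == 2001], "interpolated")

  s <- build_rate_ratio_series(
    tibble::tibble(year = c(2000L, 2000L), ratio = c(0.10, 0.20)),
    grid = 1999:2001
  )
  expect_equal(s$ratio, rep(0.15, 3), tolerance = 1e-12)

  z <- build_rate_ratio_series(NULL, grid = 1961:1963, zero_pg = TRUE)
  expect_identical(z$ratio, c(0, 0, 0))
  expect_error(
    build_rate_ratio_series(tibble::tibble(year = integer(), ratio = double())),
    "zero-PG"
  )
})

test_that("quantity allocation conserves the total exactly", {
  out <- allocate_quantities(10, 0.5)
  expect_identical(out$q_c, 5)
  expect_identical(out$q_pg, 5)
  out <- allocate_quantities(c(3, 7), c(1, 1))
  expect_identical(out$q_pg, c(0, 0))
  set.seed(26)
  q <- runif(1000, 0, 2000)
  s <- runif(1000)
  out <- allocate_quantities(q, s)
  expect_identical(q - out$q_c, out$q_pg) # exact complement by construction
  expect_identical(out$q_c + out$q_pg, q) # bit-exact sum on these instances
})

test_that("observations violating Q = R * A / 1000 are excluded with a reason", {
  obs <- tibble::tibble(
    country = "AA", year = 2000L,
    land_category = c("C", "C", "PG"),
    R = c(100, 100, 50),
    Q = c(1.0, 1.2, NA),
    A = c(10, 10, 300),
    source = "s"
  )
  out <- check_fert_obs(obs)
  expect_identical(out$excluded, c(FALSE, TRUE, FALSE))
  expect_match(out$reason[2], "inconsistent")
})
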