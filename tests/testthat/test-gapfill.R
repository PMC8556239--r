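test_that("linear interpolation fills interior gaps and nothing else", {
  s <- series(1961:1963, c(10, NA, 14))
  expect_identical(interpolate_linear(s)$value, c(10, 12, 14))

  s <- series(1961:1965, c(10, NA, NA, NA, 30))
  expect_identical(interpolate_linear(s)$value[3], 20)

  complete <- series(1961:1963, c(1, 2, 3))
  expect_identical(interpolate_linear(complete), complete)

  # leading/trailing gaps are never filled silently
  s <- series(1961:1965, c(NA, 5, NA, 7, NA))
  out <- interpolate_linear(s)
  expect_identical(out$value, c(NA, 5, 6, 7, NA))
})

test_that("constant extrapolation fills edges from the nearest observation", {
  s <- series(1992:2001, c(rep(NA, 8), 5, 6))
  expect_identical(
    extrapolate_const(s, "backward")$value,
    c(rep(5, 9), 6)
  )
  s <- series(2017:2019, c(3, 4, NA))
  expect_identical(extrapolate_const(s, "forward")$value, c(3, 4, 4))
  complete <- series(1961:1963, c(1, 2, 3))
  expect_identical(extrapolate_const(complete), complete)
  expect_error(
    extrapolate_const(series(1961:1962, c(NA, NA))),
    "all-missing"
  )
  # backward direction leaves trailing gaps untouched
  s <- series(1961:1964, c(NA, 2, 3, NA))
  expect_identical(extrapolate_const(s, "backward")$value, c(2, 2, 3, NA))
})

test_that("proportional split reproduces fixed shares and conserves the total", {
  shares <- c(G1000 = 0.29, G2100 = 0.06, G2900 = 0.42, G9000 = 0.23)
  out <- proportional_split(series(1980L, 100), shares)
  expect_equal(out$value, c(29, 6, 42, 23), tolerance = 1e-12)

  expect_identical(
    proportional_split(series(1980L, 7), c(only = 1))$value, 7
  )
  expect_error(
    proportional_split(series(1980L, 1), c(a = 1.2, b = -0.2)), "negative"
  )
  expect_error(
    proportional_split(series(1980L, 1), c(a = 0.5, b = 0.6)), "sum to 1"
  )
})

test_that("proportional split conserves the total exactly on randomized instances", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(2:6, 1)
    raw <- runif(n)
    sh <- raw / sum(raw)
    sh[n] <- 1 - sum(sh[-n])
    names(sh) <- paste0("c", seq_len(n))
    tot <- series(1961:1970, runif(10, 0, 1e4))
    out <- proportional_split(tot, sh)
    comps <- lapply(names(sh), function(cc) out$value[out$component == cc])
    expect_identical(Reduce(`+`, comps), tot$value)
  }
})

test_that("reference-year shares reproduce the observed components in that year", {
  p <- small_panel()
  sh <- reference_year_shares(p, "AA", c("G1000", "G2100"), 1964)
  expect_equal(unname(sh), c(16, 8) / 24, tolerance = 1e-12)
  expect_identical(sum(sh), 1)
  split <- proportional_split(
    series(1964L, 24),
    sh
  )
  expect_equal(split$value, c(16, 8), tolerance = 1e-12)
  expect_error(
    reference_year_shares(p, "AA", c("G1000", "G2100"), 1963),
    "not observed"
  )
})

test_that("residuals subtract children, propagate missing, and clip at zero", {
  parent <- series(1990:1992, c(50, 50, NA))
  c1 <- series(1990:1992, c(30, 30, 30))
  c2 <- series(1990:1992, c(15, 21, 15))
  expect_warning(
    out <- residual_series(parent, list(c1, c2)),
    "clipped"
  )
  expect_identical(out$value, c(5, 0, NA))
  expect_identical(
    residual_series(series(1990L, 45), list(series(1990L, 45)))$value, 0
  )
})

test_that("merge_sum treats missing as absent, not zero", {
  a <- series(1990:1992, c(3, NA, NA))
  b <- series(1990:1992, c(7, 4, NA))
  expect_identical(merge_sum(a, b)$value, c(10, 4, NA))
})

test_that("the rule engine applies rules in order, deterministically, with a log", {
  p <- small_panel()
  rules <- list(
    list(kind = "interpolate_linear", country = "AA", variable = "G1000"),
    list(kind = "extrapolate_const", country = "AA", variable = "G2100"),
    list(kind = "merge_sum", country = "AA", variable = "G0000", a = "G1000", b = "G2100"),
    list(kind = "scale", country = "AA", variable = "G2100", factor = 2)
  )
  out1 <- apply_edit_rules(p, rules)
  out2 <- apply_edit_rules(p, rules)
  expect_identical(out1, out2)
  log <- attr(out1, "edit_log")
  expect_identical(nrow(log), 4L)
  expect_identical(log$filled[1], 1L) # one interior gap in G1000
  g2100 <- panel_series(out1, "AA", "G2100")
  expect_identical(g2100$value, c(5, 5, 5, 8, 9) * 2)
  expect_error(
    apply_edit_rules(p, list(list(kind = "frobnicate", country = "AA", variable = "G1000"))),
    "unknown edit rule"
  )
})

test_that("discard and replace rules edit observed values explicitly", {
  p <- small_panel()
  out <- apply_edit_rules(p, list(
    list(kind = "discard", country = "AA", variable = "G1000", years = c(1961, 1962)),
    list(kind = "replace", country = "AA", variable = "G2100",
      values = list(year = list(1962, 1963), value = list(6.5, 7.0)))
  ))
  expect_identical(panel_series(out, "AA", "G1000")$value, c(NA, NA, NA, 16, 18))
  expect_identical(panel_series(out, "AA", "G2100")$value, c(NA, 6.5, 7.0, 8, 9))
})

test_that("the shipped hay-split config reproduces its fixed proportions", {
  rules <- read_edit_rules(
    system.file("extdata", "poland_hay_split.yaml", package = "nbudgetr")
  )
  expect_identical(rules[[1]]$kind, "proportional_split")
  p <- as_panel(tibble::tibble(
    country = "POL",
    year = rep(1960:1961, 5),
    variable = rep(c("hay", "G1000", "G2100", "G2900", "G9000"), each = 2),
    unit = "kha",
    value = c(1500, 1600, rep(NA, 8))
  ), grid = 1960:1961)
  out <- apply_edit_rules(p, rules)
  expect_identical(panel_series(out, "POL", "G2900")$value, c(1500, 1600) * 0.42)
  expect_identical(panel_series(out, "POL", "G1000")$value, c(1500, 1600) * 0.29)
})
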