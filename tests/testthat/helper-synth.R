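# Shared synthetic scenarios, generated once per test run.
synth_cache <- new.env(parent = emptyenv())

get_synth <- function(key = c("clean", "degraded")) {
  key <- match.arg(key)
  if (!exists(key, envir = synth_cache)) {
    val <- switch(key,
      clean = nb_generate(synth_config(seed = 42, degrade = NULL)),
      degraded = nb_generate(synth_config(seed = 42))
    )
    assign(key, val, envir = synth_cache)
  }
  get(key, envir = synth_cache)
}

series <- function(years, values) tibble::tibble(year = years, value = values)

small_panel <- function() {
  tibble::tibble(
    country = "AA",
    year = rep(1961:1965, 2),
    variable = rep(c("G1000", "G2100"), each = 5),
    unit = "kha",
    value = c(10, 12, NA, 16, 18, NA, NA, 5, 8, 9)
  ) |> as_panel(grid = 1961:1965)
}
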