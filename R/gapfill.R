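# Series-editing operations used throughout the gap-filling stages. All of
# them operate on a "series": a tibble with columns `year`, `value`, ordered
# by year, with explicit NA for missing. Interior gaps are only ever filled
# by linear interpolation and edges only by constant extrapolation; anything
# else must be an explicit rule.

#' Linearly interpolate interior gaps of a series
#'
#' Fills missing years strictly between observed points by linear
#' interpolation; observed values are never modified and years outside the
#' observed envelope remain missing (no silent extrapolation).
#'
#' @param s Series tibble (`year`, `value`).
#' @return Series tibble with interior gaps filled.
#' @examples
#' s <- tibble::tibble(year = 1961:1963, value = c(10, NA, 14))
#' interpolate_linear(s)$value # 10 12 14
#' @export
interpolate_linear <- function(s) {
  s <- dplyr::arrange(tibble::as_tibble(s), .data$year)
  obs <- !is.na(s$value)
  if (sum(obs) < 2) {
    return(s)
  }
  filled <- approx(s$year[obs], s$value[obs], xout = s$year, method = "linear", rule = 1)$y
  s$value[!obs] <- filled[!obs]
  s
}

#' Constant extrapolation at the edges of a series
#'
#' Leading and/or trailing missing years take the nearest observed value.
#' Interior gaps are left untouched.
#'
#' @param s Series tibble (`year`, `value`).
#' @param direction `"backward"` (fill leading years), `"forward"` (fill
#'   trailing years), or `"both"`.
#' @return Series tibble.
#' @export
extrapolate_const <- function(s, direction = c("both", "backward", "forward")) {
  direction <- match.arg(direction)
  s <- dplyr::arrange(tibble::as_tibble(s), .data$year)
  obs <- which(!is.na(s$value))
  if (length(obs) == 0) stop("cannot extrapolate an all-missing series")
  first <- obs[1]
  last <- obs[length(obs)]
  if (direction %in% c("both", "backward") && first > 1) {
    s$value[seq_len(first - 1)] <- s$value[first]
  }
  if (direction %in% c("both", "forward") && last < nrow(s)) {
    s$value[seq.int(last + 1, nrow(s))] <- s$value[last]
  }
  s
}

#' Split a total series into components with fixed shares
#'
#' Each component is `total * share`; the last-listed component takes the
#' residual so the components sum to the total exactly. Used, e.g., to divide
#' a lumped historical "hay" area between constituent crop codes in
#' proportion to a reference year's areas.
#'
#' @param total Series tibble (`year`, `value`).
#' @param shares Named numeric vector of nonnegative fractions summing to 1
#'   within 1e-9; names are the component codes.
#' @return Tibble with columns `year`, `component`, `value` (long form).
#' @export
proportional_split <- function(total, shares) {
  if (is.null(names(shares)) || any(names(shares) == "")) {
    stop("shares must be a fully named vector")
  }
  if (any(shares < 0)) stop("negative share")
  if (abs(sum(shares) - 1) > 1e-9) stop("shares must sum to 1 within 1e-9")
  total <- dplyr::arrange(tibble::as_tibble(total), .data$year)
  n <- length(shares)
  comps <- lapply(seq_len(n), function(i) {
    v <- total$value * unname(shares[i])
    tibble::tibble(year = total$year, component = names(shares)[i], value = v)
  })
  if (n > 1) {
    others <- Reduce(`+`, lapply(comps[seq_len(n - 1)], function(d) d$value))
    comps[[n]]$value <- total$value - others
  }
  dplyr::bind_rows(comps)
}

#' Shares of components in a reference year
#'
#' Convenience for reference-year proportional splits: reads the observed
#' component values in `year` and converts them to fractions of their sum.
#'
#' @param panel A panel tibble.
#' @param country Country code.
#' @param components Character vector of component variable names.
#' @param year Reference year (must be observed for every component).
#' @return Named share vector for [proportional_split()].
#' @export
reference_year_shares <- function(panel, country, components, year) {
  vals <- vapply(components, function(v) {
    s <- panel_series(panel, country, v)
    s$value[s$year == year]
  }, numeric(1))
  if (anyNA(vals)) {
    stop(
      "reference year ", year, " not observed for: ",
      paste(components[is.na(vals)], collapse = ", ")
    )
  }
  tot <- sum(vals)
  if (tot <= 0) stop("reference-year component sum is not positive")
  sh <- vals / tot
  # force exact unit sum so downstream validation never trips on rounding
  sh[length(sh)] <- 1 - sum(sh[-length(sh)])
  sh
}

#' Residual of a parent series after subtracting child series
#'
#' Year-wise `parent - sum(children)`. A value is produced only where parent
#' and all children are non-missing (missing propagates). Negative residuals
#' are clipped to 0 with a warning, since areas cannot be negative.
#'
#' @param parent Series tibble.
#' @param children List of series tibbles.
#' @return Series tibble of the residual.
#' @export
residual_series <- function(parent, children) {
  parent <- dplyr::arrange(tibble::as_tibble(parent), .data$year)
  out <- parent$value
  for (ch in children) {
    ch <- dplyr::arrange(tibble::as_tibble(ch), .data$year)
    stopifnot(identical(ch$year, parent$year))
    out <- out - ch$value
  }
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warning(
      sum(neg), " negative residual value(s) clipped to 0 (largest overshoot ",
      format(-min(out[neg])), ")"
    )
    out[neg] <- 0
  }
  tibble::tibble(year = parent$year, value = out)
}

#' Year-wise sum of two series, treating missing as absent
#'
#' `missing + value = value` (missing is treated as absent, not zero, when at
#' least one operand is observed); `missing + missing = missing`.
#'
#' @param a,b Series tibbles over the same year grid.
#' @return Series tibble of the sum.
#' @export
merge_sum <- function(a, b) {
  a <- dplyr::arrange(tibble::as_tibble(a), .data$year)
  b <- dplyr::arrange(tibble::as_tibble(b), .data$year)
  stopifnot(identical(a$year, b$year))
  v <- dplyr::case_when(
    is.na(a$value) & is.na(b$value) ~ NA_real_,
    is.na(a$value) ~ b$value,
    is.na(b$value) ~ a$value,
    .default = a$value + b$value
  )
  tibble::tibble(year = a$year, value = v)
}

# ---- declarative rule engine -------------------------------------------------

#' Read a list of edit rules from a YAML file
#'
#' Each rule is a mapping with at least `kind` plus rule-specific fields (see
#' [apply_edit_rules()]). Country-specific edits (e.g. the splitting of a
#' lumped historical hay area into constituent crop codes) ship as example
#' configs rather than being hard-coded.
#'
#' @param path YAML file path.
#' @return List of rules.
#' @export
read_edit_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  if (!is.null(rules$rules)) rules <- rules$rules
  rules
}

ensure_variable <- function(panel, country, variable, unit, years) {
  if (!any(panel$country == country & panel$variable == variable)) {
    panel <- dplyr::bind_rows(panel, tibble::tibble(
      country = country, year = as.integer(years), variable = variable,
      unit = unit, value = NA_real_
    ))
  }
  panel
}

replace_series <- function(panel, country, variable, s) {
  idx <- panel$country == country & panel$variable == variable
  m <- match(panel$year[idx], s$year)
  keep <- !is.na(m)
  vals <- panel$value[idx]
  vals[keep] <- s$value[m[keep]]
  panel$value[idx] <- vals
  panel
}

apply_one_rule <- function(panel, rule) {
  kind <- rule$kind
  country <- rule$country
  yrs <- if (!is.null(rule$years)) seq.int(rule$years[[1]], rule$years[[length(rule$years)]]) else NULL
  get <- function(v) panel_series(panel, country, v)
  in_range <- function(s) if (is.null(yrs)) s else dplyr::filter(s, .data$year %in% yrs)
  n_missing <- function(v) sum(is.na(panel_series(panel, country, v)$value))
  filled_count <- 0L
  if (kind == "interpolate_linear") {
    before <- n_missing(rule$variable)
    s <- interpolate_linear(get(rule$variable))
    panel <- replace_series(panel, country, rule$variable, s)
    filled_count <- before - n_missing(rule$variable)
  } else if (kind == "extrapolate_const") {
    before <- n_missing(rule$variable)
    dir <- if (is.null(rule$direction)) "both" else rule$direction
    s <- extrapolate_const(get(rule$variable), direction = dir)
    panel <- replace_series(panel, country, rule$variable, s)
    filled_count <- before - n_missing(rule$variable)
  } else if (kind == "proportional_split") {
    comps <- unlist(rule$components)
    if (!is.null(rule$shares)) {
      shares <- unlist(rule$shares)
      if (!setequal(names(shares), comps)) stop("shares must name every component")
      shares <- shares[comps]
    } else if (!is.null(rule$reference_year)) {
      shares <- reference_year_shares(panel, country, comps, rule$reference_year)
    } else {
      stop("proportional_split rule needs 'shares' or 'reference_year'")
    }
    total <- in_range(get(rule$variable))
    split <- proportional_split(total, shares)
    for (comp in comps) {
      s_new <- dplyr::filter(split, .data$component == comp)
      s_old <- get(comp)
      # only fill years where the component is missing and the total observed
      fill <- s_new[!is.na(s_new$value) &
        is.na(s_old$value[match(s_new$year, s_old$year)]), c("year", "value")]
      filled_count <- filled_count + nrow(fill)
      panel <- replace_series(panel, country, comp, fill)
    }
  } else if (kind == "residual") {
    children <- lapply(rule$children, get)
    parent <- get(rule$parent)
    s <- residual_series(parent, children)
    unit <- panel$unit[panel$country == country & panel$variable == rule$parent][1]
    panel <- ensure_variable(panel, country, rule$variable, unit, parent$year)
    panel <- replace_series(panel, country, rule$variable, s)
    filled_count <- sum(!is.na(s$value))
  } else if (kind == "merge_sum") {
    a <- get(rule$a)
    s <- merge_sum(a, get(rule$b))
    unit <- panel$unit[panel$country == country & panel$variable == rule$a][1]
    panel <- ensure_variable(panel, country, rule$variable, unit, a$year)
    panel <- replace_series(panel, country, rule$variable, s)
    filled_count <- sum(!is.na(s$value))
  } else if (kind == "discard") {
    s <- in_range(get(rule$variable))
    filled_count <- -sum(!is.na(s$value))
    s$value <- NA_real_
    panel <- replace_series(panel, country, rule$variable, s)
  } else if (kind == "replace") {
    s <- tibble::tibble(
      year = as.integer(unlist(rule$values$year)),
      value = as.numeric(unlist(rule$values$value))
    )
    panel <- replace_series(panel, country, rule$variable, s)
    filled_count <- nrow(s)
  } else if (kind == "scale") {
    s <- in_range(get(rule$variable))
    s$value <- s$value * rule$factor
    panel <- replace_series(panel, country, rule$variable, s)
    filled_count <- sum(!is.na(s$value))
  } else {
    stop("unknown edit rule kind: ", kind)
  }
  list(panel = panel, filled = filled_count)
}

#' Apply a declarative list of edit rules to a panel
#'
#' Rules are applied in listed order. Supported kinds:
#' \describe{
#'   \item{interpolate_linear}{fields `country`, `variable`.}
#'   \item{extrapolate_const}{fields `country`, `variable`, optional
#'     `direction`.}
#'   \item{proportional_split}{fields `country`, `variable` (the lumped
#'     total), `components`, and either `shares` (named fractions) or
#'     `reference_year` (shares taken from the components' observed values
#'     in that year); optional `years` restricting the filled range. Only
#'     missing component years are filled.}
#'   \item{residual}{fields `country`, `variable` (target), `parent`,
#'     `children`.}
#'   \item{merge_sum}{fields `country`, `variable` (target), `a`, `b`.}
#'   \item{discard}{fields `country`, `variable`, optional `years`.}
#'   \item{replace}{fields `country`, `variable`, `values` (list with `year`
#'     and `value`).}
#'   \item{scale}{fields `country`, `variable`, `factor`, optional `years`.}
#' }
#'
#' @param panel A panel tibble.
#' @param rules List of rules (see [read_edit_rules()]).
#' @return The edited panel, with an `edit_log` attribute: a tibble of the
#'   applied rules and the number of year-values each filled (negative for
#'   discards).
#' @export
apply_edit_rules <- function(panel, rules) {
  log <- tibble::tibble(
    step = integer(), kind = character(), country = character(),
    variable = character(), filled = integer()
  )
  for (i in seq_along(rules)) {
    rule <- rules[[i]]
    res <- apply_one_rule(panel, rule)
    panel <- res$panel
    log <- dplyr::bind_rows(log, tibble::tibble(
      step = i, kind = rule$kind, country = rule$country,
      variable = rule$variable %||% NA_character_, filled = as.integer(res$filled)
    ))
  }
  attr(panel, "edit_log") <- log
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a
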