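# Land-area bookkeeping: cropland in use, permanent/temporary grassland
# weights, and the fallow-land consistency check.

#' Cropland area in use
#'
#' The minimum of the summed (adjusted) crop-category areas and the reported
#' total cropland area. The crop-area sum can exceed reported cropland
#' through multi- or intercropping, in which case the reported area caps it;
#' otherwise the crop-area sum is the better estimate since reported cropland
#' may include fallow. If only one input is present it is used as-is (flagged
#' by [cropland_in_use_tbl()]); both missing gives missing.
#'
#' @param a_crop_sum Crop-area sum (kha), vectorized.
#' @param a_reported Reported cropland area (kha).
#' @return Cropland in use (kha).
#' @examples
#' cropland_in_use(105, 100) # 100
#' cropland_in_use(95, 100) # 95
#' @export
cropland_in_use <- function(a_crop_sum, a_reported) {
  dplyr::case_when(
    is.na(a_crop_sum) & is.na(a_reported) ~ NA_real_,
    is.na(a_crop_sum) ~ a_reported,
    is.na(a_reported) ~ a_crop_sum,
    .default = pmin(a_crop_sum, a_reported)
  )
}

#' Cropland in use with provenance flags
#'
#' @inheritParams cropland_in_use
#' @return Tibble with `value` and `flag` (`NA`, `"crop sum only"`, or
#'   `"reported only"`).
#' @export
cropland_in_use_tbl <- function(a_crop_sum, a_reported) {
  tibble::tibble(
    value = cropland_in_use(a_crop_sum, a_reported),
    flag = dplyr::case_when(
      is.na(a_crop_sum) & !is.na(a_reported) ~ "reported only",
      !is.na(a_crop_sum) & is.na(a_reported) ~ "crop sum only",
      .default = NA_character_
    )
  )
}

#' Fallow-land consistency check
#'
#' Compares the crop-area sum to reported cropland minus fallow land. The
#' two should agree within a few percent when reporting is consistent; the
#' check flags country-years where the relative difference exceeds `tol`
#' (default 5%), or where reported minus fallow is not positive.
#'
#' @param a_crop_sum Crop-area sum (kha), vectorized.
#' @param a_reported Reported cropland (kha).
#' @param a_fallow Fallow area (kha).
#' @param tol Relative tolerance.
#' @return Logical: `TRUE` where flagged (inconsistent).
#' @export
fallow_consistency <- function(a_crop_sum, a_reported, a_fallow, tol = 0.05) {
  ref <- a_reported - a_fallow
  dplyr::case_when(
    is.na(a_crop_sum) | is.na(ref) ~ NA,
    ref <= 0 ~ TRUE,
    .default = abs(a_crop_sum - ref) / ref > tol
  )
}

#' Grassland split weights
#'
#' Weights `A_PG / (A_PG + A_TG)` and `A_TG / (A_PG + A_TG)` used to divide
#' grassland-destined N between permanent and temporary grassland in
#' proportion to their areas. The temporary weight is computed as the
#' complement of the permanent weight so the two always sum to 1 exactly.
#' When no grassland exists (both areas zero) the weights are defined as
#' zero with a flag: there is nothing to receive the flow.
#'
#' @param a_pg Permanent grassland area (kha), vectorized.
#' @param a_tg Temporary grassland area (kha).
#' @return Tibble with `w_pg`, `w_tg`, `flag`.
#' @export
grassland_weights <- function(a_pg, a_tg) {
  stopifnot(all(a_pg >= 0 | is.na(a_pg)), all(a_tg >= 0 | is.na(a_tg)))
  tot <- a_pg + a_tg
  w_pg <- ifelse(!is.na(tot) & tot > 0, a_pg / tot, 0)
  w_tg <- ifelse(!is.na(tot) & tot > 0, 1 - w_pg, 0)
  tibble::tibble(
    w_pg = w_pg, w_tg = w_tg,
    flag = ifelse(!is.na(tot) & tot == 0, "no grassland", NA_character_)
  )
}
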