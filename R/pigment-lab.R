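#' Spectrophotometric pigment determination
#'
#' Convert UV-VIS absorbances of a 95% ethanol leaf extract into pigment
#' concentrations, and concentrations into area-based contents. Absorbances
#' are read at 665 nm (chlorophyll a), 649 nm (chlorophyll b) and 470 nm
#' (carotenoids). Concentrations may come out negative for pathological
#' absorbance combinations; they are returned unclamped with a warning so
#' that the algebraic identities between the formulas stay exact.
#'
#' @param a665,a649,a470 Extract absorbances (unitless, >= 0 for physical
#'   extracts). Vectorised; recycled to a common length.
#' @return Pigment concentration in mg/L.
#' @examples
#' chlorophyll_a(0.5, 0.2)
#' total_chlorophyll(0.5, 0.2) == chlorophyll_a(0.5, 0.2) + chlorophyll_b(0.5, 0.2)
#' @name pigment_lab
NULL

.check_absorbance <- function(...) {
  vals <- c(...)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("absorbances must be finite numeric values", call. = FALSE)
  }
  invisible(TRUE)
}

.warn_negative <- function(x, what) {
  if (any(x < 0)) {
    warning(sprintf("%d negative %s concentration(s); returned unclamped",
                    sum(x < 0), what), call. = FALSE)
  }
  x
}

#' @rdname pigment_lab
#' @export
chlorophyll_a <- function(a665, a649) {
  .check_absorbance(a665, a649)
  .warn_negative(13.95 * a665 - 6.88 * a649, "chlorophyll a")
}

#' @rdname pigment_lab
#' @export
chlorophyll_b <- function(a665, a649) {
  .check_absorbance(a665, a649)
  .warn_negative(24.96 * a649 - 7.32 * a665, "chlorophyll b")
}

#' @rdname pigment_lab
#' @export
total_chlorophyll <- function(a665, a649) {
  .check_absorbance(a665, a649)
  # coefficient identity: 13.95 - 7.32 = 6.63 on A665, 24.96 - 6.88 = 18.08 on A649
  .warn_negative(18.08 * a649 + 6.63 * a665, "total chlorophyll")
}

#' @rdname pigment_lab
#' @export
total_carotenoid <- function(a665, a649, a470) {
  .check_absorbance(a665, a649, a470)
  chla <- 13.95 * a665 - 6.88 * a649
  chlb <- 24.96 * a649 - 7.32 * a665
  .warn_negative((1000 * a470 - 2.05 * chla - 114.8 * chlb) / 245,
                 "total carotenoid")
}

#' Convert extract concentration to area-based pigment content
#'
#' Unit convention: content \[ug/cm2\] = C \[mg/L\] * n * V \[mL\] / area
#' \[cm2\], reading mg/L as ug/mL, so no further factor is applied.
#'
#' @param conc Pigment concentration in the extract, mg/L.
#' @param n Ethanol volume concentration, fraction in (0, 1].
#' @param volume Extract volume, mL (> 0).
#' @param leaf_area Sampled leaf area, cm2 (> 0).
#' @return Pigment content, ug/cm2.
#' @export
to_area_content <- function(conc, n = 0.95, volume = 10, leaf_area) {
  if (!is.numeric(conc) || anyNA(conc) || any(!is.finite(conc))) {
    stop("conc must be finite numeric", call. = FALSE)
  }
  if (any(leaf_area <= 0)) stop("leaf_area must be > 0", call. = FALSE)
  if (any(volume <= 0)) stop("volume must be > 0", call. = FALSE)
  if (any(n <= 0 | n > 1)) stop("n must be in (0, 1]", call. = FALSE)
  conc * n * volume / leaf_area
}

#' Read or write a laboratory pigment table
#'
#' Plain CSV with columns sample_id, layer, A665, A649, A470, V_mL, n,
#' leaf_area_cm2, chl_ab_ug_cm2, car_ug_cm2. `lab_table_from_absorbance()`
#' fills the two content columns from the absorbance columns.
#'
#' @param x A lab-table data.frame.
#' @param path File path.
#' @return `read_lab_table` and `lab_table_from_absorbance` return the
#'   data.frame; `write_lab_table` returns `path` invisibly.
#' @export
read_lab_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "layer", "A665", "A649", "A470",
              "V_mL", "n", "leaf_area_cm2")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("lab table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_lab_table
#' @export
write_lab_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_lab_table
#' @export
lab_table_from_absorbance <- function(x) {
  x$chl_ab_ug_cm2 <- to_area_content(total_chlorophyll(x$A665, x$A649),
                                     n = x$n, volume = x$V_mL,
                                     leaf_area = x$leaf_area_cm2)
  x$car_ug_cm2 <- to_area_content(total_carotenoid(x$A665, x$A649, x$A470),
                                  n = x$n, volume = x$V_mL,
                                  leaf_area = x$leaf_area_cm2)
  x
}
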