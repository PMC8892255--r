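#' Unit conversions for glycemia and insulinemia
#'
#' The package works internally in mM (glycemia) and pM (insulinemia).
#' Conversions use the fixed clinical factors 180 mg/dL = 10 mM (i.e. a
#' divisor of exactly 18, not the 180.16 g/mol molar mass) and
#' 1 uU/mL = 6.945 pM, so all arithmetic downstream is reproducible to the
#' printed precision of the diagnostic reference table.
#'
#' @param value numeric vector of concentrations, all `>= 0`.
#' @param from,to unit names. Glycemia: `"mg/dL"` or `"mM"`. Insulinemia:
#'   `"uU/mL"` (synonyms `"muU/mL"`, `"μU/mL"`) or `"pM"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_glycemia(180, "mg/dL", "mM")   # 10
#' convert_insulinemia(1, "uU/mL", "pM")  # 6.945
#' @export
convert_glycemia <- function(value, from = "mg/dL", to = "mM") {
  stopifnot(is.numeric(value), all(is.finite(value)), all(value >= 0))
  f <- .glycemia_unit_factor(from) # factor to mM
  t <- .glycemia_unit_factor(to)
  value * f / t
}

#' @rdname convert_glycemia
#' @export
convert_insulinemia <- function(value, from = "uU/mL", to = "pM") {
  stopifnot(is.numeric(value), all(is.finite(value)), all(value >= 0))
  f <- .insulinemia_unit_factor(from)
  t <- .insulinemia_unit_factor(to)
  value * f / t
}

# mg/dL -> mM divisor: 180 mg/dL == 10 mM
GLYCEMIA_MGDL_PER_MM <- 18
# uU/mL -> pM factor
INSULIN_PM_PER_UUML <- 6.945

.glycemia_unit_factor <- function(unit) {
  switch(unit,
    "mM" = 1,
    "mmol/L" = 1,
    "mg/dL" = 1 / GLYCEMIA_MGDL_PER_MM,
    stop("unknown glycemia unit: '", unit, "' (use 'mg/dL' or 'mM')",
         call. = FALSE)
  )
}

.insulinemia_unit_factor <- function(unit) {
  switch(unit,
    "pM" = 1,
    "pmol/L" = 1,
    "uU/mL" = INSULIN_PM_PER_UUML,
    "muU/mL" = INSULIN_PM_PER_UUML,
    "μU/mL" = INSULIN_PM_PER_UUML,
    stop("unknown insulinemia unit: '", unit, "' (use 'uU/mL' or 'pM')",
         call. = FALSE)
  )
}
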