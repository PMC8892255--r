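#' Binary clinical healthy/non-healthy classification of an OGTT-I curve
#'
#' Applies the threshold-based clinical criteria directly to the raw
#' curves. A subject is healthy iff all of the following hold (evaluated
#' after converting to the clinical units mg/dL and uU/mL):
#'
#' * fasting glycemia `< 100` mg/dL and fasting insulinemia `< 15` uU/mL
#'   (strict, per the fasting-criterion wording);
#' * glycemia never exceeds `160` mg/dL and does not persist above `140`
#'   mg/dL at 2 h (the 120-min sample);
#' * insulinemia never exceeds `100` uU/mL and does not persist above `60`
#'   uU/mL at 2 h.
#'
#' "Does not exceed" is treated as `<=`; only the fasting thresholds are
#' strict. "After 2 h" is evaluated at the 120-min sample alone (the
#' protocol's last sample), with no interpolation.
#'
#' @param record an [ogtt_record()] containing a 120-min sample.
#' @return a list of class `clinical_label` with `label` (`"healthy"` /
#'   `"non-healthy"`) and `violations`, a character vector naming each
#'   violated rule with the offending value.
#' @examples
#' rec <- ogtt_record("s1", c(0, 30, 60, 90, 120),
#'                    c(86.4, 120, 130, 110, 95), c(4.32, 25, 40, 35, 20),
#'                    glycemia_unit = "mg/dL", insulinemia_unit = "uU/mL")
#' classify_clinical(rec)$label
#' @export
classify_clinical <- function(record) {
  stopifnot(inherits(record, "ogtt_record"))
  if (!120 %in% record$times) {
    stop("subject '", record$subject_id,
         "': clinical classification needs a 120-min sample", call. = FALSE)
  }
  g <- convert_glycemia(record$glycemia, "mM", "mg/dL")
  i <- convert_insulinemia(record$insulinemia, "pM", "uU/mL")
  g120 <- g[record$times == 120]
  i120 <- i[record$times == 120]
  # absolute tolerance absorbs round-trip float error from the internal
  # mM/pM representation; far below assay resolution in clinical units
  eps <- 1e-9
  v <- character(0)
  if (g[1L] >= 100 - eps) {
    v <- c(v, sprintf("fasting glycemia %.1f mg/dL >= 100 mg/dL", g[1L]))
  }
  if (i[1L] >= 15 - eps) {
    v <- c(v, sprintf("fasting insulinemia %.1f uU/mL >= 15 uU/mL", i[1L]))
  }
  if (max(g) > 160 + eps) {
    v <- c(v, sprintf("glycemia %.1f mg/dL exceeds 160 mg/dL at t = %g min",
                      max(g), record$times[which.max(g)]))
  }
  if (g120 > 140 + eps) {
    v <- c(v, sprintf("glycemia persists above 140 mg/dL after 2 h (%.1f)",
                      g120))
  }
  if (max(i) > 100 + eps) {
    v <- c(v, sprintf("insulinemia %.1f uU/mL exceeds 100 uU/mL at t = %g min",
                      max(i), record$times[which.max(i)]))
  }
  if (i120 > 60 + eps) {
    v <- c(v, sprintf("insulinemia persists above 60 uU/mL after 2 h (%.1f)",
                      i120))
  }
  structure(list(label = if (length(v)) "non-healthy" else "healthy",
                 violations = v, subject_id = record$subject_id),
            class = "clinical_label")
}

#' @export
print.clinical_label <- function(x, ...) {
  cat("<clinical_label>", x$subject_id, "->", x$label, "\n")
  if (length(x$violations)) {
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  }
  invisible(x)
}
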