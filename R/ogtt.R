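#' Construct a single-subject OGTT record
#'
#' An `ogtt_record` holds one subject's timed glycemia/insulinemia
#' measurements during an oral glucose tolerance test, stored internally in
#' mM (glycemia) and pM (insulinemia). The default clinical protocol takes
#' five samples at 0, 30, 60, 90 and 120 min after a 75 g glucose bolus;
#' time 0 is the fasting (basal) sample and must be present.
#'
#' @param subject_id character scalar identifying the subject.
#' @param times numeric vector of minutes since glucose ingestion, strictly
#'   increasing, starting at 0.
#' @param glycemia,insulinemia numeric vectors, same length as `times`,
#'   strictly positive, in the units given by `glycemia_unit` /
#'   `insulinemia_unit`.
#' @param dose_g glucose dose in grams (default 75, the standard OGTT bolus).
#' @param glycemia_unit,insulinemia_unit units the data arrive in; converted
#'   to mM / pM on construction.
#' @return an object of class `ogtt_record` with elements `subject_id`,
#'   `times`, `glycemia` (mM), `insulinemia` (pM), `dose_g`, `dose_mmol`,
#'   and `source_units`.
#' @examples
#' ogtt_record("s1", c(0, 30, 60, 90, 120),
#'             glycemia = c(86.4, 120, 135, 110, 95),
#'             insulinemia = c(4.32, 30, 45, 35, 20),
#'             glycemia_unit = "mg/dL", insulinemia_unit = "uU/mL")
#' @export
ogtt_record <- function(subject_id, times, glycemia, insulinemia,
                        dose_g = 75,
                        glycemia_unit = "mM", insulinemia_unit = "pM") {
  subject_id <- as.character(subject_id)
  stopifnot(length(subject_id) == 1L)
  if (length(times) != length(glycemia) ||
      length(times) != length(insulinemia)) {
    stop("subject '", subject_id,
         "': times, glycemia and insulinemia must have equal length",
         call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("subject '", subject_id, "': need at least 2 samples", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("subject '", subject_id, "': times must be strictly increasing",
         call. = FALSE)
  }
  if (times[1L] != 0) {
    stop("subject '", subject_id, "': missing basal sample (times[1] != 0)",
         call. = FALSE)
  }
  if (any(!is.finite(glycemia)) || any(glycemia <= 0) ||
      any(!is.finite(insulinemia)) || any(insulinemia <= 0)) {
    stop("subject '", subject_id,
         "': all concentrations must be finite and > 0", call. = FALSE)
  }
  stopifnot(is.numeric(dose_g), dose_g >= 0)
  rec <- structure(list(
    subject_id   = subject_id,
    times        = as.numeric(times),
    glycemia     = convert_glycemia(glycemia, glycemia_unit, "mM"),
    insulinemia  = convert_insulinemia(insulinemia, insulinemia_unit, "pM"),
    dose_g       = dose_g,
    dose_mmol    = dose_g_to_mmol(dose_g),
    source_units = c(glycemia = glycemia_unit, insulinemia = insulinemia_unit)
  ), class = "ogtt_record")
  rec
}

#' Convert a glucose dose in grams to mmol
#'
#' Uses the same fixed factor as the glycemia conversion (180 mg/dL = 10 mM,
#' i.e. 0.18 g per mmol), so 75 g maps to 416.67 mmol.
#' @param grams dose in grams.
#' @return dose in mmol.
#' @export
dose_g_to_mmol <- function(grams) grams / 0.18 * 1

#' @export
print.ogtt_record <- function(x, ...) {
  cat("<ogtt_record> subject", x$subject_id,
      sprintf("(%d samples, dose %.0f g)\n", length(x$times), x$dose_g))
  print(data.frame(time_min = x$times,
                   glycemia_mM = round(x$glycemia, 3),
                   insulinemia_pM = round(x$insulinemia, 2)),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ogtt_record <- function(x, ...) {
  data.frame(subject_id = x$subject_id, time_min = x$times,
             glycemia = x$glycemia, insulinemia = x$insulinemia,
             stringsAsFactors = FALSE)
}

#' Read OGTT records from a CSV table
#'
#' Accepts two layouts. Long: columns `subject_id, time_min, glycemia,
#' insulinemia`, one row per sample. Wide: one row per subject with columns
#' `glycemia_<t>` and `insulinemia_<t>` for each sample time `<t>` in
#' minutes. The dialect is fixed: comma-separated, header required, `.`
#' decimal, UTF-8. Concentrations are converted to internal units (mM, pM)
#' on read.
#'
#' @param path CSV file path.
#' @param glycemia_unit,insulinemia_unit units of the stored values.
#' @param dose_g glucose dose in grams applied to every record.
#' @return a named list of [ogtt_record()] objects.
#' @export
read_ogtt_table <- function(path, glycemia_unit = "mg/dL",
                            insulinemia_unit = "uU/mL", dose_g = 75) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  long_cols <- c("subject_id", "time_min", "glycemia", "insulinemia")
  if (all(long_cols %in% names(df))) {
    recs <- lapply(split(df, df$subject_id), function(d) {
      d <- d[order(d$time_min), , drop = FALSE]
      ogtt_record(d$subject_id[1L], d$time_min, d$glycemia, d$insulinemia,
                  dose_g = dose_g, glycemia_unit = glycemia_unit,
                  insulinemia_unit = insulinemia_unit)
    })
    return(recs[unique(df$subject_id)])
  }
  g_cols <- grep("^glycemia_[0-9]+$", names(df), value = TRUE)
  i_cols <- grep("^insulinemia_[0-9]+$", names(df), value = TRUE)
  if ("subject_id" %in% names(df) && length(g_cols) && length(i_cols)) {
    g_times <- as.numeric(sub("^glycemia_", "", g_cols))
    i_times <- as.numeric(sub("^insulinemia_", "", i_cols))
    if (!setequal(g_times, i_times)) {
      stop("wide CSV: glycemia and insulinemia time columns disagree",
           call. = FALSE)
    }
    ord <- order(g_times)
    i_ord <- order(i_times)
    recs <- lapply(seq_len(nrow(df)), function(i) {
      ogtt_record(df$subject_id[i], g_times[ord],
                  as.numeric(df[i, g_cols[ord]]),
                  as.numeric(df[i, i_cols[i_ord]]),
                  dose_g = dose_g, glycemia_unit = glycemia_unit,
                  insulinemia_unit = insulinemia_unit)
    })
    names(recs) <- df$subject_id
    return(recs)
  }
  stop("unrecognised OGTT CSV layout: need long columns ",
       paste(long_cols, collapse = ", "),
       " or wide columns subject_id + glycemia_<t>/insulinemia_<t>",
       call. = FALSE)
}

#' Write OGTT records to a long-format CSV (internal units: mM, pM)
#' @param records list of [ogtt_record()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ogtt_table <- function(records, path) {
  df <- do.call(rbind, lapply(records, as.data.frame))
  # 17 significant digits round-trip doubles exactly through text
  for (nm in c("time_min", "glycemia", "insulinemia")) {
    df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
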