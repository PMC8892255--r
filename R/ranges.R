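#' Packaged diagnostic reference ranges
#'
#' Loads the cohort-derived normal/undesirable/abnormal diagnostic ranges
#' for the model's physiological parameters and dimensionless indices, as a
#' `range_table` (a data frame, one row per index). The healthy interval is
#' the central 90% interval of the healthy-cohort log-logistic fit; the
#' undesirable interval runs from the equal-density threshold between the
#' healthy and non-healthy density fits to the healthy-interval boundary on
#' the non-healthy side; the abnormal region continues past that boundary.
#' Note the `eta` row stores its units string as printed in the source
#' table (`L^-3`) without reinterpretation.
#'
#' @param path optional path to a JSON range file with the packaged schema;
#'   defaults to the table shipped with the package.
#' @return a data frame of class `range_table` with columns `index`,
#'   `process`, `units`, `healthy_lo`, `healthy_hi`, `undesirable_lo`,
#'   `undesirable_hi`, `abnormal_direction` (`"below"`/`"above"`) and
#'   `abnormal_bound`.
#' @examples
#' rt <- load_reference_ranges()
#' rt[rt$index == "G_b", ]
#' @export
load_reference_ranges <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_ranges.json",
                        package = "glycofit", mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rows <- lapply(raw$rows, function(r) {
    data.frame(index = r$index, process = r$process, units = r$units,
               healthy_lo = r$healthy[[1]], healthy_hi = r$healthy[[2]],
               undesirable_lo = r$undesirable[[1]],
               undesirable_hi = r$undesirable[[2]],
               abnormal_direction = r$abnormal_direction,
               abnormal_bound = r$abnormal_bound,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  validate_range_table(tab)
  class(tab) <- c("range_table", "data.frame")
  tab
}

validate_range_table <- function(tab) {
  stopifnot(all(c("index", "healthy_lo", "healthy_hi", "undesirable_lo",
                  "undesirable_hi", "abnormal_direction",
                  "abnormal_bound") %in% names(tab)))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!r$abnormal_direction %in% c("below", "above")) {
      stop("row ", r$index, ": abnormal_direction must be below/above",
           call. = FALSE)
    }
    if (r$healthy_lo >= r$healthy_hi ||
        r$undesirable_lo >= r$undesirable_hi) {
      stop("row ", r$index, ": malformed interval", call. = FALSE)
    }
    # undesirable interval must be adjacent to the healthy one on the
    # abnormal side, and the abnormal bound must continue it outward
    if (r$abnormal_direction == "below") {
      ok <- isTRUE(all.equal(r$undesirable_hi, r$healthy_lo)) &&
        isTRUE(all.equal(r$abnormal_bound, r$undesirable_lo))
    } else {
      ok <- isTRUE(all.equal(r$undesirable_lo, r$healthy_hi)) &&
        isTRUE(all.equal(r$abnormal_bound, r$undesirable_hi))
    }
    if (!ok) {
      stop("row ", r$index,
           ": intervals not adjacent/consistent with direction",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Classify an index value into the diagnostic ranges
#'
#' Membership is decided against the boundaries on the non-healthy side of
#' the index (the abnormal direction); a value sitting exactly on a shared
#' boundary takes the healthier label, matching the shared printed
#' endpoints of the reference table.
#'
#' @param value numeric value of the index, in the table's units.
#' @param index index name (e.g. `"G_b"`, `"Pi_X"`).
#' @param table a `range_table`, default the packaged reference ranges.
#' @return one of `"normal"`, `"undesirable"`, `"abnormal"`.
#' @examples
#' classify_in_ranges(4.5, "G_b")   # "normal"
#' classify_in_ranges(5.10, "G_b")  # "undesirable"
#' classify_in_ranges(5.40, "G_b")  # "abnormal"
#' @export
classify_in_ranges <- function(value, index, table = load_reference_ranges()) {
  stopifnot(is.numeric(value), is.finite(value))
  r <- table[table$index == index, ]
  if (nrow(r) != 1L) {
    stop("unknown index '", index, "' (known: ",
         paste(table$index, collapse = ", "), ")", call. = FALSE)
  }
  if (r$abnormal_direction == "below") {
    if (value >= r$healthy_lo) "normal"
    else if (value >= r$undesirable_lo) "undesirable"
    else "abnormal"
  } else {
    if (value <= r$healthy_hi) "normal"
    else if (value <= r$undesirable_hi) "undesirable"
    else "abnormal"
  }
}
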