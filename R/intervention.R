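#' Extract the per-subject index values of one study arm
#'
#' @param study an `intervention_study`.
#' @param index a parameter name, Pi-number name, or `"risk"`.
#' @param dose arm label.
#' @return named numeric vector over subjects.
#' @export
study_index_values <- function(study, index, dose) {
  stopifnot(inherits(study, "intervention_study"),
            dose %in% study$doses)
  vapply(study$subjects, function(arms) {
    arm <- arms[[dose]]
    if (index == "risk") {
      arm$risk
    } else if (index %in% NDN_NAMES) {
      unclass(arm$ndns)[[index]]
    } else if (index %in% PARAM_NAMES) {
      unclass(arm$params)[[index]]
    } else {
      stop("unknown index '", index, "'", call. = FALSE)
    }
  }, numeric(1L))
}

#' Significance stars for intervention p-values
#'
#' Step function matching the dose-response reporting convention:
#' `*` for `p <= 0.1`, `**` for `p <= 0.05`, `***` for `p <= 0.01`,
#' `****` for `p <= 0.001`, empty otherwise (boundaries inclusive).
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (!is.finite(pi)) ""
    else if (pi <= 0.001) "****"
    else if (pi <= 0.01) "***"
    else if (pi <= 0.05) "**"
    else if (pi <= 0.1) "*"
    else ""
  }, character(1L))
}

#' Dose-vs-control tests for one index across a crossover study
#'
#' For each dose arm, compares the index against the control arm. The
#' default is a paired t-test (the crossover design measures the same
#' subjects in every arm); an unpaired comparison of arm means is
#' available with `paired = FALSE`. Raw p-values carry significance
#' stars; Benjamini-Hochberg-adjusted q-values across the doses are
#' reported alongside.
#'
#' @param study an `intervention_study`.
#' @param index parameter/Pi-number name or `"risk"`.
#' @param paired paired (default) or unpaired t-tests.
#' @return data frame: `dose`, `n`, `mean_control`, `mean_dose`,
#'   `mean_diff` (dose minus control), `t`, `p_value`, `stars`,
#'   `q_value`.
#' @export
dose_effect_tests <- function(study, index, paired = TRUE) {
  doses <- setdiff(study$doses, "0")
  if (!length(doses)) stop("study has no treatment arms", call. = FALSE)
  ctrl <- study_index_values(study, index, "0")
  rows <- lapply(doses, function(d) {
    x <- study_index_values(study, index, d)
    keep <- is.finite(x) & is.finite(ctrl)
    if (sum(!keep)) warning(sum(!keep), " subject(s) dropped for dose ", d)
    if (sum(keep) < 2) stop("fewer than 2 complete pairs for dose ", d,
                            call. = FALSE)
    x <- x[keep]; c0 <- ctrl[keep]
    tt <- if (identical(x, c0)) {
      list(statistic = c(t = 0), p.value = 1)
    } else if (paired) {
      stats::t.test(x, c0, paired = TRUE)
    } else {
      stats::t.test(x, c0)
    }
    data.frame(dose = d, n = sum(keep), mean_control = mean(c0),
               mean_dose = mean(x), mean_diff = mean(x) - mean(c0),
               t = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p_value)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Per-subject risk trajectory across intervention arms
#'
#' Risk probabilities per arm from the published logistic model, with a
#' dose-monotonicity flag, the best dose (minimum risk; ties go to the
#' lowest dose, control counting as dose 0), and the per-index diagnostic
#' range transitions between control and best dose.
#'
#' @param study an `intervention_study`.
#' @param subject subject name (e.g. `"s17"`).
#' @param table range table used for the transition summary.
#' @return list with `risk` (named per arm), `monotone_decreasing`,
#'   `best_dose`, `range_transitions` (data frame: index, control label,
#'   best-dose label).
#' @export
risk_trajectory <- function(study, subject,
                            table = load_reference_ranges()) {
  arms <- study$subjects[[subject]]
  if (is.null(arms)) stop("unknown subject '", subject, "'", call. = FALSE)
  risk <- vapply(arms, `[[`, numeric(1L), "risk")
  names(risk) <- names(arms)
  if (length(risk) < 2) {
    stop("subject '", subject, "' has fewer than 2 arms", call. = FALSE)
  }
  ord <- order(as.numeric(names(risk)))
  risk <- risk[ord]
  best <- names(risk)[which.min(risk)]  # which.min takes first = lowest dose
  transitions <- NULL
  idxs <- intersect(table$index, c(PARAM_NAMES, NDN_NAMES))
  val_of <- function(arm, idx) {
    if (idx %in% NDN_NAMES) unclass(arm$ndns)[[idx]]
    else unclass(arm$params)[[idx]]
  }
  transitions <- do.call(rbind, lapply(idxs, function(idx) {
    data.frame(index = idx,
               control = classify_in_ranges(val_of(arms[["0"]], idx), idx,
                                            table),
               best = classify_in_ranges(val_of(arms[[best]], idx), idx,
                                         table),
               stringsAsFactors = FALSE)
  }))
  list(risk = risk,
       monotone_decreasing = all(diff(risk) <= 0),
       best_dose = best,
       range_transitions = transitions)
}

#' Split study subjects into treatment responders and non-responders
#'
#' A subject responds when their best-dose risk improves on the control
#' risk by at least `delta_threshold` (absolute probability, default
#' 0.05). For each group the summary counts, per index, how many subjects
#' moved into the normal diagnostic range at the best dose.
#'
#' @param study an `intervention_study`.
#' @param delta_threshold minimum absolute risk decrease to count as
#'   response.
#' @param table range table for the normalisation summary.
#' @return list with `responders`, `non_responders` (subject names),
#'   `deltas` (named control-minus-best risk decreases), and
#'   `normalised_indices` (data frame: index, group, n_normalised).
#' @export
responder_split <- function(study, delta_threshold = 0.05,
                            table = load_reference_ranges()) {
  subs <- names(study$subjects)
  trajs <- lapply(subs, function(s) risk_trajectory(study, s, table))
  names(trajs) <- subs
  deltas <- vapply(trajs, function(tr) {
    tr$risk[["0"]] - min(tr$risk)
  }, numeric(1L))
  responders <- subs[deltas >= delta_threshold & deltas > 0]
  non_responders <- setdiff(subs, responders)
  norm_rows <- do.call(rbind, lapply(subs, function(s) {
    tr <- trajs[[s]]$range_transitions
    tr$subject <- s
    tr$group <- if (s %in% responders) "responder" else "non-responder"
    tr
  }))
  norm_sum <- stats::aggregate(
    cbind(n_normalised = norm_rows$control != "normal" &
            norm_rows$best == "normal") ~ index + group,
    data = norm_rows, FUN = sum)
  list(responders = responders, non_responders = non_responders,
       deltas = deltas, normalised_indices = norm_sum)
}
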