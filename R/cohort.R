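#' Two-sample Kolmogorov-Smirnov comparison of cohort index values
#'
#' Thin wrapper over [stats::ks.test()] returning the statistic, the
#' asymptotic p-value, and a `different` flag at the given significance
#' level.
#'
#' @param samples_h,samples_nh numeric vectors (healthy / non-healthy
#'   cohort values of one index).
#' @param alpha significance level for the `different` flag.
#' @return list with `statistic`, `p_value`, `different`.
#' @export
ks_compare <- function(samples_h, samples_nh, alpha = 0.05) {
  stopifnot(length(samples_h) > 0, length(samples_nh) > 0)
  kt <- suppressWarnings(stats::ks.test(samples_h, samples_nh))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       different = kt$p.value < alpha)
}

#' Tail-occupancy shift test between cohorts
#'
#' Computes the healthy cohort's 90% left-tail region `[0, Q_h(tail_mass)]`
#' and right-tail region `[Q_h(1 - tail_mass), Inf)` from its empirical
#' quantiles, then compares the proportion of subjects inside each region
#' between the cohorts with a two-sample t-test on the 0/1 occupancy
#' indicators (a t-test on proportions, kept as stated in the source
#' methodology rather than the more conventional two-proportion z-test).
#' A significant *excess* of non-healthy subjects in one tail region marks
#' the direction of the non-healthy shift.
#'
#' @param samples_h,samples_nh cohort values of one index.
#' @param tail_mass mass of each healthy tail region (default 0.90).
#' @param alpha significance level.
#' @return list with `direction` (`"left"`, `"right"` or `"none"`) and the
#'   per-tail occupancy proportions and p-values.
#' @export
tail_shift_test <- function(samples_h, samples_nh, tail_mass = 0.90,
                            alpha = 0.05) {
  stopifnot(length(samples_h) > 1, length(samples_nh) > 1)
  q_left  <- stats::quantile(samples_h, tail_mass, names = FALSE)
  q_right <- stats::quantile(samples_h, 1 - tail_mass, names = FALSE)
  in_left_h   <- as.numeric(samples_h  <= q_left)
  in_left_nh  <- as.numeric(samples_nh <= q_left)
  in_right_h  <- as.numeric(samples_h  >= q_right)
  in_right_nh <- as.numeric(samples_nh >= q_right)
  tt <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    suppressWarnings(stats::t.test(a, b)$p.value)
  }
  p_left  <- tt(in_left_h, in_left_nh)
  p_right <- tt(in_right_h, in_right_nh)
  excess_left  <- mean(in_left_nh)  - mean(in_left_h)   # nh piles low
  excess_right <- mean(in_right_nh) - mean(in_right_h)  # nh piles high
  dir <- "none"
  sig_left  <- is.finite(p_left)  && p_left  < alpha && excess_left > 0
  sig_right <- is.finite(p_right) && p_right < alpha && excess_right > 0
  if (sig_left && sig_right) {
    dir <- if (excess_left >= excess_right) "left" else "right"
  } else if (sig_left) {
    dir <- "left"
  } else if (sig_right) {
    dir <- "right"
  }
  list(direction = dir,
       left = list(bound = q_left, prop_h = mean(in_left_h),
                   prop_nh = mean(in_left_nh), p_value = p_left),
       right = list(bound = q_right, prop_h = mean(in_right_h),
                    prop_nh = mean(in_right_nh), p_value = p_right))
}

#' Equal-density threshold between two log-logistic fits
#'
#' Locates the crossing point of the two fitted densities — the boundary
#' between the normal and undesirable diagnostic ranges. The root of
#' `f_h(x) - f_nh(x)` is bracketed on a fine grid between the two medians
#' (or within `search_interval`) and polished by [stats::uniroot()]
#' bisection. With multiple crossings, the one nearest the healthy median
#' is returned with a `multiple_roots` warning flag.
#'
#' @param fit_h,fit_nh `loglogistic_fit` objects for the healthy and
#'   non-healthy cohort.
#' @param search_interval optional `c(lo, hi)` overriding the
#'   between-medians bracket.
#' @param n_grid grid size used for bracketing.
#' @return list with `threshold` and `multiple_roots`.
#' @export
equal_density_threshold <- function(fit_h, fit_nh, search_interval = NULL,
                                    n_grid = 4096) {
  if (isTRUE(all.equal(c(fit_h$alpha, fit_h$beta),
                       c(fit_nh$alpha, fit_nh$beta)))) {
    stop("identical density fits: equal-density threshold is degenerate",
         call. = FALSE)
  }
  if (is.null(search_interval)) {
    med <- sort(c(fit_h$alpha, fit_nh$alpha))
    if (med[1L] == med[2L]) {
      # same medians, different shapes: search a wide band around them
      med <- med[1L] * c(0.2, 5)
    }
    search_interval <- med
  }
  stopifnot(search_interval[1L] > 0,
            search_interval[2L] > search_interval[1L])
  dd <- function(x) dllogis2(x, fit_h$alpha, fit_h$beta) -
    dllogis2(x, fit_nh$alpha, fit_nh$beta)
  # bracket on a log-spaced grid (indices span orders of magnitude)
  grid <- exp(seq(log(search_interval[1L]), log(search_interval[2L]),
                  length.out = n_grid))
  v <- dd(grid)
  sgn <- sign(v)
  flips <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  roots <- numeric(0)
  for (k in flips) {
    r <- stats::uniroot(dd, lower = grid[k], upper = grid[k + 1L],
                        tol = 1e-12)
    roots <- c(roots, r$root)
  }
  exact <- grid[v == 0]
  roots <- sort(unique(c(roots, exact)))
  if (!length(roots)) {
    stop("densities do not cross inside the search interval [",
         signif(search_interval[1L], 4), ", ",
         signif(search_interval[2L], 4), "]", call. = FALSE)
  }
  list(threshold = roots[which.min(abs(roots - fit_h$alpha))],
       multiple_roots = length(roots) > 1L)
}

#' ROC-optimal (Youden) classification threshold for one index
#'
#' Enumerates every candidate cut point (the midpoints of consecutive
#' pooled sorted unique values, plus outer sentinels), tries both
#' orientations (non-healthy above or below the cut), and returns the cut
#' maximising Youden's `J = sensitivity + specificity - 1`. Ties are
#' broken toward the healthy median.
#'
#' @param samples_h,samples_nh cohort values of one index (healthy /
#'   non-healthy).
#' @return list with `threshold`, `J`, `direction` (`"above"` means
#'   non-healthy values lie above the threshold), `sensitivity`,
#'   `specificity`.
#' @export
roc_youden_threshold <- function(samples_h, samples_nh) {
  stopifnot(length(samples_h) > 0, length(samples_nh) > 0)
  pooled <- sort(unique(c(samples_h, samples_nh)))
  cuts <- if (length(pooled) > 1L) {
    (pooled[-1L] + pooled[-length(pooled)]) / 2
  } else {
    numeric(0)
  }
  cuts <- c(pooled[1L] - 1, cuts, pooled[length(pooled)] + 1)
  med_h <- stats::median(samples_h)
  best <- list(J = -Inf)
  for (dir in c("above", "below")) {
    for (cut in cuts) {
      if (dir == "above") {
        sens <- mean(samples_nh > cut)   # non-healthy correctly flagged
        spec <- mean(samples_h <= cut)
      } else {
        sens <- mean(samples_nh < cut)
        spec <- mean(samples_h >= cut)
      }
      J <- sens + spec - 1
      better <- J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && is.finite(best$J) &&
         abs(cut - med_h) < abs(best$threshold - med_h))
      if (better) {
        best <- list(threshold = cut, J = J, direction = dir,
                     sensitivity = sens, specificity = spec)
      }
    }
  }
  best
}

#' Build a diagnostic range table from two cohorts of index values
#'
#' For each index: fit log-logistic distributions to both cohorts, test
#' whether they differ (KS test; Benjamini-Hochberg q-values reported
#' alongside the raw p-values), determine the direction of the non-healthy
#' shift (tail-occupancy test, falling back to the sign of the median
#' shift when the tail test is inconclusive but the KS test is not), and
#' assemble the three diagnostic ranges: the normal range runs from the
#' equal-density threshold toward the healthy side, clipped to the healthy
#' central-`mass` interval; the undesirable range runs from that threshold
#' to the healthy-interval boundary on the non-healthy side; abnormal is
#' beyond that boundary. Indices whose cohort distributions do not differ
#' significantly are marked not discriminative and excluded from the range
#' table. The ROC/Youden threshold is reported per index as a diagnostic
#' (it should lie close to the equal-density threshold) but does not
#' define the ranges.
#'
#' @param cohort_h,cohort_nh data frames (or matrices) of per-subject index
#'   values, one column per index, same column names.
#' @param indices columns to process; default all shared columns.
#' @param mass central healthy mass defining the healthy interval
#'   (default 0.90).
#' @param alpha significance level for the discriminative filter.
#' @return list of class `range_construction` with `table` (a
#'   `range_table` over the discriminative indices) and `details` (per
#'   index: both fits, thresholds, tests, direction).
#' @export
build_range_table <- function(cohort_h, cohort_nh, indices = NULL,
                              mass = 0.90, alpha = 0.05) {
  cohort_h <- as.data.frame(cohort_h)
  cohort_nh <- as.data.frame(cohort_nh)
  if (is.null(indices)) {
    indices <- intersect(names(cohort_h), names(cohort_nh))
  }
  stopifnot(length(indices) > 0)
  if (nrow(cohort_h) < 30 || nrow(cohort_nh) < 30) {
    warning("fewer than 30 subjects per cohort: range estimates unstable")
  }
  details <- list()
  rows <- list()
  ks_p <- setNames(numeric(length(indices)), indices)
  for (idx in indices) {
    xh <- cohort_h[[idx]]
    xnh <- cohort_nh[[idx]]
    fit_h <- fit_loglogistic(xh)
    fit_nh <- fit_loglogistic(xnh)
    ks <- ks_compare(xh, xnh, alpha = alpha)
    ks_p[idx] <- ks$p_value
    tail <- tail_shift_test(xh, xnh, alpha = alpha)
    youden <- roc_youden_threshold(xh, xnh)
    healthy_int <- central_interval(fit_h, mass)
    dir <- tail$direction
    if (dir == "none" && ks$different) {
      dir <- if (fit_nh$alpha > fit_h$alpha) "right" else "left"
    }
    det <- list(index = idx, fit_h = fit_h, fit_nh = fit_nh, ks = ks,
                tail = tail, youden = youden, healthy_interval = healthy_int,
                direction = dir, discriminative = ks$different)
    if (ks$different && dir != "none") {
      thr <- tryCatch(equal_density_threshold(fit_h, fit_nh),
                      error = function(e) NULL)
      if (!is.null(thr)) {
        det$equal_density <- thr
        # clip the threshold to the healthy central interval: normal keeps
        # the healthy side, undesirable fills to the interval limit on the
        # non-healthy side, abnormal continues past that limit
        t0 <- min(max(thr$threshold, healthy_int[1L]), healthy_int[2L])
        rows[[idx]] <- if (dir == "left") {
          data.frame(index = idx, process = "", units = "",
                     healthy_lo = t0, healthy_hi = healthy_int[2L],
                     undesirable_lo = healthy_int[1L], undesirable_hi = t0,
                     abnormal_direction = "below",
                     abnormal_bound = healthy_int[1L],
                     stringsAsFactors = FALSE)
        } else {
          data.frame(index = idx, process = "", units = "",
                     healthy_lo = healthy_int[1L], healthy_hi = t0,
                     undesirable_lo = t0, undesirable_hi = healthy_int[2L],
                     abnormal_direction = "above",
                     abnormal_bound = healthy_int[2L],
                     stringsAsFactors = FALSE)
        }
      }
    }
    details[[idx]] <- det
  }
  qv <- stats::p.adjust(ks_p, method = "BH")
  for (idx in indices) details[[idx]]$ks$q_value <- unname(qv[idx])
  tab <- if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("range_table", "data.frame")
    out
  } else {
    NULL
  }
  structure(list(table = tab, details = details,
                 not_discriminative = setdiff(indices, names(rows))),
            class = "range_construction")
}
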