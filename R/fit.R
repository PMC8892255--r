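#' Default box constraints for per-patient parameter estimation
#'
#' Lower/upper bounds for the fitted parameters. Where the packaged
#' diagnostic table constrains a parameter, the bound spans the union of
#' its abnormal-to-healthy ranges widened by a factor 10 on each side on
#' the log scale; the remaining parameters get physiologically generous
#' boxes around the canonical values.
#'
#' @return a 2-row matrix (`lo`, `hi`) with one column per fittable
#'   parameter.
#' @export
default_fit_bounds <- function() {
  b <- cbind(
    k_js     = c(0.001, 2.44),
    tau      = c(4.5, 1110),
    k_gj     = c(1e-4, 0.84),
    k_lg     = c(3.71e-4, 16.2),
    k_xg     = c(1e-4, 0.3),
    k_xgi    = c(5.67e-10, 2.59e-2),
    k_lambda = c(1e-4, 0.6),
    gamma    = c(1e-4, 0.6),
    f_gi     = c(1.95e-7, 0.092),
    eta      = c(0.00145, 69.7),
    beta     = c(2.5e-3, 25),
    k_xi     = c(5e-4, 1.5))
  rownames(b) <- c("lo", "hi")
  b
}

#' Structural closure parameters held fixed during fitting
#'
#' The canonical values of `k_gj`, `k_xg`, `k_lambda` and `gamma`, the
#' default `fixed` argument of [fit_patient()].
#'
#' @return named numeric vector.
#' @export
default_fixed_parameters <- function() {
  canonical_parameters()[c("k_gj", "k_xg", "k_lambda", "gamma")]
}

# narrower box used to place multi-start points (log-uniform): the healthy
# diagnostic ranges (or canonical value) widened x4 on each side
.default_start_box <- function() {
  ctr <- canonical_parameters()
  box <- default_fit_bounds()
  starts <- cbind(
    k_js     = c(0.0198, 0.244),
    tau      = c(72, 111),
    k_gj     = ctr[["k_gj"]] * c(1, 1),
    k_lg     = c(0.00371, 0.602),
    k_xg     = ctr[["k_xg"]] * c(1, 1),
    k_xgi    = c(9.41e-6, 2.59e-3),
    k_lambda = ctr[["k_lambda"]] * c(1, 1),
    gamma    = ctr[["gamma"]] * c(1, 1),
    f_gi     = ctr[["f_gi"]] * c(1, 1),
    eta      = c(0.0145, 0.178),
    beta     = ctr[["beta"]] * c(1, 1),
    k_xi     = ctr[["k_xi"]] * c(1, 1))
  starts[1, ] <- starts[1, ] / 4
  starts[2, ] <- starts[2, ] * 4
  # clip to the hard bounds
  starts[1, ] <- pmax(starts[1, ], box["lo", colnames(starts)])
  starts[2, ] <- pmin(starts[2, ], box["hi", colnames(starts)])
  rownames(starts) <- c("lo", "hi")
  starts
}

# solve the model at the record's sample times only (no dense grid): the
# workhorse of the fitting loop
.solve_at <- function(params, times, rtol = 1e-6, atol = 1e-8) {
  p <- unclass(params)
  y0 <- c(S = p[["D"]], J = 0, L = 0, G = p[["G_b"]], I = p[["I_b"]])
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(y = y0, times = tt, func = gim_rhs, parms = params,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol))) return(NULL)
  df <- as.data.frame(sol)
  df[match(times, df$time), , drop = FALSE]
}

# basal-normalized (G, I) residual vector of a parameter vector against a
# record, optionally extended with log-scale ridge residuals toward the
# prior centre (resolves the interpolation degeneracy of 10 measurements
# toward the physiological branch); large finite penalty on integration
# failure keeps nls.lm moving
.fit_residuals <- function(theta, free, template, record, rtol, atol,
                           prior = NULL, prior_weight = 0) {
  p <- template
  p[free] <- exp(theta)
  sol <- .solve_at(p, record$times, rtol, atol)
  res <- if (is.null(sol)) {
    rep(1e4, 2L * length(record$times))
  } else {
    c((sol$G - record$glycemia) / record$glycemia[1L],
      (sol$I - record$insulinemia) / record$insulinemia[1L])
  }
  if (!is.null(prior) && prior_weight > 0) {
    res <- c(res, sqrt(prior_weight) * (theta - prior))
  }
  res
}

#' Fit the five-compartment model to one subject's OGTT record
#'
#' Multi-start bounded nonlinear least squares. The loss is the sum of
#' squared residuals of glycemia and insulinemia at the sample times, each
#' normalized by the subject's basal value so the mM and pM scales carry
#' equal weight. `G_b` and `I_b` are fixed at the measured basal values
#' (they are directly observed and anchor the model's equilibrium) and `D`
#' at the recorded dose; the remaining parameters are optimized on the log
#' scale within box bounds. `n_starts` Latin-hypercube points are drawn in
#' log space, ranked by initial loss, and the best `n_polish` are polished
#' with Levenberg-Marquardt ([minpack.lm::nls.lm()]); the best polished
#' run wins. The procedure is deterministic given `seed`.
#'
#' @param record an [ogtt_record()] with at least 5 samples.
#' @param n_starts number of Latin-hypercube starting points.
#' @param n_polish how many of the best starts to polish.
#' @param seed RNG seed for the start design.
#' @param bounds bounds matrix as from [default_fit_bounds()].
#' @param fixed named numeric vector of parameters held fixed on top of
#'   `G_b`, `I_b` and `D`. The default ([default_fixed_parameters()])
#'   holds the structural closures `k_gj`, `k_xg`, `k_lambda` and `gamma`
#'   at their canonical values: ten measurements cannot pin down twelve
#'   rates, and these four are the ones the data constrain least (the
#'   hepatic hinges act only near basal; `k_gj` and `k_xg` trade off
#'   almost perfectly against `k_lg` and `k_xgi`). Pass `NULL` to fit
#'   every parameter (requires records with more than 5 sample times).
#' @param maxiter Levenberg-Marquardt iteration cap per polish.
#' @param rtol,atol integrator tolerances during fitting.
#' @param warm_start optional `gim_parameters` used as an additional
#'   (first-ranked) start.
#' @param prior_weight weight of the log-scale ridge penalty pulling free
#'   parameters toward the centre of the start box. Ten measurements
#'   admit multiple near-exact interpolants; the weak penalty (default
#'   1e-3, about two orders of magnitude below the measurement-noise
#'   floor of the data loss) selects the physiologically central branch
#'   without materially biasing well-identified parameters. Set 0 to
#'   disable.
#' @param n_hops maximum number of perturbation restarts around the
#'   incumbent solution, triggered while the data loss exceeds
#'   `hop_loss_tol`; stops after 3 stagnant restarts.
#' @param hop_loss_tol data loss below which the fit is accepted without
#'   further restarts.
#' @return list of class `gim_fit` with `params` (best estimate as
#'   `gim_parameters`), `loss` (weighted sum of squared data residuals),
#'   `objective` (loss + ridge penalty, the quantity minimised), `free`
#'   (names of fitted parameters), `runs` (per polished run: start/final
#'   objective, data loss, convergence), `at_bounds` (parameters within
#'   0.1% of a bound on the log scale), `weakly_identified` (parameters
#'   whose value the record's measurements do not constrain: perturbing
#'   them by 0.3 log units barely changes the data loss), `seed`.
#' @export
fit_patient <- function(record, n_starts = 24, n_polish = 6, seed = 1L,
                        bounds = default_fit_bounds(),
                        fixed = default_fixed_parameters(),
                        maxiter = 300, rtol = 1e-6, atol = 1e-8,
                        warm_start = NULL, prior_weight = 1e-3,
                        n_hops = 6, hop_loss_tol = 1e-8) {
  stopifnot(inherits(record, "ogtt_record"))
  if (length(record$times) < 5L) {
    stop("fitting requires at least 5 OGTT samples", call. = FALSE)
  }
  template <- canonical_parameters()
  template[["G_b"]] <- record$glycemia[1L]
  template[["I_b"]] <- record$insulinemia[1L]
  template[["D"]] <- record$dose_mmol
  if (!is.null(fixed)) {
    stopifnot(!is.null(names(fixed)),
              all(names(fixed) %in% colnames(bounds)))
    template[names(fixed)] <- fixed
  }
  free <- setdiff(colnames(bounds), names(fixed))
  lo <- log(bounds["lo", free])
  hi <- log(bounds["hi", free])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sb <- .default_start_box()[, free, drop = FALSE]
  u <- lhs::randomLHS(n_starts, length(free))
  starts <- t(apply(u, 1L, function(ui) {
    log(sb["lo", ]) + ui * (log(sb["hi", ]) - log(sb["lo", ]))
  }))
  if (length(free) == 1L) starts <- matrix(starts, ncol = 1L)
  colnames(starts) <- free
  starts <- pmin(pmax(starts, rep(lo, each = n_starts)),
                 rep(hi, each = n_starts))
  if (!is.null(warm_start)) {
    ws <- pmin(pmax(log(unclass(warm_start)[free]), lo), hi)
    starts <- rbind(ws, starts)
  }
  prior <- (log(sb["lo", ]) + log(sb["hi", ])) / 2
  data_loss <- function(theta) {
    sum(.fit_residuals(theta, free, template, record, rtol, atol)^2)
  }
  objective <- function(theta) {
    data_loss(theta) + prior_weight * sum((theta - prior)^2)
  }
  loss0 <- apply(starts, 1L, objective)
  ord <- order(loss0)
  polish_idx <- ord[seq_len(min(n_polish, nrow(starts)))]

  lm_polish <- function(theta, iters) {
    tryCatch(suppressWarnings(
      minpack.lm::nls.lm(
        par = theta, lower = lo, upper = hi,
        fn = .fit_residuals, free = free, template = template,
        record = record, rtol = rtol, atol = atol,
        prior = prior, prior_weight = prior_weight,
        control = minpack.lm::nls.lm.control(maxiter = iters,
                                             ptol = 1e-12, ftol = 1e-14))),
      error = function(e) NULL)
  }
  as_run <- function(lm, start_obj, theta0) {
    if (is.null(lm)) {
      return(list(start_obj = start_obj, objective = Inf, loss = Inf,
                  converged = FALSE, theta = theta0))
    }
    th <- stats::setNames(lm$par, free)
    list(start_obj = start_obj, objective = sum(lm$fvec^2),
         loss = data_loss(th), converged = lm$info %in% 1:4, theta = th)
  }
  # stage 1: short Levenberg-Marquardt polish of the best starts
  runs <- list()
  for (k in polish_idx) {
    runs[[length(runs) + 1L]] <-
      as_run(lm_polish(starts[k, ], min(25, maxiter)), loss0[k],
             starts[k, ])
  }
  # stage 2: run the two most promising to full depth
  objs <- function() vapply(runs, `[[`, numeric(1L), "objective")
  for (k in order(objs())[seq_len(min(2L, length(runs)))]) {
    if (!is.finite(runs[[k]]$objective) || runs[[k]]$converged) next
    cand <- as_run(lm_polish(runs[[k]]$theta, maxiter),
                   runs[[k]]$start_obj, runs[[k]]$theta)
    if (cand$objective <= runs[[k]]$objective) runs[[k]] <- cand
  }
  # stage 3: perturbation restarts around the incumbent while the data
  # loss stays above tolerance (escapes degenerate interpolation modes)
  stagnation <- 0L
  for (h in seq_len(n_hops)) {
    ib <- which.min(objs())
    if (!is.finite(runs[[ib]]$objective) ||
        runs[[ib]]$loss < hop_loss_tol || stagnation >= 3L) break
    th0 <- pmin(pmax(runs[[ib]]$theta +
                       stats::rnorm(length(free), 0, 0.8), lo), hi)
    cand <- as_run(lm_polish(th0, min(120, maxiter)), objective(th0), th0)
    if (is.finite(cand$objective) &&
        cand$objective < runs[[ib]]$objective * 0.99) {
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
    }
    runs[[length(runs) + 1L]] <- cand
  }
  if (all(!is.finite(objs()))) {
    stop("no fitting run converged for subject '", record$subject_id, "'",
         call. = FALSE)
  }
  best <- runs[[which.min(objs())]]
  est <- template
  est[free] <- exp(best$theta)
  at_bounds <- free[best$theta <= lo + 1e-3 | best$theta >= hi - 1e-3]
  # parameters whose +/-0.3 log-unit perturbation barely moves the data
  # loss are not constrained by this record (their value reflects the
  # prior, not the measurements)
  weakly_identified <- character(0)
  for (j in seq_along(free)) {
    dl <- 0
    for (dd in c(-0.3, 0.3)) {
      th <- best$theta
      th[j] <- min(max(th[j] + dd, lo[j]), hi[j])
      dl <- max(dl, abs(data_loss(th) - best$loss))
    }
    # 1e-3 in squared basal-normalized residuals corresponds to about a
    # 1% average change of the predicted curve at the sample points —
    # below that, the record does not distinguish the parameter's value
    if (dl < 1e-3) {
      weakly_identified <- c(weakly_identified, free[j])
    }
  }
  run_params <- do.call(rbind, lapply(runs, function(r) exp(r$theta)))
  colnames(run_params) <- free
  structure(list(params = structure(est, class = "gim_parameters"),
                 loss = best$loss, objective = best$objective,
                 free = free,
                 runs = data.frame(
                   start_obj = vapply(runs, `[[`, numeric(1L),
                                      "start_obj"),
                   objective = objs(),
                   loss = vapply(runs, `[[`, numeric(1L), "loss"),
                   converged = vapply(runs, `[[`, logical(1L),
                                      "converged")),
                 run_params = run_params,
                 at_bounds = at_bounds,
                 weakly_identified = weakly_identified, seed = seed,
                 subject_id = record$subject_id),
            class = "gim_fit")
}

#' @export
print.gim_fit <- function(x, ...) {
  cat(sprintf("<gim_fit> subject %s: loss %.3g over %d polished runs\n",
              x$subject_id, x$loss, nrow(x$runs)))
  if (length(x$at_bounds)) {
    cat("  parameters at bounds:", paste(x$at_bounds, collapse = ", "),
        "\n")
  }
  if (length(x$weakly_identified)) {
    cat("  weakly identified:",
        paste(x$weakly_identified, collapse = ", "), "\n")
  }
  print(x$params)
  invisible(x)
}

#' Repeat-fit dispersion check for parameter uniqueness
#'
#' Re-runs the full multi-start fit `n_runs` times with different start
#' designs (seeds `seed, seed+1, ...`) and reports the per-parameter
#' coefficient of variation of the best estimates across runs. Parameters
#' whose CV exceeds `cv_threshold` are flagged non-unique: their value is
#' not pinned down by the subject's 10 measurements.
#'
#' @param record an [ogtt_record()].
#' @param n_runs number of repeated fits (>= 5).
#' @param cv_threshold CV above which a parameter is flagged non-unique.
#' @param seed base seed.
#' @param ... passed to [fit_patient()].
#' @return list with `estimates` (runs x parameters matrix), `cv` (named),
#'   `non_unique` (names), `fits`.
#' @export
repeat_fit_consistency <- function(record, n_runs = 5, cv_threshold = 0.1,
                                   seed = 1L, ...) {
  stopifnot(n_runs >= 5)
  fits <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    fits[[i]] <- tryCatch(fit_patient(record, seed = seed + i - 1L, ...),
                          error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) stop("all repeated fits failed", call. = FALSE)
  fits <- fits[ok]
  free <- fits[[1L]]$free
  est <- do.call(rbind, lapply(fits, function(f) unclass(f$params)[free]))
  cv <- apply(est, 2L, function(v) stats::sd(v) / mean(v))
  list(estimates = est, cv = cv,
       non_unique = names(cv)[cv > cv_threshold], fits = fits)
}

#' Sensitivity of fitted parameters to measurement error
#'
#' Perturbs each of the subject's measurements (all glycemia and
#' insulinemia samples) up and down by `perturbation` (default 10%),
#' refits the model warm-started from the unperturbed optimum, and records
#' the relative deviation of every fitted parameter. Under the default
#' 5-point protocol this is 10 measures x 2 directions = 20 refits. A
#' parameter is labelled measurement-sensitive when its maximum relative
#' deviation exceeds `threshold` (default 20%). A zero-magnitude
#' perturbation leaves the record unchanged and yields zero deviations.
#'
#' @param record the fitted [ogtt_record()].
#' @param fit the subject's `gim_fit`.
#' @param perturbation relative perturbation magnitude (default 0.10).
#' @param threshold relative-deviation threshold for the sensitive label.
#' @param maxiter iteration cap of each warm-started refit.
#' @param ... passed to the refits ([fit_patient()]).
#' @return list of class `measurement_sensitivity` with `deviations`
#'   (refits x parameters matrix of relative deviations, rows named
#'   `<channel><time>_<up|down>`), `max_deviation` (per parameter),
#'   `sensitive` (names), `n_refits`, `failed` (rows that failed to
#'   refit).
#' @export
measurement_sensitivity <- function(record, fit, perturbation = 0.10,
                                    threshold = 0.20, maxiter = 30, ...) {
  stopifnot(inherits(fit, "gim_fit"))
  free <- fit$free
  base <- unclass(fit$params)[free]
  n_t <- length(record$times)
  labels <- c(paste0("G", record$times), paste0("I", record$times))
  dev <- matrix(NA_real_, nrow = 2L * n_t * 2L, ncol = length(free),
                dimnames = list(NULL, free))
  rn <- character(nrow(dev))
  failed <- character(0)
  row <- 0L
  for (m in seq_len(2L * n_t)) {
    for (dir in c(1, -1)) {
      row <- row + 1L
      rn[row] <- paste0(labels[m], if (dir > 0) "_up" else "_down")
      pr <- record
      fac <- 1 + dir * perturbation
      if (m <= n_t) {
        pr$glycemia[m] <- pr$glycemia[m] * fac
      } else {
        pr$insulinemia[m - n_t] <- pr$insulinemia[m - n_t] * fac
      }
      if (identical(pr$glycemia, record$glycemia) &&
          identical(pr$insulinemia, record$insulinemia)) {
        dev[row, ] <- 0  # identity perturbation: nothing to refit
        next
      }
      refit <- tryCatch(
        fit_patient(pr, n_starts = 1, n_polish = 1, seed = fit$seed,
                    warm_start = fit$params, maxiter = maxiter,
                    n_hops = 0, ...),
        error = function(e) NULL)
      if (is.null(refit)) {
        failed <- c(failed, rn[row])
        next
      }
      dev[row, ] <- abs(unclass(refit$params)[free] - base) / base
    }
  }
  rownames(dev) <- rn
  max_dev <- apply(dev, 2L, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  structure(list(deviations = dev, max_deviation = max_dev,
                 sensitive = names(max_dev)[!is.na(max_dev) &
                                              max_dev > threshold],
                 n_refits = nrow(dev), failed = failed,
                 perturbation = perturbation, threshold = threshold),
            class = "measurement_sensitivity")
}

#' Curve-shape sensitivity of the model to each parameter
#'
#' Quantifies how much a +/-`perturbation` change of each parameter (one
#' at a time) changes the simulated basal-normalized (G, I) curves, as the
#' L2 norm of the curve change divided by the L2 norm of the unperturbed
#' curves, averaged over the two directions. Parameters with an index
#' above `threshold` (default 5% of the curve norm) are labelled
#' sensitive: they shape the subject's OGTT response.
#'
#' @param params a [model_parameters()] vector.
#' @param perturbation relative parameter perturbation (default 0.10).
#' @param threshold sensitivity label threshold (default 0.05).
#' @param which parameters to assess (default all except the dose `D`).
#' @param grid_dt time step of the comparison grid (min).
#' @return list of class `curve_sensitivity` with `index` (named numeric,
#'   `NA` when a perturbed integration fails), `sensitive` (names),
#'   `threshold`.
#' @export
curve_shape_sensitivity <- function(params, perturbation = 0.10,
                                    threshold = 0.05,
                                    which = setdiff(PARAM_NAMES, "D"),
                                    grid_dt = 2) {
  validate_parameters(params)
  p0 <- unclass(params)
  sim0 <- simulate_ogtt(params, dense_dt = grid_dt,
                        rtol = 1e-7, atol = 1e-9)
  base <- cbind(sim0$dense$G / p0[["G_b"]], sim0$dense$I / p0[["I_b"]])
  norm0 <- sqrt(sum(base^2))
  idx <- stats::setNames(rep(NA_real_, length(which)), which)
  for (nm in which) {
    if (perturbation == 0) { idx[nm] <- 0; next }
    deltas <- numeric(0)
    ok <- TRUE
    for (dir in c(1, -1)) {
      pp <- p0
      pp[nm] <- pp[nm] * (1 + dir * perturbation)
      sim <- tryCatch(
        simulate_ogtt(structure(pp, class = "gim_parameters"),
                      dense_dt = grid_dt, rtol = 1e-7, atol = 1e-9),
        error = function(e) NULL)
      if (is.null(sim)) { ok <- FALSE; break }
      # normalize by the *unperturbed* basal scales so G_b/I_b
      # perturbations register as curve changes
      pert <- cbind(sim$dense$G / p0[["G_b"]], sim$dense$I / p0[["I_b"]])
      deltas <- c(deltas, sqrt(sum((pert - base)^2)) / norm0)
    }
    if (ok) idx[nm] <- mean(deltas)
  }
  structure(list(index = idx,
                 sensitive = names(idx)[!is.na(idx) & idx > threshold],
                 threshold = threshold, perturbation = perturbation),
            class = "curve_sensitivity")
}
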