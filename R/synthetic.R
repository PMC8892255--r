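#' Specification of a synthetic OGTT cohort
#'
#' Describes how to draw a cohort of model parameter vectors and their
#' measured OGTT records. Per-parameter heterogeneity is log-logistic: for
#' parameters with a row in the packaged diagnostic table the `healthy`
#' template centres the distribution geometrically in the healthy range
#' and sets the shape so the central 90% of draws spans that range; the
#' `non-healthy` template additionally applies the characteristic
#' non-healthy shifts (slower stomach emptying and jejunal transit,
#' reduced insulin-dependent consumption, larger distribution factor, and
#' raised basal glycemia/insulinemia centred at the non-healthy cohort
#' medians 91.0 mg/dL and 8.30 uU/mL, versus 86.4 mg/dL and 4.32 uU/mL for
#' healthy), plus a shared log-normal latent factor that couples the
#' shifted subsystems and strengthens their correlations. The
#' responsiveness parameters `f_gi`, `beta` and `k_xi` receive mild
#' heterogeneity around the canonical values, while the structural
#' closures `k_gj`, `k_xg`, `k_lambda` and `gamma` are shared constants
#' (the fitter holds them fixed for the same reason, see
#' [default_fixed_parameters()]). Measurement noise is multiplicative
#' log-normal with default CVs of 3% (glycemia) and 7% (insulinemia).
#'
#' @param n number of subjects (>= 1).
#' @param template `"healthy"` or `"non-healthy"`.
#' @param cv_g,cv_i measurement noise CVs.
#' @param dose_g glucose dose (grams).
#' @param sample_times OGTT sampling times (min), must include 0.
#' @param latent_sd log-scale SD of the shared latent factor (non-healthy
#'   template only by default).
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, template = c("healthy", "non-healthy"),
                        cv_g = 0.03, cv_i = 0.07, dose_g = 75,
                        sample_times = c(0, 30, 60, 90, 120),
                        latent_sd = NULL, seed = 1L) {
  template <- match.arg(template)
  if (n < 1) stop("cohort size n must be >= 1", call. = FALSE)
  stopifnot(cv_g >= 0, cv_i >= 0, 0 %in% sample_times)
  if (is.null(latent_sd)) {
    # sized so the coupled subsystems correlate above the |r| > 0.4
    # graph cutoff in the non-healthy state, as the emulated cohorts do
    latent_sd <- if (template == "non-healthy") 0.4 else 0
  }
  structure(list(n = as.integer(n), template = template, cv_g = cv_g,
                 cv_i = cv_i, dose_g = dose_g,
                 sample_times = sort(sample_times),
                 latent_sd = latent_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# per-parameter log-logistic sampling laws: alpha = median, beta = shape
# chosen so the central 90% interval equals the given range
.llogis_from_range <- function(lo, hi) {
  alpha <- sqrt(lo * hi)
  beta <- log(19) / log(hi / alpha)  # Q(0.95)/alpha = 19^(1/beta)
  c(alpha = alpha, beta = beta)
}

.template_laws <- function(template) {
  ctr <- canonical_parameters()
  laws <- list(
    k_js  = .llogis_from_range(0.0198, 0.244),
    tau   = .llogis_from_range(72, 111),
    k_lg  = .llogis_from_range(0.00371, 0.602),
    k_xgi = .llogis_from_range(9.41e-6, 0.00259),
    eta   = .llogis_from_range(0.0145, 0.178),
    G_b   = .llogis_from_range(4.10, 5.03),
    I_b   = .llogis_from_range(13.1, 47.9),
    # responsiveness parameters: mild spread (shape 8 ~= +/-44%
    # central 90%); the structural closures k_gj, k_xg, k_lambda and
    # gamma stay at their canonical values (they are not identifiable
    # from a 5-point record and the fitter holds them fixed too)
    f_gi     = c(alpha = ctr[["f_gi"]], beta = 8),
    beta     = c(alpha = ctr[["beta"]], beta = 8),
    k_xi     = c(alpha = ctr[["k_xi"]], beta = 12))
  # healthy basal medians: 86.4 mg/dL, 4.32 uU/mL
  laws$G_b[["alpha"]] <- 4.8
  laws$I_b[["alpha"]] <- 30.0
  if (template == "non-healthy") {
    shift <- c(k_js = 0.35, tau = 0.65, k_xgi = 0.13, eta = 1.5)
    for (nm in names(shift)) {
      laws[[nm]][["alpha"]] <- laws[[nm]][["alpha"]] * shift[[nm]]
    }
    laws$G_b[["alpha"]] <- 91.0 / 18       # 5.056 mM
    laws$I_b[["alpha"]] <- 8.30 * 6.945    # 57.6 pM
    laws$G_b[["beta"]] <- 40               # basal glycemia is tight
    laws$I_b[["beta"]] <- 5
  }
  laws
}

#' Draw per-subject model parameters for a cohort
#'
#' Seeded, reproducible parameter draws following the cohort template
#' laws; draws are positive by construction
#' (log-logistic support). Under the non-healthy template a shared latent
#' factor multiplies the motility/uptake subsystem parameters
#' (`k_js`, `tau`, `k_xgi`, `f_gi`, `beta`) to induce the stronger
#' between-subsystem correlations seen in dysglycemia.
#'
#' @param spec a [cohort_spec()].
#' @return list of `gim_parameters`, length `spec$n`, named `s1..sn`.
#' @export
sample_parameters <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  laws <- .template_laws(spec$template)
  out <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    p <- canonical_parameters()
    for (nm in names(laws)) {
      p[[nm]] <- rllogis2(1L, laws[[nm]][["alpha"]], laws[[nm]][["beta"]])
    }
    if (spec$latent_sd > 0) {
      z <- stats::rnorm(1L, 0, spec$latent_sd)
      for (nm in c("k_js", "tau", "k_xgi", "f_gi", "beta")) {
        p[[nm]] <- p[[nm]] * exp(z)
      }
    }
    p[["D"]] <- dose_g_to_mmol(spec$dose_g)
    out[[i]] <- structure(p, class = "gim_parameters")
  }
  names(out) <- paste0("s", seq_len(spec$n))
  out
}

#' Generate a synthetic OGTT cohort with ground truth
#'
#' Draws per-subject parameters ([sample_parameters()]), simulates each
#' subject's OGTT with the compartmental model, samples at the protocol
#' times, and applies multiplicative measurement noise. Subjects whose
#' simulation fails are redrawn (at most 10 retries each). The generating
#' parameters are retained so recovery can be verified.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with `records` (list of
#'   [ogtt_record()]), `truth` (list of `gim_parameters`), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- sample_parameters(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 104729L)  # independent noise stream
  records <- vector("list", spec$n)
  horizon <- max(spec$sample_times)
  for (i in seq_len(spec$n)) {
    retries <- 0L
    repeat {
      sim <- tryCatch(
        simulate_ogtt(truth[[i]], horizon_min = horizon,
                      sample_times = spec$sample_times, dense_dt = horizon),
        error = function(e) NULL)
      if (!is.null(sim)) break
      retries <- retries + 1L
      if (retries > 10L) {
        stop("subject ", i, ": simulation failed after 10 redraws",
             call. = FALSE)
      }
      respec <- spec
      respec$seed <- spec$seed + 1000L * retries + i
      truth[[i]] <- sample_parameters(
        cohort_spec(1, spec$template, spec$cv_g, spec$cv_i, spec$dose_g,
                    spec$sample_times, spec$latent_sd,
                    seed = respec$seed))[[1L]]
    }
    records[[i]] <- simulation_to_record(sim, subject_id = names(truth)[i],
                                         cv_g = spec$cv_g,
                                         cv_i = spec$cv_i)
  }
  names(records) <- names(truth)
  structure(list(records = records, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' Table of per-subject indices (parameters + Pi numbers) for a cohort
#'
#' Convenience: stacks parameter vectors (and their dimensionless indices)
#' into a subjects x indices data frame, the input shape of the
#' cohort-statistics and coordination modules.
#'
#' @param params list of `gim_parameters`.
#' @param ndn whether to append the Pi numbers.
#' @return data frame, one row per subject.
#' @export
parameter_table <- function(params, ndn = TRUE) {
  rows <- lapply(params, function(p) {
    v <- unclass(p)[setdiff(PARAM_NAMES, "D")]
    if (ndn) v <- c(v, unclass(compute_ndns(p)))
    as.data.frame(as.list(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(params)
  out
}

#' Default dose-effect template for the crossover emulation
#'
#' Multiplicative parameter shifts per pre-prandial dose arm (mg labels),
#' emulating a dose-dependent slowing of intestinal transit (`tau` up)
#' and improvement of insulin sensitivity (`k_xgi` up): +30% `tau` at the
#' top dose.
#'
#' @return named list suitable for [generate_intervention_study()].
#' @export
default_dose_effects <- function() {
  list("60"  = c(tau = 1.10),
       "120" = c(tau = 1.20, k_xgi = 1.15),
       "180" = c(tau = 1.30, k_xgi = 1.30))
}

#' Generate a synthetic paired crossover intervention study
#'
#' Each subject (drawn once from `spec`, the shared subject-level
#' baseline) is measured under a control arm and one arm per dose.
#' `dose_effects` maps dose -> named multiplicative shifts of chosen
#' parameters (e.g. `list("180" = c(tau = 1.3))` for a +30% jejunal
#' transit time at the 180 mg dose). Within-subject between-visit
#' variability multiplies every shifted arm's physiological parameters by
#' an independent log-normal factor (`visit_cv`), mirroring week-to-week
#' biological variation in a crossover design.
#'
#' @param spec a [cohort_spec()] for the subjects' baseline.
#' @param dose_effects named list: names are dose labels (e.g. `"60"`,
#'   `"120"`, `"180"`), values named multiplicative parameter shifts.
#' @param visit_cv within-subject between-visit CV on parameters
#'   (default 0.10).
#' @return list of class `intervention_study` with `doses` (character,
#'   control `"0"` first), `subjects` (per subject: per-arm `params`,
#'   `record`, `ndns`, `risk`), and `spec`.
#' @export
generate_intervention_study <- function(spec, dose_effects,
                                        visit_cv = 0.10) {
  stopifnot(inherits(spec, "cohort_spec"), is.list(dose_effects))
  shiftable <- setdiff(PARAM_NAMES, c("D", "G_b", "I_b"))
  for (d in names(dose_effects)) {
    bad <- setdiff(names(dose_effects[[d]]), shiftable)
    if (length(bad)) {
      stop("dose_effects[", d, "]: unknown parameter(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  baseline <- sample_parameters(spec)
  doses <- c("0", names(dose_effects))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 7919L)
  horizon <- max(spec$sample_times)
  subjects <- lapply(seq_len(spec$n), function(i) {
    arms <- lapply(doses, function(d) {
      p <- unclass(baseline[[i]])
      if (d != "0") {
        eff <- dose_effects[[d]]
        if (length(eff)) p[names(eff)] <- p[names(eff)] * eff
        if (visit_cv > 0) {
          jit <- exp(stats::rnorm(length(shiftable), 0,
                                  sqrt(log(1 + visit_cv^2))))
          p[shiftable] <- p[shiftable] * jit
        }
      }
      p <- structure(p, class = "gim_parameters")
      sim <- simulate_ogtt(p, horizon_min = horizon,
                           sample_times = spec$sample_times,
                           dense_dt = horizon)
      rec <- simulation_to_record(sim,
                                  subject_id = paste0("s", i, "_d", d),
                                  cv_g = spec$cv_g, cv_i = spec$cv_i)
      nd <- compute_ndns(p)
      list(dose = d, params = p, record = rec, ndns = nd,
           risk = published_risk(p, nd))
    })
    names(arms) <- doses
    arms
  })
  names(subjects) <- paste0("s", seq_len(spec$n))
  structure(list(doses = doses, subjects = subjects, spec = spec),
            class = "intervention_study")
}
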