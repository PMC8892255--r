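#' Right-hand side of the five-compartment glucose-insulin model
#'
#' State: glucose in the stomach `S`, jejunum `J` and ileum `L` (mmol),
#' blood glucose `G` (mM) and blood insulin `I` (pM). The bolus `D` starts
#' in the stomach and empties into the jejunum at rate `k_js`; jejunal
#' glucose is absorbed at `k_gj` or transits to the ileum with transit time
#' `tau` (rate `1/tau`); ileal glucose is absorbed at `k_lg`. Absorbed
#' glucose enters the blood scaled by the distribution factor `eta`.
#' Glycemia is consumed insulin-independently (`k_xg`) and
#' insulin-dependently (`k_xgi * G * I`), and the liver releases
#' (`k_lambda`) or takes up (`gamma`) glucose in proportion to the deficit
#' or excess relative to basal. Insulin is secreted in proportion to the
#' glycemic excess, potentiated by the incretin signal `1 + f_gi*(J+L)`
#' from gut glucose, and cleared at `k_xi` toward its basal level. Constant
#' basal endogenous production `P0 = k_xg*G_b + k_xgi*G_b*I_b` makes
#' `(0, 0, 0, G_b, I_b)` an exact equilibrium.
#'
#' @param t time (min); unused (autonomous system), present for the
#'   `deSolve` calling convention.
#' @param state named numeric vector `c(S=, J=, L=, G=, I=)`.
#' @param params a [model_parameters()] vector (class `gim_parameters` or a
#'   named numeric vector covering [PARAM_NAMES]).
#' @return list with the derivative vector, as expected by
#'   [deSolve::ode()].
#' @export
gim_rhs <- function(t, state, params) {
  if (any(!is.finite(state))) {
    stop("non-finite model state at t = ", t, call. = FALSE)
  }
  p <- unclass(params)
  S <- state[[1L]]; J <- state[[2L]]; L <- state[[3L]]
  G <- state[[4L]]; I <- state[[5L]]
  P0 <- p[["k_xg"]] * p[["G_b"]] + p[["k_xgi"]] * p[["G_b"]] * p[["I_b"]]
  excess  <- max(G - p[["G_b"]], 0)
  deficit <- max(p[["G_b"]] - G, 0)
  dS <- -p[["k_js"]] * S
  dJ <- p[["k_js"]] * S - J / p[["tau"]] - p[["k_gj"]] * J
  dL <- J / p[["tau"]] - p[["k_lg"]] * L
  dG <- p[["eta"]] * (p[["k_gj"]] * J + p[["k_lg"]] * L) + P0 -
    p[["k_xg"]] * G - p[["k_xgi"]] * G * I +
    p[["k_lambda"]] * deficit - p[["gamma"]] * excess
  dI <- p[["beta"]] * excess * (1 + p[["f_gi"]] * (J + L)) -
    p[["k_xi"]] * (I - p[["I_b"]])
  list(c(dS, dJ, dL, dG, dI))
}

#' Simulate an OGTT with the five-compartment model
#'
#' Integrates the model from the post-ingestion initial state
#' `(S, J, L, G, I) = (D, 0, 0, G_b, I_b)` with a stiff-capable adaptive
#' integrator (`deSolve::lsoda`). The hinge terms (`max(., 0)`) in the
#' hepatic and secretion fluxes are continuous but not smooth, so tight
#' default tolerances are used.
#'
#' @param params a [model_parameters()] vector.
#' @param horizon_min integration horizon (min); must cover
#'   `sample_times`.
#' @param sample_times times (min) at which sampled values are reported;
#'   default the 5-point clinical protocol `c(0, 30, 60, 90, 120)`.
#' @param dense_dt spacing of the dense output grid (min).
#' @param rtol,atol integrator tolerances.
#' @return an object of class `gim_simulation`: list with `dense` (data
#'   frame `time, S, J, L, G, I` on the dense grid), `sampled` (same
#'   columns at `sample_times`), and `params`.
#' @examples
#' sim <- simulate_ogtt(model_parameters())
#' sim$sampled
#' @export
simulate_ogtt <- function(params, horizon_min = 120,
                          sample_times = c(0, 30, 60, 90, 120),
                          dense_dt = 1, rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  stopifnot(horizon_min >= max(sample_times))
  p <- unclass(params)
  y0 <- c(S = p[["D"]], J = 0, L = 0, G = p[["G_b"]], I = p[["I_b"]])
  times <- sort(unique(c(seq(0, horizon_min, by = dense_dt),
                         horizon_min, sample_times)))
  sol <- deSolve::lsoda(y = y0, times = times, func = gim_rhs,
                        parms = params, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    stop("OGTT integration failed (istate = ", attr(sol, "istate")[1L],
         "); parameters: ",
         paste(sprintf("%s=%.4g", PARAM_NAMES, p[PARAM_NAMES]),
               collapse = ", "), call. = FALSE)
  }
  dense <- as.data.frame(sol)
  sampled <- dense[match(sample_times, dense$time), , drop = FALSE]
  rownames(sampled) <- NULL
  structure(list(dense = dense, sampled = sampled, params = params),
            class = "gim_simulation")
}

#' Sampled (G, I) values of a simulation at the protocol times
#' @param sim a `gim_simulation`.
#' @return data frame with `time`, `G` (mM), `I` (pM).
#' @export
sampled_curves <- function(sim) {
  sim$sampled[, c("time", "G", "I")]
}

#' Turn a simulation into a measurable OGTT record
#'
#' Optionally applies multiplicative log-normal measurement noise with the
#' given coefficients of variation (assay noise is relative, hence
#' multiplicative).
#'
#' @param sim a `gim_simulation`.
#' @param subject_id subject identifier for the record.
#' @param cv_g,cv_i coefficients of variation of glycemia / insulinemia
#'   measurement noise (0 = noiseless).
#' @return an [ogtt_record()] in internal units.
#' @export
simulation_to_record <- function(sim, subject_id = "sim", cv_g = 0,
                                 cv_i = 0) {
  s <- sim$sampled
  g <- s$G
  i <- s$I
  if (cv_g > 0) {
    sd_g <- sqrt(log(1 + cv_g^2))
    g <- g * exp(stats::rnorm(length(g), -sd_g^2 / 2, sd_g))
  }
  if (cv_i > 0) {
    sd_i <- sqrt(log(1 + cv_i^2))
    i <- i * exp(stats::rnorm(length(i), -sd_i^2 / 2, sd_i))
  }
  ogtt_record(subject_id, s$time, g, i,
              dose_g = unclass(sim$params)[["D"]] * 0.18)
}

#' @export
print.gim_simulation <- function(x, ...) {
  cat("<gim_simulation> horizon", max(x$dense$time), "min\n")
  print(x$sampled, row.names = FALSE)
  invisible(x)
}
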