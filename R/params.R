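#' Physiological parameter vector of the five-compartment G-I model
#'
#' Builds and validates the per-subject parameter set of the glucose-insulin
#' model. All rates are per minute on the internal unit system (glucose in
#' mM / mmol, insulin in pM, time in min):
#'
#' * `k_js` stomach-emptying rate (min^-1)
#' * `tau` jejunal transit time (min); glucose moves jejunum -> ileum at
#'   rate `1/tau`
#' * `k_gj` jejunal absorption rate (min^-1)
#' * `k_lg` ileal absorption rate (min^-1)
#' * `k_xg` insulin-independent glucose consumption rate (min^-1)
#' * `k_xgi` insulin-dependent glucose consumption rate (min^-1 pM^-1)
#' * `k_lambda` hepatic glucose-release responsiveness (min^-1)
#' * `gamma` hepatic glucose-uptake responsiveness (min^-1)
#' * `f_gi` incretin potentiation coefficient (per mmol of gut glucose)
#' * `eta` gut-to-blood distribution factor (mM per mmol; inverse
#'   distribution-volume role)
#' * `beta` pancreatic responsiveness (pM min^-1 mM^-1)
#' * `k_xi` insulin turnover rate (min^-1)
#' * `G_b` basal glycemia (mM)
#' * `I_b` basal insulinemia (pM)
#' * `D` glucose dose (mmol); 75 g corresponds to 416.67 mmol
#'
#' @param ... named parameter values overriding the canonical healthy
#'   defaults of [canonical_parameters()].
#' @param .values optionally a full named numeric vector/list instead of
#'   `...`.
#' @return a named numeric vector of class `gim_parameters`.
#' @examples
#' p <- model_parameters(k_js = 0.08, G_b = 4.8)
#' p["k_js"]
#' @export
model_parameters <- function(..., .values = NULL) {
  base <- canonical_parameters()
  over <- if (is.null(.values)) list(...) else as.list(.values)
  if (length(over)) {
    bad <- setdiff(names(over), PARAM_NAMES)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    base[names(over)] <- unlist(over)
  }
  validate_parameters(base)
  structure(base, class = "gim_parameters")
}

#' @rdname model_parameters
#' @export
PARAM_NAMES <- c("k_js", "tau", "k_gj", "k_lg", "k_xg", "k_xgi",
                 "k_lambda", "gamma", "f_gi", "eta", "beta", "k_xi",
                 "G_b", "I_b", "D")

#' Canonical healthy-subject parameter values
#'
#' A reference parameter set representing a typical healthy adult: rates
#' centred (geometrically) in the healthy diagnostic ranges of the packaged
#' reference table where the table lists them, basal glycemia 4.8 mM
#' (86.4 mg/dL) and basal insulinemia 30 pM (4.32 uU/mL) at the healthy
#' cohort medians, and a 75 g (416.67 mmol) glucose dose. Parameters the
#' reference table does not constrain (`k_gj`, `k_xg`, `k_lambda`, `gamma`,
#' `beta`, `k_xi`, `f_gi`) are set to physiologically plausible values that
#' yield a normal OGTT excursion (glycemia peaking near 8 mM around
#' 60-90 min and returning toward basal by 120 min).
#'
#' @return named numeric vector over [PARAM_NAMES].
#' @export
canonical_parameters <- function() {
  c(k_js     = 0.0695,     # geometric centre of healthy 0.0198-0.244
    tau      = 89.4,       # geometric centre of healthy 72-111 min
    k_gj     = 0.020,      # jejunal absorption (structural closure)
    k_lg     = 0.0473,     # geometric centre of healthy 0.00371-0.602
    k_xg     = 0.010,      # insulin-independent consumption
    k_xgi    = 1.561e-4,   # geometric centre of healthy 9.41e-6-2.59e-3
    k_lambda = 0.030,      # hepatic release
    gamma    = 0.030,      # hepatic uptake
    f_gi     = 4.0e-3,     # incretin potentiation (Pi_N ~ 1.7 at 75 g)
    eta      = 0.0508,     # geometric centre of healthy 0.0145-0.178
    beta     = 1.2,        # pancreatic responsiveness
    k_xi     = 0.03,       # insulin turnover
    G_b      = 4.8,        # 86.4 mg/dL
    I_b      = 30.0,       # 4.32 uU/mL
    D        = 416.6667)   # 75 g
}

validate_parameters <- function(p) {
  p <- unclass(p)
  if (!all(PARAM_NAMES %in% names(p))) {
    stop("parameter vector missing: ",
         paste(setdiff(PARAM_NAMES, names(p)), collapse = ", "),
         call. = FALSE)
  }
  v <- p[PARAM_NAMES]
  if (any(!is.finite(v))) stop("non-finite parameter value", call. = FALSE)
  pos <- setdiff(PARAM_NAMES, "D")
  if (any(v[pos] <= 0)) {
    stop("parameters must be strictly positive: ",
         paste(pos[v[pos] <= 0], collapse = ", "), call. = FALSE)
  }
  if (v[["D"]] < 0) stop("dose D must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.gim_parameters <- function(x, ...) {
  cat("<gim_parameters>\n")
  print(signif(unclass(x), 4))
  invisible(x)
}
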