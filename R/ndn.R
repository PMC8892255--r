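#' Dimensionless subsystem indices (Pi numbers)
#'
#' Maps a physiological parameter vector to the seven dimensionless Pi
#' numbers characterising the model's subsystems on a subject-independent
#' scale. The scale variables are basal glycemia `G_b`, basal insulinemia
#' `I_b`, the ingested dose `D`, and the glucose turnover time
#' `t_c = 1 / (k_xg + k_xgi * I_b)`. The default (`"reference"`) mapping is:
#'
#' * `Pi_S = k_js * tau` — digestive motility number
#' * `Pi_N = f_gi * D` — incretin activity load
#' * `Pi_D = eta * D / G_b` — glucose distribution number
#' * `Pi_B = (k_xgi * I_b) / k_xg` — basal insulin-dependent/independent
#'   uptake ratio
#' * `Pi_X = k_xgi * I_b * t_c` — insulin activity load
#' * `Pi_I = beta * G_b * t_c / I_b` — pancreatic response number
#' * `Pi_R = (k_lambda + gamma) * t_c` — hepatic response number
#'
#' Each index lands in the subsystem group the diagnostic reference table
#' assigns it, and all are invariant under any consistent rescaling of the
#' underlying units. The mapping registry is extensible: register an
#' alternative set of formulas under a new name with
#' `register_ndn_mapping()`.
#'
#' @param params a [model_parameters()] vector; `D` must be positive for
#'   the dose-scaled numbers `Pi_N` and `Pi_D`.
#' @param mapping registered mapping name; default `"reference"`.
#' @return named numeric vector of class `ndn_set` with attribute
#'   `mapping` recording which mapping produced it.
#' @examples
#' compute_ndns(model_parameters(k_js = 0.1, tau = 100))[["Pi_S"]]  # 10
#' @export
compute_ndns <- function(params, mapping = "reference") {
  validate_parameters(params)
  p <- unclass(params)
  if (p[["D"]] <= 0) {
    stop("dose-scaled Pi numbers are undefined at D = 0", call. = FALSE)
  }
  fn <- .ndn_registry[[mapping]]
  if (is.null(fn)) {
    stop("unknown NDN mapping '", mapping, "'; registered: ",
         paste(names(.ndn_registry), collapse = ", "), call. = FALSE)
  }
  out <- fn(p)
  stopifnot(identical(names(out), NDN_NAMES))
  structure(out, mapping = mapping, class = "ndn_set")
}

#' @rdname compute_ndns
#' @export
NDN_NAMES <- c("Pi_S", "Pi_N", "Pi_D", "Pi_B", "Pi_X", "Pi_I", "Pi_R")

.ndn_reference <- function(p) {
  t_c <- 1 / (p[["k_xg"]] + p[["k_xgi"]] * p[["I_b"]])
  c(Pi_S = p[["k_js"]] * p[["tau"]],
    Pi_N = p[["f_gi"]] * p[["D"]],
    Pi_D = p[["eta"]] * p[["D"]] / p[["G_b"]],
    Pi_B = p[["k_xgi"]] * p[["I_b"]] / p[["k_xg"]],
    Pi_X = p[["k_xgi"]] * p[["I_b"]] * t_c,
    Pi_I = p[["beta"]] * p[["G_b"]] * t_c / p[["I_b"]],
    Pi_R = (p[["k_lambda"]] + p[["gamma"]]) * t_c)
}

.ndn_registry <- new.env(parent = emptyenv())
assign("reference", .ndn_reference, envir = .ndn_registry)

#' @rdname compute_ndns
#' @param name registry name for the new mapping.
#' @param fn function taking the named parameter vector and returning a
#'   named numeric vector over [NDN_NAMES].
#' @export
register_ndn_mapping <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .ndn_registry)
  invisible(name)
}

#' @export
print.ndn_set <- function(x, ...) {
  cat("<ndn_set> mapping:", attr(x, "mapping"), "\n")
  print(signif(unclass(x), 4))
  invisible(x)
}
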