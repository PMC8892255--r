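#' Published dysglycemia-risk logistic model coefficients
#'
#' The fixed cohort-derived coefficients of the simple dysglycemia-risk
#' logistic model. The linear predictor is
#' `z = a1*eta + a2*Pi_X + a3*G_b + a4*I_b + a5*tau + a6*k_xgi + a0`
#' with the predictors on the reference-table unit scales (`G_b` mM, `I_b`
#' pM, `tau` min, `k_xgi` min^-1 pM^-1, `eta` as tabulated, `Pi_X`
#' dimensionless) — the coefficient magnitudes (e.g. `a6` of order -800
#' against `k_xgi` of order 1e-4) only make sense on those scales.
#'
#' @return named numeric vector `c(a1, a2, a3, a4, a5, a6, a0)`.
#' @export
published_risk_coefficients <- function() {
  c(a1 = 0.5310, a2 = 0.1960, a3 = 1.2799, a4 = 0.0330,
    a5 = -0.0187, a6 = -798.2059, a0 = -6.0103)
}

#' Dysglycemia-risk probability from the published logistic model
#'
#' Evaluates `P(dysglycemia) = exp(z) / (1 + exp(z))` with the fixed
#' published coefficients (see [published_risk_coefficients()]). Predictors
#' are taken from the parameter vector (`eta`, `G_b`, `I_b`, `tau`,
#' `k_xgi`) and the dimensionless set (`Pi_X`); alternatively pass a named
#' list/vector covering all six predictor names via `predictors`.
#'
#' @param params a [model_parameters()] vector (ignored when `predictors`
#'   is given).
#' @param ndns an `ndn_set` from [compute_ndns()] (ignored when
#'   `predictors` is given).
#' @param predictors optional named vector/list with `eta`, `Pi_X`, `G_b`,
#'   `I_b`, `tau`, `k_xgi`.
#' @return probability in (0, 1).
#' @examples
#' p <- model_parameters()
#' published_risk(p, compute_ndns(p))
#' @export
published_risk <- function(params = NULL, ndns = NULL, predictors = NULL) {
  if (is.null(predictors)) {
    stopifnot(!is.null(params), !is.null(ndns))
    pp <- unclass(params)
    predictors <- c(eta = pp[["eta"]], Pi_X = unclass(ndns)[["Pi_X"]],
                    G_b = pp[["G_b"]], I_b = pp[["I_b"]],
                    tau = pp[["tau"]], k_xgi = pp[["k_xgi"]])
  }
  predictors <- unlist(predictors)
  need <- c("eta", "Pi_X", "G_b", "I_b", "tau", "k_xgi")
  miss <- setdiff(need, names(predictors))
  if (length(miss)) {
    stop("missing risk predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(predictors[need]))) {
    stop("non-finite risk predictor", call. = FALSE)
  }
  a <- published_risk_coefficients()
  z <- a[["a1"]] * predictors[["eta"]] + a[["a2"]] * predictors[["Pi_X"]] +
    a[["a3"]] * predictors[["G_b"]] + a[["a4"]] * predictors[["I_b"]] +
    a[["a5"]] * predictors[["tau"]] + a[["a6"]] * predictors[["k_xgi"]] +
    a[["a0"]]
  stats::plogis(z)
}

#' Binary risk classification from a probability
#'
#' Non-healthy iff `p >= threshold`; the default boundary-inclusive
#' threshold is 0.60.
#'
#' @param p probability (or vector of probabilities) in `[0, 1]`.
#' @param threshold classification threshold.
#' @return character vector `"healthy"` / `"non-healthy"`.
#' @export
classify_risk <- function(p, threshold = 0.60) {
  stopifnot(all(p >= 0), all(p <= 1))
  ifelse(p >= threshold, "non-healthy", "healthy")
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits a binomial GLM by iteratively reweighted least squares
#' ([stats::glm()]) and returns the coefficients with Wald standard errors
#' and p-values from the observed information. Complete separation and
#' singular designs are raised as errors rather than silently tolerated.
#'
#' @param X numeric predictor matrix/data frame (no intercept column).
#' @param y binary labels (0/1, logical, or a two-level factor where the
#'   second level is the positive class).
#' @return list of class `logistic_fit` with `coefficients` (incl.
#'   `(Intercept)`), `se`, `z`, `p_values`, `loglik`, `aic`, `fitted`,
#'   `glm` (the underlying fit).
#' @export
fit_logistic <- function(X, y) {
  X <- as.data.frame(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y))
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  dat <- cbind(X, .y = y)
  form <- if (ncol(X) == 0L) .y ~ 1 else .y ~ .
  fit <- suppressWarnings(
    stats::glm(form, data = dat, family = stats::binomial()))
  if (!fit$converged) {
    stop("logistic fit did not converge", call. = FALSE)
  }
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: collinear column(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  if (ncol(X) > 0L && fit$deviance < 1e-6) {
    stop("complete separation: logistic coefficients not identifiable",
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  structure(list(coefficients = stats::coef(fit),
                 se = stats::setNames(sm[, "Std. Error"], rownames(sm)),
                 z = stats::setNames(sm[, "z value"], rownames(sm)),
                 p_values = stats::setNames(sm[, "Pr(>|z|)"], rownames(sm)),
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), fitted = fit$fitted.values,
                 glm = fit),
            class = "logistic_fit")
}

#' Backward elimination of logistic predictors by Wald p-value
#'
#' Repeatedly refits the logistic model, dropping the predictor with the
#' largest Wald p-value (intercept excluded) while any p-value is at or
#' above `alpha`, until every remaining coefficient is significant. If all
#' predictors are eliminated the intercept-only model is returned with a
#' warning.
#'
#' @param X predictor table.
#' @param y binary labels.
#' @param alpha significance level (default 0.05).
#' @param design `"main"` (columns as given), `"full"` (adds all pairwise
#'   products) or `"quadratic"` (adds squared terms).
#' @return list with `fit` (final `logistic_fit`), `kept`, `trace` (data
#'   frame: step, dropped predictor, its p-value).
#' @export
wald_backward_eliminate <- function(X, y, alpha = 0.05,
                                    design = c("main", "full",
                                               "quadratic")) {
  design <- match.arg(design)
  X <- build_logistic_design(X, design)
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- fit_logistic(X, y)
    p <- fit$p_values[setdiff(names(fit$p_values), "(Intercept)")]
    if (!length(p)) {
      warning("all predictors eliminated; returning intercept-only model")
      break
    }
    if (max(p) < alpha) break
    step <- step + 1L
    worst <- names(p)[which.max(p)]
    trace <- rbind(trace, data.frame(step = step, dropped = worst,
                                     p_value = unname(max(p)),
                                     stringsAsFactors = FALSE))
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
    if (ncol(X) == 0L) {
      fit <- fit_logistic(data.frame(row.names = seq_along(y)), y)
      warning("all predictors eliminated; returning intercept-only model")
      break
    }
  }
  list(fit = fit, kept = setdiff(names(fit$coefficients), "(Intercept)"),
       trace = trace)
}

#' Design-matrix builders for the logistic risk models
#'
#' `"main"` keeps the columns as given; `"full"` appends every pairwise
#' product column (`a.x.b`); `"quadratic"` appends squared columns
#' (`a.sq`). Column names are syntactic so the GLM formula interface keeps
#' them intact.
#'
#' @param X predictor table.
#' @param design one of `"main"`, `"full"`, `"quadratic"`.
#' @return data frame.
#' @export
build_logistic_design <- function(X, design = c("main", "full",
                                                "quadratic")) {
  design <- match.arg(design)
  X <- as.data.frame(X)
  names(X) <- make.names(names(X))
  if (design == "main") return(X)
  extra <- list()
  if (design == "full") {
    nm <- names(X)
    for (i in seq_along(nm)) {
      for (j in seq_along(nm)) {
        if (j > i) {
          extra[[paste(nm[i], nm[j], sep = ".x.")]] <- X[[i]] * X[[j]]
        }
      }
    }
  } else {
    for (nm in names(X)) extra[[paste0(nm, ".sq")]] <- X[[nm]]^2
  }
  cbind(X, as.data.frame(extra))
}

#' Binary classifier performance metrics
#'
#' Confusion counts at the given probability threshold (positive class =
#' label 1 = non-healthy, predicted positive iff `p >= threshold`), with
#' sensitivity, specificity, diagnostic odds ratio, Matthews correlation
#' coefficient, and — when a `logistic_fit` is supplied — the AIC
#' `2k - 2 logL` of the associated model. A zero confusion cell triggers
#' the 0.5-cell Haldane correction for the DOR, flagged in the output.
#'
#' @param p predicted probabilities.
#' @param y true binary labels (0/1; 1 = positive/non-healthy).
#' @param threshold classification threshold (default 0.60).
#' @param fit optional `logistic_fit` for the AIC.
#' @return list of class `classifier_metrics`.
#' @export
classifier_metrics <- function(p, y, threshold = 0.60, fit = NULL) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), length(p) == length(y),
            all(p >= 0), all(p <= 1))
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  haldane <- any(c(tp, tn, fp, fn) == 0)
  cc <- if (haldane) 0.5 else 0
  dor <- ((tp + cc) * (tn + cc)) / ((fp + cc) * (fn + cc))
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec,
                 dor = dor, dor_haldane_corrected = haldane, mcc = mcc,
                 aic = if (!is.null(fit)) fit$aic else NA_real_,
                 threshold = threshold),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(
    "<classifier_metrics> thr %.2f | TP %d FP %d TN %d FN %d | sens %.3f spec %.3f DOR %.2f MCC %.3f\n",
    x$threshold, x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity,
    x$dor, x$mcc))
  invisible(x)
}
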