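test_that("published coefficients are stored exactly", {
  a <- published_risk_coefficients()
  expect_identical(unname(a), c(0.5310, 0.1960, 1.2799, 0.0330, -0.0187,
                                -798.2059, -6.0103))
})

test_that("risk probability matches an independent hand evaluation", {
  pred <- c(eta = 1, Pi_X = 0.1, G_b = 4.5, I_b = 30, tau = 90,
            k_xgi = 1e-4)
  z <- 0.5310 * 1 + 0.1960 * 0.1 + 1.2799 * 4.5 + 0.0330 * 30 +
    (-0.0187) * 90 + (-798.2059) * 1e-4 + (-6.0103)
  expect_equal(published_risk(predictors = pred), exp(z) / (1 + exp(z)),
               tolerance = 1e-12)
  # z = 0 gives exactly one half: solve the intercept out via G_b
  pred0 <- pred
  pred0[["G_b"]] <- pred0[["G_b"]] - z / 1.2799
  expect_equal(published_risk(predictors = pred0), 0.5, tolerance = 1e-12)
  expect_error(published_risk(predictors = pred[-3]), "G_b")
})

test_that("risk is monotone in each predictor per its coefficient sign", {
  base <- c(eta = 0.05, Pi_X = 0.3, G_b = 4.8, I_b = 30, tau = 90,
            k_xgi = 1.5e-4)
  p0 <- published_risk(predictors = base)
  bump <- function(nm, f) {
    b <- base; b[[nm]] <- b[[nm]] * f
    published_risk(predictors = b)
  }
  expect_gt(bump("G_b", 1.1), p0)
  expect_gt(bump("I_b", 1.1), p0)
  expect_gt(bump("eta", 1.1), p0)
  expect_gt(bump("Pi_X", 1.1), p0)
  expect_lt(bump("tau", 1.1), p0)
  expect_lt(bump("k_xgi", 1.1), p0)
})

test_that("risk classification threshold is boundary-inclusive at 0.60", {
  expect_equal(classify_risk(0.60), "non-healthy")
  expect_equal(classify_risk(0.599), "healthy")
  expect_equal(classify_risk(0), "healthy")
  expect_equal(classify_risk(1), "non-healthy")
  grid <- seq(0, 1, by = 0.01)
  expect_equal(classify_risk(grid) == "non-healthy", grid >= 0.60)
})

test_that("logistic fit recovers generating coefficients within 2 SE", {
  set.seed(45)
  n <- 2000
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  truth <- c(`(Intercept)` = -0.4, x1 = 1.2, x2 = -0.8)
  z <- truth[1] + truth[2] * X$x1 + truth[3] * X$x2
  y <- rbinom(n, 1, plogis(z))
  fit <- fit_logistic(X, y)
  for (nm in names(truth)) {
    expect_lt(abs(fit$coefficients[[nm]] - truth[[nm]]),
              2 * fit$se[[nm]])
  }
  # refitting from the solution is a fixed point of IRLS
  refit <- fit_logistic(X, y)
  expect_equal(refit$coefficients, fit$coefficients, tolerance = 1e-12)
})

test_that("intercept-only fit on balanced labels gives log-odds zero", {
  y <- rep(c(0, 1), 50)
  fit <- fit_logistic(data.frame(row.names = seq_along(y)), y)
  expect_lt(abs(fit$coefficients[["(Intercept)"]]), 1e-8)
})

test_that("log-likelihood matches a dense grid search on a toy problem", {
  set.seed(42)
  n <- 150
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 + x))
  fit <- fit_logistic(data.frame(x = x), y)
  ll <- function(b0, b1) sum(dbinom(y, 1, plogis(b0 + b1 * x), log = TRUE))
  grid <- expand.grid(b0 = seq(-1, 2, by = 0.01),
                      b1 = seq(-1, 3, by = 0.01))
  best <- max(mapply(ll, grid$b0, grid$b1))
  expect_equal(fit$loglik, best, tolerance = 1e-4)
  expect_gte(fit$loglik, best - 1e-6)
})

test_that("separation and collinearity raise explicit errors", {
  x <- c(-2, -1.5, -1, 1, 1.5, 2)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_error(fit_logistic(data.frame(x = x), y), "separation")
  set.seed(43)
  X <- data.frame(a = rnorm(40))
  X$b <- 2 * X$a
  yy <- rbinom(40, 1, 0.5)
  expect_error(fit_logistic(X, yy), "collinear")
})

test_that("Wald backward elimination drops noise and keeps signal", {
  set.seed(44)
  n <- 2000
  X <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * X$signal))
  res <- wald_backward_eliminate(X, y)
  expect_true("signal" %in% res$kept)
  expect_true(all(res$fit$p_values[res$kept] < 0.05))
  # the trace never eliminates a predictor significant at its step
  expect_true(all(res$trace$p_value >= 0.05))
  # already-significant model returns unchanged with empty trace
  res2 <- wald_backward_eliminate(data.frame(signal = X$signal), y)
  expect_equal(nrow(res2$trace), 0)
  # alpha = 1 eliminates nothing
  res3 <- wald_backward_eliminate(X, y, alpha = 1)
  expect_equal(nrow(res3$trace), 0)
  expect_length(res3$kept, 4)
})

test_that("design builders create interaction and quadratic columns", {
  X <- data.frame(a = 1:4, b = c(2, 3, 5, 7))
  full <- build_logistic_design(X, "full")
  expect_true("a.x.b" %in% names(full))
  expect_equal(full$a.x.b, X$a * X$b)
  quad <- build_logistic_design(X, "quadratic")
  expect_equal(quad$a.sq, X$a^2)
  expect_equal(ncol(quad), 4)
})

test_that("classifier metrics reproduce direct confusion arithmetic", {
  # constructed confusion table: TP 77, FN 23, TN 74, FP 26
  y <- c(rep(1, 100), rep(0, 100))
  p <- c(rep(0.9, 77), rep(0.1, 23), rep(0.1, 74), rep(0.9, 26))
  m <- classifier_metrics(p, y, threshold = 0.60)
  expect_equal(m$sensitivity, 0.77)
  expect_equal(m$specificity, 0.74)
  expect_equal(m$dor, (77 * 74) / (26 * 23), tolerance = 1e-12)
  expect_false(m$dor_haldane_corrected)
  # perfect classifier
  mp <- classifier_metrics(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(mp$sensitivity, 1)
  expect_equal(mp$specificity, 1)
  expect_equal(mp$mcc, 1)
  expect_true(mp$dor_haldane_corrected)  # zero FP/FN cells
  # AIC from the definition: logL = -10, k = 3 gives 26
  fake_fit <- structure(list(aic = 2 * 3 - 2 * (-10)),
                        class = "logistic_fit")
  expect_equal(classifier_metrics(p, y, fit = fake_fit)$aic, 26)
})
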