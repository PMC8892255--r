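test_that("parameter draws are reproducible and respect the template", {
  spec <- cohort_spec(50, "healthy", seed = 71)
  p1 <- sample_parameters(spec)
  p2 <- sample_parameters(spec)
  expect_identical(p1, p2)
  expect_length(p1, 50)
  expect_true(all(vapply(p1, function(p) all(unclass(p) > 0),
                         logical(1))))
  expect_error(cohort_spec(0, "healthy"), "n must be >= 1")
})

test_that("healthy template keeps most k_js draws in the healthy range", {
  draws <- sample_parameters(cohort_spec(1000, "healthy", seed = 72))
  kjs <- vapply(draws, function(p) p[["k_js"]], numeric(1))
  expect_gte(mean(kjs >= 0.0198 & kjs <= 0.244), 0.80)
})

test_that("non-healthy template shifts the flagged subsystems", {
  ph <- sample_parameters(cohort_spec(300, "healthy", seed = 73))
  pnh <- sample_parameters(cohort_spec(300, "non-healthy", seed = 74))
  med <- function(ps, nm) median(vapply(ps, `[[`, numeric(1), nm))
  expect_lt(med(pnh, "k_js"), med(ph, "k_js"))
  expect_lt(med(pnh, "tau"), med(ph, "tau"))
  expect_lt(med(pnh, "k_xgi"), med(ph, "k_xgi"))
  expect_gt(med(pnh, "G_b"), med(ph, "G_b"))
  expect_gt(med(pnh, "I_b"), med(ph, "I_b"))
})

test_that("generated records follow the 5-point protocol with truth attached", {
  coh <- generate_cohort(cohort_spec(3, "healthy", seed = 75))
  expect_length(coh$records, 3)
  expect_identical(names(coh$records), names(coh$truth))
  for (r in coh$records) {
    expect_equal(r$times, c(0, 30, 60, 90, 120))
    expect_length(c(r$glycemia, r$insulinemia), 10)
  }
  # zero noise reproduces the simulator output exactly
  spec0 <- cohort_spec(2, "healthy", cv_g = 0, cv_i = 0, seed = 76)
  coh0 <- generate_cohort(spec0)
  sim <- simulate_ogtt(coh0$truth[[1]])
  expect_equal(coh0$records[[1]]$glycemia, sim$sampled$G,
               tolerance = 1e-7)
  expect_equal(coh0$records[[1]]$insulinemia, sim$sampled$I,
               tolerance = 1e-7)
})

test_that("measurement noise calibrates to the requested CV", {
  p <- model_parameters()
  sim <- simulate_ogtt(p)
  set.seed(77)
  vals <- replicate(1000, simulation_to_record(sim, cv_g = 0.03)$glycemia[3])
  cv_emp <- sd(vals) / mean(vals)
  expect_gte(cv_emp, 0.025)
  expect_lte(cv_emp, 0.035)
  # noise is unbiased on the mean (multiplicative log-normal, mean 1)
  expect_lt(abs(mean(vals) / sim$sampled$G[3] - 1), 0.005)
})

test_that("intervention studies have a control plus one arm per dose", {
  spec <- cohort_spec(3, "healthy", cv_g = 0, cv_i = 0, seed = 78)
  study <- generate_intervention_study(
    spec, list("60" = c(tau = 1.1), "120" = c(tau = 1.2),
               "180" = c(tau = 1.3)))
  expect_equal(length(study$doses), 4)
  expect_true(all(vapply(study$subjects, length, integer(1)) == 4))
  expect_error(
    generate_intervention_study(spec, list("60" = c(nope = 1.1))),
    "unknown parameter")
  # no dose effects and no visit variability: arms are identical
  study0 <- generate_intervention_study(spec, list("60" = NULL),
                                        visit_cv = 0)
  expect_equal(study_index_values(study0, "tau", "0"),
               study_index_values(study0, "tau", "60"))
})

test_that("cohort index tables feed range construction and coordination", {
  ph <- sample_parameters(cohort_spec(120, "healthy", seed = 81))
  pnh <- sample_parameters(cohort_spec(120, "non-healthy", seed = 82))
  th <- parameter_table(ph)
  tnh <- parameter_table(pnh)
  expect_equal(dim(th), c(120, 14 + 7))
  expect_true(all(unlist(th) > 0))
  vary <- c("k_js", "tau", "k_xgi", "G_b", "I_b", "Pi_S", "Pi_X")
  rc <- build_range_table(th[vary], tnh[vary])
  # the shifted motility/uptake indices separate the cohorts
  expect_true(all(c("k_js", "tau", "k_xgi") %in% rc$table$index))
  expect_equal(rc$details$k_js$direction, "left")
  expect_equal(rc$details$G_b$direction, "right")
  # the latent factor makes the non-healthy cohort more correlated:
  # more supra-cutoff edges and a larger total edge weight
  g_h <- build_graph(correlation_matrix(th[vary]))
  g_nh <- build_graph(correlation_matrix(tnh[vary]))
  cmp <- compare_cohort_graphs(g_h, g_nh)
  expect_gt(cmp$n_edges_nh, cmp$n_edges_h)
  expect_gt(cmp$total_weight_diff, 0)
})

test_that("full pipeline closure runs end-to-end on a small cohort", {
  coh <- generate_cohort(cohort_spec(3, "healthy", seed = 79))
  rep <- run_assessment(coh$records, seed = 2, n_starts = 8, n_polish = 2,
                        maxiter = 40, n_hops = 0)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 3)
  expect_true(all(df$risk >= 0 & df$risk <= 1))
  expect_true(all(df$error == ""))
  # same records and seed reproduce the serialized report byte for byte
  rep2 <- run_assessment(coh$records, seed = 2, n_starts = 8,
                         n_polish = 2, maxiter = 40, n_hops = 0)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_assessment_json(rep, f1)
  write_assessment_json(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
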