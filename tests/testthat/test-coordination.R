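test_that("correlation matrix matches a hand-computable fixture", {
  # 5 subjects, y = x^2 on the log scale gives r(log x, log y) = 1
  x <- c(0.5, 1, 2, 4, 8)
  d <- data.frame(x = x, y = x^2, z = c(1.1, 0.9, 1.3, 0.8, 1.2))
  m <- correlation_matrix(d)
  expect_equal(diag(m), c(x = 1, y = 1, z = 1))
  expect_equal(m["x", "y"], 1)
  expect_equal(m, t(m))
  # brute-force covariance/sd on the log scale
  lx <- log10(d$x); lz <- log10(d$z)
  r_brute <- sum((lx - mean(lx)) * (lz - mean(lz))) /
    sqrt(sum((lx - mean(lx))^2) * sum((lz - mean(lz))^2))
  expect_equal(m["x", "z"], r_brute, tolerance = 1e-12)
  # constant columns yield NA with a warning
  expect_warning(m2 <- correlation_matrix(cbind(d, w = 1)), "constant")
  expect_true(is.na(m2["x", "w"]))
})

test_that("graph edges obey the strict |r| cutoff", {
  m <- diag(3)
  colnames(m) <- rownames(m) <- c("a", "b", "c")
  m["a", "b"] <- m["b", "a"] <- 0.39
  m["a", "c"] <- m["c", "a"] <- -0.41
  g <- build_graph(m, cutoff = 0.4)
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::are_adjacent(g, "a", "c"))
  expect_false(igraph::are_adjacent(g, "a", "b"))
  expect_equal(igraph::E(g)$weight, 0.41)
  # cutoff zero connects everything with nonzero correlation
  expect_equal(igraph::ecount(build_graph(m, cutoff = 0)), 2)
  # raising the cutoff never adds edges
  e_counts <- vapply(c(0, 0.2, 0.4, 0.6),
                     function(ct) igraph::ecount(build_graph(m, ct)),
                     numeric(1))
  expect_true(all(diff(e_counts) <= 0))
})

test_that("Louvain separates disjoint communities and handles isolates", {
  m <- diag(6)
  nm <- letters[1:6]
  colnames(m) <- rownames(m) <- nm
  for (pr in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    m[pr[1], pr[2]] <- m[pr[2], pr[1]] <- 0.8
  }
  g <- build_graph(m)
  cl <- louvain_communities(g, seed = 3)
  expect_equal(length(unique(cl$membership)), 2)
  expect_equal(length(unique(cl$membership[c("a", "b", "c")])), 1)
  expect_equal(length(unique(cl$membership[c("d", "e", "f")])), 1)
  # edgeless graph: all singletons, zero modularity
  g0 <- build_graph(diag(4) + 0, cutoff = 0.4)
  cl0 <- louvain_communities(g0)
  expect_equal(length(unique(cl0$membership)), 4)
  expect_equal(cl0$modularity, 0)
})

test_that("Louvain modularity attains the exhaustive-search optimum", {
  set.seed(33)
  m <- diag(6)
  colnames(m) <- rownames(m) <- letters[1:6]
  edges <- list(c(1, 2, 0.9), c(2, 3, 0.7), c(1, 3, 0.6), c(4, 5, 0.8),
                c(5, 6, 0.85), c(3, 4, 0.45))
  for (e in edges) m[e[1], e[2]] <- m[e[2], e[1]] <- e[3]
  g <- build_graph(m, cutoff = 0.4)
  cl <- louvain_communities(g, seed = 1)
  w <- igraph::E(g)$weight
  best <- max(vapply(all_partitions(6), function(p) {
    memb <- integer(6)
    for (k in seq_along(p)) memb[p[[k]]] <- k
    igraph::modularity(g, memb, weights = w)
  }, numeric(1)))
  expect_equal(cl$modularity, best, tolerance = 1e-12)
  # modularity of the found partition beats all-singletons
  expect_gte(cl$modularity,
             igraph::modularity(g, seq_len(6), weights = w))
})

test_that("cohort graph comparison detects latent-factor coupling", {
  set.seed(34)
  n <- 120
  base <- function() {
    data.frame(a = rllogis2(n, 1, 6), b = rllogis2(n, 2, 6),
               c = rllogis2(n, 0.5, 6), d = rllogis2(n, 1, 6))
  }
  d_h <- base()
  d_nh <- base()
  z <- exp(rnorm(n, 0, 0.6))  # shared latent factor
  d_nh$a <- d_nh$a * z; d_nh$b <- d_nh$b * z; d_nh$c <- d_nh$c * z
  g_h <- build_graph(correlation_matrix(d_h))
  g_nh <- build_graph(correlation_matrix(d_nh))
  cmp <- compare_cohort_graphs(g_h, g_nh, d_h, d_nh, seed = 5)
  expect_gt(cmp$total_weight_diff, 0)
  expect_lt(cmp$perm_p_value, 0.05)
  # identical graphs: no differences, permutation p near 1
  cmp0 <- compare_cohort_graphs(g_h, g_h, d_h, d_h, seed = 5)
  expect_equal(cmp0$total_weight_diff, 0)
  expect_gt(cmp0$perm_p_value, 0.9)
  expect_true(all(cmp0$edge_diff$diff == 0))
  # hub report is deterministic with lexicographic ties
  expect_equal(cmp0$hub_h, sort(cmp0$hub_h))
  expect_error(compare_cohort_graphs(g_h, build_graph(diag(2))),
               "node sets")
})
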