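#' Pairwise correlation matrix of cohort parameters/indices
#'
#' Pearson correlations across subjects. By default the positive indices
#' are log10-transformed first: parameter values span orders of magnitude,
#' and raw-scale Pearson coefficients would be dominated by a handful of
#' extreme subjects. Raw-scale correlation is available with
#' `transform = "identity"`. Constant columns have undefined correlation;
#' their entries are returned as `NA` with a warning.
#'
#' @param cohort_params data frame or matrix of per-subject index values,
#'   columns named by index; at least 3 subjects.
#' @param transform `"log10"` (default; requires positive values) or
#'   `"identity"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(cohort_params, transform = c("log10",
                                                            "identity")) {
  transform <- match.arg(transform)
  x <- as.matrix(as.data.frame(cohort_params))
  stopifnot(nrow(x) >= 3, is.numeric(x))
  if (transform == "log10") {
    if (any(x <= 0)) {
      stop("log10 transform requires strictly positive values; ",
           "use transform = 'identity'", call. = FALSE)
    }
    x <- log10(x)
  }
  const <- apply(x, 2L, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning("constant column(s): ",
            paste(colnames(x)[const], collapse = ", "),
            "; correlations reported as NA")
  }
  m <- suppressWarnings(stats::cor(x, method = "pearson"))
  diag(m) <- 1
  m
}

#' Build a correlation graph from a correlation matrix
#'
#' Nodes are index names; an undirected edge joins indices `i` and `j` iff
#' `|r_ij| > cutoff` (strict), weighted by `|r_ij|`. `NA` entries never
#' produce edges. Node degree is stored as the `degree` vertex attribute.
#'
#' @param matrix symmetric correlation matrix with named dimensions.
#' @param cutoff absolute-correlation threshold (default 0.4).
#' @return an [igraph::graph][igraph] object with edge attribute `weight`
#'   (`|r|`), edge attribute `r` (signed), and vertex attribute `degree`.
#' @export
build_graph <- function(matrix, cutoff = 0.4) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  nm <- colnames(matrix)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(matrix)))
  g <- igraph::make_empty_graph(n = ncol(matrix), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nm)
  idx <- which(upper.tri(matrix), arr.ind = TRUE)
  keep <- !is.na(matrix[idx]) & abs(matrix[idx]) > cutoff
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx)) {
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "r", value = matrix[idx])
    g <- igraph::set_edge_attr(g, "weight", value = abs(matrix[idx]))
  }
  igraph::set_vertex_attr(g, "degree", value = igraph::degree(g))
}

#' Louvain community detection on a correlation graph
#'
#' Weighted-modularity Louvain clustering (resolution 1). The seed fixes
#' the vertex processing order used for tie-breaking, making the partition
#' reproducible; isolated nodes form singleton communities.
#'
#' @param graph an igraph graph (weights taken from the `weight` edge
#'   attribute when present).
#' @param seed integer seed controlling tie-break order.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
louvain_communities <- function(graph, seed = 1L) {
  stopifnot(igraph::vcount(graph) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample(igraph::vcount(graph))
  gp <- igraph::permute(graph, perm)
  cl <- igraph::cluster_louvain(gp, resolution = 1)
  memb_p <- igraph::membership(cl)
  memb <- integer(igraph::vcount(graph))
  memb[] <- memb_p[perm]
  names(memb) <- igraph::V(graph)$name
  # relabel communities in order of first appearance for determinism
  memb <- match(memb, unique(memb))
  names(memb) <- igraph::V(graph)$name
  w <- igraph::E(graph)$weight
  list(membership = memb,
       modularity = if (igraph::ecount(graph) > 0) {
         igraph::modularity(graph, memb, weights = w)
       } else 0)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Compare healthy and non-healthy correlation graphs
#'
#' Reports per-edge weight differences over the union of edges, the
#' edge-count difference, the maximum-degree hub of each graph (ties listed
#' lexicographically), and — when the underlying per-subject tables are
#' supplied — a permutation p-value for the difference in total edge
#' weight under subject-label permutation.
#'
#' @param graph_h,graph_nh igraph graphs over the same node set.
#' @param data_h,data_nh optional per-subject index tables used to rebuild
#'   graphs under permuted cohort labels.
#' @param cutoff,transform passed to [correlation_matrix()] /
#'   [build_graph()] during permutation.
#' @param n_perm number of label permutations.
#' @param seed permutation seed.
#' @return list with `edge_diff` (data frame), `n_edges_h`, `n_edges_nh`,
#'   `total_weight_diff` (non-healthy minus healthy), `hub_h`, `hub_nh`,
#'   and (with data) `perm_p_value`.
#' @export
compare_cohort_graphs <- function(graph_h, graph_nh, data_h = NULL,
                                  data_nh = NULL, cutoff = 0.4,
                                  transform = "log10", n_perm = 200,
                                  seed = 1L) {
  nh <- sort(igraph::V(graph_h)$name)
  nn <- sort(igraph::V(graph_nh)$name)
  if (!identical(nh, nn)) {
    stop("graphs have different node sets", call. = FALSE)
  }
  wmat <- function(g) {
    m <- if (igraph::ecount(g) > 0) {
      igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    } else {
      n <- igraph::vcount(g)
      matrix(0, n, n, dimnames = list(igraph::V(g)$name,
                                      igraph::V(g)$name))
    }
    m[order(rownames(m)), order(colnames(m))]
  }
  mh <- wmat(graph_h)
  mnh <- wmat(graph_nh)
  ut <- upper.tri(mh)
  pairs <- which(ut & (mh > 0 | mnh > 0), arr.ind = TRUE)
  edge_diff <- data.frame(
    from = rownames(mh)[pairs[, 1L]], to = colnames(mh)[pairs[, 2L]],
    weight_h = mh[pairs], weight_nh = mnh[pairs],
    diff = mnh[pairs] - mh[pairs], stringsAsFactors = FALSE)
  hub <- function(g) {
    d <- igraph::degree(g)
    sort(names(d)[d == max(d)])
  }
  obs <- sum(mnh[ut]) - sum(mh[ut])
  out <- list(edge_diff = edge_diff,
              n_edges_h = igraph::ecount(graph_h),
              n_edges_nh = igraph::ecount(graph_nh),
              total_weight_diff = obs,
              hub_h = hub(graph_h), hub_nh = hub(graph_nh))
  if (!is.null(data_h) && !is.null(data_nh)) {
    data_h <- as.data.frame(data_h)
    data_nh <- as.data.frame(data_nh)
    stopifnot(identical(names(data_h), names(data_nh)))
    pooled <- rbind(data_h, data_nh)
    n1 <- nrow(data_h)
    total_weight <- function(d) {
      m <- suppressWarnings(correlation_matrix(d, transform = transform))
      a <- abs(m[upper.tri(m)])
      sum(a[!is.na(a) & a > cutoff])
    }
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    perm_stats <- replicate(n_perm, {
      sh <- sample(nrow(pooled))
      total_weight(pooled[sh[seq_len(n1)], , drop = FALSE]) -
        total_weight(pooled[sh[-seq_len(n1)], , drop = FALSE])
    })
    # two observed totals under the same cutoff for comparability
    obs_cut <- total_weight(data_nh) - total_weight(data_h)
    out$perm_p_value <- (1 + sum(abs(perm_stats) >= abs(obs_cut))) /
      (1 + n_perm)
    out$perm_observed <- obs_cut
  }
  out
}
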