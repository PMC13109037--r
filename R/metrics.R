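#' @title Graph metrics for binarized structural covariance networks
#' @description Global segregation/integration measures (clustering,
#'   modularity, global efficiency, characteristic path length,
#'   small-worldness against degree-preserving nulls) and nodal centralities
#'   (betweenness, eigenvector, closeness) on binary undirected graphs.
#'   Computation is delegated to igraph; each wrapper fixes the convention
#'   (normalization, component handling, determinism) used throughout the
#'   pipeline.
#' @name graph-metrics
NULL

# Coerce an idscn_network, 0/1 adjacency matrix, or igraph object to an
# undirected igraph graph without self-loops.
as_graph <- function(net) {
  if (igraph::is_igraph(net)) return(net)
  adj <- if (inherits(net, "idscn_network")) net$adj else net
  stopifnot(is.matrix(adj))
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected", diag = FALSE)
}

#' Nodal and mean clustering coefficients
#'
#' c_i = 2 t_i / (k_i (k_i - 1)) with t_i the number of triangles through
#' node i and k_i its degree; nodes of degree < 2 get c_i = 0. The global
#' value is the unweighted mean over all nodes.
#'
#' @param net an `idscn_network`, adjacency matrix, or igraph graph.
#' @return list with `nodal` (numeric vector) and `mean`.
#' @export
clustering_coefficients <- function(net) {
  g <- as_graph(net)
  c_i <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  c_i[!is.finite(c_i)] <- 0
  list(nodal = c_i, mean = mean(c_i))
}

#' Global efficiency
#'
#' Mean over unordered node pairs of 1/d_ij with hop-count geodesic
#' distances; disconnected pairs contribute 0.
#'
#' @inheritParams clustering_coefficients
#' @return scalar in [0, 1] (0 for graphs with < 2 nodes).
#' @export
global_efficiency <- function(net) {
  g <- as_graph(net)
  if (igraph::vcount(g) < 2) return(0)
  e <- igraph::global_efficiency(g, directed = FALSE)
  if (!is.finite(e)) 0 else e
}

#' Modularity maximization by the multilevel heuristic with restarts
#'
#' Maximizes Newman modularity Q = sum_c (e_c/m - (d_c/2m)^2) with the greedy
#' multilevel (Louvain) algorithm run `n_restarts` times under random node
#' orders; the best-Q partition is returned. Deterministic given `seed`.
#'
#' @inheritParams clustering_coefficients
#' @param n_restarts number of random-order restarts (default 20).
#' @param seed integer seed, or NULL to consume the current RNG stream.
#' @return list with `Q` and `partition` (integer membership vector).
#' @export
modularity_partition <- function(net, n_restarts = 20, seed = NULL) {
  g <- as_graph(net)
  if (igraph::ecount(g) == 0) abort("modularity undefined for an edgeless graph")
  with_seed(seed, {
    best_q <- -Inf
    best_mem <- NULL
    for (r in seq_len(n_restarts)) {
      # igraph's multilevel implementation shuffles the node order from the
      # RNG on every call, so repeated seeded calls are the random restarts
      cl <- igraph::cluster_louvain(g)
      q <- igraph::modularity(cl)
      if (q > best_q) {
        best_q <- q
        best_mem <- as.integer(igraph::membership(cl))
      }
    }
    list(Q = best_q, partition = best_mem)
  })
}

#' Characteristic path length
#'
#' Mean geodesic (hop) distance over unordered pairs within the largest
#' connected component.
#'
#' @inheritParams clustering_coefficients
#' @return scalar >= 1.
#' @export
characteristic_path_length <- function(net) {
  g <- as_graph(net)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  if (comp$csize[big] < 2) abort("largest component has fewer than 2 nodes")
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  igraph::mean_distance(sub, directed = FALSE)
}

#' Null-model configuration for small-worldness
#'
#' @param n_nulls number of rewired reference graphs (default 100).
#' @param rewires_per_edge attempted degree-preserving swaps per edge
#'   (default 10).
#' @param seed integer seed for the null ensemble.
#' @return list of class `idscn_null_config`.
#' @export
null_model_config <- function(n_nulls = 100, rewires_per_edge = 10, seed = NULL) {
  if (n_nulls < 1) abort("n_nulls must be >= 1")
  structure(list(n_nulls = as.integer(n_nulls),
                 rewires_per_edge = as.integer(rewires_per_edge),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "idscn_null_config")
}

#' Degree-preserving rewired null network
#'
#' Randomizes topology while preserving every node's degree exactly, via
#' double-edge swaps (`rewires_per_edge * m` attempted swaps). Connectivity
#' is not enforced. Graphs admitting no swap (e.g. complete graphs) are
#' returned unchanged with a warning.
#'
#' @inheritParams clustering_coefficients
#' @param seed integer seed, or NULL to consume the current RNG stream.
#' @param rewires_per_edge attempted swaps per edge (default 10).
#' @return an igraph graph with the same degree sequence.
#' @export
degree_preserving_null <- function(net, seed = NULL, rewires_per_edge = 10) {
  g <- as_graph(net)
  m <- igraph::ecount(g)
  if (m < 2) abort("need at least 2 edges to rewire")
  with_seed(seed, {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = rewires_per_edge * m))
    if (igraph::identical_graphs(igraph::as_undirected(gr), igraph::as_undirected(g)) &&
        isTRUE(all.equal(igraph::as_adjacency_matrix(gr, sparse = FALSE),
                         igraph::as_adjacency_matrix(g, sparse = FALSE))))
      warning("no degree-preserving swap changed the graph; returning it unchanged")
    gr
  })
}

#' Small-worldness sigma against a degree-preserving null ensemble
#'
#' sigma = (C / C_null) / (L / L_null), where C is the mean clustering
#' coefficient and L the characteristic path length of the network, and
#' C_null, L_null are means over `n_nulls` rewired graphs. sigma > 1
#' indicates small-world organization (clustering above chance at near-random
#' path length).
#'
#' @inheritParams clustering_coefficients
#' @param null_config an [null_model_config()].
#' @return scalar sigma >= 0.
#' @export
small_worldness <- function(net, null_config = null_model_config()) {
  g <- as_graph(net)
  comp <- igraph::components(g)
  if (max(comp$csize) < 3) abort("largest component must have >= 3 nodes")
  C <- clustering_coefficients(g)$mean
  L <- characteristic_path_length(g)
  m <- igraph::ecount(g)
  with_seed(null_config$seed, {
    c_null <- numeric(null_config$n_nulls)
    l_null <- numeric(null_config$n_nulls)
    for (i in seq_len(null_config$n_nulls)) {
      gn <- suppressWarnings(
        igraph::rewire(g, igraph::keeping_degseq(
          niter = null_config$rewires_per_edge * m)))
      c_null[i] <- clustering_coefficients(gn)$mean
      l_null[i] <- characteristic_path_length(gn)
    }
    cbar <- mean(c_null); lbar <- mean(l_null)
    if (cbar == 0) abort("null clustering is zero (degenerate degree sequence)")
    (C / cbar) / (L / lbar)
  })
}

#' Betweenness centrality (unnormalized geodesic counts)
#'
#' b(v) = sum over unordered pairs s != v != t of the fraction of shortest
#' s-t paths passing through v.
#'
#' @inheritParams clustering_coefficients
#' @return numeric vector of nodal values >= 0.
#' @export
betweenness_centrality <- function(net) {
  g <- as_graph(net)
  as.numeric(igraph::betweenness(g, directed = FALSE, normalized = FALSE))
}

#' Eigenvector centrality (unit Euclidean norm)
#'
#' Leading eigenvector of the binary adjacency matrix with nonnegative
#' entries, scaled to unit Euclidean norm.
#'
#' @inheritParams clustering_coefficients
#' @return numeric vector of nodal values >= 0 with L2 norm 1.
#' @export
eigenvector_centrality <- function(net) {
  g <- as_graph(net)
  if (igraph::ecount(g) == 0) abort("eigenvector centrality undefined for an edgeless graph")
  # fixed internal seed: ARPACK draws its start vector from the RNG, and the
  # leading eigenvector must not depend on (or disturb) the caller's stream
  v <- with_seed(171717L, igraph::eigen_centrality(g, directed = FALSE)$vector)
  v <- abs(as.numeric(v))
  v / sqrt(sum(v^2))
}

#' Closeness centrality (within-component convention)
#'
#' For a node v in a connected component of size s >= 2:
#' (s - 1) / sum of geodesic distances to the other members of its component;
#' isolated nodes score 0.
#'
#' @inheritParams clustering_coefficients
#' @return numeric vector of nodal values in [0, 1].
#' @export
closeness_centrality <- function(net) {
  g <- as_graph(net)
  cl <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  cl <- as.numeric(cl)
  cl[!is.finite(cl)] <- 0
  cl
}

#' Fraction of nodes in the largest connected component
#'
#' @inheritParams clustering_coefficients
#' @return scalar in (0, 1].
#' @export
largest_component_fraction <- function(net) {
  g <- as_graph(net)
  comp <- igraph::components(g)
  max(comp$csize) / igraph::vcount(g)
}

#' Global metrics for one network
#'
#' @inheritParams clustering_coefficients
#' @param null_config an [null_model_config()] for sigma, or NULL to skip
#'   small-worldness (reported as NA).
#' @param n_restarts,seed passed to [modularity_partition()].
#' @return one-row data.frame: clustering, efficiency, modularity_Q,
#'   path_length, small_worldness, lcc_fraction.
#' @export
network_metrics <- function(net, null_config = NULL, n_restarts = 20, seed = NULL) {
  C <- clustering_coefficients(net)$mean
  sigma <- if (is.null(null_config)) NA_real_ else
    tryCatch(small_worldness(net, null_config), error = function(e) {
      # very sparse networks can rewire to triangle-free ensembles; score
      # them 0 when the network itself has no clustering (not small-world),
      # Inf when it is more clustered than every null
      if (grepl("degenerate degree sequence", conditionMessage(e)))
        (if (C == 0) 0 else Inf) else stop(e)
    })
  data.frame(
    clustering = C,
    efficiency = global_efficiency(net),
    modularity_Q = modularity_partition(net, n_restarts = n_restarts, seed = seed)$Q,
    path_length = characteristic_path_length(net),
    small_worldness = sigma,
    lcc_fraction = largest_component_fraction(net)
  )
}

#' Global metrics for every subject across a density grid
#'
#' @param networks output of [build_all_networks()].
#' @param null_config an [null_model_config()] used for sigma at every
#'   density (its seed is advanced deterministically per network), or NULL
#'   to skip sigma.
#' @param n_restarts modularity restarts per network.
#' @param seed master seed; per-network child seeds are derived from it.
#' @return data.frame with one row per subject x density.
#' @export
metrics_table <- function(networks, null_config = null_model_config(n_nulls = 10),
                          n_restarts = 20, seed = 1L) {
  rows <- vector("list", length(networks) * length(networks[[1]]))
  ri <- 0L
  for (s in seq_along(networks)) {
    for (d in seq_along(networks[[s]])) {
      net <- networks[[s]][[d]]
      g <- as_graph(net)                   # convert once per network
      child <- (seed + 7919L * s + 104729L * d) %% 2147483647L
      nc <- if (is.null(null_config)) NULL else
        null_model_config(null_config$n_nulls, null_config$rewires_per_edge,
                          seed = child)
      row <- network_metrics(g, null_config = nc, n_restarts = n_restarts,
                             seed = child)
      row$subject_id <- names(networks)[s]
      row$density <- net$density
      ri <- ri + 1L
      rows[[ri]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[c("subject_id", "density", setdiff(names(out), c("subject_id", "density")))]
}

#' Nodal centralities for every subject, averaged across a density range
#'
#' Computes betweenness, eigenvector and closeness centrality for each
#' subject's network at each density in `densities` and averages per node
#' across densities — the profile used for hub comparison.
#'
#' @param networks output of [build_all_networks()].
#' @param densities densities to average over (default: all in `networks`).
#' @return data.frame with one row per subject x region: subject_id, region,
#'   betweenness, eigenvector, closeness.
#' @export
centrality_table <- function(networks, densities = NULL) {
  all_k <- as.numeric(names(networks[[1]]))
  use <- if (is.null(densities)) seq_along(all_k) else {
    idx <- match(sprintf("%.2f", densities), names(networks[[1]]))
    if (anyNA(idx)) abort("requested densities absent from networks")
    idx
  }
  rows <- vector("list", length(networks))
  for (s in seq_along(networks)) {
    acc_b <- acc_e <- acc_c <- 0
    for (d in use) {
      net <- networks[[s]][[d]]
      g <- as_graph(net)
      acc_b <- acc_b + betweenness_centrality(g)
      acc_e <- acc_e + eigenvector_centrality(g)
      acc_c <- acc_c + closeness_centrality(g)
    }
    nd <- length(use)
    regions <- colnames(networks[[s]][[1]]$adj)
    if (is.null(regions)) regions <- sprintf("ROI%02d", seq_along(acc_b))
    rows[[s]] <- data.frame(
      subject_id = names(networks)[s], region = regions,
      betweenness = acc_b / nd, eigenvector = acc_e / nd, closeness = acc_c / nd,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
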