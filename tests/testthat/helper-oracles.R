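# Independent brute-force oracles for graph metrics and rank statistics.
# Everything here works directly on 0/1 adjacency matrices with loops over
# nodes/pairs/paths, deliberately avoiding igraph so the package's metric
# implementations are checked against an independent route.

rand_adj <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# All-pairs hop distances by Floyd-Warshall.
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    t <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      t <- t + adj[nb[a], nb[b]]
    2 * t / (k * (k - 1))
  })
}

bf_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bf_distances(adj)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

bf_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1))))
      nxt <- nxt[comp[nxt] == 0]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

bf_path_length <- function(adj) {
  comp <- bf_components(adj)
  big <- as.integer(names(which.max(table(comp))))
  keep <- which(comp == big)
  stopifnot(length(keep) >= 2)
  d <- bf_distances(adj[keep, keep, drop = FALSE])
  mean(d[upper.tri(d)])
}

bf_closeness <- function(adj) {
  n <- nrow(adj)
  comp <- bf_components(adj)
  d <- bf_distances(adj)
  sapply(seq_len(n), function(v) {
    mem <- setdiff(which(comp == comp[v]), v)
    if (!length(mem)) return(0)
    length(mem) / sum(d[v, mem])
  })
}

# Betweenness by exhaustive enumeration of all simple paths per pair; the
# geodesics are the minimum-length ones, and each interior node gets the
# fraction of geodesics through it.
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1L]] <<- path; return() }
      for (w in which(adj[v, ] == 1)) if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    out
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, 0L)
    geo <- ps[lens == min(lens)]
    for (g in geo) {
      interior <- g[-c(1, length(g))]
      b[interior] <- b[interior] + 1 / length(geo)
    }
  }
  b
}

bf_eigenvector <- function(adj) {
  ev <- eigen(adj, symmetric = TRUE)
  v <- ev$vectors[, which.max(ev$values)]
  v <- abs(v)
  v / sqrt(sum(v^2))
}

# All set partitions of n elements as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(mx + 1L)) grow(c(prefix, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

bf_modularity_Q <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    ec <- sum(adj[idx, idx]) / 2
    dc <- sum(deg[idx])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

bf_modularity_opt <- function(adj, partitions = all_partitions(nrow(adj))) {
  max(vapply(partitions, function(p) bf_modularity_Q(adj, p), 0))
}

# O(n^2) pair-counting Cliff's delta plus dominance-probability identity.
bf_cliffs_delta <- function(a, b) {
  gt <- lt <- eq <- 0L
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1L else if (x < y) lt <- lt + 1L else eq <- eq + 1L
  }
  list(delta = (gt - lt) / (length(a) * length(b)),
       p_gt = gt / (length(a) * length(b)),
       p_eq = eq / (length(a) * length(b)))
}

# Adjacency helpers for named small graphs.
path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}
ring_graph <- function(n) {
  a <- path_graph(n)
  a[1, n] <- a[n, 1] <- 1L
  a
}
complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}
star_graph <- function(leaves) {
  n <- leaves + 1L
  a <- matrix(0L, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1L
  a
}
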