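#' Joint-variation edge weights from a subject's regional z-scores
#'
#' Builds one subject's individualized structural covariance network: a
#' region x region similarity matrix whose edge weight is high when two
#' regions deviate from the normative reference concordantly. The default is
#' a Gaussian kernel of the z-score difference,
#' w_ij = exp(-(z_i - z_j)^2 / (2 c^2)), which lies in (0, 1], equals 1 iff
#' the two deviations are identical, and decreases monotonically in
#' |z_i - z_j|. Alternative kernels with the same range and semantics are
#' available.
#'
#' @param z_row numeric vector of one subject's regional z-scores.
#' @param kernel one of "gaussian", "laplacian", "inverse".
#' @param scale kernel scale c > 0 (default 1).
#' @return an `idscn_similarity`: symmetric matrix, zero diagonal,
#'   off-diagonal in (0, 1].
#' @export
joint_variation_weights <- function(z_row, kernel = c("gaussian", "laplacian", "inverse"),
                                    scale = 1) {
  kernel <- match.arg(kernel)
  if (!all(is.finite(z_row))) abort("z-scores must be finite")
  if (scale <= 0) abort("kernel scale must be > 0")
  d <- abs(outer(z_row, z_row, "-"))
  w <- switch(kernel,
    gaussian  = exp(-d^2 / (2 * scale^2)),
    laplacian = exp(-d / scale),
    inverse   = 1 / (1 + d / scale)
  )
  diag(w) <- 0
  if (!is.null(names(z_row))) dimnames(w) <- list(names(z_row), names(z_row))
  structure(w, class = c("idscn_similarity", "matrix"))
}

#' Construct a density grid
#'
#' @param from,to,by grid bounds and step (defaults 0.05 to 0.30 by 0.01,
#'   26 values).
#' @return numeric vector of strictly increasing densities in (0, 0.5].
#' @export
density_grid <- function(from = 0.05, to = 0.30, by = 0.01) {
  k <- round(seq(from, to, by = by), 10)
  if (any(k <= 0 | k > 0.5)) abort("densities must lie in (0, 0.5]")
  if (is.unsorted(k, strictly = TRUE)) abort("density grid must be strictly increasing")
  k
}

# Deterministic ranking of the upper-triangle edges of a similarity matrix:
# decreasing weight, ties broken by ascending (i, j). Shared by
# threshold_binarize() and the prefix-based fast path, so networks across
# densities are nested by construction.
edge_ranking <- function(w) {
  n <- nrow(w)
  idx <- which(upper.tri(w))
  i <- row(w)[idx]; j <- col(w)[idx]
  ord <- order(-w[idx], i, j)
  list(i = i[ord], j = j[ord], n = n)
}

# Edge count at density K for an n-node graph (half-away-from-zero rounding).
edge_count <- function(K, n) as.integer(round_half_away(K * n * (n - 1) / 2))

#' Threshold and binarize a similarity matrix at a target density
#'
#' Retains the m = round(K n(n-1)/2) largest off-diagonal weights as edges,
#' breaking ties deterministically by ascending (i, j) index pair so that
#' results are reproducible and edge sets are nested across densities.
#'
#' @param idscn symmetric similarity matrix (e.g. from
#'   [joint_variation_weights()]).
#' @param K target density in (0, 0.5].
#' @return an `idscn_network`: list with `adj` (0/1 symmetric matrix, zero
#'   diagonal), `density` and edge count `m`.
#' @export
threshold_binarize <- function(idscn, K) {
  if (K <= 0 || K > 0.5) abort("density K must lie in (0, 0.5]")
  n <- nrow(idscn)
  m <- edge_count(K, n)
  if (m < 1) abort("density %.3f too low: zero edges for %d nodes", K, n)
  rk <- edge_ranking(idscn)
  adj <- matrix(0L, n, n, dimnames = dimnames(idscn))
  keep <- seq_len(m)
  adj[cbind(rk$i[keep], rk$j[keep])] <- 1L
  adj[cbind(rk$j[keep], rk$i[keep])] <- 1L
  structure(list(adj = adj, density = K, m = m), class = "idscn_network")
}

#' Build binarized networks for every subject across a density grid
#'
#' Computes each subject's joint-variation similarity matrix once, ranks its
#' edges once, and materializes the binary network at every density in the
#' grid (edge sets at lower densities are prefixes of those at higher
#' densities).
#'
#' @param zscores an `idscn_zscores` (or bare subjects x regions z matrix).
#' @param grid density grid from [density_grid()].
#' @param kernel,scale passed to [joint_variation_weights()].
#' @return list indexed by subject, each a list of `idscn_network` indexed by
#'   density (names = formatted densities).
#' @export
build_all_networks <- function(zscores, grid = density_grid(),
                               kernel = "gaussian", scale = 1) {
  z <- if (inherits(zscores, "idscn_zscores")) zscores$z else zscores
  stopifnot(is.matrix(z))
  n <- ncol(z)
  ms <- vapply(grid, edge_count, integer(1), n = n)
  if (any(ms < 1)) abort("grid contains densities with zero edges for %d nodes", n)
  out <- vector("list", nrow(z))
  names(out) <- rownames(z)
  kname <- sprintf("%.2f", grid)
  for (k in seq_len(nrow(z))) {
    w <- joint_variation_weights(z[k, ], kernel = kernel, scale = scale)
    rk <- edge_ranking(w)
    nets <- vector("list", length(grid))
    for (gi in seq_along(grid)) {
      m <- ms[gi]
      adj <- matrix(0L, n, n, dimnames = dimnames(w))
      keep <- seq_len(m)
      adj[cbind(rk$i[keep], rk$j[keep])] <- 1L
      adj[cbind(rk$j[keep], rk$i[keep])] <- 1L
      nets[[gi]] <- structure(list(adj = adj, density = grid[gi], m = m),
                              class = "idscn_network")
    }
    names(nets) <- kname
    out[[k]] <- nets
  }
  out
}
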