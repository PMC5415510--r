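#' Build the binary delta-neighborhood spatial constraint matrix
#'
#' The constraint matrix Q has `Q[i, j] = 1` exactly when units i and j are
#' within `delta` hops of each other on the adjacency graph (breadth-first
#' hop distance), and 1 on the diagonal. Small `delta` restricts affinity to
#' near neighbors and so makes spatial structure dominate the constrained
#' clustering; `delta` at or above the graph diameter leaves the clustering
#' unconstrained. Q is elementwise non-decreasing in `delta` and stored
#' sparsely.
#'
#' @param graph named undirected igraph of unit contiguity.
#' @param delta positive integer neighborhood size in hops.
#' @param unit_ids optional unit ordering (defaults to graph vertex order).
#' @return an object of class `constraint_matrix`: `delta`, sparse symmetric
#'   binary `Q` with unit dimnames, `unit_id`.
#' @export
build_constraint_matrix <- function(graph, delta, unit_ids = NULL) {
  abort_if(!is.numeric(delta) || delta < 1 || delta != round(delta),
           "`delta` must be a positive integer")
  abort_if(igraph::vcount(graph) == 0, "empty graph")
  unit_ids <- unit_ids %||% igraph::V(graph)$name
  check_graph_alignment(graph, unit_ids)
  n <- length(unit_ids)
  hoods <- igraph::ego(graph, order = delta,
                       nodes = unit_ids, mode = "all")
  idx <- setNames(seq_len(n), unit_ids)
  ii <- rep(seq_len(n), lengths(hoods))
  jj <- unlist(lapply(hoods, function(v) unname(idx[igraph::as_ids(v)])),
               use.names = FALSE)
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n),
                            dimnames = list(unit_ids, unit_ids))
  Q <- 1 * ((Q + Matrix::t(Q)) > 0)  # symmetrize
  Matrix::diag(Q) <- 1
  structure(list(delta = as.integer(delta), Q = Q, unit_id = unit_ids),
            class = "constraint_matrix")
}

#' Gaussian feature-similarity matrix between spatial units
#'
#' Computes `W[i, j] = exp(-d_ij^2 / (2 sigma^2))` with `d_ij` the Euclidean
#' distance between units i and j in the feature embedding, so `W` lies in
#' (0, 1] with a unit diagonal. When `bandwidth` is not given, sigma is set
#' from the median embedding distance over pairs of adjacent units (`graph`
#' then required), scaled so that the median adjacent pair receives
#' similarity `adjacent_similarity`:
#' `sigma = median_dist / sqrt(2 * log(1 / adjacent_similarity))`.
#' The scaling keeps the affinities off the saturated regime — with sigma
#' near the typical pair distance almost all weights crowd toward 1, the
#' similarity matrix carries no feature contrast, and constrained spectral
#' clustering degenerates to clustering the spatial constraint alone. The
#' sigma used is always recorded in the result.
#'
#' @param embedding a `feature_embedding` from [pca_reduce()], or a plain
#'   numeric matrix with unit rownames.
#' @param bandwidth optional positive sigma.
#' @param graph adjacency graph, used only for the default bandwidth.
#' @param adjacent_similarity target similarity of the median adjacent pair
#'   for the default bandwidth (default 0.1).
#' @param max_units refuse to materialize the dense n x n matrix above this
#'   number of units.
#' @return an object of class `similarity_matrix`: dense symmetric `W`,
#'   `bandwidth`, `unit_id`, and `S = NULL` until [combine_similarity()].
#' @export
build_feature_similarity <- function(embedding, bandwidth = NULL,
                                     graph = NULL, adjacent_similarity = 0.1,
                                     max_units = 30000) {
  x <- embedding_scores(embedding)
  n <- nrow(x)
  abort_if(n < 2, "need at least 2 units")
  abort_if(n > max_units,
           sprintf("refusing to build a dense %d x %d similarity matrix (max_units = %d)",
                   n, n, max_units))
  if (is.null(bandwidth)) {
    abort_if(is.null(graph),
             "supply `bandwidth` or `graph` (for the adjacent-pair median heuristic)")
    abort_if(adjacent_similarity <= 0 || adjacent_similarity >= 1,
             "`adjacent_similarity` must lie in (0, 1)")
    bandwidth <- median_adjacent_distance(x, graph) /
      sqrt(2 * log(1 / adjacent_similarity))
  }
  abort_if(bandwidth <= 0, "`bandwidth` (sigma) must be positive")
  d2 <- rowdist2(x, x)
  W <- exp(-d2 / (2 * bandwidth^2))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(rownames(x), rownames(x))
  structure(list(W = W, bandwidth = bandwidth, S = NULL,
                 unit_id = rownames(x)),
            class = "similarity_matrix")
}

median_adjacent_distance <- function(scores, graph) {
  el <- igraph::as_edgelist(graph)
  el <- el[el[, 1] %in% rownames(scores) & el[, 2] %in% rownames(scores), ,
           drop = FALSE]
  abort_if(nrow(el) == 0, "graph has no edges among embedded units")
  d <- sqrt(rowSums((scores[el[, 1], , drop = FALSE] -
                     scores[el[, 2], , drop = FALSE])^2))
  m <- stats::median(d)
  if (m <= 0) m <- mean(d[d > 0]) %||% 1
  if (!is.finite(m) || m <= 0) m <- 1
  m
}

#' Mask feature similarity by the spatial constraint (Hadamard product)
#'
#' Sets the combined affinity `S = W * Q` elementwise, so only unit pairs
#' within the delta-neighborhood retain their feature similarity. S inherits
#' W's symmetry and Q's sparsity pattern, and its graph is connected whenever
#' the adjacency graph is (W is strictly positive).
#'
#' @param sim a `similarity_matrix` from [build_feature_similarity()].
#' @param constraint a `constraint_matrix` from [build_constraint_matrix()].
#' @return `sim` with the sparse combined matrix `S` and the constraint's
#'   `delta` filled in.
#' @export
combine_similarity <- function(sim, constraint) {
  abort_if(!identical(sim$unit_id, constraint$unit_id),
           "similarity and constraint matrices have mismatched units")
  S <- Matrix::Matrix(sim$W * as.matrix(constraint$Q > 0), sparse = TRUE)
  sim$S <- S
  sim$delta <- constraint$delta
  sim
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d units, sigma = %.4g%s\n",
              nrow(x$W), x$bandwidth,
              if (!is.null(x$S))
                sprintf(", combined with delta = %d constraint", x$delta)
              else ""))
  invisible(x)
}

#' @export
print.constraint_matrix <- function(x, ...) {
  cat(sprintf("<constraint_matrix> %d units, delta = %d, %d nonzero pairs\n",
              length(x$unit_id), x$delta,
              (Matrix::nnzero(x$Q) - length(x$unit_id)) / 2))
  invisible(x)
}

embedding_scores <- function(embedding) {
  x <- if (inherits(embedding, "feature_embedding")) embedding$scores
       else if (inherits(embedding, "unit_table")) embedding$values
       else as.matrix(embedding)
  abort_if(is.null(rownames(x)), "embedding needs unit-id rownames")
  x
}
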