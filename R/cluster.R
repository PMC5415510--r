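#' Construct a regionalization (unit -> region assignment)
#'
#' @param unit_id character vector of unit ids.
#' @param label integer region labels in `1..k`; every label must occur.
#' @param k number of regions (default `max(label)`).
#' @param provenance list recording how the assignment was produced (method,
#'   delta, k, seed, restarts, sigma, achieved objective, ...).
#' @return an object of class `regionalization`.
#' @export
regionalization <- function(unit_id, label, k = max(label),
                            provenance = list()) {
  label <- as.integer(label)
  abort_if(length(unit_id) != length(label),
           "unit_id and label differ in length")
  abort_if(any(label < 1L) || any(label > k), "labels must lie in 1..k")
  empty <- setdiff(seq_len(k), unique(label))
  abort_if(length(empty) > 0, "empty region label(s): ",
           paste(empty, collapse = ", "))
  structure(list(unit_id = as.character(unit_id), label = label,
                 k = as.integer(k), provenance = provenance),
            class = "regionalization")
}

#' @export
print.regionalization <- function(x, ...) {
  sz <- table(x$label)
  cat(sprintf("<regionalization> %d units in %d regions (sizes %d-%d)%s\n",
              length(x$unit_id), x$k, min(sz), max(sz),
              if (!is.null(x$provenance$method))
                paste0(", method = ", x$provenance$method) else ""))
  invisible(x)
}

#' Generalized Laplacian eigenvectors of a similarity matrix
#'
#' Solves `L u = lambda D u` with `L = D - S` and `D = diag(rowSums(S))` —
#' the random-walk-normalized spectral embedding — and returns the
#' eigenvectors for the `k` smallest eigenvalues in ascending order. The
#' computation reduces to the symmetric problem for `D^{-1/2} L D^{-1/2}`,
#' then maps back via `u = D^{-1/2} v`. Sign convention: each vector's
#' largest-magnitude entry is positive. Does not require connectivity; for a
#' graph with c components the eigenvalue 0 has multiplicity c and the
#' corresponding eigenvectors are constant within components.
#'
#' @param S symmetric non-negative matrix (dense or sparse) with positive
#'   row sums.
#' @param k number of leading (smallest-eigenvalue) eigenvectors.
#' @return list with `vectors` (n x k) and `values` (ascending).
#' @export
laplacian_eigen <- function(S, k) {
  S <- as.matrix(S)
  n <- nrow(S)
  abort_if(k > n, "`k` cannot exceed the number of units")
  abort_if(max(abs(S - t(S))) > 1e-8, "S must be symmetric")
  d <- rowSums(S)
  abort_if(any(d <= 0), "zero row-sum in similarity matrix")
  dis <- 1 / sqrt(d)
  Lsym <- -S * tcrossprod(dis)
  diag(Lsym) <- diag(Lsym) + 1
  eig <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  sel <- seq(n, n - k + 1)  # eigen() returns decreasing order
  vals <- pmax(eig$values[sel], 0)
  vecs <- eig$vectors[, sel, drop = FALSE] * dis
  for (j in seq_len(k)) {  # deterministic sign
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- rownames(S)
  list(vectors = vecs, values = vals)
}

#' Spectral embedding of a combined similarity matrix
#'
#' Front end to [laplacian_eigen()] for clustering: checks that the nonzero
#' pattern of `S` is connected (spatially isolated units must be removed
#' before clustering, as disconnected affinity graphs make the embedding
#' degenerate) and returns the n x k coordinate matrix.
#'
#' @param S symmetric non-negative affinity matrix (e.g. the combined `S`
#'   from [combine_similarity()], or a constraint matrix's `Q`).
#' @param k number of embedding coordinates (= target number of regions).
#' @return n x k matrix of spectral coordinates.
#' @export
spectral_embed <- function(S, k) {
  A <- as.matrix(S) != 0
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  abort_if(comp$no > 1,
           sprintf(paste("affinity graph has %d connected components;",
                         "remove spatially isolated units (islands) or",
                         "bridge them before clustering"), comp$no))
  laplacian_eigen(S, k)$vectors
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers with
# probability proportional to squared distance from the chosen set.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  if (k > 1) {
    d2 <- rowdist2(x, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      tot <- sum(d2)
      i <- if (tot <= 0) sample.int(n, 1)
           else sample.int(n, 1, prob = d2 / tot)
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowdist2(x, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

# One Lloyd k-means run from given centers, with farthest-point repair of
# empty clusters (stats::kmeans errors on them with user-supplied centers).
lloyd_once <- function(x, centers, iter_max = 100) {
  k <- nrow(centers)
  for (it in seq_len(iter_max)) {
    d2 <- rowdist2(x, centers)
    lab <- max.col(-d2, ties.method = "first")
    for (c_empty in setdiff(seq_len(k), unique(lab))) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), lab)])
      lab[far] <- c_empty
      d2[far, ] <- Inf; d2[far, c_empty] <- 0
    }
    new_centers <- centers
    for (c in seq_len(k))
      new_centers[c, ] <- colMeans(x[lab == c, , drop = FALSE])
    if (max(abs(new_centers - centers)) < 1e-12) {centers <- new_centers; break}
    centers <- new_centers
  }
  d2 <- rowdist2(x, centers)
  lab <- max.col(-d2, ties.method = "first")
  if (length(unique(lab)) < k) { # final repair pass
    for (c_empty in setdiff(seq_len(k), unique(lab))) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), lab)])
      lab[far] <- c_empty
    }
    for (c in seq_len(k)) centers[c, ] <- colMeans(x[lab == c, , drop = FALSE])
  }
  obj <- sum((x - centers[lab, , drop = FALSE])^2)
  list(cluster = lab, objective = obj, centers = centers)
}

#' Multi-restart k-means minimizing within-cluster sum of squares
#'
#' Runs Lloyd's k-means `restarts` times from k-means++ initializations
#' drawn from a prefix-stable seeded stream and keeps the run with the
#' lowest within-cluster sum of squares (k-means is sensitive to center
#' initialization, so the paper-scale default elsewhere in the package is
#' 1,000 restarts). Empty clusters are repaired by reseeding to the point
#' farthest from its center. The best objective is non-increasing in
#' `restarts` under a fixed seed.
#'
#' @param points numeric matrix (units x coordinates).
#' @param k number of clusters, `1 <= k <= n`.
#' @param restarts number of random restarts.
#' @param seed integer seed for the restart stream.
#' @return list with `labels` (relabeled 1..k by first appearance),
#'   `objective` (the minimized SSW) and `restarts`.
#' @export
kmeans_min_ssw <- function(points, k, restarts = 1000, seed = 1) {
  x <- as.matrix(points)
  n <- nrow(x)
  abort_if(k > n, "`k` cannot exceed the number of points")
  abort_if(k < 1 || restarts < 1, "`k` and `restarts` must be >= 1")
  if (k == n) {
    return(list(labels = seq_len(n), objective = 0, restarts = restarts))
  }
  if (k == 1) {
    obj <- sum(scale(x, scale = FALSE)^2)
    return(list(labels = rep(1L, n), objective = obj, restarts = restarts))
  }
  seeds <- derive_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seeds[r], {
      centers <- kmeanspp_centers(x, k)
      km <- tryCatch(
        kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == k)
        list(cluster = km$cluster, objective = km$tot.withinss)
      else
        lloyd_once(x, centers)
    })
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  lab <- as.integer(factor(best$cluster, levels = unique(best$cluster)))
  list(labels = lab, objective = best$objective, restarts = restarts)
}

#' Cluster spatial units into regions
#'
#' Four methods sharing one interface:
#' \describe{
#'   \item{`"ssc"`}{spatially constrained spectral clustering — the Gaussian
#'     feature similarity `W` masked by the delta-neighborhood constraint `Q`
#'     (Hadamard product), generalized Laplacian eigenvectors, then
#'     multi-restart k-means on the eigenvectors. Balances landscape
#'     homogeneity and region contiguity.}
#'   \item{`"sc"`}{constraint-only spectral clustering — identical but with
#'     `W` replaced by all-ones, i.e. spectral clustering of `Q` alone
#'     (contiguity without landscape homogeneity).}
#'   \item{`"kmeans"`}{multi-restart k-means directly on the feature
#'     embedding, ignoring the graph (homogeneity without contiguity).}
#'   \item{`"random"`}{uniform random labels with no empty region — the
#'     null baseline that considers neither.}
#' }
#'
#' @param embedding `feature_embedding` (or matrix with unit rownames);
#'   ignored by `"random"`, may be NULL for `"sc"`/`"random"` if `graph`
#'   carries the units.
#' @param graph adjacency graph (required for `"ssc"`/`"sc"`).
#' @param k number of regions.
#' @param method one of `"ssc"`, `"sc"`, `"kmeans"`, `"random"`.
#' @param delta neighborhood parameter, required for `"ssc"`/`"sc"`.
#' @param restarts k-means restarts (default 1000; sweeps use fewer).
#' @param seed integer seed.
#' @param bandwidth optional Gaussian sigma (default: adjacent-pair median).
#' @param restart_selection_space `"embedding"` (default) selects the best
#'   restart by SSW in the space k-means ran in; `"features"` re-scores the
#'   candidate restarts in the feature embedding.
#' @return a [regionalization()] with full provenance.
#' @export
cluster_regions <- function(embedding = NULL, graph = NULL, k,
                            method = c("ssc", "sc", "kmeans", "random"),
                            delta = NULL, restarts = 1000, seed = 1,
                            bandwidth = NULL,
                            restart_selection_space = c("embedding", "features")) {
  method <- match.arg(method)
  restart_selection_space <- match.arg(restart_selection_space)
  needs_delta <- method %in% c("ssc", "sc")
  abort_if(needs_delta && is.null(delta),
           sprintf("method '%s' requires `delta`", method))
  abort_if(!needs_delta && !is.null(delta),
           sprintf("method '%s' does not take `delta`", method))

  unit_ids <- if (!is.null(embedding)) rownames(embedding_scores(embedding))
              else igraph::V(graph)$name
  abort_if(is.null(unit_ids), "cannot determine unit ids")
  n <- length(unit_ids)
  abort_if(k > n, "`k` cannot exceed the number of units")
  prov <- list(method = method, k = k, delta = delta, restarts = restarts,
               seed = seed)

  if (method == "random") {
    lab <- with_seed(seed, {
      repeat {
        l <- sample.int(k, n, replace = TRUE)
        if (length(unique(l)) == k) break
      }
      l
    })
    return(regionalization(unit_ids, lab, k, prov))
  }

  if (method == "kmeans") {
    x <- embedding_scores(embedding)
    fit <- kmeans_min_ssw(x, k, restarts, seed)
    prov$objective <- fit$objective
    return(regionalization(unit_ids, fit$labels, k, prov))
  }

  # spectral methods
  check_graph_alignment(graph, unit_ids)
  Q <- build_constraint_matrix(graph, delta, unit_ids)
  if (method == "ssc") {
    sim <- build_feature_similarity(embedding, bandwidth = bandwidth,
                                    graph = graph)
    abort_if(!identical(sim$unit_id, unit_ids), "unit order mismatch")
    S <- combine_similarity(sim, Q)$S
    prov$bandwidth <- sim$bandwidth
  } else {
    S <- Q$Q
  }
  coords <- spectral_embed(S, k)
  if (restart_selection_space == "features" && !is.null(embedding)) {
    fit <- kmeans_best_in_space(coords, embedding_scores(embedding),
                                k, restarts, seed)
  } else {
    fit <- kmeans_min_ssw(coords, k, restarts, seed)
  }
  prov$objective <- fit$objective
  regionalization(unit_ids, fit$labels, k, prov)
}

# select the restart whose partition minimizes SSW in an alternative space
kmeans_best_in_space <- function(coords, space, k, restarts, seed) {
  seeds <- derive_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seeds[r], lloyd_once(coords, kmeanspp_centers(coords, k)))
    ssw <- partition_ssw(space, fit$cluster)
    if (is.null(best) || ssw < best$objective)
      best <- list(cluster = fit$cluster, objective = ssw)
  }
  lab <- as.integer(factor(best$cluster, levels = unique(best$cluster)))
  list(labels = lab, objective = best$objective, restarts = restarts)
}

partition_ssw <- function(x, labels) {
  x <- as.matrix(x)
  ssw <- 0
  for (l in unique(labels)) {
    xi <- x[labels == l, , drop = FALSE]
    ssw <- ssw + sum(scale(xi, scale = FALSE)^2)
  }
  ssw
}
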