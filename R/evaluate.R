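#' Within/between sum-of-squares decomposition of points over groups
#'
#' `SSW = sum over groups of squared deviations from the group mean`;
#' `SSB = sum over groups of n_g * squared deviation of the group mean from
#' the grand mean`. The two always add to the total sum of squares.
#'
#' @param x numeric matrix or vector of coordinates (rows = observations).
#' @param labels group label per row.
#' @return list with `ssw`, `ssb`, `total_ss`.
#' @export
ss_decomposition <- function(x, labels) {
  x <- as.matrix(x)
  abort_if(nrow(x) != length(labels), "rows and labels differ in length")
  grand <- colMeans(x)
  total <- sum(sweep(x, 2, grand)^2)
  ssw <- 0; ssb <- 0
  for (l in unique(labels)) {
    xi <- x[labels == l, , drop = FALSE]
    mu <- colMeans(xi)
    ssw <- ssw + sum(sweep(xi, 2, mu)^2)
    ssb <- ssb + nrow(xi) * sum((mu - grand)^2)
  }
  list(ssw = ssw, ssb = ssb, total_ss = total)
}

#' Score a regionalization for landscape homogeneity and spatial contiguity
#'
#' Computes, in the supplied feature space: SSW (within-region sum of
#' squares; lower = more homogeneous regions), SSB (between-region), their
#' ratio SSW:SSB (+Inf when SSB = 0, e.g. k = 1), and two contiguity
#' metrics on the adjacency graph: PctML, the percentage of must-link
#' constraints preserved — unordered unit pairs within `eval_delta` hops
#' that received the same region label — and `n_contiguous`, the number of
#' regions whose induced adjacency subgraph is connected. Every reported
#' quantity is invariant to region relabeling.
#'
#' @param regionalization a [regionalization()].
#' @param space numeric matrix with unit rownames: the standardized clean
#'   variables (default analysis space) or a PCA embedding.
#' @param graph adjacency graph over the units.
#' @param eval_delta neighborhood defining the must-link constraint set;
#'   conventionally the delta used for clustering, or 1 (plain adjacency)
#'   for methods without a delta.
#' @return an object of class `cluster_quality`: `ssw`, `ssb`, `total_ss`,
#'   `ratio`, `pct_ml`, `eval_delta`, `n_contiguous`, `k`.
#' @export
evaluate_regionalization <- function(regionalization, space, graph,
                                     eval_delta = NULL) {
  x <- embedding_scores(space)
  ids <- regionalization$unit_id
  abort_if(length(ids) < 2, "need at least 2 units")
  abort_if(!all(ids %in% rownames(x)),
           "space is missing rows for some units")
  x <- x[ids, , drop = FALSE]
  check_graph_alignment(graph, ids)
  eval_delta <- eval_delta %||% regionalization$provenance$delta %||% 1L
  abort_if(eval_delta < 1, "`eval_delta` must be >= 1")

  lab <- regionalization$label
  ss <- ss_decomposition(x, lab)
  ratio <- if (ss$ssb > 0) ss$ssw / ss$ssb else Inf

  Q <- build_constraint_matrix(graph, eval_delta, ids)$Q
  idx <- Matrix::which(Q != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]  # unordered pairs, no diag
  pct_ml <- if (nrow(idx) == 0) 100
            else 100 * mean(lab[idx[, 1]] == lab[idx[, 2]])

  sub <- igraph::induced_subgraph(graph, ids)
  n_contig <- sum(vapply(seq_len(regionalization$k), function(r) {
    members <- ids[lab == r]
    comp <- igraph::components(igraph::induced_subgraph(sub, members))
    comp$no == 1
  }, logical(1)))

  structure(list(ssw = ss$ssw, ssb = ss$ssb, total_ss = ss$total_ss,
                 ratio = ratio, pct_ml = pct_ml,
                 eval_delta = as.integer(eval_delta),
                 n_contiguous = n_contig, k = regionalization$k),
            class = "cluster_quality")
}

#' @export
print.cluster_quality <- function(x, ...) {
  cat(sprintf(paste0("<cluster_quality> k = %d\n",
                     "  SSW = %.4g  SSB = %.4g  SSW:SSB = %.3g\n",
                     "  PctML (delta = %d) = %.1f%%  contiguous regions: %d/%d\n"),
              x$k, x$ssw, x$ssb, x$ratio, x$eval_delta, x$pct_ml,
              x$n_contiguous, x$k))
  invisible(x)
}
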