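#' Clean and standardize a spatial-unit feature table
#'
#' Three steps, in order: (1) iterative spatial imputation — each missing
#' value is replaced by the mean of the unit's graph-neighbors' observed
#' values for that variable, repeated up to `impute_max_rounds` so values
#' propagate across contiguous gaps, with the column mean as a final
#' fallback; (2) outlier winsorizing — per variable, values with |z| >
#' `outlier_z` are clamped to the corresponding bound; (3) standardization of
#' every variable to mean 0, variance 1 (constant variables are dropped with
#' a warning). Imputation is a no-op on complete data, and winsorizing never
#' moves a value across the column mean.
#'
#' @param table a [unit_table()].
#' @param graph the unit adjacency graph (named igraph covering the table).
#' @param variance_threshold,outlier_z,impute_max_rounds,whiten preprocessing
#'   parameters; `variance_threshold` and `whiten` are carried along for
#'   [pca_reduce()]. Defaults: 85% cumulative variance, |z| > 6 winsorizing,
#'   10 imputation rounds, whitened scores.
#' @return a cleaned, standardized [unit_table()].
#' @export
preprocess_features <- function(table, graph, outlier_z = 6,
                                impute_max_rounds = 10,
                                variance_threshold = 0.85, whiten = TRUE) {
  abort_if(outlier_z <= 0, "`outlier_z` must be positive")
  check_graph_alignment(graph, table$unit_id)
  x <- table$values
  all_missing <- colSums(!is.na(x)) == 0
  abort_if(any(all_missing), "variable(s) entirely missing: ",
           paste(colnames(x)[all_missing], collapse = ", "))

  # (1) iterative adjacency-neighbor mean imputation
  if (anyNA(x)) {
    nb <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
    nb <- nb[table$unit_id, table$unit_id]
    for (round in seq_len(impute_max_rounds)) {
      miss <- is.na(x)
      if (!any(miss)) break
      obs <- !miss
      xz <- x; xz[miss] <- 0
      sums <- as.matrix(nb %*% xz)
      cnts <- as.matrix(nb %*% obs)
      fill <- miss & cnts > 0
      if (!any(fill)) break
      x[fill] <- (sums / pmax(cnts, 1))[fill]
    }
    if (anyNA(x)) {  # column-mean fallback for units with no observed neighbor
      cm <- colMeans(x, na.rm = TRUE)
      idx <- which(is.na(x), arr.ind = TRUE)
      x[idx] <- cm[idx[, 2]]
    }
  }

  # (2) winsorize at |z| > outlier_z
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  for (j in seq_len(ncol(x))) {
    if (s[j] == 0) next
    lo <- mu[j] - outlier_z * s[j]
    hi <- mu[j] + outlier_z * s[j]
    x[, j] <- pmin(pmax(x[, j], lo), hi)
  }

  # (3) standardize; drop constants
  s2 <- apply(x, 2, sd)
  const <- s2 == 0
  abort_if(all(const), "all variables are constant after cleaning")
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  out <- unit_table(x, themes = table$themes[colnames(x)], area = table$area)
  attr(out, "preprocess") <- list(outlier_z = outlier_z,
                                  impute_max_rounds = impute_max_rounds,
                                  variance_threshold = variance_threshold,
                                  whiten = whiten)
  out
}

#' Reduce a clean feature table to leading principal components
#'
#' Retains the minimal number of leading principal components whose
#' cumulative explained variance reaches `variance_threshold` (default 85%).
#' With `whiten = TRUE` (default) the retained scores are rescaled to unit
#' sample variance per component, so every retained axis contributes equally
#' to the Euclidean distances used downstream.
#'
#' @param table a cleaned, standardized [unit_table()] (no missing values).
#' @param variance_threshold cumulative explained-variance target in (0, 1].
#' @param whiten rescale retained scores to unit variance?
#' @return an object of class `feature_embedding`: `unit_id`, `scores`
#'   (n x m matrix), `explained_fraction` per retained component,
#'   `cumulative_fraction`, `whitened`.
#' @export
pca_reduce <- function(table, variance_threshold = 0.85, whiten = TRUE) {
  abort_if(variance_threshold <= 0 || variance_threshold > 1,
           "`variance_threshold` must be in (0, 1]")
  x <- table$values
  abort_if(nrow(x) < 2, "need at least 2 units for PCA")
  abort_if(anyNA(x), "feature table still has missing values; preprocess first")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  evar <- pc$sdev^2
  frac <- evar / sum(evar)
  m <- which(cumsum(frac) >= variance_threshold - 1e-12)[1]
  scores <- pc$x[, seq_len(m), drop = FALSE]
  if (whiten) {
    sds <- apply(scores, 2, sd)
    sds[sds == 0] <- 1
    scores <- sweep(scores, 2, sds, "/")
  }
  rownames(scores) <- table$unit_id
  structure(list(unit_id = table$unit_id,
                 scores = scores,
                 explained_fraction = frac[seq_len(m)],
                 cumulative_fraction = sum(frac[seq_len(m)]),
                 whitened = whiten,
                 rotation = pc$rotation[, seq_len(m), drop = FALSE]),
            class = "feature_embedding")
}

#' @export
print.feature_embedding <- function(x, ...) {
  cat(sprintf("<feature_embedding> %d units x %d components (%.1f%% variance%s)\n",
              nrow(x$scores), ncol(x$scores), 100 * x$cumulative_fraction,
              if (x$whitened) ", whitened" else ""))
  invisible(x)
}

check_graph_alignment <- function(graph, unit_ids) {
  vn <- igraph::V(graph)$name
  abort_if(is.null(vn), "adjacency graph must have named vertices")
  missing <- setdiff(unit_ids, vn)
  abort_if(length(missing) > 0, "graph lacks unit(s): ",
           paste(head(missing, 5), collapse = ", "))
  invisible(TRUE)
}
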