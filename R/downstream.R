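#' Random-forest Gini importance of variables for a regionalization
#'
#' Fits a seeded random-forest classifier predicting region labels from the
#' raw (pre-PCA, standardized) geospatial variables and reports each
#' variable's mean decrease in Gini impurity — the summed impurity reduction
#' over all splits on that variable across the forest's classification
#' trees — together with the out-of-bag (OOB) error. High importance marks
#' the variables that drive region formation; a near-zero OOB error means
#' the regions are sharply separable in variable space.
#'
#' @param table a [unit_table()] of raw standardized variables.
#' @param regionalization a [regionalization()] over the same units; `k >= 2`.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed.
#' @param region_set_id optional label naming the region set in the output.
#' @return an object of class `importance_table`: `variable_name`,
#'   `importance` (mean decrease in Gini, >= 0), `oob_error` between 0 and
#'   1, `n_trees`, `region_set_id`.
#' @export
region_variable_importance <- function(table, regionalization, n_trees = 500,
                                       seed = 1, region_set_id = "") {
  abort_if(regionalization$k < 2,
           "variable importance needs k >= 2 regions")
  x <- table$values[regionalization$unit_id, , drop = FALSE]
  abort_if(anyNA(x), "raw table has missing values; preprocess first")
  zerovar <- apply(x, 2, sd) == 0
  if (any(zerovar)) {
    warning("zero-variance variable(s) will score 0 importance: ",
            paste(colnames(x)[zerovar], collapse = ", "), call. = FALSE)
  }
  y <- factor(regionalization$label)
  fit <- with_seed(seed,
    randomForest::randomForest(x = as.data.frame(x), y = y,
                               ntree = n_trees))
  imp <- fit$importance[, "MeanDecreaseGini"]
  oob <- unname(fit$err.rate[n_trees, "OOB"])
  structure(list(variable_name = colnames(x),
                 importance = unname(imp[colnames(x)]),
                 oob_error = oob,
                 n_trees = as.integer(n_trees),
                 region_set_id = region_set_id),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  ord <- order(x$importance, decreasing = TRUE)
  cat(sprintf("<importance_table> %d variables, %d trees, OOB error %.3f\n",
              length(x$variable_name), x$n_trees, x$oob_error))
  top <- head(ord, 5)
  for (i in top)
    cat(sprintf("  %-24s %.3f\n", x$variable_name[i], x$importance[i]))
  invisible(x)
}

#' Partition a point response's variance within and among regions
#'
#' Joins each point (e.g. a lake) to a region through its containing spatial
#' unit, then decomposes the response's total sum of squares into
#' within-region (SSW) and among-region (SSB) parts over the occupied
#' regions. `among_fraction = SSB / (SSW + SSB)` is the share of variation
#' captured at the regional scale (the intraclass pattern the regions were
#' never trained on); it is invariant to affine transformation of the
#' response. Points with a missing response, and points in units absent
#' from the regionalization, are dropped with a message.
#'
#' @param responses a `response_table` (or data.frame with `point_id`,
#'   `unit_id` and response columns).
#' @param regionalization a [regionalization()].
#' @param response_name which response column to partition.
#' @return an object of class `response_partition`: `response_name`, `ssw`,
#'   `ssb`, `total_ss`, `ratio` (SSW:SSB), `among_fraction`, `n_points`,
#'   `k_occupied`.
#' @export
partition_response_variance <- function(responses, regionalization,
                                        response_name) {
  abort_if(!response_name %in% names(responses),
           "no response column named '", response_name, "'")
  reg <- setNames(regionalization$label, regionalization$unit_id)
  y <- responses[[response_name]]
  in_reg <- responses$unit_id %in% names(reg)
  n_out <- sum(!in_reg)
  if (n_out > 0)
    message(n_out, " point(s) in units outside the regionalization dropped")
  n_miss <- sum(is.na(y) & in_reg)
  if (n_miss > 0)
    message(n_miss, " point(s) with missing '", response_name, "' dropped")
  keep <- in_reg & !is.na(y)
  y <- y[keep]
  lab <- unname(reg[responses$unit_id[keep]])
  abort_if(length(y) < 2, "need at least 2 points with data")
  k_occ <- length(unique(lab))
  abort_if(k_occ < 2, "need at least 2 occupied regions")
  ss <- ss_decomposition(matrix(y, ncol = 1), lab)
  structure(list(response_name = response_name,
                 ssw = ss$ssw, ssb = ss$ssb, total_ss = ss$total_ss,
                 ratio = if (ss$ssb > 0) ss$ssw / ss$ssb else Inf,
                 among_fraction = if (ss$total_ss > 0) ss$ssb / ss$total_ss
                                  else 0,
                 n_points = length(y), k_occupied = k_occ),
            class = "response_partition")
}

#' @export
print.response_partition <- function(x, ...) {
  cat(sprintf(paste0("<response_partition> '%s': %d points over %d regions\n",
                     "  SSW = %.4g  SSB = %.4g  SSW:SSB = %.3g",
                     "  among-region fraction = %.1f%%\n"),
              x$response_name, x$n_points, x$k_occupied,
              x$ssw, x$ssb, x$ratio, 100 * x$among_fraction))
  invisible(x)
}
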