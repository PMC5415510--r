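#' Default k grid for the number-of-regions sweep
#'
#' Step 5 over 5-600, step 10 over 610-800, step 50 over 850-1000 — dense
#' where region counts are plausible, coarse where they are not.
#'
#' @return increasing integer vector.
#' @export
default_k_grid <- function() {
  c(seq(5L, 600L, by = 5L), seq(610L, 800L, by = 10L),
    seq(850L, 1000L, by = 50L))
}

# SSW for many labelings at once: SSW = total - SSB via group sums
ssw_by_labels <- function(x, labels, total = NULL, grand = NULL) {
  x <- as.matrix(x)
  grand <- grand %||% colMeans(x)
  total <- total %||% sum(sweep(x, 2, grand)^2)
  gs <- rowsum(x, labels)
  gn <- as.vector(rowsum(rep(1, nrow(x)), labels))
  ssb <- sum(rowSums(sweep(gs / gn, 2, grand)^2) * gn)
  total - ssb
}

#' SSW-versus-k curves for constrained clustering and the random null
#'
#' For each k in the grid, runs one spatially constrained spectral
#' clustering (at the given `delta`) and records its SSW, and averages the
#' SSW of `n_random` independent random regionalizations of the same units.
#' Both SSWs are computed in the same space (the embedding by default). The
#' Laplacian eigendecomposition is computed once at the largest k and
#' truncated per grid point. Grid values with k >= n are skipped with a
#' warning. All randomness derives from `seed`.
#'
#' The random-null mean is the yardstick: SSW decreases in k even for
#' meaningless clusterings (expected random-partition SSW is
#' `TotalSS * (n - k) / (n - 1)`), so only improvement beyond the null
#' indicates real structure.
#'
#' @param embedding `feature_embedding` or matrix with unit rownames.
#' @param graph adjacency graph.
#' @param delta neighborhood parameter for the constrained runs.
#' @param k_grid increasing integer grid (default [default_k_grid()]).
#' @param n_random random clusterings per k (default 200).
#' @param restarts_per_k k-means restarts inside the sweep; the default 20
#'   keeps sweeps tractable — raise toward 1000 for final analyses.
#' @param seed integer seed.
#' @param bandwidth optional Gaussian sigma.
#' @param space optional alternative matrix in which to score SSW.
#' @param restart_selection_space `"embedding"` keeps each k's best restart
#'   by the k-means objective; `"features"` (default here) re-scores
#'   restarts in the SSW-reporting space, which keeps the reported curve
#'   monotone-noise low — the quantity the slope ratio differentiates.
#' @return an object of class `k_selection_curve` with `k`, `ssw_ssc`,
#'   `ssw_random_mean` (slopes and selection fields unset until
#'   [select_optimal_k()]).
#' @export
ssw_vs_k_curves <- function(embedding, graph, delta, k_grid = default_k_grid(),
                            n_random = 200, restarts_per_k = 20, seed = 1,
                            bandwidth = NULL, space = NULL,
                            restart_selection_space = c("features",
                                                        "embedding")) {
  restart_selection_space <- match.arg(restart_selection_space)
  x <- embedding_scores(embedding)
  n <- nrow(x)
  abort_if(any(diff(k_grid) <= 0) || min(k_grid) < 2,
           "`k_grid` must be strictly increasing with min >= 2")
  abort_if(n_random < 2, "`n_random` must be >= 2")
  keep <- k_grid < n
  if (!all(keep)) {
    warning("skipping grid values with k >= n: ",
            paste(k_grid[!keep], collapse = ", "), call. = FALSE)
    k_grid <- k_grid[keep]
  }
  abort_if(length(k_grid) < 5, "need at least 5 usable grid points")
  sp <- if (is.null(space)) x else embedding_scores(space)[rownames(x), , drop = FALSE]
  grand <- colMeans(sp)
  total <- sum(sweep(sp, 2, grand)^2)

  check_graph_alignment(graph, rownames(x))
  Q <- build_constraint_matrix(graph, delta, rownames(x))
  sim <- build_feature_similarity(x, bandwidth = bandwidth, graph = graph)
  S <- combine_similarity(sim, Q)$S
  kmax <- max(k_grid)
  coords_all <- spectral_embed(S, kmax)

  seeds <- derive_seeds(seed, 2 * length(k_grid))
  ssw_ssc <- numeric(length(k_grid))
  ssw_rand <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    coords_k <- coords_all[, seq_len(k), drop = FALSE]
    fit <- if (restart_selection_space == "features")
      kmeans_best_in_space(coords_k, sp, k, restarts_per_k, seeds[2 * i - 1])
    else
      kmeans_min_ssw(coords_k, k, restarts_per_k, seeds[2 * i - 1])
    ssw_ssc[i] <- ssw_by_labels(sp, fit$labels, total, grand)
    ssw_rand[i] <- with_seed(seeds[2 * i], {
      mean(vapply(seq_len(n_random), function(r) {
        repeat {
          lab <- sample.int(k, n, replace = TRUE)
          if (length(unique(lab)) == k) break
        }
        ssw_by_labels(sp, lab, total, grand)
      }, numeric(1)))
    })
  }
  structure(list(k = k_grid, ssw_ssc = ssw_ssc, ssw_random_mean = ssw_rand,
                 total_ss = total, n = n,
                 params = list(delta = delta, n_random = n_random,
                               restarts_per_k = restarts_per_k, seed = seed,
                               bandwidth = sim$bandwidth)),
            class = "k_selection_curve")
}

#' Choose the number of regions by the windowed ratio of slopes
#'
#' Completes a [ssw_vs_k_curves()] object. Per consecutive grid pair the
#' slope is the finite difference `dSSW / dk` (normalized by grid spacing,
#' so non-uniform grids are handled). The slope ratio at grid point k
#' compares how fast the constrained curve is still dropping with how fast
#' the random-null curve drops over the interval ending at k:
#' `ratio(k) = Slope_ssc(k-1, k) / Slope_rand(k-1, k)`.
#' While the constrained clustering is still resolving real structure its
#' SSW falls much faster than random's, so the ratio starts well above 1;
#' once additional regions buy no more than random relabeling would, the
#' two curves fall in parallel and the ratio approaches 1. Because the
#' empirical ratio fluctuates — once real structure is exhausted it bounces
#' noisily around 1 — it is averaged over windows `[k - w/2, k + w/2]`
#' (window size w + 1 on a unit grid), and the chosen k is the first window
#' center, in ascending k, whose average ratio lies within `ratio_band` of
#' 1 without equaling it: the onset of the near-1 regime. (A global
#' "closest to 1" minimizer would land arbitrarily deep in the noisy
#' plateau; the onset is what marks the optimum, and is used as fallback
#' when no window enters the band.) The ratio for the interval
#' `[k, k_next]` is attributed to k — it measures the marginal gain of
#' going beyond k regions. Points with a (near-)zero random slope are
#' excluded from window averages.
#'
#' @param curve a `k_selection_curve` from [ssw_vs_k_curves()].
#' @param window_halfwidth w/2, in k units (default 10, i.e. window size 21).
#' @param ratio_band half-width of the acceptance band around 1 (default 1:
#'   a window average closer to 1 than to 0 or 2 counts as "near 1").
#' @return the curve with `slope_ssc`, `slope_random`, `slope_ratio`,
#'   `window_avg`, `chosen_k` and `chosen_window` filled in.
#' @export
select_optimal_k <- function(curve, window_halfwidth = 10, ratio_band = 1) {
  k <- curve$k
  m <- length(k)
  abort_if(m < 5, "curve must be populated on >= 5 grid points")
  abort_if(window_halfwidth < 1, "`window_halfwidth` must be >= 1")
  dk <- diff(k)
  slope_ssc <- diff(curve$ssw_ssc) / dk
  slope_rand <- diff(curve$ssw_random_mean) / dk

  # ratio of the interval [k_i, k_{i+1}] attributed to its lower end k_i
  tol <- 1e-12 * max(abs(slope_rand), 1e-300)
  ratio <- rep(NA_real_, m)
  ok <- abs(slope_rand) > tol
  ratio[seq_len(m - 1)[ok]] <- slope_ssc[ok] / slope_rand[ok]

  window_avg <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    inside <- which(abs(k - k[j]) <= window_halfwidth & !is.na(ratio))
    if (length(inside) > 0) window_avg[j] <- mean(ratio[inside])
  }
  cand <- which(!is.na(window_avg) & window_avg != 1)
  abort_if(length(cand) == 0,
           "curves indistinguishable from random: no informative window")
  in_band <- cand[abs(window_avg[cand] - 1) < ratio_band]
  best <- if (length(in_band) > 0) in_band[1]
          else cand[which.min(abs(window_avg[cand] - 1))]
  curve$slope_ssc <- slope_ssc
  curve$slope_random <- slope_rand
  curve$slope_ratio <- ratio
  curve$window_avg <- window_avg
  curve$window_halfwidth <- window_halfwidth
  curve$chosen_k <- k[best]
  curve$chosen_window <- c(k[best] - window_halfwidth,
                           k[best] + window_halfwidth)
  curve
}

#' @export
print.k_selection_curve <- function(x, ...) {
  cat(sprintf("<k_selection_curve> %d grid points over k = %d..%d\n",
              length(x$k), min(x$k), max(x$k)))
  if (!is.null(x$chosen_k))
    cat(sprintf("  chosen k = %d (window %d-%d, avg slope ratio %.4f)\n",
                x$chosen_k, x$chosen_window[1], x$chosen_window[2],
                x$window_avg[match(x$chosen_k, x$k)]))
  invisible(x)
}

selection_curve_frame <- function(curve) {
  m <- length(curve$k)
  pad <- function(v, at = "end") {
    if (is.null(v)) return(rep(NA_real_, m))
    if (length(v) == m) return(v)
    c(v, rep(NA_real_, m - length(v)))
  }
  data.frame(k = curve$k,
             ssw_ssc = curve$ssw_ssc,
             ssw_random_mean = curve$ssw_random_mean,
             slope_ssc = pad(curve$slope_ssc),
             slope_random = pad(curve$slope_random),
             slope_ratio = pad(curve$slope_ratio),
             window_avg = pad(curve$window_avg))
}
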