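#' Rook-adjacency lattice graph
#'
#' A rows x cols grid of square cells, adjacent when they share an edge —
#' the synthetic stand-in for a polygon contiguity graph.
#'
#' @param rows,cols lattice dimensions.
#' @return a named undirected igraph; vertex names are `"r<i>c<j>"`.
#' @export
lattice_graph <- function(rows, cols) {
  abort_if(rows < 1 || cols < 1, "lattice dimensions must be positive")
  ids <- outer(seq_len(rows), seq_len(cols),
               function(i, j) sprintf("r%dc%d", i, j))
  ids <- as.vector(t(ids))  # row-major
  at <- function(i, j) (i - 1) * cols + j
  from <- integer(0); to <- integer(0)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      if (j < cols) { from <- c(from, at(i, j)); to <- c(to, at(i, j + 1)) }
      if (i < rows) { from <- c(from, at(i, j)); to <- c(to, at(i + 1, j)) }
    }
  }
  g <- igraph::make_empty_graph(n = rows * cols, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  igraph::add_edges(g, rbind(from, to))
}

# contiguous planted regions: graph-Voronoi growth from k_true random seed
# cells — each unit joins the hop-nearest seed, ties to the lowest seed
# index, which guarantees every region is a connected subgraph
grow_regions <- function(graph, k_true) {
  n <- igraph::vcount(graph)
  abort_if(k_true > n, "`k_true` cannot exceed the number of units")
  seeds_v <- sample.int(n, k_true)
  d <- igraph::distances(graph, v = igraph::V(graph)[seeds_v])
  abort_if(any(!is.finite(d)),
           "graph is disconnected; cannot grow contiguous regions")
  lab <- apply(d, 2, which.min)  # ties -> lowest seed index
  abort_if(length(unique(lab)) < k_true, "degenerate Voronoi growth")
  as.integer(lab)
}

# deterministic equal rectangular blocks: k_true factored into the most
# nearly square br x bc grid of contiguous blocks (k = 4 gives quadrants)
block_regions <- function(rows, cols, k_true) {
  br <- floor(sqrt(k_true))
  while (k_true %% br != 0) br <- br - 1
  bc <- k_true %/% br
  if (rows < cols) { tmp <- br; br <- min(br, bc); bc <- max(tmp, bc) }
  abort_if(br > rows || bc > cols, "lattice too small for that many blocks")
  ri <- ceiling(seq_len(rows) / (rows / br))
  ci <- ceiling(seq_len(cols) / (cols / bc))
  lab <- outer(ri, ci, function(a, b) (a - 1L) * bc + b)
  as.integer(as.vector(t(lab)))
}

# k_true region mean vectors with (near-)equal pairwise separation `sep`,
# living on a random subset of informative feature axes
simplex_means <- function(k_true, informative, n_features, sep) {
  q <- length(informative)
  M <- matrix(0, k_true, n_features)
  if (k_true == 1 || sep == 0 || q == 0) return(M)
  A <- diag(k_true) - 1 / k_true        # centered simplex, pairwise dist sqrt(2)
  B <- svd(A)$u[, seq_len(k_true - 1), drop = FALSE] *
       rep(sqrt(svd(A)$d[seq_len(k_true - 1)]), each = k_true)
  B <- B * sep / sqrt(2)
  if (q >= k_true - 1) {
    R <- qr.Q(qr(matrix(rnorm(q * (k_true - 1)), q)))[, seq_len(k_true - 1),
                                                      drop = FALSE]
    M[, informative] <- B %*% t(R)
  } else {
    # fewer informative axes than k-1: best-effort projection
    M[, informative] <- B[, seq_len(q), drop = FALSE]
  }
  M
}

#' Generate a synthetic landscape with planted contiguous regions
#'
#' Builds a rook-adjacency lattice of spatial units, plants `k_true`
#' contiguous regions (irregular seeded-growth shapes by default, or exact
#' quadrants for deterministic tests), and draws themed features as
#' region-specific means plus Gaussian noise. Region mean vectors sit at
#' (near-)equal pairwise Euclidean separation `effect_size * noise_sd` on a
#' random half of the features within each theme (the informative subset);
#' the remaining features are pure noise. Optionally the noise is spatially
#' autocorrelated, and missing values and inflated outliers are injected at
#' the stated rates. Fully reproducible from `seed`.
#'
#' @param rows,cols lattice dimensions.
#' @param k_true number of planted regions.
#' @param n_features number of features.
#' @param theme_split three non-negative integers (terrestrial, climate,
#'   freshwater block sizes) summing to `n_features`; default splits evenly.
#' @param effect_size between-region mean separation in within-region SD
#'   units (0 = no region signal).
#' @param noise_sd within-region feature SD.
#' @param spatial_noise_range length scale (in cells) of autocorrelated
#'   noise; 0 (default) = white noise.
#' @param missing_rate,outlier_rate fraction of cells set missing / inflated
#'   to ~10 SD outliers.
#' @param region_mode `"growth"` (irregular Voronoi-style regions, default)
#'   or `"blocks"` (deterministic equal rectangular blocks; `k_true = 4`
#'   gives the four quadrants).
#' @param seed integer seed.
#' @return list with `table` (a [unit_table()]), `graph` (rook lattice
#'   igraph), and `truth` (the planted [regionalization()]).
#' @export
generate_landscape <- function(rows, cols, k_true, n_features = 10,
                               theme_split = NULL, effect_size = 3,
                               noise_sd = 1, spatial_noise_range = 0,
                               missing_rate = 0, outlier_rate = 0,
                               region_mode = c("growth", "blocks"),
                               seed = 1) {
  region_mode <- match.arg(region_mode)
  abort_if(effect_size < 0 || noise_sd <= 0,
           "`effect_size` must be >= 0 and `noise_sd` > 0")
  abort_if(missing_rate < 0 || missing_rate >= 1 ||
           outlier_rate < 0 || outlier_rate >= 1,
           "rates must lie in [0, 1)")
  theme_split <- theme_split %||% {
    base <- n_features %/% 3
    c(base, base, n_features - 2 * base)
  }
  abort_if(length(theme_split) != 3 || any(theme_split < 0) ||
           sum(theme_split) != n_features,
           "`theme_split` must be three non-negative counts summing to `n_features`")
  graph <- lattice_graph(rows, cols)
  n <- rows * cols
  ids <- igraph::V(graph)$name

  out <- with_seed(seed, {
    lab <- if (region_mode == "blocks") {
      block_regions(rows, cols, k_true)
    } else {
      grow_regions(graph, k_true)
    }

    themes <- rep(c("terrestrial", "climate", "freshwater"), theme_split)
    vars <- sprintf("%s_%02d", substr(themes, 1, 4), seq_len(n_features))
    # informative subset: a random half (>= 1) of each non-empty theme block,
    # widened round-robin to at least min(p, k_true - 1) features so the
    # planted simplex of region means can realize its pairwise separation
    informative <- integer(0)
    offset <- 0L
    for (b in theme_split) {
      if (b > 0) {
        take <- max(1L, b %/% 2L)
        informative <- c(informative, offset + sort(sample.int(b, take)))
      }
      offset <- offset + b
    }
    need <- min(n_features, k_true - 1L)
    if (length(informative) < need) {
      pool <- setdiff(seq_len(n_features), informative)
      informative <- sort(c(informative,
                            sample(pool, need - length(informative))))
    }
    M <- simplex_means(k_true, informative, n_features,
                       sep = effect_size * noise_sd)
    x <- M[lab, , drop = FALSE]
    if (spatial_noise_range > 0) {
      coord <- cbind(rep(seq_len(rows), each = cols), rep(seq_len(cols), rows))
      K <- exp(-rowdist2(coord, coord) / (2 * spatial_noise_range^2))
      for (f in seq_len(n_features)) {
        z <- as.vector(K %*% rnorm(n))
        x[, f] <- x[, f] + noise_sd * (z - mean(z)) / sd(z)
      }
    } else {
      x <- x + matrix(rnorm(n * n_features, sd = noise_sd), n, n_features)
    }
    if (outlier_rate > 0) {
      cells <- which(runif(n * n_features) < outlier_rate)
      if (length(cells) > 0) {
        cm <- colMeans(x)[((cells - 1) %/% n) + 1]
        x[cells] <- cm + sample(c(-1, 1), length(cells), replace = TRUE) *
          10 * noise_sd
      }
    }
    if (missing_rate > 0) {
      x[runif(n * n_features) < missing_rate] <- NA
    }
    dimnames(x) <- list(ids, vars)
    list(x = x, lab = lab, themes = setNames(themes, vars))
  })

  table <- unit_table(out$x, themes = out$themes)
  truth <- regionalization(ids, out$lab, k_true,
                           provenance = list(method = "planted", seed = seed,
                                             region_mode = region_mode,
                                             effect_size = effect_size))
  list(table = table, graph = graph, truth = truth)
}

#' Generate synthetic point responses with a target among-region variance
#'
#' Draws `n_points` points (e.g. lakes), places each in a spatial unit, and
#' generates `response = region_effect + residual` on a unit total-variance
#' scale: region effects are Gaussian with variance `f = among_fraction_true`
#' (the realized effects are centered and rescaled to that exact sample
#' variance, so the planted among-region share does not wander with the
#' effect draw), and the residual SD defaults to `sqrt(1 - f)`. With the
#' defaults the expected among-region share of the response's total sum of
#' squares, SSB/(SSW+SSB), equals `f`; with `f = 0` the response carries no
#' regional signal, and as `residual_sd` shrinks toward 0 the among-region
#' share tends to 1.
#'
#' @param regionalization the region labeling to condition on (e.g. a
#'   planted truth or a fitted regionalization).
#' @param n_points number of points (>= 2).
#' @param among_fraction_true target SSB share in [0, 1); also the
#'   region-effect variance on the unit-total-variance scale.
#' @param residual_sd residual (within-region) SD; default
#'   `sqrt(1 - among_fraction_true)`.
#' @param points_per_unit `"uniform"` (each point's unit drawn uniformly) or
#'   `"proportional"` (proportional to unit `area`, if available).
#' @param area optional positive weights per unit for `"proportional"`.
#' @param response_name name of the response column (default `"response"`).
#' @param seed integer seed.
#' @return a `response_table` data.frame: `point_id`, `unit_id`, response.
#' @export
generate_responses <- function(regionalization, n_points,
                               among_fraction_true = 0.4, residual_sd = NULL,
                               points_per_unit = c("uniform", "proportional"),
                               area = NULL, response_name = "response",
                               seed = 1) {
  points_per_unit <- match.arg(points_per_unit)
  abort_if(n_points < 2, "`n_points` must be >= 2")
  abort_if(among_fraction_true < 0 || among_fraction_true >= 1,
           "`among_fraction_true` must lie in [0, 1)")
  f <- among_fraction_true
  residual_sd <- residual_sd %||% sqrt(1 - f)
  abort_if(residual_sd <= 0, "`residual_sd` must be positive")
  sd_b <- sqrt(f)
  units <- regionalization$unit_id
  w <- if (points_per_unit == "proportional") {
    abort_if(is.null(area) || length(area) != length(units),
             "`proportional` allocation needs one positive `area` per unit")
    area / sum(area)
  } else NULL
  df <- with_seed(seed, {
    u <- sample(units, n_points, replace = TRUE, prob = w)
    b <- rnorm(regionalization$k, sd = sd_b)
    if (sd_b > 0 && regionalization$k >= 2 && sd(b) > 0) {
      b <- (b - mean(b)) / sd(b) * sd_b  # exact planted effect variance
    }
    lab <- regionalization$label[match(u, units)]
    y <- b[lab] + rnorm(n_points, sd = residual_sd)
    data.frame(point_id = sprintf("p%05d", seq_len(n_points)),
               unit_id = u, y = y, stringsAsFactors = FALSE)
  })
  names(df)[3] <- response_name
  class(df) <- c("response_table", "data.frame")
  df
}
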