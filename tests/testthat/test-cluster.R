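test_that("generalized eigenpairs match the nonsymmetric dense oracle", {
  set.seed(10)
  for (rep in 1:3) {
    S <- matrix(runif(64, 0.05, 1), 8)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    got <- laplacian_eigen(S, 8)
    orc <- gen_eigen_oracle(S)
    expect_equal(got$values, orc$values, tolerance = 1e-8)
    # vectors agree up to sign and scale, column by column
    for (j in 1:8) {
      v <- got$vectors[, j]; w <- orc$vectors[, j]
      w <- w * as.numeric(crossprod(v, w)) / sum(w^2)
      expect_equal(v, w, tolerance = 1e-6)
    }
  }
})

test_that("two-component affinity has a double zero eigenvalue with component-constant vectors", {
  set.seed(12)
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- 0.8
  S[4:6, 4:6] <- 0.6
  diag(S) <- 1
  e <- laplacian_eigen(S, 3)
  expect_equal(e$values[1:2], c(0, 0), tolerance = 1e-10)
  expect_gt(e$values[3], 1e-6)
  for (j in 1:2) {
    expect_lt(diff(range(e$vectors[1:3, j])), 1e-8)
    expect_lt(diff(range(e$vectors[4:6, j])), 1e-8)
  }
  # spectral_embed refuses the disconnected pattern outright
  expect_error(spectral_embed(S, 2), "connected components")
})

test_that("complete uniform graph has a constant first eigenvector at eigenvalue 0", {
  S <- matrix(0.5, 7, 7); diag(S) <- 1
  e <- laplacian_eigen(S, 1)
  expect_equal(e$values[1], 0, tolerance = 1e-12)
  expect_lt(diff(range(e$vectors[, 1])), 1e-10)
})

test_that("k-means degenerate cases: k = n and k = 1", {
  set.seed(14)
  x <- matrix(rnorm(14), 7)
  fit_n <- kmeans_min_ssw(x, 7, restarts = 3, seed = 1)
  expect_equal(fit_n$objective, 0)
  expect_equal(sort(fit_n$labels), 1:7)
  fit_1 <- kmeans_min_ssw(x, 1, restarts = 3, seed = 1)
  expect_equal(fit_1$objective, sum(scale(x, scale = FALSE)^2),
               tolerance = 1e-12)
})

test_that("multi-restart k-means attains the exhaustive minimum on 4 planted blobs", {
  set.seed(16)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  x <- centers[rep(1:4, each = 3), ] + matrix(rnorm(24, sd = 0.5), 12)
  fit <- kmeans_min_ssw(x, 4, restarts = 50, seed = 2)
  orc <- ssw_brute_min(x, 4)
  expect_equal(fit$objective, orc, tolerance = 1e-8)
  expect_equal(adjusted_rand_index(fit$labels, rep(1:4, each = 3)), 1)
})

test_that("best restart objective is non-increasing in the restart count", {
  set.seed(18)
  x <- matrix(rnorm(60), 20)
  objs <- vapply(c(1, 3, 10, 25), function(r)
    kmeans_min_ssw(x, 4, restarts = r, seed = 9)$objective, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("SSC recovers the cliques of a barbell graph (normalized-cut oracle)", {
  g <- barbell_graph(5)
  x <- matrix(0, 10, 2)  # uniform features: W is all-ones
  x <- x + 1
  rownames(x) <- igraph::V(g)$name
  reg <- cluster_regions(x, g, k = 2, method = "ssc", delta = 1,
                         restarts = 20, seed = 3)
  clique <- rep(1:2, each = 5)
  expect_equal(adjusted_rand_index(reg$label, clique), 1)
  # brute-force oracle: the cliques minimize normalized cut on Q
  Q <- as.matrix(build_constraint_matrix(g, 1)$Q)
  brute <- ncut_brute_2(Q)
  expect_equal(adjusted_rand_index(brute$labels, clique), 1)
  expect_equal(ncut_oracle(Q, reg$label), brute$ncut, tolerance = 1e-12)
})

test_that("SSC recovers planted quadrants on a lattice (ARI >= 0.9)", {
  land <- generate_landscape(20, 20, 4, n_features = 5, effect_size = 3,
                             region_mode = "blocks", seed = 7)
  clean <- preprocess_features(land$table, land$graph)
  emb <- pca_reduce(clean)
  reg <- cluster_regions(emb, land$graph, k = 4, method = "ssc", delta = 2,
                         restarts = 50, seed = 7)
  expect_gte(adjusted_rand_index(reg$label, land$truth$label), 0.9)
})

test_that("SSC with uniform features reduces to constraint-only SC", {
  g <- lattice_graph(4, 5)
  x <- matrix(1, 20, 3)
  rownames(x) <- igraph::V(g)$name
  ssc <- cluster_regions(x, g, k = 3, method = "ssc", delta = 1,
                         restarts = 20, seed = 4)
  sc <- cluster_regions(embedding = x, graph = g, k = 3, method = "sc",
                        delta = 1, restarts = 20, seed = 4)
  expect_equal(adjusted_rand_index(ssc$label, sc$label), 1)
})

test_that("random assignment is seeded, reproducible, and never empty", {
  r1 <- cluster_regions(graph = lattice_graph(2, 5), k = 3,
                        method = "random", seed = 11)
  r2 <- cluster_regions(graph = lattice_graph(2, 5), k = 3,
                        method = "random", seed = 11)
  expect_identical(r1$label, r2$label)
  expect_setequal(unique(r1$label), 1:3)
  r3 <- cluster_regions(graph = lattice_graph(2, 5), k = 3,
                        method = "random", seed = 12)
  expect_false(identical(r1$label, r3$label))
})

test_that("k-means clustering ignores the adjacency graph entirely", {
  set.seed(20)
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 6), 10))
  g1 <- lattice_graph(4, 5)
  rownames(x) <- igraph::V(g1)$name
  g2 <- path_graph(20)  # completely different edges, same vertex names
  k1 <- cluster_regions(x, g1, k = 2, method = "kmeans", restarts = 10,
                        seed = 5)
  k2 <- cluster_regions(x, g2, k = 2, method = "kmeans", restarts = 10,
                        seed = 5)
  expect_identical(k1$label, k2$label)
})

test_that("method and delta must be consistent", {
  g <- path_graph(4)
  x <- matrix(rnorm(8), 4)
  rownames(x) <- igraph::V(g)$name
  expect_error(cluster_regions(x, g, k = 2, method = "ssc"), "delta")
  expect_error(cluster_regions(x, g, k = 2, method = "kmeans", delta = 1),
               "does not take")
})

test_that("identical inputs and seed give identical regionalizations", {
  land <- generate_landscape(8, 8, 4, n_features = 4, effect_size = 3,
                             seed = 9)
  emb <- pca_reduce(preprocess_features(land$table, land$graph))
  for (m in c("ssc", "sc", "kmeans", "random")) {
    d <- if (m %in% c("ssc", "sc")) 1 else NULL
    a <- cluster_regions(emb, land$graph, k = 3, method = m, delta = d,
                         restarts = 5, seed = 21)
    b <- cluster_regions(emb, land$graph, k = 3, method = m, delta = d,
                         restarts = 5, seed = 21)
    expect_identical(a$label, b$label, info = m)
  }
})
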