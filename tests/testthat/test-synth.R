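test_that("lattice graphs have the right rook edge structure", {
  g <- lattice_graph(3, 4)
  expect_equal(igraph::vcount(g), 12)
  expect_equal(igraph::ecount(g), 3 * 3 + 2 * 4)  # horizontal + vertical
  expect_equal(igraph::diameter(lattice_graph(5, 5)), 8)
})

test_that("generated landscapes are reproducible and fully labeled", {
  a <- generate_landscape(6, 7, 3, n_features = 6, seed = 55)
  b <- generate_landscape(6, 7, 3, n_features = 6, seed = 55)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$truth$label, b$truth$label)
  c2 <- generate_landscape(6, 7, 3, n_features = 6, seed = 56)
  expect_false(identical(a$table$values, c2$table$values))
  expect_setequal(unique(a$truth$label), 1:3)
  expect_equal(unname(table(a$table$themes)[c("terrestrial", "climate",
                                              "freshwater")]),
               c(2L, 2L, 2L), ignore_attr = TRUE)
})

test_that("planted regions induce connected rook subgraphs", {
  for (seed in c(57, 58, 59)) {
    land <- generate_landscape(10, 10, 6, n_features = 4, seed = seed)
    for (r in 1:6) {
      members <- land$truth$unit_id[land$truth$label == r]
      sub <- igraph::induced_subgraph(land$graph, members)
      expect_equal(igraph::components(sub)$no, 1,
                   info = sprintf("seed %d region %d", seed, r))
    }
  }
  blocks <- generate_landscape(8, 8, 4, n_features = 4,
                               region_mode = "blocks", seed = 60)
  expect_equal(unname(table(blocks$truth$label)), rep(16L, 4),
               ignore_attr = TRUE)
})

test_that("missingness lands at the requested binomial rate", {
  land <- generate_landscape(20, 20, 4, n_features = 10,
                             missing_rate = 0.05, seed = 61)
  n_cells <- 400 * 10
  n_missing <- sum(is.na(land$table$values))
  se <- sqrt(n_cells * 0.05 * 0.95)
  expect_lt(abs(n_missing - n_cells * 0.05), 3 * se)
})

test_that("zero effect size leaves k-means at chance agreement with truth", {
  aris <- vapply(1:6, function(s) {
    land <- generate_landscape(10, 10, 4, n_features = 5, effect_size = 0,
                               seed = 70 + s)
    emb <- pca_reduce(preprocess_features(land$table, land$graph))
    km <- cluster_regions(emb, k = 4, method = "kmeans", restarts = 10,
                          seed = s)
    adjusted_rand_index(km$label, land$truth$label)
  }, numeric(1))
  se <- sd(aris) / sqrt(length(aris))
  expect_lt(abs(mean(aris)), max(3 * se, 0.02))
})

test_that("planted-recovery ARI is non-decreasing in effect size", {
  mean_ari <- vapply(c(0, 1, 3), function(eff) {
    mean(vapply(1:5, function(s) {
      land <- generate_landscape(12, 12, 4, n_features = 5,
                                 effect_size = eff, region_mode = "blocks",
                                 seed = 80 + s)
      emb <- pca_reduce(preprocess_features(land$table, land$graph))
      ssc <- cluster_regions(emb, land$graph, k = 4, method = "ssc",
                             delta = 2, restarts = 15, seed = s)
      adjusted_rand_index(ssc$label, land$truth$label)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ari) > -0.02))
  expect_gt(mean_ari[3], mean_ari[1])
})

test_that("generated responses hit the target among-region variance fraction", {
  land <- generate_landscape(25, 40, 50, n_features = 4, seed = 90)
  resp <- generate_responses(land$truth, 2000, among_fraction_true = 0.4,
                             residual_sd = sqrt(0.6), seed = 91)
  out <- partition_response_variance(resp, land$truth, "response")
  expect_gte(out$among_fraction, 0.35)
  expect_lte(out$among_fraction, 0.45)
  # the residual_sd -> 0 limit concentrates all variance among regions
  tight <- generate_responses(land$truth, 500, among_fraction_true = 0.4,
                              residual_sd = 1e-6, seed = 92)
  out2 <- partition_response_variance(tight, land$truth, "response")
  expect_gte(out2$among_fraction, 0.999)
})

test_that("zero among-fraction responses match the permutation null", {
  land <- generate_landscape(10, 10, 10, n_features = 3, seed = 93)
  fr <- vapply(1:5, function(s) {
    resp <- generate_responses(land$truth, 1000, among_fraction_true = 0,
                               seed = 200 + s)
    partition_response_variance(resp, land$truth, "response")$among_fraction
  }, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 9 / 999), max(3 * se, 0.01))
})

test_that("responses are reproducible and respect allocation weights", {
  land <- generate_landscape(5, 5, 3, n_features = 3, seed = 95)
  a <- generate_responses(land$truth, 100, seed = 96)
  b <- generate_responses(land$truth, 100, seed = 96)
  expect_identical(a, b)
  w <- c(1000, rep(1e-6, 24))
  skew <- generate_responses(land$truth, 200,
                             points_per_unit = "proportional",
                             area = w, seed = 97)
  expect_gt(mean(skew$unit_id == land$truth$unit_id[1]), 0.95)
})
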