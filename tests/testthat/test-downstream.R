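make_two_region_table <- function(n = 400, p = 10, sep = 4, seed = 40) {
  set.seed(seed)
  lab <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * p), n)
  x[, 1] <- x[, 1] + sep * (lab - 1)  # only v1 carries the regions
  x <- scale(x)
  rownames(x) <- paste0("u", seq_len(n))
  colnames(x) <- paste0("v", seq_len(p))
  list(table = unit_table(x),
       reg = regionalization(rownames(x), lab, 2))
}

test_that("the single informative variable ranks first with low OOB error", {
  fx <- make_two_region_table()
  imp <- region_variable_importance(fx$table, fx$reg, n_trees = 500,
                                    seed = 41)
  expect_equal(fx$table$unit_id, fx$reg$unit_id)
  expect_equal(imp$variable_name[which.max(imp$importance)], "v1")
  expect_lte(imp$oob_error, 0.05)
  expect_true(all(imp$importance >= 0))
  expect_equal(imp$n_trees, 500L)
})

test_that("a constant variable scores exactly zero importance", {
  fx <- make_two_region_table(n = 200, p = 5)
  vals <- cbind(fx$table$values, vconst = 0)
  tab <- unit_table(vals)
  expect_warning(
    imp <- region_variable_importance(tab, fx$reg, n_trees = 100, seed = 43),
    "zero-variance")
  expect_equal(imp$importance[imp$variable_name == "vconst"], 0)
})

test_that("importance is deterministic given the seed and requires k >= 2", {
  fx <- make_two_region_table(n = 100, p = 4)
  a <- region_variable_importance(fx$table, fx$reg, n_trees = 50, seed = 45)
  b <- region_variable_importance(fx$table, fx$reg, n_trees = 50, seed = 45)
  expect_identical(a$importance, b$importance)
  expect_identical(a$oob_error, b$oob_error)
  one <- regionalization(fx$table$unit_id, rep(1L, 100))
  expect_error(region_variable_importance(fx$table, one), "k >= 2")
})

test_that("permuted labels push OOB error to the majority-class rate", {
  set.seed(47)
  n <- 300
  x <- matrix(rnorm(n * 6), n)
  rownames(x) <- paste0("u", seq_len(n))
  colnames(x) <- paste0("v", 1:6)
  tab <- unit_table(x)
  lab <- rep(1:2, c(180, 120))  # majority-class error = 0.4
  errs <- vapply(1:5, function(r) {
    reg <- regionalization(rownames(x), sample(lab), 2)
    region_variable_importance(tab, reg, n_trees = 200,
                               seed = 100 + r)$oob_error
  }, numeric(1))
  se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs) - 0.4), max(3 * se, 0.06))
})

test_that("response variance partitions exactly for region-constant responses", {
  reg <- regionalization(paste0("u", 1:6), rep(1:3, each = 2))
  resp <- data.frame(point_id = paste0("p", 1:12),
                     unit_id = rep(paste0("u", 1:6), 2),
                     tp = rep(c(5, 5, 9, 9, 1, 1), 2))
  out <- partition_response_variance(resp, reg, "tp")
  expect_equal(out$among_fraction, 1)
  expect_equal(out$ssw, 0)
  expect_equal(out$k_occupied, 3)
  expect_equal(out$ssw + out$ssb, out$total_ss, tolerance = 1e-12)
})

test_that("among-region fraction is invariant to affine response transforms", {
  land <- generate_landscape(6, 6, 4, n_features = 3, effect_size = 2,
                             seed = 49)
  resp <- generate_responses(land$truth, 300, among_fraction_true = 0.3,
                             seed = 50)
  a <- partition_response_variance(resp, land$truth, "response")
  resp2 <- resp
  resp2$response <- 3.7 * resp$response - 11
  b <- partition_response_variance(resp2, land$truth, "response")
  expect_equal(b$among_fraction, a$among_fraction, tolerance = 1e-12)
  expect_equal(b$ratio, a$ratio, tolerance = 1e-12)
})

test_that("merging two regions never increases the response SSB", {
  set.seed(51)
  reg <- regionalization(paste0("u", 1:30),
                         sample(rep(1:5, each = 6)), 5)
  resp <- data.frame(point_id = paste0("p", 1:90),
                     unit_id = sample(paste0("u", 1:30), 90, replace = TRUE),
                     y = rnorm(90))
  full <- partition_response_variance(resp, reg, "y")
  merged_lab <- reg$label
  merged_lab[merged_lab == 5L] <- 4L
  merged <- regionalization(reg$unit_id, merged_lab, 4)
  out <- partition_response_variance(resp, merged, "y")
  expect_lte(out$ssb, full$ssb + 1e-10)
  expect_equal(out$total_ss, full$total_ss, tolerance = 1e-10)
})

test_that("permuted responses give the null among-fraction (k-1)/(n-1)", {
  set.seed(53)
  n <- 2000
  reg <- regionalization(paste0("u", 1:100),
                         c(1:10, sample.int(10, 90, replace = TRUE)), 10)
  fr <- vapply(1:5, function(r) {
    resp <- data.frame(point_id = paste0("p", 1:n),
                       unit_id = sample(paste0("u", 1:100), n,
                                        replace = TRUE),
                       y = rnorm(n))
    partition_response_variance(resp, reg, "y")$among_fraction
  }, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 9 / (n - 1)), max(3 * se, 0.01))
})

test_that("points with missing responses or unknown units are dropped, not fatal", {
  reg <- regionalization(paste0("u", 1:4), c(1L, 1L, 2L, 2L))
  resp <- data.frame(point_id = paste0("p", 1:6),
                     unit_id = c("u1", "u2", "u3", "u4", "zz", "u1"),
                     y = c(1, 2, 3, 4, 5, NA))
  expect_message(expect_message(
    out <- partition_response_variance(resp, reg, "y"),
    "outside the regionalization"), "missing")
  expect_equal(out$n_points, 4)
})
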