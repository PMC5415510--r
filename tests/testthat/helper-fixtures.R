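# Shared fixtures and independent oracles. All fixtures are built in code;
# oracles deliberately avoid the code paths they check.

# small unit table with ids u1..un
toy_table <- function(values, themes = NULL) {
  rownames(values) <- paste0("u", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("v", seq_len(ncol(values)))
  unit_table(values, themes = themes)
}

# path graph u1 - u2 - ... - un
path_graph <- function(n) {
  ids <- paste0("u", seq_len(n))
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::set_vertex_attr(g, "name", value = ids)
}

# barbell: two m-cliques joined by a single bridge edge
barbell_graph <- function(m = 5) {
  ids <- paste0("u", seq_len(2 * m))
  el <- NULL
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    el <- rbind(el, c(i, j), c(m + i, m + j))
  }
  el <- rbind(el, c(m, m + 1))
  g <- igraph::make_empty_graph(2 * m, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  igraph::add_edges(g, t(el))
}

# oracle: total/within/between SS by direct per-element loops
ss_oracle <- function(x, lab) {
  x <- as.matrix(x)
  grand <- colMeans(x)
  tot <- 0; ssw <- 0; ssb <- 0
  for (i in seq_len(nrow(x))) tot <- tot + sum((x[i, ] - grand)^2)
  for (l in unique(lab)) {
    rows <- which(lab == l)
    mu <- colMeans(x[rows, , drop = FALSE])
    for (i in rows) ssw <- ssw + sum((x[i, ] - mu)^2)
    ssb <- ssb + length(rows) * sum((mu - grand)^2)
  }
  list(total = tot, ssw = ssw, ssb = ssb)
}

# oracle: normalized cut of a labeling on affinity S
ncut_oracle <- function(S, lab) {
  S <- as.matrix(S)
  d <- rowSums(S)
  tot <- 0
  for (l in unique(lab)) {
    inl <- lab == l
    tot <- tot + sum(S[inl, !inl]) / sum(d[inl])
  }
  tot
}

# oracle: minimum normalized cut over all 2-partitions of n <= ~15 nodes
ncut_brute_2 <- function(S) {
  n <- nrow(S)
  best <- Inf; best_lab <- NULL
  for (code in 1:(2^(n - 1) - 1)) {  # fix node 1 in part 1; skip empty part
    lab <- c(1L, 1L + as.integer(intToBits(code)[1:(n - 1)]))
    v <- ncut_oracle(S, lab)
    if (v < best) { best <- v; best_lab <- lab }
  }
  list(ncut = best, labels = best_lab)
}

# oracle: exact minimum SSW over all partitions of n points into at most k
# blocks (equals the exactly-k minimum when n > k and splitting helps, as
# any split cannot increase SSW). Enumerates all k^(n-1) labelings with
# point 1 fixed in block 1, vectorized in chunks:
# SSW = sum_j x_j^2 - sum_blocks (block sum)^2 / block size, per dimension.
ssw_brute_min <- function(x, k, chunk = 2^16) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k^(n - 1) <= 2^24)
  total_codes <- k^(n - 1)
  sq <- sum(x^2)
  best <- Inf
  start <- 0
  while (start < total_codes) {
    m <- min(chunk, total_codes - start)
    codes <- start + seq_len(m) - 1
    L <- matrix(0L, m, n)
    for (j in 2:n) L[, j] <- as.integer((codes %/% k^(j - 2)) %% k)
    ssb_like <- numeric(m)
    for (b in 0:(k - 1)) {
      M <- (L == b)
      nb <- rowSums(M)
      s2 <- numeric(m)
      for (d in seq_len(ncol(x))) s2 <- s2 + (M %*% x[, d])^2
      ok <- nb > 0
      ssb_like[ok] <- ssb_like[ok] + s2[ok] / nb[ok]
    }
    best <- min(best, sq - max(ssb_like))
    start <- start + m
  }
  best
}

# oracle: generalized eigenpairs of L u = lambda D u via the nonsymmetric
# solver on D^{-1} L (independent route from the package's symmetric one)
gen_eigen_oracle <- function(S) {
  S <- as.matrix(S)
  d <- rowSums(S)
  L <- diag(d) - S
  e <- eigen(diag(1 / d) %*% L)
  ord <- order(Re(e$values))
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}

write_tmp_csv <- function(df, dir = tempdir(), name = "x.csv") {
  p <- file.path(dir, name)
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE, na = "")
  p
}

# analytic curve pair with a known change point: the constrained curve
# drops `pre` times faster than the (linear) random-null curve up to k*,
# then `post` times as fast; slope ratios are exactly pre / post by design
analytic_curve <- function(k_grid, k_star, n = 576, total = 1000,
                           pre = 40, post = 0.98) {
  rand <- total * (n - k_grid) / (n - 1)
  slope <- -total / (n - 1)
  ssc <- numeric(length(k_grid))
  ssc[1] <- total
  for (i in 2:length(k_grid)) {
    mult <- if (k_grid[i] <= k_star) pre else post
    ssc[i] <- ssc[i - 1] + mult * slope * (k_grid[i] - k_grid[i - 1])
  }
  structure(list(k = k_grid, ssw_ssc = ssc, ssw_random_mean = rand,
                 total_ss = total, n = n, params = list()),
            class = "k_selection_curve")
}
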