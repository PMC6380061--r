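test_that("pearson_cor matches direct evaluation of the Pearson formula", {
  expr <- random_expr(3, 5, seed = 21)
  cc <- pearson_cor(expr)
  # hand-coded formula oracle
  pear <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cc[i, j], pear(expr[i, ], expr[j, ]), tolerance = 1e-12)
  }
  expect_equal(diag(cc), setNames(rep(1, 3), rownames(expr)))
})

test_that("duplicated and negated genes hit the correlation extremes", {
  base <- random_expr(1, 6, seed = 2)
  expr <- rbind(a = base[1, ], b = base[1, ], c = -base[1, ])
  colnames(expr) <- colnames(base)
  cc <- pearson_cor(expr)
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
})

test_that("pearson_cor guards its preconditions", {
  expr <- random_expr(4, 2)
  expect_error(pearson_cor(expr), "3 samples")
  expr2 <- random_expr(4, 5)
  expr2[2, ] <- 7  # constant gene
  expect_warning(cc <- pearson_cor(expr2), "zero-variance")
  expect_equal(nrow(cc), 3)
})

test_that("two genes with k = 1 give a single undirected edge", {
  expr <- random_expr(2, 5, seed = 5)
  net <- build_rank_network(pearson_cor(expr), k = 1)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::graph_attr(net, "selection_count"), 2)
  expect_equal(igraph::E(net)$selected_by, "both")
})

test_that("rank network equals a brute-force all-pairs oracle", {
  expr <- random_expr(30, 12, seed = 31)
  cc <- pearson_cor(expr)
  net <- build_rank_network(cc, k = 3)
  # oracle: sort every row's partners by |r| then gene ID, take 3, union
  oracle_edges <- character(0)
  for (g in rownames(cc)) {
    others <- setdiff(rownames(cc), g)
    o <- others[order(-abs(cc[g, others]), others)][1:3]
    oracle_edges <- c(oracle_edges,
                      paste(pmin(g, o), pmax(g, o), sep = "|"))
  }
  oracle_edges <- sort(unique(oracle_edges))
  el <- igraph::as_edgelist(net)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
  expect_equal(got, oracle_edges)
})

test_that("network construction is invariant to gene order", {
  expr <- random_expr(25, 10, seed = 8)
  cc1 <- pearson_cor(expr)
  set.seed(99); perm <- sample(nrow(expr))
  cc2 <- pearson_cor(expr[perm, ])
  canon <- function(net) {
    el <- igraph::as_edgelist(net)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
  }
  expect_equal(canon(build_rank_network(cc1, k = 4)),
               canon(build_rank_network(cc2, k = 4)))
})

test_that("every gene selects exactly k partners and mean degree lies in [k, 2k]", {
  for (seed in 1:3) {
    expr <- random_expr(60, 15, seed = seed)
    k <- 5
    net <- build_rank_network(pearson_cor(expr), k = k)
    qc <- network_qc(net)
    expect_equal(qc$selection_count, 60 * k)
    expect_gte(qc$mean_neighbors, k)
    expect_lte(qc$mean_neighbors, 2 * k)
    expect_true(qc$union_edge_count <= qc$selection_count)
    expect_equal(qc$mean_neighbors, 2 * qc$union_edge_count / qc$node_count)
  }
})

test_that("k out of range is rejected", {
  expr <- random_expr(10, 5)
  cc <- pearson_cor(expr)
  expect_error(build_rank_network(cc, k = 10), "smaller than")
  expect_error(build_rank_network(cc, k = 0), "positive")
})

test_that("signed ranking prefers positive correlations", {
  set.seed(14)
  x <- rnorm(20)
  expr <- rbind(a = x, b = x + rnorm(20, sd = 0.1), c = -x + rnorm(20, sd = 0.05),
                d = rnorm(20), e = rnorm(20))
  colnames(expr) <- paste0("s", 1:20)
  cc <- pearson_cor(expr)
  net_abs <- build_rank_network(cc, k = 1, ranking = "absolute")
  net_sgn <- build_rank_network(cc, k = 1, ranking = "signed")
  nb_abs <- igraph::neighbors(net_abs, "a")$name
  nb_sgn <- igraph::neighbors(net_sgn, "a")$name
  expect_true("c" %in% nb_abs || "b" %in% nb_abs)
  expect_false(identical(nb_sgn, "c"))  # anti-correlated partner not chosen
})

test_that("an exact power-law degree histogram fits with R-squared 1", {
  degrees <- rep(c(1, 2, 3, 6), c(36, 9, 4, 1))  # counts = 36/d^2
  fit <- powerlaw_fit(degrees = degrees)
  expect_true(fit$applicable)
  expect_equal(fit$powerlaw_r2, 1, tolerance = 1e-12)
  expect_equal(fit$powerlaw_correlation, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -2, tolerance = 1e-10)
})

test_that("a regular graph has no usable degree spectrum", {
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- paste0("r", 1:10)
  fit <- powerlaw_fit(ring)
  expect_false(fit$applicable)
  expect_true(is.na(fit$powerlaw_r2))
})

test_that("a preferential-attachment network looks scale-free", {
  set.seed(42)
  g <- igraph::sample_pa(2000, m = 5, directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(2000))
  fit <- powerlaw_fit(g)
  expect_true(fit$applicable)
  expect_gte(fit$powerlaw_r2, 0.8)
})
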