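test_that("probe rows mapping to one gene are averaged per sample", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe\ts1\ts2",
               "p1\t1\t3",
               "p2\t3\t5",
               "p3\t7\t9"), f)
  pm <- c(p1 = "G", p2 = "G", p3 = "H")
  mat <- read_expression(f, probe_map = pm)
  expect_equal(mat["G", ], c(s1 = 2, s2 = 4))
  expect_equal(mat["H", ], c(s1 = 7, s2 = 9))  # single probe passes through
})

test_that("probe averaging is invariant to probe row order and matches a brute-force average", {
  set.seed(11)
  n_probe <- 9
  vals <- matrix(round(rnorm(n_probe * 4), 3), nrow = n_probe,
                 dimnames = list(paste0("p", 1:n_probe), paste0("s", 1:4)))
  pm <- setNames(rep(c("gA", "gB", "gC"), each = 3), rownames(vals))
  write_fixture <- function(m) {
    f <- tempfile(fileext = ".csv")
    df <- data.frame(probe = rownames(m), m, check.names = FALSE)
    write.table(df, f, sep = ",", quote = FALSE, row.names = FALSE)
    f
  }
  m1 <- read_expression(write_fixture(vals), probe_map = pm)
  perm <- sample(n_probe)
  m2 <- read_expression(write_fixture(vals[perm, ]), probe_map = pm)
  expect_equal(m1, m2)
  # independent oracle: per-gene column means via tapply
  for (g in c("gA", "gB", "gC")) {
    for (s in colnames(vals)) {
      expect_equal(m1[g, s],
                   unname(tapply(vals[, s], pm, mean)[g]))
    }
  }
})

test_that("expression validation enforces the matrix invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(read_expression(f), "duplicate gene IDs")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "g1\t1\toops", "g2\t3\t4"), f2)
  expect_error(read_expression(f2), "row 'g1', column 's2'")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "g1\t1\tNA", "g2\t3\t4"), f3)
  expect_message(m <- read_expression(f3), "1 genes with missing values")
  expect_equal(rownames(m), "g2")
})

test_that("expression and clinical tables round-trip through write/read", {
  mat <- random_expr(20, 6, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(mat, f)
  expect_equal(read_expression(f), mat)

  cl <- random_clinical(10, seed = 4)
  fc <- withr::local_tempfile(fileext = ".csv")
  write_clinical(cl, fc)
  back <- read_clinical(fc)
  expect_equal(back$sample, cl$sample)
  expect_equal(back$time, cl$time, tolerance = 1e-12)
  expect_equal(back$event, cl$event)
})

test_that("clinical validation rejects bad times and event codes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,time,event", "S1,120,1"), f)
  cl <- read_clinical(f)
  expect_equal(cl$time, 120)
  expect_equal(cl$event, 1L)

  writeLines(c("sample,time,event", "S1,120,2"), f)
  expect_error(read_clinical(f), "event status")
  writeLines(c("sample,time,event", "S1,-3,1"), f)
  expect_error(read_clinical(f), "non-negative")
})

test_that("sample alignment keeps the intersection of matrix and clinical samples", {
  mat <- random_expr(5, 6)
  cl <- random_clinical(8)  # s001..s008; matrix has s001..s006
  expect_message(al <- align_samples(mat, cl), "dropped")
  expect_equal(colnames(al$expr), al$clinical$sample)
  expect_setequal(colnames(al$expr), paste0("s00", 1:6))
})

test_that("graph export round-trips structure and attributes", {
  tri <- named_clique(3)
  igraph::E(tri)$pearson_r <- c(0.9, -0.5, 0.2)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(tri, f, "graphml")
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 3)
  expect_equal(sort(igraph::E(back)$pearson_r), sort(c(0.9, -0.5, 0.2)))

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  fe <- withr::local_tempfile(fileext = ".gml")
  export_graph(empty, fe, "gml")
  expect_equal(igraph::vcount(igraph::read_graph(fe, format = "gml")), 0)

  expect_error(export_graph(tri, f, "dot"), "arg")
})

test_that("a random attributed graph survives a graphml round trip isomorphically", {
  set.seed(7)
  g <- igraph::sample_gnp(50, 0.1)
  igraph::V(g)$name <- sprintf("n%02d", 1:50)
  igraph::E(g)$p_value <- runif(igraph::ecount(g))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml")
  back <- igraph::read_graph(f, format = "graphml")
  expect_true(igraph::isomorphic(g, back))
  key <- function(gr) {
    el <- igraph::as_edgelist(gr)
    o <- order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    cbind(pmin(el[, 1], el[, 2])[o], pmax(el[, 1], el[, 2])[o],
          round(igraph::E(gr)$p_value[o], 10))
  }
  expect_equal(key(g), key(back))
})

test_that("edge list export writes two name columns", {
  tri <- named_clique(3)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_graph(tri, f, "edgelist")
  el <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(dim(el), c(3, 2))
  expect_setequal(unlist(el), paste0("v", 1:3))
})
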