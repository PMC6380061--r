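make_mods <- function(genes_list, coefs) {
  mods <- data.frame(module_id = seq_along(genes_list), score = 1,
                     n_genes = lengths(genes_list))
  mods$genes <- genes_list
  prof <- data.frame(module_id = mods$module_id,
                     sig_frequency = 10L, n_rep = 10L,
                     mean_coefficient = coefs,
                     initial_importance = 1)
  list(mods = mods, prof = prof)
}

test_that("risk scores are the signed sum of module statistics", {
  expr <- random_expr(10, 6, seed = 71)
  gl <- list(rownames(expr)[1:3], rownames(expr)[4:6])
  mp <- make_mods(gl, c(0.8, -0.5))
  rs <- risk_scores(expr, mp$mods, mp$prof)
  sA <- module_statistic(expr, gl[[1]])
  sB <- module_statistic(expr, gl[[2]])
  expect_equal(rs, sA - sB)

  one <- make_mods(gl[1], 1.2)
  expect_equal(risk_scores(expr, one$mods, one$prof), sA)

  # five modules with random signs against an independently coded signed sum
  gl5 <- split(rownames(expr), rep(1:5, each = 2))
  coefs <- c(0.3, -0.1, 0.7, -2, 0.01)
  mp5 <- make_mods(unname(gl5), coefs)
  oracle <- rep(0, ncol(expr))
  for (i in 1:5) {
    oracle <- oracle + sign(coefs[i]) * colMeans(expr[gl5[[i]], ])
  }
  expect_equal(unname(risk_scores(expr, mp5$mods, mp5$prof)), unname(oracle))
  expect_error(risk_scores(expr, mp5$mods[0, ], mp5$prof), "empty")
})

test_that("a risk score tracking true event order separates the groups", {
  set.seed(72)
  n <- 60
  t_ev <- sort(rexp(n, 0.1), decreasing = TRUE)  # longest survivors first
  cl <- data.frame(sample = sprintf("s%03d", 1:n), time = t_ev,
                   event = 1L)
  scores <- setNames(seq_len(n), cl$sample)  # highest score = shortest time
  # perfect separation makes the group HR diverge; that warning is expected
  st <- suppressWarnings(split_and_test(scores, cl))
  expect_lt(st$logrank_p, 1e-6)
  expect_gt(st$hazard_ratio, 1)
  expect_equal(sum(st$group == "high"), 30)
})

test_that("identical survival in both groups gives a null log-rank statistic", {
  times <- rep(c(2, 4, 6, 8, 10), 2)
  cl <- data.frame(sample = sprintf("s%03d", 1:10), time = times, event = 1L)
  # top half by score = first 5 samples = one copy of each event time
  scores <- setNames(c(10:6, 5:1), cl$sample)
  st <- split_and_test(scores, cl)
  expect_equal(st$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(st$logrank_p, 1, tolerance = 1e-10)
})

test_that("group assignment is invariant under increasing score transforms; odd n favors low", {
  cl <- random_clinical(25, seed = 73)
  set.seed(74)
  scores <- setNames(rnorm(25), cl$sample)
  s1 <- split_and_test(scores, cl)
  s2 <- split_and_test(exp(scores) + 5, cl)
  expect_identical(s1$group, s2$group)
  expect_equal(s1$logrank_p, s2$logrank_p)
  expect_equal(sum(s1$group == "high"), 12)  # floor(25/2), extra to low
  expect_error(split_and_test(setNames(rep(1, 25), cl$sample), cl),
               "identical")
})

test_that("the log-rank p-value matches a textbook hand computation", {
  cl <- random_clinical(18, seed = 75)
  set.seed(76)
  scores <- setNames(rnorm(18), cl$sample)
  st <- split_and_test(scores, cl)
  # independent oracle: standard two-group log-rank chi-square
  grp <- st$group[cl$sample]
  ev_times <- sort(unique(cl$time[cl$event == 1]))
  O <- E <- V <- 0
  for (tt in ev_times) {
    at_risk <- cl$time >= tt
    n1 <- sum(at_risk & grp == "high"); n0 <- sum(at_risk)
    d <- sum(cl$time == tt & cl$event == 1)
    d1 <- sum(cl$time == tt & cl$event == 1 & grp == "high")
    O <- O + d1
    E <- E + d * n1 / n0
    if (n0 > 1) V <- V + d * (n1 / n0) * (1 - n1 / n0) * (n0 - d) / (n0 - 1)
  }
  chisq <- (O - E)^2 / V
  expect_equal(st$logrank_chisq, chisq, tolerance = 1e-8)
  expect_equal(st$logrank_p, pchisq(chisq, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("the discrimination score follows its defining arithmetic", {
  expect_equal(dscore(1), 0)
  expect_equal(dscore(c(0.1, 0.01)), 3)
  p <- c(0.2, 0.05, 0.001)
  expect_equal(dscore(p), sum(vapply(p, dscore, numeric(1))))  # additive
  expect_gt(dscore(c(0.01, 0.5)), dscore(c(0.02, 0.5)))        # decreasing
  expect_error(dscore(c(0.5, 0)), "0, 1")
  expect_error(dscore(1.2), "0, 1")
  expect_error(dscore(numeric(0)), "at least one")
})

test_that("random-gene-set baseline: degenerate observed score and determinism", {
  cfg <- synth_config(n_genes = 80, n_samples = 120, module_sizes = 10L,
                      beta = 0.9, censoring_rate = 0.2, seed = 81)
  dat <- generate_synthetic(cfg)
  ds <- list(d1 = list(expr = dat$expr, clinical = dat$clinical))
  r0 <- random_geneset_test(ds, gene_count = 10, observed_dscore = 0,
                            n_sets = 20, seed = 1)
  expect_equal(r0$p_value, 1)  # every Dscore is >= 0
  r1 <- random_geneset_test(ds, gene_count = 10, observed_dscore = 2,
                            n_sets = 20, seed = 2)
  r2 <- random_geneset_test(ds, gene_count = 10, observed_dscore = 2,
                            n_sets = 20, seed = 2)
  expect_identical(r1, r2)
  expect_error(random_geneset_test(ds, gene_count = 1000, 1, n_sets = 2),
               "exceeds")
})

test_that("a planted prognostic module beats random gene sets", {
  cfg <- synth_config(n_genes = 150, n_samples = 250, module_sizes = 12L,
                      beta = 1, censoring_rate = 0.3, seed = 82)
  dat <- generate_synthetic(cfg)
  ds <- list(d1 = list(expr = dat$expr, clinical = dat$clinical))
  mp <- make_mods(list(dat$truth$membership$M1), 1)
  ev <- evaluate_modules(ds, mp$mods, mp$prof)
  res <- random_geneset_test(ds, gene_count = 12,
                             observed_dscore = ev$dscore,
                             n_sets = 100, seed = 3)
  expect_lte(res$p_value, 0.05)
})
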