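# Fixtures built in code: tiny graphs, matrices and survival tables shared
# across the suite.

# genes x samples matrix of iid noise with deterministic names
random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples),
         nrow = n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

named_clique <- function(n, prefix = "v") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

# exponential survival independent of everything, fixed seed
random_clinical <- function(n, seed = 1, censor = 0.3) {
  set.seed(seed)
  t_ev <- rexp(n, 0.1)
  cens <- runif(n, 0, quantile(t_ev, 0.9) * (1 - censor) / censor * 1.5)
  data.frame(sample = sprintf("s%03d", seq_len(n)),
             time = pmin(t_ev, cens),
             event = as.integer(t_ev <= cens),
             stringsAsFactors = FALSE)
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a), as.character(b))
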