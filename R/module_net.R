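# Module cross-talk network: inter-module edge counts tested against a
# random-gene-set permutation null.

#' Count edges crossing two disjoint gene sets
#'
#' @param network Co-expression network (igraph).
#' @param genes_a,genes_b Disjoint character vectors of gene IDs, all present
#'   in the network.
#' @return Integer edge count with one endpoint in each set.
#' @export
count_cross_edges <- function(network, genes_a, genes_b) {
  if (length(intersect(genes_a, genes_b)) > 0)
    stop("gene sets must be disjoint")
  miss <- setdiff(c(genes_a, genes_b), igraph::V(network)$name)
  if (length(miss) > 0)
    stop("genes absent from the network: ", paste(head(miss, 3), collapse = ", "))
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  as.integer(sum(A[genes_a, genes_b, drop = FALSE]))
}

cross_count_idx <- function(A, ia, ib) {
  sum(A[ia, ib, drop = FALSE])
}

# dense adjacency is far faster to subset for the permutation loop and is
# affordable at desk scale; fall back to sparse for large networks
adjacency_for_perms <- function(network) {
  if (igraph::vcount(network) <= 3000) {
    as.matrix(igraph::as_adjacency_matrix(network, sparse = TRUE))
  } else {
    igraph::as_adjacency_matrix(network, sparse = TRUE)
  }
}

#' Permutation test for cross-talk between two modules
#'
#' The observed count of co-expression edges between the two modules is
#' compared with the counts between `n_perm` pairs of random disjoint gene
#' sets of the same sizes, drawn uniformly from the network's nodes. The
#' p-value uses the permutation-inclusive estimator
#' `(1 + #(null >= observed)) / (n_perm + 1)`, so it is always in (0, 1].
#'
#' @param network Co-expression network (igraph).
#' @param genes_a,genes_b Disjoint gene sets (the two modules).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional RNG seed.
#' @return List: `cross_edge_count`, `p_value`, `null_mean`.
#' @export
crosstalk_pvalue <- function(network, genes_a, genes_b, n_perm = 1000,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- adjacency_for_perms(network)
  nm <- igraph::V(network)$name
  na <- length(genes_a); nb <- length(genes_b)
  if (na + nb > length(nm))
    stop("combined module size exceeds the network's node count")
  obs <- count_cross_edges(network, genes_a, genes_b)
  null <- perm_null_counts(A, na, nb, n_perm)
  list(cross_edge_count = obs,
       p_value = (1 + sum(null >= obs)) / (n_perm + 1),
       null_mean = mean(null))
}

perm_null_counts <- function(A, na, nb, n_perm) {
  n <- nrow(A)
  vapply(seq_len(n_perm), function(r) {
    idx <- sample.int(n, na + nb)
    cross_count_idx(A, idx[seq_len(na)], idx[na + seq_len(nb)])
  }, numeric(1))
}

#' Build the module cross-talk network
#'
#' Every unordered module pair is permutation-tested; pairs with p below
#' `alpha` (optionally after Benjamini-Hochberg adjustment) become edges of
#' the module network. All modules appear as nodes, including isolated ones.
#'
#' @param network Co-expression network (igraph).
#' @param modules Module data frame from [detect_modules()].
#' @param n_perm Permutations per pair (default 1000).
#' @param alpha Significance level for an edge (default 0.05).
#' @param seed Optional RNG seed making the whole network reproducible.
#' @param p_adjust `"none"` (default, raw p < alpha) or `"BH"`.
#' @return igraph whose vertices are module IDs (as characters); edges carry
#'   `cross_edge_count` and `p_value`. Graph attributes: `mean_neighbors`,
#'   `n_perm`, `alpha`, and the all-pairs table `pair_tests`.
#' @export
build_module_network <- function(network, modules, n_perm = 1000,
                                 alpha = 0.05, seed = NULL,
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  m <- nrow(modules)
  if (m < 2) stop("need at least 2 modules")
  if (!is.null(seed)) set.seed(seed)
  A <- adjacency_for_perms(network)
  nm <- igraph::V(network)$name
  idx_of <- lapply(modules$genes, function(g) match(g, nm))
  pairs <- utils::combn(m, 2)
  res <- apply(pairs, 2, function(pr) {
    ia <- idx_of[[pr[1]]]; ib <- idx_of[[pr[2]]]
    obs <- cross_count_idx(A, ia, ib)
    null <- perm_null_counts(A, length(ia), length(ib), n_perm)
    c(obs = obs, p = (1 + sum(null >= obs)) / (n_perm + 1))
  })
  tab <- data.frame(module_a = modules$module_id[pairs[1, ]],
                    module_b = modules$module_id[pairs[2, ]],
                    cross_edge_count = as.integer(res["obs", ]),
                    p_value = res["p", ])
  tab$p_used <- if (p_adjust == "BH") stats::p.adjust(tab$p_value, "BH") else tab$p_value
  sig <- tab$p_used < alpha
  edges <- data.frame(from = as.character(tab$module_a[sig]),
                      to = as.character(tab$module_b[sig]),
                      cross_edge_count = tab$cross_edge_count[sig],
                      p_value = tab$p_value[sig],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = as.character(modules$module_id)))
  igraph::graph_attr(g, "mean_neighbors") <- 2 * igraph::ecount(g) / m
  igraph::graph_attr(g, "n_perm") <- n_perm
  igraph::graph_attr(g, "alpha") <- alpha
  igraph::graph_attr(g, "pair_tests") <- tab
  g
}
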