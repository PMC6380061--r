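# MCODE-style dense-module detection: vertex weighting by the highest k-core
# of the closed neighborhood, greedy seeded growth, haircut, size filter.

#' MCODE vertex weights
#'
#' For each vertex v, the induced subgraph of v's closed neighborhood
#' (v plus its neighbors) is reduced to its highest k-core; the vertex weight
#' is that core's k multiplied by the core's edge density. Vertices whose
#' neighborhood core falls below `degree_cutoff` (and isolated vertices)
#' get weight 0.
#'
#' @param network Simple undirected igraph.
#' @param degree_cutoff Minimum core level for a non-zero weight (default 2).
#' @return Named numeric vector of weights (>= 0), one per vertex.
#' @export
mcode_vertex_weights <- function(network, degree_cutoff = 2) {
  stopifnot(igraph::is_igraph(network))
  n <- igraph::vcount(network)
  w <- setNames(numeric(n), igraph::V(network)$name)
  if (n == 0) return(w)
  nbrs <- igraph::adjacent_vertices(network, igraph::V(network))
  for (i in seq_len(n)) {
    nb <- as.integer(nbrs[[i]])
    if (length(nb) == 0) next
    vs <- c(i, nb)
    sub <- igraph::induced_subgraph(network, vs)
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    if (kmax < degree_cutoff) next
    core_sub <- igraph::induced_subgraph(sub, which(cores >= kmax))
    m <- igraph::vcount(core_sub)
    dens <- if (m > 1) igraph::ecount(core_sub) / (m * (m - 1) / 2) else 0
    w[i] <- kmax * dens
  }
  w
}

#' Detect dense modules (MCODE-style)
#'
#' Seeds are taken in descending vertex weight (ties by gene ID). From each
#' unconsumed seed with positive weight, the complex grows outward over
#' neighbors whose weight is at least `seed_weight * (1 - node_score_cutoff)`.
#' With `haircut`, the grown complex is trimmed to its 2-core (iteratively
#' removing degree-1 members). All grown vertices are consumed, so modules are
#' vertex-disjoint. Modules smaller than `min_size` are discarded. Each
#' module's score is the density of its induced subgraph times its size.
#'
#' @param network Simple undirected igraph.
#' @param node_score_cutoff Growth tolerance in (0,1) (default 0.2).
#' @param haircut Trim the complex to its 2-core (default TRUE).
#' @param fluff Fluff expansion is not supported; must be FALSE.
#' @param min_size Minimum module size after trimming (default 5).
#' @param degree_cutoff Passed to [mcode_vertex_weights()].
#' @return Data frame: `module_id`, `score`, `n_genes`, and list column
#'   `genes` (sorted gene IDs), ordered by score descending, ties by
#'   smallest gene ID.
#' @export
detect_modules <- function(network, node_score_cutoff = 0.2, haircut = TRUE,
                           fluff = FALSE, min_size = 5, degree_cutoff = 2) {
  if (isTRUE(fluff))
    stop("fluff expansion (overlapping modules) is not supported")
  stopifnot(igraph::is_igraph(network))
  n <- igraph::vcount(network)
  empty <- data.frame(module_id = integer(0), score = numeric(0),
                      n_genes = integer(0))
  empty$genes <- list()
  if (n == 0) return(empty)
  w <- mcode_vertex_weights(network, degree_cutoff)
  names_v <- igraph::V(network)$name
  nbrs <- igraph::adjacent_vertices(network, igraph::V(network))
  consumed <- logical(n)
  seed_order <- order(-w, names_v)
  found <- list()
  for (s in seed_order) {
    if (consumed[s] || w[s] <= 0) next
    thr <- w[s] * (1 - node_score_cutoff)
    members <- s
    consumed[s] <- TRUE
    frontier <- s
    while (length(frontier) > 0) {
      cand <- unique(unlist(lapply(frontier, function(v) as.integer(nbrs[[v]]))))
      cand <- cand[!consumed[cand] & w[cand] >= thr]
      if (length(cand) == 0) break
      consumed[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    sub <- igraph::induced_subgraph(network, members)
    if (haircut) {
      core <- igraph::coreness(sub)
      keep <- core >= 2
      if (!any(keep)) next
      sub <- igraph::induced_subgraph(sub, which(keep))
    }
    m <- igraph::vcount(sub)
    if (m < min_size) next
    dens <- if (m > 1) igraph::ecount(sub) / (m * (m - 1) / 2) else 0
    found[[length(found) + 1]] <- list(genes = sort(igraph::V(sub)$name),
                                       score = dens * m)
  }
  if (length(found) == 0) return(empty)
  scores <- vapply(found, `[[`, numeric(1), "score")
  first_gene <- vapply(found, function(f) f$genes[1], character(1))
  ord <- order(-scores, first_gene)
  out <- data.frame(module_id = seq_along(ord),
                    score = scores[ord],
                    n_genes = vapply(found[ord], function(f) length(f$genes),
                                     integer(1)))
  out$genes <- lapply(found[ord], `[[`, "genes")
  out
}

#' Write / read a module table
#'
#' Modules are stored as TSV with a comma-joined gene list column, the format
#' emitted by the pipeline driver.
#'
#' @param modules Module data frame from [detect_modules()].
#' @param path Output path.
#' @export
write_modules <- function(modules, path) {
  df <- data.frame(module_id = modules$module_id,
                   score = modules$score,
                   n_genes = modules$n_genes,
                   genes = vapply(modules$genes, paste, character(1),
                                  collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules
#' @param path Path of a module TSV.
#' @export
read_modules <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- df[, c("module_id", "score", "n_genes")]
  out$genes <- strsplit(df$genes, ",", fixed = TRUE)
  out
}
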