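# Hypergeometric over-representation of module genes in annotation lists
# (cancer genes, drug targets, gene-age classes, ...).

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least `x` annotated genes among the
#' `K` query genes, drawing from a universe of `M` genes of which `N` are
#' annotated:
#' `p = 1 - sum_{i=0}^{x-1} choose(K, i) * choose(M-K, N-i) / choose(M, N)`.
#' The annotation list is intersected with the universe before testing; the
#' query must be a subset of the universe.
#'
#' @param query Character vector of query genes (e.g. all genes of the
#'   selected modules).
#' @param annotation Character vector of annotated genes.
#' @param universe Character vector defining the universe (e.g. all genes of
#'   the co-expression network).
#' @return List: `x` (overlap), `M`, `K`, `N`, `p_value`.
#' @export
hypergeom_test <- function(query, annotation, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) stop("universe is empty")
  if (length(query) == 0) stop("query is empty")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  annotation <- intersect(unique(annotation), universe)
  M <- length(universe)
  K <- length(query)
  N <- length(annotation)
  x <- length(intersect(query, annotation))
  p <- phyper(x - 1, K, M - K, N, lower.tail = FALSE)
  list(x = x, M = M, K = K, N = N, p_value = min(1, p))
}

#' Test several annotation lists at once
#'
#' @param query Query gene set.
#' @param annotations Named list of annotation gene vectors.
#' @param universe Universe gene set.
#' @return Data frame with one row per annotation list: `list_name`, `x`,
#'   `M`, `K`, `N`, `p_value`.
#' @export
test_enrichment <- function(query, annotations, universe) {
  nm <- names(annotations) %||% paste0("list", seq_along(annotations))
  rows <- lapply(seq_along(annotations), function(i) {
    r <- hypergeom_test(query, annotations[[i]], universe)
    data.frame(list_name = nm[i], x = r$x, M = r$M, K = r$K, N = r$N,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read an annotation gene list (one gene ID per line)
#'
#' @param path Plain-text file, one gene per line.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
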