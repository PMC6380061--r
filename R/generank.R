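# GeneRank prioritization: PageRank-with-prior over the module network, with
# the resampling significance frequency as the prior.

#' Solve the GeneRank system
#'
#' Computes module importances r satisfying
#' `(I - d W^T D^-1) r = (1 - d) p`, where W is the symmetric 0/1 adjacency
#' of the module network, D the diagonal of neighbor counts and p the prior
#' (initial importance) vector. Equivalently, the fixed point of the Jacobi
#' iteration `r_j <- (1 - d) p_j + d * sum_i w_ij r_i / degree_i`. Isolated
#' modules (degree 0) contribute nothing to the sum (0-safe division) and
#' settle at `(1 - d) p_j` plus whatever they receive - i.e. nothing.
#'
#' @param W Symmetric 0/1 adjacency matrix, zero diagonal.
#' @param prior Non-negative prior vector (length = number of modules).
#' @param d Damping constant in \[0, 1); larger d weights network structure
#'   more, smaller d the prior (default 0.70).
#' @param method `"direct"` (dense linear solve, default) or `"jacobi"`.
#' @param tol Convergence/accuracy tolerance (default 1e-10).
#' @param max_iter Jacobi iteration cap (default 10000).
#' @return Numeric vector r, named like `prior`/rows of W.
#' @export
generank <- function(W, prior, d = 0.7, method = c("direct", "jacobi"),
                     tol = 1e-10, max_iter = 10000) {
  method <- match.arg(method)
  W <- as.matrix(W)
  n <- nrow(W)
  if (!isTRUE(all.equal(W, t(W), tolerance = 0, check.attributes = FALSE)))
    stop("adjacency matrix must be symmetric")
  if (any(diag(W) != 0)) stop("adjacency matrix must have a zero diagonal")
  if (length(prior) != n) stop("prior length must match the adjacency dimension")
  if (any(prior < 0)) stop("prior must be non-negative")
  if (d < 0 || d >= 1) stop("d must be in [0, 1)")
  deg <- colSums(W)
  invdeg <- ifelse(deg > 0, 1 / deg, 0)
  M <- t(W * invdeg)             # M[j, i] = w_ij / degree_i
  r <- if (method == "direct") {
    as.vector(solve(diag(n) - d * M, (1 - d) * prior))
  } else {
    cur <- as.numeric(prior)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      nxt <- (1 - d) * prior + d * as.vector(M %*% cur)
      if (max(abs(nxt - cur)) < tol) { cur <- nxt; ok <- TRUE; break }
      cur <- nxt
    }
    if (!ok) stop("Jacobi did not converge within max_iter; try method = 'direct'")
    cur
  }
  names(r) <- rownames(W) %||% names(prior)
  r
}

#' Rank modules by GeneRank over the module network
#'
#' Builds W from the module network, takes each module's
#' `initial_importance` (significance frequency / n_rep) as the prior, and
#' returns the profile table augmented with the GeneRank importance `r` and
#' the rank order.
#'
#' @param module_network igraph from [build_module_network()].
#' @param profiles Profile data frame from [profile_all()].
#' @param d,method,tol,max_iter Passed to [generank()].
#' @return `profiles` with added columns `r` and `rank` (1 = most important),
#'   rows sorted by rank. Ties in `r` are broken by higher
#'   `initial_importance`, then by `module_id`.
#' @export
generank_modules <- function(module_network, profiles, d = 0.7,
                             method = c("direct", "jacobi"), tol = 1e-10,
                             max_iter = 10000) {
  ids <- as.character(profiles$module_id)
  vn <- igraph::V(module_network)$name
  if (!setequal(ids, vn))
    stop("module network vertices and profile module_ids must coincide")
  W <- as.matrix(igraph::as_adjacency_matrix(module_network))[ids, ids]
  W[W > 1] <- 1
  r <- generank(W, profiles$initial_importance, d = d, method = method,
                tol = tol, max_iter = max_iter)
  out <- profiles
  out$r <- as.numeric(r)
  ord <- order(-out$r, -out$initial_importance, out$module_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-ranked modules
#'
#' Selects the top fraction of modules by GeneRank importance. The count is
#' `fraction * n` rounded half-up, with a floor of 1 (so 258 modules at 5%
#' give 13, 150 give 8, 181 give 9). A `count` override replaces the
#' fraction rule.
#'
#' @param ranked Ranked data frame from [generank_modules()].
#' @param fraction Fraction of modules to keep (default 0.05).
#' @param count Optional explicit number of modules to keep.
#' @return Vector of selected `module_id`s, best first.
#' @export
select_top <- function(ranked, fraction = 0.05, count = NULL) {
  n <- nrow(ranked)
  if (is.null(count)) {
    if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
    count <- top_fraction_count(n, fraction)
  }
  if (count < 1 || count > n) stop("selection count out of range")
  ranked$module_id[seq_len(count)]
}

#' Round-half-up selection count
#'
#' `floor(fraction * n + 0.5)` with a floor of 1; the rounding convention
#' that reproduces top-5% counts such as 258 -> 13, 150 -> 8, 181 -> 9.
#'
#' @param n Number of modules.
#' @param fraction Selection fraction.
#' @return Integer count >= 1.
#' @export
top_fraction_count <- function(n, fraction) {
  max(1L, as.integer(floor(fraction * n + 0.5)))
}

#' Select control modules by resampling rank alone
#'
#' Baseline that ignores the module network: the `count` modules with the
#' highest significance frequency (ties by larger absolute mean coefficient,
#' then by module_id).
#'
#' @param profiles Profile data frame from [profile_all()].
#' @param count Number of modules to select.
#' @return Vector of selected `module_id`s.
#' @export
select_control <- function(profiles, count) {
  if (count <= 0) stop("count must be positive")
  if (count > nrow(profiles)) stop("count exceeds the number of modules")
  ord <- order(-profiles$sig_frequency, -abs(profiles$mean_coefficient),
               profiles$module_id)
  profiles$module_id[ord][seq_len(count)]
}
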