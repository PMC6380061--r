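# Risk scoring with selected modules, equal-split stratification, log-rank /
# hazard-ratio evaluation, the discrimination score, and the random-gene-set
# permutation baseline.

#' Per-sample risk scores from selected modules
#'
#' Risk score = sum of the statistics of modules with a positive mean Cox
#' coefficient minus the sum for modules with a negative one. A coefficient
#' of exactly 0 is treated as positive (with a message).
#'
#' @param expr Expression matrix.
#' @param modules Module data frame (rows restricted to the selected
#'   modules).
#' @param profiles Profile data frame ([profile_all()]) supplying
#'   `mean_coefficient` per module.
#' @return Named numeric vector of risk scores, one per sample.
#' @export
risk_scores <- function(expr, modules, profiles) {
  if (nrow(modules) == 0) stop("selected module set is empty")
  coefs <- profiles$mean_coefficient[match(modules$module_id,
                                           profiles$module_id)]
  if (any(is.na(coefs))) stop("every selected module needs a mean_coefficient")
  if (any(coefs == 0)) message("mean coefficient exactly 0 treated as positive")
  sgn <- ifelse(coefs >= 0, 1, -1)
  stats_mat <- vapply(modules$genes, function(g) module_statistic(expr, g),
                      numeric(ncol(expr)))
  setNames(as.vector(stats_mat %*% sgn), colnames(expr))
}

#' Split patients into equal risk groups and test survival separation
#'
#' Samples are sorted by risk score descending (ties by sample ID); the top
#' half is the high-risk group (with odd n the extra sample goes to the
#' low-risk group). Separation is tested by the two-sample log-rank test
#' (1 df chi-square) and summarized by the hazard ratio of high vs low from
#' a univariate Cox fit on the group indicator.
#'
#' @param scores Named per-sample risk scores.
#' @param clinical Clinical data frame.
#' @return List: `group` (named character vector "high"/"low"), `logrank_p`,
#'   `logrank_chisq`, `hazard_ratio`, `n`.
#' @export
split_and_test <- function(scores, clinical) {
  common <- intersect(names(scores), clinical$sample)
  if (length(common) < 4) stop("need at least 4 samples")
  cl <- clinical[match(common, clinical$sample), ]
  x <- scores[common]
  if (length(unique(x)) == 1)
    stop("all risk scores identical; cannot stratify")
  ord <- order(-x, names(x))
  n <- length(x)
  n_high <- floor(n / 2)
  group <- setNames(rep("low", n), names(x))
  group[ord[seq_len(n_high)]] <- "high"
  if (sum(cl$event[group == "high"]) < 1 || sum(cl$event[group == "low"]) < 1)
    stop("each risk group needs at least one observed event")
  gf <- factor(group, levels = c("low", "high"))
  sdf <- survival::survdiff(survival::Surv(cl$time, cl$event) ~ gf)
  p <- pchisq(sdf$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(cl$time, cl$event) ~ gf)
  list(group = group,
       logrank_p = p,
       logrank_chisq = unname(sdf$chisq),
       hazard_ratio = unname(exp(stats::coef(cx))),
       n = n)
}

#' Discrimination score across data sets
#'
#' `Dscore = -sum(log10(p_i))` over per-data-set log-rank p-values: the
#' aggregate stratification strength of a module set across cohorts. Strictly
#' decreasing in each p and additive over data sets.
#'
#' @param p_values Numeric vector of p-values, each in (0, 1].
#' @return Non-negative Dscore.
#' @export
dscore <- function(p_values) {
  if (length(p_values) == 0) stop("need at least one p-value")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  -sum(log10(p_values))
}

#' Evaluate selected modules on one or more data sets
#'
#' Computes risk scores, splits, and tests each data set, then aggregates the
#' log-rank p-values into a Dscore.
#'
#' @param datasets List of `list(expr = , clinical = )` pairs.
#' @param modules Selected module data frame.
#' @param profiles Profile data frame with `mean_coefficient`.
#' @return List: `per_dataset` data frame (`dataset`, `n`, `hazard_ratio`,
#'   `logrank_p`) and `dscore`.
#' @export
evaluate_modules <- function(datasets, modules, profiles) {
  nm <- names(datasets) %||% paste0("dataset", seq_along(datasets))
  rows <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    rs <- risk_scores(ds$expr, modules, profiles)
    st <- split_and_test(rs, ds$clinical)
    data.frame(dataset = nm[i], n = st$n, hazard_ratio = st$hazard_ratio,
               logrank_p = st$logrank_p, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_dataset = per, dscore = dscore(per$logrank_p))
}

#' Random-gene-set permutation baseline for a Dscore
#'
#' Draws `n_sets` random gene sets of size `gene_count`, scores each as a
#' single positive module (risk score = the set's mean-expression statistic),
#' evaluates it on every data set and aggregates into a Dscore. The returned
#' permutation p-value is `(1 + #(random Dscore >= observed)) / (n_sets + 1)`.
#'
#' @param datasets List of `list(expr = , clinical = )` pairs; genes are
#'   drawn from the genes common to all data sets.
#' @param gene_count Size of each random gene set.
#' @param observed_dscore Dscore of the modules under evaluation.
#' @param n_sets Number of random sets (default 1000).
#' @param seed Optional RNG seed.
#' @return List: `p_value`, `null_dscores`, `observed`.
#' @export
random_geneset_test <- function(datasets, gene_count, observed_dscore,
                                n_sets = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- Reduce(intersect, lapply(datasets, function(d) rownames(d$expr)))
  if (gene_count > length(pool))
    stop("gene_count exceeds the number of genes shared by the data sets")
  null <- vapply(seq_len(n_sets), function(i) {
    genes <- sample(pool, gene_count)
    ps <- vapply(datasets, function(ds) {
      s <- module_statistic(ds$expr, genes)
      split_and_test(s, ds$clinical)$logrank_p
    }, numeric(1))
    dscore(ps)
  }, numeric(1))
  list(p_value = (1 + sum(null >= observed_dscore)) / (n_sets + 1),
       null_dscores = null,
       observed = observed_dscore)
}
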