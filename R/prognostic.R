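# Per-module summary statistic (mean expression across member genes) and its
# prognostic stability under resampled univariate Cox regression.

#' Module summary statistic
#'
#' Per-sample arithmetic mean of the expression of the module's genes.
#' Module genes missing from the matrix are dropped with a warning; an empty
#' effective gene set is an error.
#'
#' @param expr Expression matrix, genes x samples.
#' @param genes Character vector of the module's gene IDs.
#' @return Named numeric vector, one value per sample.
#' @export
module_statistic <- function(expr, genes) {
  present <- genes %in% rownames(expr)
  if (!all(present)) {
    warning(sum(!present), " module genes missing from the expression matrix")
    genes <- genes[present]
  }
  if (length(genes) == 0) stop("no module genes present in the matrix")
  colMeans(expr[genes, , drop = FALSE])
}

# one univariate Efron-ties Cox fit through the low-overhead backend;
# Wald p from coef/se (identical to summary(coxph(...)))
fit_cox_once <- function(time, event, x) {
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      matrix(x, ncol = 1), survival::Surv(time, event),
      strata = NULL, offset = NULL, init = NULL,
      control = survival::coxph.control(), weights = NULL,
      method = "efron", rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$coefficients))
    return(c(coef = NA_real_, p = NA_real_))
  co <- unname(fit$coefficients[1])
  se <- sqrt(fit$var[1, 1])
  if (!is.finite(co) || !is.finite(se) || se <= 0)
    return(c(coef = NA_real_, p = NA_real_))
  c(coef = co, p = 2 * stats::pnorm(-abs(co / se)))
}

resample_index_sets <- function(n, n_rep, sample_fraction) {
  m <- floor(sample_fraction * n)
  if (m < 2) stop("resampled subset too small")
  lapply(seq_len(n_rep), function(i) sample.int(n, m))
}

#' Prognostic profile of one module by resampled Cox regression
#'
#' In each of `n_rep` repetitions, `floor(sample_fraction * n)` samples are
#' drawn without replacement and a univariate Cox model of survival on the
#' module statistic is fitted. The significance frequency (number of
#' repetitions with Wald p below `cox_alpha`) measures prognostic stability;
#' the mean coefficient over converged fits gives the module's effect sign.
#' Non-converged fits count as non-significant and are excluded from the
#' mean, with their tally reported.
#'
#' @param stat Named per-sample module statistic ([module_statistic()]).
#' @param clinical Clinical data frame (`sample`, `time`, `event`).
#' @param n_rep Repetitions (default 400).
#' @param sample_fraction Fraction drawn per repetition (default 0.9).
#' @param cox_alpha Per-fit significance level (default 0.05).
#' @param seed Optional RNG seed.
#' @param index_sets Optional precomputed list of index vectors (used by
#'   [profile_all()] to share resamples across modules).
#' @return List: `sig_frequency`, `n_rep`, `mean_coefficient`,
#'   `initial_importance` (= sig_frequency / n_rep), `n_failed`, `valid`.
#' @export
resample_cox <- function(stat, clinical, n_rep = 400, sample_fraction = 0.9,
                         cox_alpha = 0.05, seed = NULL, index_sets = NULL) {
  common <- intersect(names(stat), clinical$sample)
  if (length(common) < 20) stop("need at least 20 samples for resampled Cox")
  cl <- clinical[match(common, clinical$sample), ]
  if (sum(cl$event) < 2) stop("need at least 2 observed events")
  x <- stat[common]
  if (is.null(index_sets)) {
    if (!is.null(seed)) set.seed(seed)
    index_sets <- resample_index_sets(length(common), n_rep, sample_fraction)
  }
  fits <- vapply(index_sets, function(idx) {
    fit_cox_once(cl$time[idx], cl$event[idx], x[idx])
  }, c(coef = 0, p = 0))
  failed <- is.na(fits["p", ])
  sig <- sum(fits["p", !failed] < cox_alpha)
  list(sig_frequency = as.integer(sig),
       n_rep = length(index_sets),
       mean_coefficient = if (all(failed)) NA_real_ else mean(fits["coef", !failed]),
       initial_importance = sig / length(index_sets),
       n_failed = as.integer(sum(failed)),
       valid = !all(failed))
}

#' Prognostic profiles for all modules
#'
#' Runs [resample_cox()] for every module. The same resampled index sets are
#' shared across modules within a repetition, so significance frequencies are
#' comparable module to module under identical data perturbations. With a
#' fixed seed the result is bit-reproducible.
#'
#' @param expr Expression matrix (training samples).
#' @param modules Module data frame from [detect_modules()].
#' @param clinical Clinical data frame.
#' @inheritParams resample_cox
#' @return Data frame: `module_id`, `sig_frequency`, `n_rep`,
#'   `mean_coefficient`, `initial_importance`, `n_failed`.
#' @export
profile_all <- function(expr, modules, clinical, n_rep = 400,
                        sample_fraction = 0.9, cox_alpha = 0.05, seed = NULL) {
  if (nrow(modules) == 0) {
    return(data.frame(module_id = integer(0), sig_frequency = integer(0),
                      n_rep = integer(0), mean_coefficient = numeric(0),
                      initial_importance = numeric(0), n_failed = integer(0)))
  }
  al <- align_samples(expr, clinical)
  common <- colnames(al$expr)
  if (!is.null(seed)) set.seed(seed)
  index_sets <- resample_index_sets(length(common), n_rep, sample_fraction)
  rows <- lapply(seq_len(nrow(modules)), function(i) {
    s <- module_statistic(al$expr, modules$genes[[i]])
    pr <- resample_cox(s, al$clinical, n_rep = n_rep,
                       sample_fraction = sample_fraction,
                       cox_alpha = cox_alpha, index_sets = index_sets)
    data.frame(module_id = modules$module_id[i],
               sig_frequency = pr$sig_frequency,
               n_rep = pr$n_rep,
               mean_coefficient = pr$mean_coefficient,
               initial_importance = pr$initial_importance,
               n_failed = pr$n_failed)
  })
  do.call(rbind, rows)
}
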