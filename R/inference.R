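# Second-order inference: model-data RDM correspondence, permutation
# null over condition labelings, sign-flip model comparison, and FDR.

upper_cells <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

# Kendall's tau-a: pair-count statistic without tie correction in the
# denominator; appropriate when one vector (a categorical model RDM) is
# heavily tied.
kendall_tau_a <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  ut <- upper.tri(dx)
  sum(dx[ut] * dy[ut]) / (n * (n - 1) / 2)
}

second_order_cor <- function(dvec, mvec, method) {
  switch(method,
         spearman = stats::cor(dvec, mvec, method = "spearman"),
         pearson = stats::cor(dvec, mvec),
         kendall_tau_a = kendall_tau_a(dvec, mvec))
}

#' Second-order correlation between a data RDM and a model RDM
#'
#' Correlates the vectorized upper triangles of an activation RDM and a
#' hypothesis model RDM, restricted to the cells the model constrains
#' (unconstrained `NA` cells and the diagonal are excluded). Spearman rank
#' correlation is the default; Kendall's tau-a (pair counting without tie
#' correction) is offered because categorical model RDMs are heavily tied;
#' plain Pearson is available for completeness.
#'
#' @param data An `rdm` (no missing cells).
#' @param model A `model_rdm` of the same dimension.
#' @param method `"spearman"` (default), `"kendall_tau_a"` or `"pearson"`.
#' @return The correlation statistic in `[-1, 1]`.
#' @export
rdm_correlation <- function(data, model,
                            method = c("spearman", "kendall_tau_a",
                                       "pearson")) {
  method <- match.arg(method)
  if (!inherits(data, "rdm")) stop("`data` must be an `rdm`", call. = FALSE)
  if (!inherits(model, "model_rdm")) {
    stop("`model` must be a `model_rdm`", call. = FALSE)
  }
  if (!identical(dim(data$dissim), dim(model$dissim))) {
    stop("data and model RDM shapes differ", call. = FALSE)
  }
  if (any(is.na(data$dissim))) {
    stop("data RDM contains missing cells", call. = FALSE)
  }
  ut <- upper.tri(model$dissim)
  keep <- ut & !is.na(model$dissim)
  mvec <- model$dissim[keep]
  if (length(mvec) < 3) {
    stop("fewer than 3 constrained cells in model `", model$name, "`",
         call. = FALSE)
  }
  if (length(unique(mvec)) < 2) {
    stop("constant model vector for `", model$name, "`", call. = FALSE)
  }
  second_order_cor(data$dissim[keep], mvec, method)
}

#' Permutation test of model-data RDM correspondence
#'
#' Tests the observed second-order correlation against a null distribution
#' obtained by repeatedly randomizing the condition labels of the data RDM
#' (the same random permutation applied to its rows and columns) and
#' recomputing the statistic. The p-value is one-sided (a model fit is a
#' positive correlation), with the add-one Monte-Carlo estimator
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, which is strictly
#' positive and valid.
#'
#' @inheritParams rdm_correlation
#' @param n_perm Number of random permutations (>= 100).
#' @param seed Integer seed; required for reproducibility.
#' @return A list with `statistic`, `p_value`, `null` (the permutation
#'   sample), `n_perm` and `seed`.
#' @export
permutation_test <- function(data, model,
                             method = c("spearman", "kendall_tau_a",
                                        "pearson"),
                             n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  observed <- rdm_correlation(data, model, method)  # also validates
  n <- nrow(data$dissim)
  ut <- upper.tri(model$dissim)
  keep <- ut & !is.na(model$dissim)
  idx <- which(keep, arr.ind = TRUE)
  ii <- idx[, 1]; jj <- idx[, 2]
  mvec <- model$dissim[keep]
  D <- data$dissim
  if (!is.null(seed)) set.seed(seed)
  use_rank <- method == "spearman"
  if (use_rank) mref <- rank(mvec)
  null <- vapply(seq_len(n_perm), function(b) {
    pi <- sample.int(n)
    dvec <- D[cbind(pi[ii], pi[jj])]
    if (use_rank) stats::cor(rank(dvec), mref)
    else second_order_cor(dvec, mvec, method)
  }, numeric(1))
  p <- (1 + sum(null >= observed - 1e-12)) / (n_perm + 1)
  list(statistic = observed, p_value = p, null = null,
       n_perm = as.integer(n_perm), seed = seed)
}

#' Compare two hypothesis models on the same data
#'
#' Computes, for each subject, the difference between the second-order
#' statistics of model A and model B (each model evaluated on its own
#' constrained cells of that subject's activation RDM), and tests whether
#' the mean difference departs from zero with a two-sided sign-flip
#' permutation test on the per-subject differences. With `S <= 12`
#' subjects all `2^S` sign assignments are enumerated exactly; otherwise a
#' Monte-Carlo sample of `n_perm` flips is used with the add-one
#' estimator.
#'
#' @param subject_rdms List of per-subject `rdm` objects (>= 2 subjects).
#' @param model_a,model_b `model_rdm` objects.
#' @inheritParams permutation_test
#' @return A list with `mean_difference` (A minus B), `p_value`,
#'   `differences` (per subject), `exhaustive` (logical) and `n_flips`.
#' @export
compare_models <- function(subject_rdms, model_a, model_b,
                           method = c("spearman", "kendall_tau_a",
                                      "pearson"),
                           n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  s <- length(subject_rdms)
  if (s < 2) {
    stop("model comparison needs >= 2 subjects (no within-subject variance ",
         "with a single subject)", call. = FALSE)
  }
  stat_a <- vapply(subject_rdms, rdm_correlation, numeric(1),
                   model = model_a, method = method)
  stat_b <- vapply(subject_rdms, rdm_correlation, numeric(1),
                   model = model_b, method = method)
  d <- stat_a - stat_b
  obs <- mean(d)
  if (s <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), s)))
    null <- as.numeric(signs %*% d) / s
    p <- mean(abs(null) >= abs(obs) - 1e-12)
    exhaustive <- TRUE
    n_flips <- nrow(signs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(b) {
      mean(sample(c(-1, 1), s, replace = TRUE) * d)
    }, numeric(1))
    p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1)
    exhaustive <- FALSE
    n_flips <- n_perm
  }
  list(mean_difference = obs, p_value = p, differences = d,
       exhaustive = exhaustive, n_flips = as.integer(n_flips))
}

#' Storey q-values with lambda-grid pi0 estimation
#'
#' Estimates the proportion of true nulls `pi0` from the counts of
#' p-values above each lambda in a grid, `pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda))`. With `m >= 100` the grid estimates
#' are smoothed with a natural cubic spline and evaluated at the largest
#' lambda; with fewer p-values the tail counts behind the smoother are too
#' unstable (a handful of p-values drive the extrapolation), so the
#' single-lambda estimate nearest `lambda = 0.5` is used instead. The
#' estimate is clamped to `[1/m, 1]`.
#' Each q-value is the minimum estimated positive FDR over
#' rejection thresholds at or beyond that p-value:
#' `q_i = min_(t >= p_i) pi0 m t / #\{p <= t\}`, which makes q monotone in
#' p.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @param lambda_grid Grid of lambda values in `[0, 1)` (default
#'   `seq(0.05, 0.95, by = 0.05)`).
#' @return A list with `qvalues` (same order as input) and `pi0`.
#' @export
storey_qvalues <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(pvalues) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  lambda_grid <- sort(lambda_grid[lambda_grid >= 0 & lambda_grid < 1])
  pi0_l <- vapply(lambda_grid, function(l) mean(pvalues > l) / (1 - l),
                  numeric(1))
  if (m >= 100 && length(lambda_grid) >= 4 && length(unique(pi0_l)) > 1) {
    fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  } else {
    pi0 <- pi0_l[which.min(abs(lambda_grid - 0.5))]
  }
  pi0 <- min(max(pi0, 1 / m), 1)
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  q_sorted <- pi0 * m * p_sorted / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))  # running min over t >= p_i
  q_sorted <- pmin(q_sorted, 1)
  qvalues <- numeric(m)
  qvalues[ord] <- q_sorted
  list(qvalues = qvalues, pi0 = pi0)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Fallback FDR procedure: indices of the p-values rejected by the
#' Benjamini-Hochberg step-up rule at level `alpha` (computed from
#' [stats::p.adjust()] BH-adjusted values).
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @param alpha FDR level in `(0, 1)`.
#' @return Integer vector of rejected indices (possibly empty).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  which(stats::p.adjust(pvalues, method = "BH") <= alpha)
}
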