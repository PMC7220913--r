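# Inference and evaluation: parametric and partial correlations, permutation
# null for the cross-validated prediction, Steiger's z for dependent
# correlations, explained variance, and network-level consensus summaries.

#' Pearson correlation with a two-tailed parametric p
#'
#' p is computed via the Student-t transform `t = r * sqrt((n-2)/(1-r^2))`
#' at n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return Named numeric `c(r, p)`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input to pearson_with_p", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * stats::pt(-abs(tt), df))
}

#' Permutation test of the cross-validated prediction
#'
#' The connectivity matrices are kept fixed while the observed scores are
#' shuffled B times; the entire LOOCV prediction procedure (including
#' fold-internal feature selection) is re-run on each shuffled score vector.
#' The permutation p is `#\{null r >= observed r\} / B` (one-sided: the
#' alternative is better-than-chance prediction). With `plus_one = TRUE` the
#' smoothed estimate `(# + 1) / (B + 1)` is returned instead.
#'
#' @param cohort A `cpm_cohort` valid for [cpm_loocv()].
#' @param B Number of shuffles (default 5000).
#' @param seed RNG seed for the shuffles.
#' @param p_threshold,variant,alpha_motion Passed to the LOOCV procedure.
#' @param plus_one Use the +1-smoothed p estimate.
#' @return Object of class `permutation_result`: `observed_r`, `null_r`
#'   (length B), `p_permutation`, `B`, `seed`.
#' @export
permutation_test <- function(cohort, B = 5000, seed = 1L, p_threshold = 0.01,
                             variant = "glm", alpha_motion = 0.05,
                             plus_one = FALSE) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  X <- cohort$edges
  y <- cohort$participants$gf
  n <- nrow(X)
  pre <- cpm_precompute(X, cohort$participants$mean_fd, alpha_motion)
  obs_pred <- loocv_core(pre, y, p_threshold, variant)$predicted
  observed_r <- safe_cor(y, obs_pred)
  null_r <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      yp <- sample(y)
      safe_cor(yp, loocv_core(pre, yp, p_threshold, variant)$predicted)
    }, numeric(1))
  })
  hits <- sum(null_r >= observed_r)
  p <- if (plus_one) (hits + 1) / (B + 1) else hits / B
  structure(list(observed_r = observed_r, null_r = null_r,
                 p_permutation = p, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "permutation_result")
}

safe_cor <- function(a, b) {
  if (stats::sd(b) == 0) 0 else stats::cor(a, b)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed r = %.3f, p = %.4g (B = %d)\n",
              x$observed_r, x$p_permutation, x$B))
  invisible(x)
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the least-squares residuals of `x` and `y` on
#' `[1, covariates]`; the two-tailed p uses df = n - 2 - p covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix (n x p) or vector.
#' @return Named numeric `c(r, p)`. If either residual is (numerically)
#'   zero-variance, r = 0 is returned with a warning and p = NA.
#' @export
partial_correlation <- function(x, y, covariates) {
  covariates <- as.matrix(covariates)
  n <- length(x)
  p <- ncol(covariates)
  stopifnot(length(y) == n, nrow(covariates) == n)
  if (n <= p + 2) stop("need n > p + 2 observations", call. = FALSE)
  D <- cbind(1, covariates)
  if (qr(D)$rank < ncol(D)) stop("rank-deficient covariate design", call. = FALSE)
  rx <- stats::lm.fit(D, x)$residuals
  ry <- stats::lm.fit(D, y)$residuals
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    warning("zero-variance residual: variable is collinear with covariates",
            call. = FALSE)
    return(c(r = 0, p = NA_real_))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - p
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * stats::pt(-abs(tt), df))
}

#' Steiger's z for two dependent correlations sharing one variable
#'
#' Tests r12 = r13 where variable 1 (e.g. the observed score) is common to
#' both correlations and r23 is the correlation between the two predictors.
#' Uses Steiger's (1980) statistic: Fisher transforms of r12 and r13, with
#' the asymptotic variance evaluated at the mean of the two correlations.
#'
#' @param r12,r13 The two dependent correlations (|r| < 1).
#' @param r23 Correlation between variables 2 and 3 (|r| < 1).
#' @param n Sample size (>= 4).
#' @return Named numeric `c(z, p)` with a two-tailed normal p.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  vals <- c(r12, r13, r23)
  if (any(!is.finite(vals)) || any(abs(vals) >= 1)) {
    stop("correlations must be finite with |r| < 1", call. = FALSE)
  }
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  z12 <- atanh(r12); z13 <- atanh(r13)
  rm_ <- (r12 + r13) / 2
  f <- (1 - r23) / (2 * (1 - rm_^2))
  if (f > 1) f <- 1
  h <- (1 - f * rm_^2) / (1 - rm_^2)
  z <- (z12 - z13) * sqrt((n - 3) / (2 * (1 - r23) * h))
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Explained variance of a correlation
#'
#' @param r Correlation coefficient with |r| <= 1.
#' @return Percentage `100 * r^2`.
#' @export
explained_variance <- function(r) {
  stopifnot(all(abs(r) <= 1))
  100 * r^2
}

#' Count consensus edges within and between functional networks
#'
#' Each consensus edge (positive and negative sets pooled) increments the
#' symmetric cell of its two nodes' networks; the diagonal holds
#' within-network counts. Node degree is the number of consensus edges
#' incident to each node.
#'
#' @param consensus A [feature_mask()].
#' @param parc A [parcellate()] result with networks assigned
#'   ([assign_networks()]).
#' @return Object of class `network_edge_counts`: `counts` (symmetric
#'   n_networks x n_networks matrix), `node_degree` (per node),
#'   `n_networks`.
#' @export
network_edge_counts <- function(consensus, parc) {
  stopifnot(inherits(consensus, "feature_mask"), inherits(parc, "parcellation"))
  nets <- parc$network_of_node
  if (anyNA(nets)) stop("parcellation has unassigned nodes; run assign_networks()",
                        call. = FALSE)
  K <- length(parc$sizes)
  pairs <- edge_nodes(K)
  idx <- c(consensus$positive_edges, consensus$negative_edges)
  check_mask_indices(consensus, nrow(pairs))
  n_net <- max(nets)
  counts <- matrix(0L, n_net, n_net)
  degree <- integer(K)
  for (e in idx) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    a <- nets[i]; b <- nets[j]
    counts[a, b] <- counts[a, b] + 1L
    if (a != b) counts[b, a] <- counts[b, a] + 1L
    degree[i] <- degree[i] + 1L
    degree[j] <- degree[j] + 1L
  }
  structure(list(counts = counts, node_degree = degree, n_networks = n_net),
            class = "network_edge_counts")
}

#' @export
print.network_edge_counts <- function(x, ...) {
  total <- sum(x$counts[upper.tri(x$counts, diag = TRUE)])
  cat(sprintf("<network_edge_counts> %d networks, %d consensus edges\n",
              x$n_networks, total))
  invisible(x)
}
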