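# Connectome-based predictive modeling (CPM): motion-edge exclusion,
# correlation-p feature selection, positive/negative network strengths,
# linear model fitting, LOOCV, repeated k-fold CV, consensus features.
#
# The cross-validation core works on downdated sums so that leave-one-out
# edge-behavior correlations for every fold cost O(nE) total; the same
# machinery serves the permutation test, which re-runs the entire LOOCV per
# shuffled score vector.

#' Construct a feature mask
#'
#' @param positive_edges,negative_edges Disjoint integer index sets into the
#'   canonical edge order.
#' @param p_threshold Selection significance level that produced the mask.
#' @return An object of class `feature_mask`.
#' @export
feature_mask <- function(positive_edges = integer(0),
                         negative_edges = integer(0), p_threshold = 0.01) {
  positive_edges <- sort(unique(as.integer(positive_edges)))
  negative_edges <- sort(unique(as.integer(negative_edges)))
  if (length(intersect(positive_edges, negative_edges))) {
    stop("positive and negative edge sets must be disjoint", call. = FALSE)
  }
  structure(list(positive_edges = positive_edges,
                 negative_edges = negative_edges,
                 p_threshold = p_threshold),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d positive, %d negative edges (p < %g)\n",
              length(x$positive_edges), length(x$negative_edges),
              x$p_threshold))
  invisible(x)
}

# Pearson r of every column of X with y; returns list(r, p) with two-tailed p
# from the Student-t transform at df = n - 2
edgewise_cor <- function(X, y) {
  n <- nrow(X)
  xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sxy <- as.vector(crossprod(xc, yc))
  sxx <- colSums(xc^2)
  syy <- sum(yc^2)
  r <- sxy / sqrt(sxx * syy)
  r[!is.finite(r)] <- 0
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), df))
}

# critical |r| for a two-tailed test at level alpha with df degrees of freedom
r_critical <- function(alpha, df) {
  if (alpha <= 0) return(Inf)
  if (alpha >= 1) return(0)
  tcrit <- stats::qt(1 - alpha / 2, df)
  tcrit / sqrt(df + tcrit^2)
}

#' Exclude motion-sensitive edges
#'
#' Edges whose correlation with participants' mean framewise displacement is
#' significant at `alpha_motion` (two-tailed) are removed from candidacy
#' before feature selection, so that motion-coupled connectivity cannot enter
#' the predictive model.
#'
#' @param edge_matrix Participants x edges matrix.
#' @param mean_fd Per-participant mean FD.
#' @param alpha_motion Two-tailed significance level (default 0.05; 0
#'   disables exclusion).
#' @return Integer vector of admissible (retained) edge indices.
#' @export
exclude_motion_edges <- function(edge_matrix, mean_fd, alpha_motion = 0.05) {
  stopifnot(nrow(edge_matrix) >= 4, length(mean_fd) == nrow(edge_matrix))
  if (stats::sd(mean_fd) == 0) {
    message("mean FD has zero variance; no motion edges excluded")
    return(seq_len(ncol(edge_matrix)))
  }
  if (alpha_motion <= 0) return(seq_len(ncol(edge_matrix)))
  cp <- edgewise_cor(edge_matrix, mean_fd)
  which(cp$p >= alpha_motion)
}

#' Select behavior-correlated edges in a training sample
#'
#' Per admissible edge, the Pearson correlation with the training Gf scores
#' and its two-tailed p (Student-t transform, df = n - 2); edges with
#' p < `p_threshold` are split by the sign of r into the positive and
#' negative sets.
#'
#' @param edge_matrix_train Training participants x edges matrix.
#' @param gf_train Training scores.
#' @param p_threshold Selection level (default 0.01).
#' @param admissible Integer indices of candidate edges (default all).
#' @return A [feature_mask()].
#' @export
select_features <- function(edge_matrix_train, gf_train, p_threshold = 0.01,
                            admissible = NULL) {
  stopifnot(nrow(edge_matrix_train) >= 4,
            length(gf_train) == nrow(edge_matrix_train))
  if (is.null(admissible)) admissible <- seq_len(ncol(edge_matrix_train))
  if (!length(admissible)) stop("admissible edge set is empty", call. = FALSE)
  if (stats::sd(gf_train) == 0) {
    warning("constant Gf in training sample; empty feature mask", call. = FALSE)
    return(feature_mask(p_threshold = p_threshold))
  }
  cp <- edgewise_cor(edge_matrix_train[, admissible, drop = FALSE], gf_train)
  sel <- cp$p < p_threshold
  feature_mask(positive_edges = admissible[sel & cp$r > 0],
               negative_edges = admissible[sel & cp$r < 0],
               p_threshold = p_threshold)
}

#' Positive and negative network strengths
#'
#' The positive (negative) strength is the sum of Fisher-z edge values over
#' the mask's positive (negative) set; an empty set contributes 0.
#'
#' @param edges An edge vector, or a participants x edges matrix.
#' @param mask A [feature_mask()].
#' @return For a vector, named numeric `c(S_pos, S_neg)`; for a matrix, an
#'   n x 2 matrix with columns `S_pos`, `S_neg`.
#' @export
network_strength <- function(edges, mask) {
  stopifnot(inherits(mask, "feature_mask"))
  if (is.matrix(edges)) {
    ne <- ncol(edges)
    check_mask_indices(mask, ne)
    sp <- if (length(mask$positive_edges)) {
      rowSums(edges[, mask$positive_edges, drop = FALSE])
    } else rep(0, nrow(edges))
    sn <- if (length(mask$negative_edges)) {
      rowSums(edges[, mask$negative_edges, drop = FALSE])
    } else rep(0, nrow(edges))
    cbind(S_pos = sp, S_neg = sn)
  } else {
    check_mask_indices(mask, length(edges))
    c(S_pos = sum(edges[mask$positive_edges]),
      S_neg = sum(edges[mask$negative_edges]))
  }
}

check_mask_indices <- function(mask, n_edges) {
  idx <- c(mask$positive_edges, mask$negative_edges)
  if (length(idx) && (min(idx) < 1 || max(idx) > n_edges)) {
    stop(sprintf("feature mask indexes edges outside 1..%d (edge-count mismatch?)",
                 n_edges), call. = FALSE)
  }
}

# OLS with pseudoinverse fallback for singular designs
ols_coef <- function(D, y) {
  ans <- tryCatch(solve(crossprod(D), crossprod(D, y)),
                  error = function(e) NULL)
  if (is.null(ans)) {
    message("collinear design; pseudoinverse solution used")
    sv <- svd(D)
    pos <- sv$d > max(dim(D)) * .Machine$double.eps * sv$d[1]
    ans <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  }
  as.vector(ans)
}

#' Fit a CPM model on network strengths
#'
#' Ordinary least squares of the training scores on `[1, S_pos, S_neg]`
#' (variant `"glm"`), or on the single corresponding strength (variants
#' `"positive"`, `"negative"`).
#'
#' @param strengths n x 2 matrix from [network_strength()] (columns `S_pos`,
#'   `S_neg`).
#' @param gf Training scores (length >= 3).
#' @param variant One of `"glm"`, `"positive"`, `"negative"`.
#' @param mask The training [feature_mask()], stored for later application.
#' @return An object of class `cpm_model` with elements `variant`, `coef`
#'   (named: `b0` and `b_pos`/`b_neg` per variant) and `mask`.
#' @export
fit_cpm <- function(strengths, gf, variant = c("glm", "positive", "negative"),
                    mask = NULL) {
  variant <- match.arg(variant)
  strengths <- as.matrix(strengths)
  stopifnot(nrow(strengths) >= 3, length(gf) == nrow(strengths),
            ncol(strengths) == 2)
  if (variant == "glm") {
    # an all-zero strength column (empty edge set) gets coefficient 0, so the
    # glm variant reduces exactly to the single-strength model
    active <- colSums(strengths != 0) > 0
    if (!any(active)) stop("both strength columns are identically zero",
                           call. = FALSE)
    b <- ols_coef(cbind(1, strengths[, active, drop = FALSE]), gf)
    coef <- stats::setNames(c(b[1], 0, 0), c("b0", "b_pos", "b_neg"))
    coef[c(FALSE, active)] <- b[-1]
  } else {
    D <- switch(variant,
      positive = cbind(1, strengths[, 1]),
      negative = cbind(1, strengths[, 2]))
    b <- ols_coef(D, gf)
    coef <- switch(variant,
      positive = stats::setNames(b, c("b0", "b_pos")),
      negative = stats::setNames(b, c("b0", "b_neg")))
  }
  if (any(!is.finite(coef))) stop("non-finite model coefficients", call. = FALSE)
  structure(list(variant = variant, coef = coef, mask = mask),
            class = "cpm_model")
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf("<cpm_model> variant '%s': %s\n", x$variant,
              paste(sprintf("%s = %.4g", names(x$coef), x$coef),
                    collapse = ", ")))
  invisible(x)
}

#' Predict scores from network strengths
#'
#' @param object A [fit_cpm()] model.
#' @param strengths n x 2 strengths matrix (or named length-2 vector).
#' @param ... Unused.
#' @return Numeric predicted scores.
#' @export
predict.cpm_model <- function(object, strengths, ...) {
  if (!is.matrix(strengths)) strengths <- matrix(strengths, nrow = 1)
  b <- object$coef
  switch(object$variant,
    glm = b[["b0"]] + b[["b_pos"]] * strengths[, 1] + b[["b_neg"]] * strengths[, 2],
    positive = b[["b0"]] + b[["b_pos"]] * strengths[, 1],
    negative = b[["b0"]] + b[["b_neg"]] * strengths[, 2])
}

new_prediction_result <- function(observed, predicted, fold_masks = NULL,
                                  p_permutation = NULL) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(predicted) == 0) {
    r <- 0; p <- 1
    warning("constant predictions; r set to 0", call. = FALSE)
  } else {
    rp <- pearson_with_p(observed, predicted)
    r <- rp[["r"]]; p <- rp[["p"]]
  }
  structure(list(observed = observed, predicted = predicted,
                 r_pred_obs = r, p_parametric = p,
                 p_permutation = p_permutation, fold_masks = fold_masks),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> n = %d, r(pred, obs) = %.3f, p = %.3g%s\n",
              length(x$observed), x$r_pred_obs, x$p_parametric,
              if (is.null(x$p_permutation)) "" else
                sprintf(", p_perm = %.3g", x$p_permutation)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Fast cross-validation core.
#
# cpm_precompute caches everything that depends on X (edges) and FD only, so
# a permutation test can re-run full LOOCVs over shuffled y without
# recomputing motion admissibility or X sums.

cpm_precompute <- function(X, mean_fd, alpha_motion) {
  n <- nrow(X)
  pre <- list(
    X = X, n = n, E = ncol(X),
    Sx = colSums(X), Sxx = colSums(X^2)
  )
  # per-fold admissible edges: motion exclusion recomputed within each
  # training fold (leave-one-out on FD), never on the full sample
  if (alpha_motion <= 0 || stats::sd(mean_fd) == 0) {
    if (alpha_motion > 0 && stats::sd(mean_fd) == 0) {
      message("mean FD has zero variance; no motion edges excluded")
    }
    pre$adm <- matrix(TRUE, n, ncol(X))
  } else {
    rfd <- loo_cor_matrix(pre, mean_fd)
    rc <- r_critical(alpha_motion, n - 1 - 2)
    pre$adm <- abs(rfd) <= rc         # TRUE = admissible (p >= alpha) for fold i
  }
  pre
}

# n x E matrix R: R[i, e] = cor(X[-i, e], y[-i]), via downdated sums
loo_cor_matrix <- function(pre, y) {
  X <- pre$X; n <- pre$n
  m <- n - 1
  Sxy <- as.vector(crossprod(X, y))
  Sy <- sum(y); Syy <- sum(y^2)
  SxyM <- matrix(Sxy, n, pre$E, byrow = TRUE) - X * y
  SxM <- matrix(pre$Sx, n, pre$E, byrow = TRUE) - X
  SxxM <- matrix(pre$Sxx, n, pre$E, byrow = TRUE) - X^2
  yd <- Sy - y
  num <- m * SxyM - SxM * yd
  denx <- m * SxxM - SxM^2
  deny <- m * (Syy - y^2) - yd^2
  R <- num / (sqrt(pmax(denx, 0)) * sqrt(pmax(deny, 0)))
  R[!is.finite(R)] <- 0
  R
}

# One full LOOCV pass for score vector y. Returns predictions and, if
# want_masks, the per-fold feature masks.
loocv_core <- function(pre, y, p_threshold, variant, want_masks = FALSE) {
  n <- pre$n
  X <- pre$X
  R <- loo_cor_matrix(pre, y)
  rc <- r_critical(p_threshold, n - 1 - 2)
  predicted <- numeric(n)
  masks <- if (want_masks) vector("list", n) else NULL
  empty_folds <- 0L
  for (i in seq_len(n)) {
    sel_pos <- which(pre$adm[i, ] & R[i, ] > rc)
    sel_neg <- which(pre$adm[i, ] & R[i, ] < -rc)
    if (want_masks) {
      masks[[i]] <- feature_mask(sel_pos, sel_neg, p_threshold)
    }
    train <- setdiff(seq_len(n), i)
    if ((variant == "positive" && !length(sel_pos)) ||
        (variant == "negative" && !length(sel_neg)) ||
        (variant == "glm" && !length(sel_pos) && !length(sel_neg))) {
      predicted[i] <- mean(y[train])
      empty_folds <- empty_folds + 1L
      next
    }
    Sp <- if (length(sel_pos)) rowSums(X[, sel_pos, drop = FALSE]) else numeric(n)
    Sn <- if (length(sel_neg)) rowSums(X[, sel_neg, drop = FALSE]) else numeric(n)
    # the glm design keeps only nonempty strength columns, so a fold whose
    # negative set is empty reduces exactly to the positive-variant model
    S_cols <- switch(variant,
      glm = cbind(Sp, Sn)[, c(length(sel_pos) > 0, length(sel_neg) > 0),
                          drop = FALSE],
      positive = cbind(Sp),
      negative = cbind(Sn))
    b <- ols_coef(cbind(1, S_cols[train, , drop = FALSE]), y[train])
    predicted[i] <- b[1] + sum(b[-1] * S_cols[i, ])
  }
  list(predicted = predicted, masks = masks, empty_folds = empty_folds)
}

#' Leave-one-out cross-validated CPM
#'
#' For each participant: motion-sensitive edges are excluded within the
#' training fold, behavior-correlated edges are selected among the remaining
#' candidates (p < `p_threshold`, split by sign), network strengths are
#' summed, a linear model is fitted on the n - 1 training participants, and
#' the held-out participant's score is predicted. Folds whose mask is empty
#' predict the training-mean score (logged).
#'
#' @param cohort A `cpm_cohort` (participant table with `gf` and `mean_fd`,
#'   plus the edge matrix).
#' @param p_threshold Edge-selection significance level (default 0.01).
#' @param variant Model variant: `"glm"` (both strengths), `"positive"`,
#'   `"negative"`.
#' @param alpha_motion Motion-edge exclusion level (default 0.05).
#' @param test_edges Optional matrix, same participants and edge order: each
#'   fold's model is evaluated on this matrix's held-out row instead (used to
#'   test fold models on a retest session of the same participants).
#' @return A `prediction_result` with per-fold `fold_masks`.
#' @export
cpm_loocv <- function(cohort, p_threshold = 0.01, variant = "glm",
                      alpha_motion = 0.05, test_edges = NULL) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  X <- cohort$edges
  y <- cohort$participants$gf
  n <- nrow(X)
  if (n < 10) stop("LOOCV requires at least 10 participants", call. = FALSE)
  pre <- cpm_precompute(X, cohort$participants$mean_fd, alpha_motion)
  res <- loocv_core(pre, y, p_threshold, variant, want_masks = TRUE)
  predicted <- res$predicted
  if (!is.null(test_edges)) {
    if (!identical(dim(test_edges), dim(X))) {
      stop("test_edges must match the training edge matrix in shape", call. = FALSE)
    }
    # re-evaluate each fold's model on the held-out row of test_edges
    predicted <- refit_predict_on(pre, y, res$masks, variant, test_edges)
  }
  if (res$empty_folds > 0) {
    message(sprintf("%d fold(s) had an empty feature mask; training mean used",
                    res$empty_folds))
  }
  new_prediction_result(y, predicted, fold_masks = res$masks)
}

# apply fold models to the held-out rows of another edge matrix
refit_predict_on <- function(pre, y, masks, variant, test_edges) {
  n <- pre$n
  X <- pre$X
  predicted <- numeric(n)
  for (i in seq_len(n)) {
    mk <- masks[[i]]
    train <- setdiff(seq_len(n), i)
    has_pos <- length(mk$positive_edges) > 0
    has_neg <- length(mk$negative_edges) > 0
    if ((variant == "positive" && !has_pos) ||
        (variant == "negative" && !has_neg) ||
        (variant == "glm" && !has_pos && !has_neg)) {
      predicted[i] <- mean(y[train])
      next
    }
    S <- network_strength(X, mk)
    model <- fit_cpm(S[train, , drop = FALSE], y[train], variant, mask = mk)
    predicted[i] <- predict(model,
                            network_strength(test_edges[i, ], mk))
  }
  predicted
}

#' Repeated k-fold cross-validated CPM
#'
#' Per repeat, participants are shuffled into k equal-as-possible folds
#' (sizes differ by at most 1); each fold is predicted by a model trained on
#' the other k - 1 folds with fold-internal motion exclusion and feature
#' selection. One r(pred, obs) per repeat.
#'
#' @inheritParams cpm_loocv
#' @param k Number of folds (default 20).
#' @param repeats Number of random re-partitions (default 50).
#' @param seed RNG seed for the partitions.
#' @return List with `r` (one value per repeat), `mean_r`, `sd_r`,
#'   `fold_sizes` (from the first repeat).
#' @export
cpm_kfold <- function(cohort, k = 20, repeats = 50, seed = 1L,
                      p_threshold = 0.01, variant = "glm",
                      alpha_motion = 0.05) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  X <- cohort$edges
  y <- cohort$participants$gf
  fd <- cohort$participants$mean_fd
  n <- nrow(X)
  if (k > n) stop(sprintf("k = %d exceeds n = %d", k, n), call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  k <- as.integer(k)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  rs <- with_seed(seed, {
    vapply(seq_len(repeats), function(rep_i) {
      perm <- sample.int(n)
      fold_of <- integer(n)
      fold_of[perm] <- rep.int(seq_len(k), times = sizes)
      predicted <- numeric(n)
      for (f in seq_len(k)) {
        test <- which(fold_of == f)
        train <- which(fold_of != f)
        adm <- exclude_motion_edges_quiet(X[train, , drop = FALSE], fd[train],
                                          alpha_motion)
        mk <- select_features(X[train, , drop = FALSE], y[train],
                              p_threshold, adm)
        if (!length(mk$positive_edges) && !length(mk$negative_edges)) {
          predicted[test] <- mean(y[train])
          next
        }
        S <- network_strength(X, mk)
        model <- fit_cpm(S[train, , drop = FALSE], y[train], variant, mask = mk)
        predicted[test] <- predict(model, S[test, , drop = FALSE])
      }
      if (stats::sd(predicted) == 0) 0 else stats::cor(y, predicted)
    }, numeric(1))
  })
  list(r = rs, mean_r = mean(rs), sd_r = stats::sd(rs), fold_sizes = sizes)
}

exclude_motion_edges_quiet <- function(X, fd, alpha) {
  if (alpha <= 0 || stats::sd(fd) == 0) return(seq_len(ncol(X)))
  suppressMessages(exclude_motion_edges(X, fd, alpha))
}

#' Consensus features across cross-validation folds
#'
#' The consensus positive (negative) set is the intersection of the positive
#' (negative) sets over all fold masks: edges selected in every fold.
#'
#' @param per_fold_masks List of [feature_mask()] objects.
#' @return A [feature_mask()]; empty consensus produces a warning.
#' @export
consensus_features <- function(per_fold_masks) {
  stopifnot(length(per_fold_masks) >= 1)
  pos <- Reduce(intersect, lapply(per_fold_masks, `[[`, "positive_edges"))
  neg <- Reduce(intersect, lapply(per_fold_masks, `[[`, "negative_edges"))
  if (!length(pos) && !length(neg)) {
    warning("consensus feature set is empty", call. = FALSE)
  }
  feature_mask(pos, neg, per_fold_masks[[1]]$p_threshold)
}

#' Fit the consensus model on a full training cohort
#'
#' Network strengths are computed from the consensus mask for every training
#' participant and a single model is fitted on the full cohort (the model
#' subsequently applied to retest or external data).
#'
#' @param train_cohort A `cpm_cohort`.
#' @param consensus A nonempty [feature_mask()].
#' @param variant Model variant.
#' @return A `cpm_model` carrying the consensus mask.
#' @export
fit_consensus_model <- function(train_cohort, consensus, variant = "glm") {
  stopifnot(inherits(train_cohort, "cpm_cohort"),
            inherits(consensus, "feature_mask"))
  if (!length(consensus$positive_edges) && !length(consensus$negative_edges)) {
    stop("consensus feature mask is empty", call. = FALSE)
  }
  S <- network_strength(train_cohort$edges, consensus)
  fit_cpm(S, train_cohort$participants$gf, variant, mask = consensus)
}

#' Apply a fitted CPM model to a test cohort
#'
#' Strengths are computed at the model's training feature positions in the
#' test cohort's edge matrix (which must use the same canonical edge order);
#' predictions are evaluated against the observed scores with a parametric p
#' only.
#'
#' @param model A `cpm_model` with a stored mask.
#' @param test_cohort A `cpm_cohort`.
#' @return A `prediction_result`.
#' @export
apply_cpm <- function(model, test_cohort) {
  stopifnot(inherits(model, "cpm_model"), inherits(test_cohort, "cpm_cohort"))
  if (is.null(model$mask)) stop("model carries no feature mask", call. = FALSE)
  S <- network_strength(test_cohort$edges, model$mask)
  new_prediction_result(test_cohort$participants$gf,
                        as.numeric(predict(model, S)))
}
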