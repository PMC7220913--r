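# Independent oracles and small fixtures, all built in code.
# Oracles deliberately use a different computational path than the package
# (cor.test / lm / explicit enumeration) so agreement is evidence, not an
# identity.

# cohort from raw pieces; edge counts that are not triangular numbers get a
# formally consistent n_nodes via the internal constructor (the CPM machinery
# never requires E = K(K-1)/2, only the public constructor validates it)
make_cohort <- function(edges, gf, mean_fd = NULL, session = "time1") {
  n <- nrow(edges)
  if (is.null(mean_fd)) mean_fd <- seq(0.03, 0.1, length.out = n)
  participants <- data.frame(
    id = sprintf("p%03d", seq_len(n)), gf = gf,
    age = rep(20, n), sex = rep(c("F", "M"), length.out = n),
    mean_fd = mean_fd, session = session, stringsAsFactors = FALSE)
  K <- (1 + sqrt(1 + 8 * ncol(edges))) / 2
  if (K == round(K)) {
    cpm_cohort(participants, edges, as.integer(K), session)
  } else {
    wmcpm:::new_cohort(participants, as.matrix(edges),
                       ceiling(K), session)
  }
}

# brute-force fold-by-fold LOOCV re-implementation using cor.test and lm
brute_loocv <- function(X, y, fd, p_threshold = 0.01, variant = "glm",
                        alpha_motion = 0.05) {
  n <- nrow(X)
  predicted <- numeric(n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    adm <- if (alpha_motion <= 0 || sd(fd[train]) == 0) {
      seq_len(ncol(X))
    } else {
      which(vapply(seq_len(ncol(X)), function(e) {
        stats::cor.test(X[train, e], fd[train])$p.value >= alpha_motion
      }, logical(1)))
    }
    rs <- vapply(adm, function(e) cor(X[train, e], y[train]), numeric(1))
    ps <- vapply(adm, function(e) {
      stats::cor.test(X[train, e], y[train])$p.value
    }, numeric(1))
    pos <- adm[ps < p_threshold & rs > 0]
    neg <- adm[ps < p_threshold & rs < 0]
    masks[[i]] <- list(pos = pos, neg = neg)
    Sp <- rowSums(X[, pos, drop = FALSE])
    Sn <- rowSums(X[, neg, drop = FALSE])
    cols <- switch(variant,
      glm = cbind(Sp, Sn)[, c(length(pos) > 0, length(neg) > 0), drop = FALSE],
      positive = if (length(pos)) cbind(Sp) else NULL,
      negative = if (length(neg)) cbind(Sn) else NULL)
    if (is.null(cols) || ncol(cols) == 0) {
      predicted[i] <- mean(y[train])
    } else {
      df <- data.frame(y = y[train], cols[train, , drop = FALSE])
      fit <- lm(y ~ ., data = df)
      predicted[i] <- predict(fit, newdata = data.frame(cols)[i, , drop = FALSE])
    }
  }
  list(predicted = predicted, masks = masks)
}

# window-enumeration scrubbing oracle: censored frame set for an fd trace
brute_censored <- function(fd, threshold = 0.5) {
  n <- length(fd)
  cens <- logical(n)
  for (i in seq_len(n)) {
    if (fd[i] > threshold) {
      for (w in (i - 2):(i + 1)) if (w >= 1 && w <= n) cens[w] <- TRUE
    }
  }
  which(cens)
}

# partial correlation via the inverse-correlation-matrix closed form
brute_partial_cor <- function(x, y, Z) {
  M <- cbind(x, y, Z)
  P <- solve(stats::cor(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# time series with a pure sinusoid channel
sinusoid_ts <- function(freq_hz, n = 200, tr = 2) {
  t <- (seq_len(n) - 1) * tr
  wm_time_series(matrix(sin(2 * pi * freq_hz * t), ncol = 1), tr_seconds = tr)
}
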