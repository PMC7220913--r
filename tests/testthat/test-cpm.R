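# CPM core: motion exclusion, feature selection, strengths, model fit,
# LOOCV / k-fold, consensus, application to new cohorts.

test_that("exclude_motion_edges removes FD-coupled edges", {
  set.seed(21)
  n <- 100
  fd <- 0.05 + abs(rnorm(n, sd = 0.02))
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 4] <- fd * 5  # exactly proportional to FD
  adm <- exclude_motion_edges(X, fd, 0.05)
  expect_false(4 %in% adm)
  expect_identical(exclude_motion_edges(X, fd, 0), 1:10)

  # planted FD coupling at r = 0.6, n = 100: essentially always excluded
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    fd2 <- rnorm(n)
    e <- 0.6 * scale(fd2)[, 1] + sqrt(1 - 0.36) * rnorm(n)
    !(1 %in% exclude_motion_edges(cbind(e, rnorm(n)), fd2, 0.05))
  }, logical(1))
  expect_true(all(hits))

  expect_message(adm0 <- exclude_motion_edges(X, rep(0.05, n), 0.05),
                 "zero variance")
  expect_identical(adm0, 1:10)
})

test_that("select_features thresholds on the t-transformed p and splits by sign", {
  # selection boundary at n = 326: |r| just above/below the critical value
  n <- 326
  tcrit <- qt(1 - 0.01 / 2, n - 2)
  r_boundary <- tcrit / sqrt(n - 2 + tcrit^2)
  expect_equal(r_boundary, 0.1426, tolerance = 3e-3)
  expect_equal(wmcpm:::r_critical(0.01, n - 2), r_boundary, tolerance = 1e-12)

  set.seed(8)
  n <- 60
  gf <- rnorm(n)
  X <- cbind(gf, -gf, matrix(rnorm(n * 6), n, 6))
  mk <- select_features(X, gf, p_threshold = 0.01)
  expect_true(1 %in% mk$positive_edges)
  expect_true(2 %in% mk$negative_edges)
  expect_length(intersect(mk$positive_edges, mk$negative_edges), 0)

  expect_warning(empty <- select_features(X, rep(3, n)), "constant Gf")
  expect_length(empty$positive_edges, 0)

  # respects the admissible set
  mk2 <- select_features(X, gf, 0.01, admissible = 2:8)
  expect_false(1 %in% mk2$positive_edges)
})

test_that("network_strength sums z values per set and is linear", {
  mask <- feature_mask(c(1, 2), 4)
  v <- c(0.2, 0.3, 9, -0.1)
  s <- network_strength(v, mask)
  expect_equal(unname(s), c(0.5, -0.1))
  expect_equal(unname(network_strength(2 * v, mask)), c(1.0, -0.2))
  expect_equal(unname(network_strength(v, feature_mask())), c(0, 0))

  M <- rbind(v, 2 * v)
  sm <- network_strength(M, mask)
  expect_equal(unname(sm[, "S_pos"]), c(0.5, 1.0))

  expect_error(feature_mask(c(1, 2), c(2, 3)), "disjoint")
  expect_error(network_strength(v, feature_mask(10, integer(0))), "mismatch")
})

test_that("fit_cpm recovers exact and random linear models", {
  set.seed(12)
  S <- cbind(S_pos = rnorm(40), S_neg = rnorm(40))
  gf <- 3 + 2 * S[, 1] - 1 * S[, 2]
  m <- fit_cpm(S, gf, "glm")
  expect_equal(unname(m$coef), c(3, 2, -1), tolerance = 1e-9)

  const <- fit_cpm(S, rep(7, 40), "glm")
  expect_equal(unname(const$coef), c(7, 0, 0), tolerance = 1e-9)

  # normal-equations oracle on noisy data
  gf2 <- gf + rnorm(40)
  D <- cbind(1, S)
  beta <- solve(t(D) %*% D, t(D) %*% gf2)
  m2 <- fit_cpm(S, gf2, "glm")
  expect_equal(unname(m2$coef), as.vector(beta), tolerance = 1e-8)

  mp <- fit_cpm(S, gf2, "positive")
  bp <- solve(t(cbind(1, S[, 1])) %*% cbind(1, S[, 1]),
              t(cbind(1, S[, 1])) %*% gf2)
  expect_equal(unname(mp$coef), as.vector(bp), tolerance = 1e-8)

  # predictions: hand-evaluated affine map, and the OLS mean property
  news <- cbind(rnorm(5), rnorm(5))
  expect_equal(as.numeric(predict(m2, news)),
               beta[1] + beta[2] * news[, 1] + beta[3] * news[, 2],
               tolerance = 1e-10)
  expect_equal(as.numeric(predict(m2, rbind(colMeans(S)))), mean(gf2),
               tolerance = 1e-10)
  simple <- fit_cpm(cbind(c(0, 1, 2), c(0, 0, 0)), c(0, 1, 2), "positive")
  expect_equal(as.numeric(predict(simple, rbind(c(2.5, 0)))), 2.5,
               tolerance = 1e-9)
})

test_that("LOOCV matches the brute-force fold-by-fold oracle", {
  set.seed(77)
  for (case in 1:3) {
    n <- sample(10:12, 1)
    E <- sample(6:10, 1)
    gf <- rnorm(n, 65, 7)
    X <- matrix(rnorm(n * E), n, E)
    X[, 1] <- 0.8 * scale(gf)[, 1] + 0.2 * rnorm(n)
    fd <- 0.03 + abs(rnorm(n, sd = 0.02))
    cohort <- make_cohort(X, gf, fd)
    for (variant in c("glm", "positive", "negative")) {
      got <- suppressMessages(suppressWarnings(
        cpm_loocv(cohort, p_threshold = 0.05, variant = variant,
                  alpha_motion = 0.05)))
      oracle <- brute_loocv(X, gf, fd, p_threshold = 0.05, variant = variant,
                            alpha_motion = 0.05)
      expect_equal(got$predicted, oracle$predicted, tolerance = 1e-9)
      for (i in seq_len(n)) {
        expect_identical(got$fold_masks[[i]]$positive_edges,
                         as.integer(oracle$masks[[i]]$pos))
        expect_identical(got$fold_masks[[i]]$negative_edges,
                         as.integer(oracle$masks[[i]]$neg))
      }
    }
  }
})

test_that("feature selection in fold i never sees participant i (no leakage)", {
  set.seed(5)
  n <- 30; E <- 20
  gf <- rnorm(n, 65, 7)
  X <- matrix(rnorm(n * E), n, E)
  cohort <- make_cohort(X, gf)
  res <- suppressMessages(suppressWarnings(cpm_loocv(cohort, p_threshold = 0.1)))
  # metamorphic: corrupt participant 3's edges and score arbitrarily
  X2 <- X; X2[3, ] <- 100 * rnorm(E)
  gf2 <- gf; gf2[3] <- 999
  cohort2 <- make_cohort(X2, gf2, cohort$participants$mean_fd)
  res2 <- suppressMessages(suppressWarnings(cpm_loocv(cohort2, p_threshold = 0.1)))
  expect_identical(res$fold_masks[[3]]$positive_edges,
                   res2$fold_masks[[3]]$positive_edges)
  expect_identical(res$fold_masks[[3]]$negative_edges,
                   res2$fold_masks[[3]]$negative_edges)
})

test_that("glm predictions equal positive-variant ones when the negative set is empty", {
  set.seed(31)
  spec <- synthetic_spec(n_participants = 80, n_nodes = 10, n_pos_edges = 4,
                         n_neg_edges = 0, effect_r = 0.7, seed = 31)
  gen <- generate_cohort(spec)
  g <- suppressMessages(cpm_loocv(gen$cohort, variant = "glm"))
  p <- suppressMessages(cpm_loocv(gen$cohort, variant = "positive"))
  empty_neg <- vapply(g$fold_masks,
                      function(m) length(m$negative_edges) == 0, logical(1))
  expect_true(any(empty_neg))
  expect_equal(g$predicted[empty_neg], p$predicted[empty_neg],
               tolerance = 1e-10)
})

test_that("null cohorts give no better-than-chance LOOCV prediction", {
  # Under the null the CV'd r is noisy with a selection-driven negative bias
  # (it does NOT concentrate at 1/sqrt(n) scale -- the reason inference uses
  # the permutation test, whose calibration the acceptance suite checks).
  # The honest contract: the null median is at/below zero and far beneath the
  # planted-effect median.
  null_r <- vapply(1:25, function(s) {
    spec <- synthetic_spec(n_participants = 150, n_nodes = 30,
                           n_pos_edges = 0, n_neg_edges = 0, effect_r = 0,
                           seed = 1000 + s)
    gen <- generate_cohort(spec)
    suppressMessages(suppressWarnings(cpm_loocv(gen$cohort)))$r_pred_obs
  }, numeric(1))
  planted_r <- vapply(1:10, function(s) {
    spec <- synthetic_spec(n_participants = 150, n_nodes = 30,
                           n_pos_edges = 8, n_neg_edges = 8, effect_r = 0.4,
                           seed = 1000 + s)
    gen <- generate_cohort(spec)
    suppressMessages(suppressWarnings(cpm_loocv(gen$cohort)))$r_pred_obs
  }, numeric(1))
  expect_lt(median(null_r), 0.1)
  expect_gt(median(planted_r) - median(null_r), 0.25)
})

test_that("kfold partitions correctly and reduces to LOOCV at k = n", {
  spec <- synthetic_spec(n_participants = 326, n_nodes = 6, n_pos_edges = 2,
                         n_neg_edges = 2, effect_r = 0.35, seed = 44)
  gen <- generate_cohort(spec)
  kf <- suppressMessages(cpm_kfold(gen$cohort, k = 20, repeats = 2, seed = 1))
  expect_identical(sort(unique(kf$fold_sizes)), c(16L, 17L))
  expect_identical(sum(kf$fold_sizes == 17L), 6L)
  expect_length(kf$r, 2)
  kf_again <- suppressMessages(cpm_kfold(gen$cohort, k = 20, repeats = 2, seed = 1))
  expect_identical(kf$r, kf_again$r)

  small <- generate_cohort(synthetic_spec(n_participants = 20, n_nodes = 10,
                                          n_pos_edges = 3, n_neg_edges = 3,
                                          effect_r = 0.6, seed = 9))
  loo <- suppressMessages(suppressWarnings(cpm_loocv(small$cohort)))
  kfn <- suppressMessages(suppressWarnings(
    cpm_kfold(small$cohort, k = 20, repeats = 3, seed = 2)))
  expect_equal(kfn$r, rep(cor(loo$observed, loo$predicted), 3),
               tolerance = 1e-8)

  expect_error(cpm_kfold(small$cohort, k = 21), "exceeds n")
})

test_that("consensus features are the intersection across folds", {
  m1 <- feature_mask(c(1, 2, 3), c(10, 11))
  m2 <- feature_mask(c(2, 3, 4), c(10, 12))
  cons <- consensus_features(list(m1, m2))
  expect_identical(cons$positive_edges, c(2L, 3L))
  expect_identical(cons$negative_edges, 10L)
  expect_identical(consensus_features(list(m1, m1))[1:2], m1[1:2])
  expect_warning(consensus_features(list(m1, feature_mask())), "empty")
})

test_that("consensus model fits the full cohort and shows in-sample optimism", {
  # noiseless: gf is an exact linear function of the planted strengths
  set.seed(2)
  n <- 40
  X <- matrix(rnorm(n * 10), n, 10)
  gf <- 5 + 2 * (X[, 1] + X[, 2]) - 3 * X[, 7]
  cohort <- make_cohort(X, gf)
  cons <- feature_mask(c(1, 2), 7)
  model <- fit_consensus_model(cohort, cons)
  expect_equal(unname(model$coef), c(5, 2, -3), tolerance = 1e-9)
  model_b <- fit_consensus_model(cohort, cons)
  expect_identical(model$coef, model_b$coef)

  expect_error(fit_consensus_model(cohort, feature_mask()), "empty")

  optimism <- vapply(1:5, function(s) {
    spec <- synthetic_spec(n_participants = 100, n_nodes = 14,
                           n_pos_edges = 5, n_neg_edges = 5, effect_r = 0.45,
                           seed = 300 + s)
    gen <- generate_cohort(spec)
    loo <- suppressMessages(suppressWarnings(cpm_loocv(gen$cohort)))
    cons <- suppressWarnings(consensus_features(loo$fold_masks))
    if (!length(cons$positive_edges) && !length(cons$negative_edges)) {
      return(NA)
    }
    m <- fit_consensus_model(gen$cohort, cons)
    apply_cpm(m, gen$cohort)$r_pred_obs - loo$r_pred_obs
  }, numeric(1))
  expect_gte(median(optimism, na.rm = TRUE), 0)
})

test_that("apply_cpm handles retest attenuation and affine score invariance", {
  set.seed(6)
  diffs <- vapply(1:20, function(s) {
    spec <- synthetic_spec(n_participants = 120, n_nodes = 16, n_pos_edges = 6,
                           n_neg_edges = 6, effect_r = 0.4, seed = 400 + s)
    gen <- generate_cohort(spec)
    loo <- suppressMessages(suppressWarnings(cpm_loocv(gen$cohort)))
    retest <- generate_retest(gen$cohort, gen$truth, 0.7, seed = 500 + s)
    loo2 <- suppressMessages(suppressWarnings(
      cpm_loocv(gen$cohort, test_edges = retest$edges)))
    c(loo$r_pred_obs, loo2$r_pred_obs)
  }, numeric(2))
  expect_gt(median(diffs[2, ]), 0)              # retest prediction works
  expect_gt(median(diffs[1, ] - diffs[2, ]), 0) # but is attenuated

  # affine rescaling of test scores leaves r unchanged
  spec <- synthetic_spec(n_participants = 60, n_nodes = 10, n_pos_edges = 4,
                         n_neg_edges = 4, effect_r = 0.6, seed = 88)
  gen <- generate_cohort(spec)
  loo <- suppressMessages(suppressWarnings(cpm_loocv(gen$cohort)))
  cons <- suppressWarnings(consensus_features(loo$fold_masks))
  m <- fit_consensus_model(gen$cohort, cons)
  test1 <- gen$cohort
  res1 <- apply_cpm(m, test1)
  test2 <- test1
  test2$participants$gf <- 2 * test1$participants$gf + 10
  res2 <- apply_cpm(m, test2)
  expect_equal(res1$r_pred_obs, res2$r_pred_obs, tolerance = 1e-12)
  # and test-on-train reproduces the consensus model's in-sample result
  S <- network_strength(test1$edges, cons)
  expect_equal(res1$predicted, as.numeric(predict(m, S)), tolerance = 1e-12)

  wrong <- make_cohort(matrix(rnorm(60 * 10), 60, 10), rnorm(60))
  expect_error(apply_cpm(m, wrong), "mismatch")
})

test_that("prediction quality increases with the planted effect size", {
  med_r <- vapply(c(0.3, 0.4, 0.5), function(er) {
    rs <- vapply(1:20, function(s) {
      spec <- synthetic_spec(n_participants = 300, n_nodes = 16,
                             n_pos_edges = 6, n_neg_edges = 6, effect_r = er,
                             seed = 700 + s)
      gen <- generate_cohort(spec)
      suppressMessages(suppressWarnings(cpm_loocv(gen$cohort)))$r_pred_obs
    }, numeric(1))
    median(rs)
  }, numeric(1))
  expect_true(all(diff(med_r) > 0))
})
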