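# Preprocessing: frame discard, FD, nuisance regression, band-pass,
# scrubbing, QC thresholds, outlier screening.

test_that("discard_initial drops exactly the leading frames", {
  ts <- wm_time_series(matrix(rnorm(242 * 3), 242, 3))
  expect_equal(nrow(discard_initial(ts, 7)$values), 235)
  expect_equal(ncol(discard_initial(ts, 7)$values), 3)
  expect_identical(discard_initial(ts, 0), ts)
  short <- wm_time_series(matrix(rnorm(10), 10, 1))
  expect_error(discard_initial(short, 10), "discard")
})

test_that("compute_fd matches closed-form cases and its symmetries", {
  zero <- compute_fd(motion_trace(matrix(0, 10, 6)))
  expect_true(all(zero$fd == 0) && zero$mean_fd == 0)

  p <- matrix(0, 10, 6); p[5:10, 2] <- 0.1  # +0.1 mm translation step
  fd <- compute_fd(motion_trace(p))$fd
  expect_equal(fd[5], 0.1)
  expect_true(all(fd[-5] == 0))

  p <- matrix(0, 10, 6); p[5:10, 5] <- 0.01  # +0.01 rad rotation step
  expect_equal(compute_fd(motion_trace(p))$fd[5], 0.5)  # 50 mm * 0.01

  # permutation of translation axes leaves fd unchanged
  p <- cbind(matrix(rnorm(30, sd = 0.05), 10, 3), matrix(0, 10, 3))
  expect_equal(compute_fd(motion_trace(p))$fd,
               compute_fd(motion_trace(p[, c(3, 1, 2, 4, 5, 6)]))$fd)

  # fd scales linearly with head radius for pure rotations
  p <- cbind(matrix(0, 10, 3), matrix(rnorm(30, sd = 0.01), 10, 3))
  expect_equal(compute_fd(motion_trace(p), head_radius_mm = 100)$fd,
               2 * compute_fd(motion_trace(p), head_radius_mm = 50)$fd)

  expect_error(motion_trace(matrix(0, 10, 5)), "6 columns")
})

test_that("degree rotations are converted on construction", {
  p <- matrix(0, 4, 6); p[2:4, 4] <- 90
  m <- motion_trace(p, rotation_units = "degrees")
  expect_equal(m$params[2, 4], pi / 2)
})

test_that("build_motion24 stacks params, derivatives and squares", {
  zero <- build_motion24(motion_trace(matrix(0, 8, 6)))
  expect_true(all(zero == 0) && ncol(zero) == 24)

  const <- build_motion24(motion_trace(matrix(2, 8, 6)))
  expect_true(all(const[, 7:12] == 0))     # derivatives of a constant
  expect_true(all(const[, 13:18] == 4))    # squares

  ramp <- matrix(seq_len(8), 8, 6) * rep(1:6, each = 8)
  m24 <- build_motion24(motion_trace(ramp))
  fd_oracle <- rbind(0, apply(ramp, 2, diff))  # finite differences
  expect_equal(m24[, 7:12], fd_oracle, ignore_attr = TRUE)
})

test_that("regress_nuisance matches a normal-equations oracle", {
  set.seed(42)
  n <- 50
  reg <- matrix(rnorm(n * 3), n, 3)
  # channel equal to a regressor -> zero residual
  ts <- wm_time_series(cbind(reg[, 1], rnorm(n)))
  out <- regress_nuisance(ts, reg)
  expect_lt(max(abs(out$values[, 1])), 1e-10)

  # independent oracle: explicit normal equations
  Y <- matrix(rnorm(n * 4), n, 4)
  D <- cbind(1, reg)
  beta <- solve(t(D) %*% D, t(D) %*% Y)
  oracle <- Y - D %*% beta
  got <- regress_nuisance(wm_time_series(Y), reg)$values
  expect_equal(got, oracle, tolerance = 1e-8, ignore_attr = TRUE)

  # residuals orthogonal to the design; idempotent
  expect_lt(max(abs(t(D) %*% got)), 1e-8)
  twice <- regress_nuisance(wm_time_series(got), reg)$values
  expect_equal(twice, got, tolerance = 1e-10, ignore_attr = TRUE)

  # regressors orthogonal to all channels (and to the mean) -> output equals
  # the demeaned input
  rego <- qr.Q(qr(scale(cbind(rnorm(n), rnorm(n)), scale = FALSE)))
  Yc <- sweep(Y, 2, colMeans(Y))
  Yo <- Yc - rego %*% (t(rego) %*% Yc)  # construct channels orthogonal to regs
  outo <- regress_nuisance(wm_time_series(Yo), rego)$values
  expect_equal(outo, Yo, tolerance = 1e-8, ignore_attr = TRUE)

  expect_warning(regress_nuisance(wm_time_series(Y), cbind(reg, reg[, 1])),
                 "rank-deficient")
})

test_that("bandpass keeps in-band and kills out-of-band power", {
  # independent response oracle for a pure sinusoid: squared 4th-order
  # Butterworth magnitude evaluated at the tone frequency
  gain2 <- function(f, lo = 0.01, hi = 0.10, o = 4) {
    (1 / (1 + (lo / f)^(2 * o))) * (1 / (1 + (f / hi)^(2 * o)))
  }
  inband <- sinusoid_ts(0.05)
  v_in <- var(bandpass(inband)$values) / var(inband$values)
  expect_gte(v_in, 0.80)
  expect_equal(as.numeric(v_in), gain2(0.05)^2, tolerance = 0.05)

  outband <- sinusoid_ts(0.2)
  v_out <- var(bandpass(outband)$values) / var(outband$values)
  expect_lte(as.numeric(v_out), 0.05)

  const <- wm_time_series(matrix(5, 100, 1))
  expect_lt(max(abs(bandpass(const)$values)), 1e-10)

  expect_error(bandpass(inband, 0.01, 0.30), "Nyquist")
  expect_error(bandpass(inband, 0.10, 0.01), "invalid")
})

test_that("scrub censors the stated window, clipped at boundaries", {
  mk_motion <- function(fd) {
    m <- motion_trace(matrix(0, length(fd), 6))
    m$fd <- fd; m$mean_fd <- mean(fd)
    m
  }
  ts8 <- wm_time_series(matrix(rnorm(8), 8, 1))

  clean <- scrub(ts8, mk_motion(rep(0.1, 8)))
  expect_true(all(clean$frame_retained))

  one <- scrub(ts8, mk_motion(c(0, 0, 0, 0.9, 0, 0, 0, 0)))  # spike at frame 4
  expect_identical(which(!one$frame_retained), c(2L, 3L, 4L, 5L))

  first <- scrub(ts8, mk_motion(c(0.9, rep(0, 7))))
  expect_identical(which(!first$frame_retained), c(1L, 2L))

  # censored-set equality with the window-enumeration oracle
  set.seed(7)
  for (rep_i in 1:200) {
    fd <- rexp(sample(5:30, 1), rate = 4)
    ts <- wm_time_series(matrix(0, length(fd), 1))
    got <- which(!scrub(ts, mk_motion(fd))$frame_retained)
    expect_identical(got, brute_censored(fd))
  }
})

test_that("qc_participant applies the printed exclusion limits", {
  mk <- function(max_trans = 0.5, max_rot_deg = 0.5, mean_fd = 0.05) {
    p <- matrix(0, 20, 6)
    p[10, 1] <- max_trans
    p[12, 4] <- max_rot_deg * pi / 180
    m <- motion_trace(p)
    m <- compute_fd(m)
    m$mean_fd <- mean_fd  # override to test the threshold directly
    m
  }
  expect_false(qc_participant(mk(mean_fd = 0.16), retention = 1)$included)
  expect_false(qc_participant(mk(), retention = 0.79)$included)
  expect_false(qc_participant(mk(max_trans = 2.5), retention = 1)$included)
  expect_false(qc_participant(mk(max_rot_deg = 2.5), retention = 1)$included)
  rep_ok <- qc_participant(mk(max_trans = 1, max_rot_deg = 1, mean_fd = 0.05),
                           retention = 1)
  expect_true(rep_ok$included)
  expect_false(any(unlist(rep_ok[2:6])))
})

test_that("exclude_outliers screens on full-sample mean +/- k SD", {
  expect_identical(exclude_outliers(rep(100, 5)), 1:5)
  expect_identical(exclude_outliers(c(100, 101, 99, 100, 100, 130)), 1:5)
  expect_identical(exclude_outliers(c(0, 100)), 1:2)
})
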