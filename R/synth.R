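# Synthetic cohorts with planted edge-behavior effects.
#
# The generator states a small world that mirrors the design of the study the
# package automates: a training cohort with a K-node white-matter connectome
# in which sparse positive and negative edge sets carry a known correlation
# with the behavioral score (Gf), a retest session with attenuated edge
# reliability, an external cohort whose score is an affine re-scaling of the
# latent trait, and rigid-body motion traces with occasional FD spikes.

#' Specification of a synthetic cohort
#'
#' Defaults describe the stated world used throughout the package's tests:
#' a cohort of 326 participants (the size of the training sample the design
#' emulates), a 128-node connectome, 20 planted positive and 20 planted
#' negative edges, Gf scores on a Raven's-type total-score scale
#' (mean 65, SD 7, rounded to integers), retest reliability 0.7, an external
#' cohort of 53 scored on an IQ-like scale (15 x latent + 100), and a 2%
#' per-frame FD-spike rate.
#'
#' Each planted edge is generated as
#' `sign * effect_r * latent + sqrt(1 - effect_r^2) * noise` with
#' standard-normal latent trait and noise, so its population correlation with
#' the latent Gf is exactly `effect_r` (sign per set). Non-planted edges are
#' independent standard-normal noise.
#'
#' @param n_participants Cohort size.
#' @param n_nodes Number of connectome nodes K (edges = K(K-1)/2).
#' @param n_pos_edges,n_neg_edges Number of planted positively / negatively
#'   correlated edges. The two sets are disjoint.
#' @param effect_r Target edge-behavior correlation magnitude, in (0, 1)
#'   (0 allowed: a null cohort).
#' @param gf_mean,gf_sd Behavioral score distribution; scores are rounded to
#'   integers to mimic psychometric test totals.
#' @param retest_reliability Default edgewise test-retest correlation for
#'   [generate_retest()].
#' @param external_scale,external_offset Affine map from the latent trait to
#'   the external cohort's score units.
#' @param external_noise_sd SD of latent-scale noise added to the external
#'   score before the affine map (0 = noiseless).
#' @param n_external External cohort size.
#' @param fd_spike_rate Per-frame probability of an FD spike in generated
#'   motion traces.
#' @param seed Integer RNG seed; all generators are deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_cohort()], [generate_retest()], [generate_external()]
#' @export
synthetic_spec <- function(n_participants = 326, n_nodes = 128,
                           n_pos_edges = 20, n_neg_edges = 20,
                           effect_r = 0.4, gf_mean = 65, gf_sd = 7,
                           retest_reliability = 0.7,
                           external_scale = 15, external_offset = 100,
                           external_noise_sd = 0.5, n_external = 53,
                           fd_spike_rate = 0.02, seed = 1L) {
  stopifnot(n_participants >= 2, n_nodes >= 2, n_pos_edges >= 0,
            n_neg_edges >= 0, gf_sd >= 0, n_external >= 2)
  if (!is.numeric(effect_r) || effect_r < 0 || effect_r >= 1) {
    stop("effect_r must lie in [0, 1)", call. = FALSE)
  }
  assert_scalar_prob(retest_reliability, "retest_reliability")
  assert_scalar_prob(fd_spike_rate, "fd_spike_rate")
  n_edges <- n_edges_for(n_nodes)
  if (n_pos_edges + n_neg_edges > n_edges) {
    stop(sprintf(
      "infeasible edge counts: n_pos_edges + n_neg_edges = %d exceeds K(K-1)/2 = %d",
      n_pos_edges + n_neg_edges, n_edges), call. = FALSE)
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_nodes = as.integer(n_nodes),
    n_pos_edges = as.integer(n_pos_edges),
    n_neg_edges = as.integer(n_neg_edges),
    effect_r = effect_r, gf_mean = gf_mean, gf_sd = gf_sd,
    retest_reliability = retest_reliability,
    external_scale = external_scale, external_offset = external_offset,
    external_noise_sd = external_noise_sd,
    n_external = as.integer(n_external),
    fd_spike_rate = fd_spike_rate, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Construct a cohort from a participant table and an edge matrix
#'
#' Entry point for real (non-synthetic) data: supply one row per participant
#' and the participants x edges matrix of Fisher-z connectivity values in the
#' canonical edge order (see [edge_nodes()]).
#'
#' @param participants Data frame with at least columns `id`, `gf` and
#'   `mean_fd` (plus optional `age`, `sex`, `session`).
#' @param edges Numeric participants x edges matrix; column count must be
#'   K(K-1)/2 for `n_nodes` = K.
#' @param n_nodes Number of connectome nodes.
#' @param session Session label.
#' @return An object of class `cpm_cohort`.
#' @export
cpm_cohort <- function(participants, edges, n_nodes, session = "time1") {
  stopifnot(is.data.frame(participants))
  needed <- c("id", "gf", "mean_fd")
  missing_cols <- setdiff(needed, names(participants))
  if (length(missing_cols)) {
    stop(sprintf("participants table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  edges <- as.matrix(edges)
  if (nrow(edges) != nrow(participants)) {
    stop("edge matrix rows must match participant rows", call. = FALSE)
  }
  if (ncol(edges) != n_edges_for(n_nodes)) {
    stop(sprintf("edge matrix has %d columns; expected K(K-1)/2 = %d for K = %d",
                 ncol(edges), n_edges_for(n_nodes), n_nodes), call. = FALSE)
  }
  new_cohort(participants, edges, n_nodes, session)
}

new_cohort <- function(participants, edges, n_nodes, session) {
  stopifnot(nrow(participants) == nrow(edges))
  rownames(edges) <- participants$id
  structure(list(participants = participants, edges = edges,
                 n_nodes = as.integer(n_nodes), session = session),
            class = "cpm_cohort")
}

#' @export
print.cpm_cohort <- function(x, ...) {
  cat(sprintf("<cpm_cohort> %d participants, %d nodes (%d edges), session '%s'\n",
              nrow(x$participants), x$n_nodes, ncol(x$edges), x$session))
  invisible(x)
}

#' Generate a synthetic training cohort with planted ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `cohort` (class `cpm_cohort`: a participant
#'   table and an n x E edge matrix in canonical order) and `truth` (class
#'   `cpm_ground_truth`: planted positive/negative edge index sets, the
#'   per-participant latent trait, and the external affine map).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_participants
  n_edges <- n_edges_for(spec$n_nodes)
  with_seed(spec$seed, {
    planted <- sample.int(n_edges, spec$n_pos_edges + spec$n_neg_edges)
    pos <- sort(planted[seq_len(spec$n_pos_edges)])
    neg <- sort(setdiff(planted, pos))
    latent <- stats::rnorm(n)
    gf <- round(spec$gf_mean + spec$gf_sd * latent)
    edges <- matrix(stats::rnorm(n * n_edges), n, n_edges)
    r <- spec$effect_r
    if (length(pos)) {
      edges[, pos] <- r * latent + sqrt(1 - r^2) * edges[, pos]
    }
    if (length(neg)) {
      edges[, neg] <- -r * latent + sqrt(1 - r^2) * edges[, neg]
    }
    participants <- data.frame(
      id = sprintf("sub-%04d", seq_len(n)),
      gf = gf,
      age = round(stats::rnorm(n, 20, 1)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      mean_fd = 0.03 + stats::rgamma(n, shape = 2, scale = 0.02),
      session = 1L,
      stringsAsFactors = FALSE
    )
    truth <- structure(list(
      pos_edges = pos, neg_edges = neg,
      latent = stats::setNames(latent, participants$id),
      effect_r = r, n_nodes = spec$n_nodes,
      external_scale = spec$external_scale,
      external_offset = spec$external_offset,
      seed = spec$seed
    ), class = "cpm_ground_truth")
    list(cohort = new_cohort(participants, edges, spec$n_nodes, "time1"),
         truth = truth)
  })
}

#' Generate a retest session of an existing cohort
#'
#' Edge vectors are a reliability-weighted mixture of the session-1 edges and
#' fresh standard-normal noise: `e2 = rho * e1 + sqrt(1 - rho^2) * noise`.
#' Because session-1 edges have unit population variance, the edgewise
#' test-retest correlation equals `reliability` analytically. Gf scores,
#' covariates and participant ids are unchanged (Gf is treated as a trait).
#'
#' @param cohort Session-1 cohort from [generate_cohort()].
#' @param truth Matching ground truth.
#' @param reliability Edgewise retest correlation in `[0, 1]`.
#' @param seed RNG seed.
#' @param session Session label for the new cohort.
#' @return A `cpm_cohort` for the retest session.
#' @export
generate_retest <- function(cohort, truth, reliability, seed,
                            session = "time2") {
  stopifnot(inherits(cohort, "cpm_cohort"), inherits(truth, "cpm_ground_truth"))
  assert_scalar_prob(reliability, "reliability")
  if (!identical(cohort$participants$id, names(truth$latent))) {
    stop("cohort and ground truth describe different participants",
         call. = FALSE)
  }
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(cohort$edges)),
                    nrow(cohort$edges), ncol(cohort$edges))
    edges2 <- reliability * cohort$edges + sqrt(1 - reliability^2) * noise
    participants <- cohort$participants
    participants$session <- session
    new_cohort(participants, edges2, cohort$n_nodes, session)
  })
}

#' Generate an external cohort sharing the planted edge sets
#'
#' New participants are drawn with fresh latent traits; planted edges
#' correlate with the latent trait at the spec's `effect_r` with the planted
#' signs, and the behavioral score is
#' `external_scale * (latent + noise) + external_offset`, emulating an
#' external sample scored on a different instrument.
#'
#' @param spec The [synthetic_spec()] (supplies sizes and the affine map).
#' @param truth Ground truth from [generate_cohort()] (supplies edge sets).
#' @param seed RNG seed.
#' @return A `cpm_cohort` with attribute `latent` (the new latent traits).
#' @export
generate_external <- function(spec, truth, seed) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "cpm_ground_truth"))
  n <- spec$n_external
  n_edges <- n_edges_for(spec$n_nodes)
  with_seed(seed, {
    latent <- stats::rnorm(n)
    edges <- matrix(stats::rnorm(n * n_edges), n, n_edges)
    r <- truth$effect_r
    if (length(truth$pos_edges)) {
      edges[, truth$pos_edges] <- r * latent +
        sqrt(1 - r^2) * edges[, truth$pos_edges]
    }
    if (length(truth$neg_edges)) {
      edges[, truth$neg_edges] <- -r * latent +
        sqrt(1 - r^2) * edges[, truth$neg_edges]
    }
    score <- spec$external_scale *
      (latent + stats::rnorm(n, sd = spec$external_noise_sd)) +
      spec$external_offset
    participants <- data.frame(
      id = sprintf("ext-%04d", seq_len(n)),
      gf = score,
      age = round(stats::rnorm(n, 22, 2)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      mean_fd = 0.03 + stats::rgamma(n, shape = 2, scale = 0.02),
      session = "external",
      stringsAsFactors = FALSE
    )
    out <- new_cohort(participants, edges, spec$n_nodes, "external")
    attr(out, "latent") <- stats::setNames(latent, participants$id)
    out
  })
}

#' Generate a rigid-body motion trace with FD spikes
#'
#' The baseline is a slow random walk (per-frame increments of SD 0.01 mm for
#' translations and 0.0002 rad for rotations) whose framewise displacement
#' stays well below 0.5 mm. Spikes are isolated single-frame step changes of
#' 0.8 mm in one translation axis, so each spike frame (and only that frame)
#' exceeds the 0.5 mm FD threshold; this exercises the scrubbing window
#' unambiguously.
#'
#' @param n_frames Number of frames (>= 2).
#' @param fd_spike_rate Per-frame spike probability (frames 2..n).
#' @param seed RNG seed.
#' @param tr_seconds Repetition time, carried as metadata.
#' @return A [motion_trace()] (rotations in radians).
#' @export
generate_motion_trace <- function(n_frames, fd_spike_rate = 0.02, seed = 1L,
                                  tr_seconds = 2) {
  if (n_frames < 2) stop("n_frames must be at least 2", call. = FALSE)
  assert_scalar_prob(fd_spike_rate, "fd_spike_rate")
  with_seed(seed, {
    inc <- cbind(matrix(stats::rnorm(n_frames * 3, sd = 0.01), n_frames, 3),
                 matrix(stats::rnorm(n_frames * 3, sd = 2e-4), n_frames, 3))
    inc[1, ] <- 0
    params <- apply(inc, 2, cumsum)
    spike_frames <- which(stats::runif(n_frames - 1) < fd_spike_rate) + 1L
    for (f in spike_frames) {
      step <- sample(c(-0.8, 0.8), 1L)
      params[f:n_frames, 1] <- params[f:n_frames, 1] + step
    }
    motion_trace(params, tr_seconds = tr_seconds)
  })
}

#' Generate a toy probability volume and network label volume
#'
#' Builds `n_components` disjoint box-shaped blobs of white-matter
#' probability 1 (background 0) inside a grid, plus a label volume assigning
#' each blob voxel a component id in `1..n_components`. Stand-ins for the
#' segmentation probability map and an 11-network label atlas; they carry no
#' anatomical meaning.
#'
#' @param shape Length-3 integer grid dimensions.
#' @param n_components Number of disjoint blobs (labels).
#' @param seed RNG seed (jitters blob extents).
#' @return List with `prob` (array in `[0, 1]`) and `labels` (integer array,
#'   0 = background).
#' @export
generate_toy_volume <- function(shape, n_components = 2, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1), n_components >= 1)
  if (shape[1] < 2 * n_components) {
    stop("shape[1] too small to hold disjoint components", call. = FALSE)
  }
  with_seed(seed, {
    prob <- array(0, dim = shape)
    labels <- array(0L, dim = shape)
    # partition the x axis into n_components bands; one blob per band with a
    # one-voxel gap so components are spatially disjoint
    cuts <- floor(seq(0, shape[1], length.out = n_components + 1))
    for (k in seq_len(n_components)) {
      x0 <- cuts[k] + 1L
      x1 <- max(x0, cuts[k + 1] - (if (k < n_components) 1L else 0L))
      y <- seq_len(shape[2]); z <- seq_len(shape[3])
      prob[x0:x1, y, z] <- 1
      labels[x0:x1, y, z] <- k
    }
    prob <- pmin(pmax(prob, 0), 1)
    list(prob = prob, labels = labels)
  })
}
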