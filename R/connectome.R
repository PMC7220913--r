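# Fisher-z functional connectomes and canonical edge vectors.

#' Average voxel signals into node time series
#'
#' Columns of `ts` must correspond, in array (column-major) order, to the
#' labeled voxels of the parcellation; the node signal is the arithmetic mean
#' of its voxels at each frame.
#'
#' @param ts A [wm_time_series()] over voxels.
#' @param parc A [parcellate()] result whose labeled voxel count equals the
#'   channel count of `ts`.
#' @return A `wm_time_series` over nodes (columns ordered by node id).
#' @export
node_timeseries <- function(ts, parc) {
  stopifnot(inherits(ts, "wm_time_series"), inherits(parc, "parcellation"))
  voxel_labels <- parc$labels[parc$labels > 0]
  if (length(voxel_labels) != ncol(ts$values)) {
    stop(sprintf("time series has %d channels but parcellation labels %d voxels",
                 ncol(ts$values), length(voxel_labels)), call. = FALSE)
  }
  K <- length(parc$sizes)
  if (any(tabulate(voxel_labels, K) == 0L)) {
    stop("parcellation contains an empty node", call. = FALSE)
  }
  # rowsum aggregates columns via the transpose
  sums <- t(rowsum(t(ts$values), group = voxel_labels))
  node_vals <- sweep(sums, 2, tabulate(voxel_labels, K), "/")
  colnames(node_vals) <- NULL
  wm_time_series(node_vals, ts$tr_seconds, ts$frame_retained)
}

#' Pearson connectivity matrix over retained frames
#'
#' @param node_ts A [wm_time_series()] over nodes; only frames with
#'   `frame_retained == TRUE` enter the correlation (at least 3 required).
#' @return Symmetric K x K Pearson correlation matrix (diagonal 1).
#' @export
connectivity_matrix <- function(node_ts) {
  stopifnot(inherits(node_ts, "wm_time_series"))
  vals <- node_ts$values[node_ts$frame_retained, , drop = FALSE]
  if (nrow(vals) < 3L) {
    stop("fewer than 3 retained frames; cannot estimate correlations",
         call. = FALSE)
  }
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance node(s): %s",
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(vals)
  (r + t(r)) / 2
}

#' Fisher r-to-z transform of a connectivity matrix
#'
#' `z = atanh(r)` elementwise; the diagonal is set to 0 and matrices are
#' never thresholded, binarized or sparsified. Entries with `|r| >= 1`
#' (numerically degenerate) are clamped to `1 - 1e-7` in magnitude with a
#' warning.
#'
#' @param r_matrix Symmetric correlation matrix.
#' @param n_frames_used Optional count of frames behind the estimate
#'   (metadata).
#' @return An object of class `connectome`: `z_matrix`, `edge_vector`
#'   (canonical order, see [edge_nodes()]), `n_frames_used`.
#' @export
fisher_z <- function(r_matrix, n_frames_used = NA_integer_) {
  r_matrix <- as.matrix(r_matrix)
  if (nrow(r_matrix) != ncol(r_matrix)) stop("matrix must be square", call. = FALSE)
  clamp <- abs(r_matrix) >= 1
  diag(clamp) <- FALSE
  if (any(clamp)) {
    warning(sprintf("%d |r| >= 1 entr%s clamped to 1 - 1e-7",
                    sum(clamp), if (sum(clamp) == 1) "y" else "ies"),
            call. = FALSE)
    r_matrix[clamp] <- sign(r_matrix[clamp]) * (1 - 1e-7)
  }
  z <- atanh(r_matrix)
  diag(z) <- 0
  structure(list(z_matrix = z, edge_vector = vectorize_edges(z),
                 n_frames_used = n_frames_used),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes, %d edges (Fisher z), %s frames\n",
              nrow(x$z_matrix), length(x$edge_vector),
              ifelse(is.na(x$n_frames_used), "?", x$n_frames_used)))
  invisible(x)
}

#' Vectorize a symmetric matrix into the canonical edge order
#'
#' Row-major upper triangle: (1,2), (1,3), ..., (1,K), (2,3), ...,
#' (K-1,K). The diagonal is excluded.
#'
#' @param m Symmetric matrix (or a `connectome`, whose `z_matrix` is used).
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length K(K-1)/2.
#' @seealso [devectorize_edges()], [edge_nodes()]
#' @export
vectorize_edges <- function(m, tol = 1e-8) {
  if (inherits(m, "connectome")) return(m$edge_vector)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > tol) {
    stop("matrix is asymmetric beyond tolerance", call. = FALSE)
  }
  # t(m)[lower.tri(m)] walks the upper triangle in row-major order
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' @param v Edge vector of length K(K-1)/2.
#' @param diag_value Value placed on the diagonal (default 0).
#' @return Symmetric K x K matrix.
#' @export
devectorize_edges <- function(v, diag_value = 0) {
  e <- length(v)
  K <- (1 + sqrt(1 + 8 * e)) / 2
  if (K != round(K)) stop("edge vector length is not K(K-1)/2 for integer K",
                          call. = FALSE)
  K <- as.integer(K)
  m <- matrix(0, K, K)
  m[lower.tri(m)] <- v   # fills column-major lower = row-major upper of t(m)
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}
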