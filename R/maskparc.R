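# Group white-matter mask construction and equal-size spatial parcellation.
#
# Volumes are plain 3-D R arrays on a common grid (probability volumes in
# [0, 1], masks logical, label volumes integer). Threshold comparisons are
# inclusive (>=) throughout.

assert_volume <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(sprintf("%s must be a 3-D array", name), call. = FALSE)
  }
  invisible(x)
}

assert_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("volumes are defined on different grids", call. = FALSE)
  }
}

#' Threshold an individual white-matter probability map
#'
#' A voxel enters the individual mask iff its WM probability is at least
#' `threshold` (default the rigorous 0.90 used to keep the mask clear of the
#' gray-matter boundary).
#'
#' @param prob 3-D probability array with values in `[0, 1]`.
#' @param threshold Inclusion threshold (inclusive).
#' @return Logical 3-D mask array.
#' @export
individual_wm_mask <- function(prob, threshold = 0.90) {
  assert_volume(prob, "probability volume")
  if (anyNA(prob) || min(prob) < 0 || max(prob) > 1) {
    stop("probability volume must lie in [0, 1]", call. = FALSE)
  }
  prob >= threshold
}

#' Build the group white-matter mask
#'
#' A voxel enters the group mask iff it is present in at least
#' `ceiling(coverage * n)` of the `n` individual masks ("across 80% of
#' participants" read as at-least; with 5 masks, presence in 4 qualifies).
#'
#' @param masks List of logical 3-D arrays on the same grid.
#' @param coverage Required participant fraction (default 0.80).
#' @return Logical 3-D group mask.
#' @export
group_wm_mask <- function(masks, coverage = 0.80) {
  stopifnot(is.list(masks), length(masks) >= 1)
  assert_scalar_prob(coverage, "coverage")
  lapply(masks, assert_volume, name = "mask")
  for (m in masks) assert_same_grid(masks[[1]], m)
  counts <- Reduce(`+`, masks)
  need <- ceiling(coverage * length(masks) - 1e-9)
  counts >= need
}

#' Remove atlas-labeled regions from a mask
#'
#' Voxels whose region probability (e.g. a subcortical-nuclei probability
#' atlas) is at least `threshold` (default 0.25) are removed from the mask.
#'
#' @param mask Logical 3-D mask.
#' @param region_prob 3-D probability array on the same grid.
#' @param threshold Removal threshold (inclusive).
#' @return Logical 3-D mask.
#' @export
remove_labeled_regions <- function(mask, region_prob, threshold = 0.25) {
  assert_volume(mask, "mask"); assert_volume(region_prob, "region probability")
  assert_same_grid(mask, region_prob)
  mask & !(region_prob >= threshold)
}

# 6-connectivity neighbors of voxel rows (coords: m x 3 integer matrix)
neighbor_offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

# connected components of a voxel subset, 6-connectivity; returns component
# id per voxel row
connected_components <- function(coords, dims) {
  m <- nrow(coords)
  lin <- as.integer((coords[, 3] - 1) * dims[1] * dims[2] +
                      (coords[, 2] - 1) * dims[1] + coords[, 1])
  row_of <- new.env(hash = TRUE, size = m)
  for (k in seq_len(m)) assign(as.character(lin[k]), k, envir = row_of)
  comp <- integer(m)
  cur <- 0L
  for (start in seq_len(m)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(6)) {
        nb <- coords[v, ] + neighbor_offsets[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        nlin <- as.character((nb[3] - 1) * dims[1] * dims[2] +
                               (nb[2] - 1) * dims[1] + nb[1])
        idx <- row_of[[nlin]]
        if (!is.null(idx) && comp[idx] == 0L) {
          comp[idx] <- cur
          queue <- c(queue, idx)
        }
      }
    }
  }
  comp
}

#' Parcellate a mask into roughly equal-size contiguous nodes
#'
#' Spatially constrained, size-aware k-means on voxel coordinates: k-means++
#' style seeding and Lloyd iterations (multiple starts, best size balance
#' kept), followed by a contiguity repair that reattaches detached fragments
#' to the neighboring node with the largest contact surface, and a balance
#' pass that moves boundary voxels from oversized to adjacent smaller nodes.
#' Deterministic given `seed`.
#'
#' @param mask Logical 3-D array.
#' @param K Number of nodes (default 128); must not exceed the voxel count.
#' @param seed RNG seed.
#' @param nstart Number of k-means starts.
#' @return An object of class `parcellation`: `labels` (integer array,
#'   0 = background), `sizes` (voxel count per node), `network_of_node`
#'   (filled by [assign_networks()], initially `NA`).
#' @export
parcellate <- function(mask, K = 128, seed = 1L, nstart = 5L) {
  assert_volume(mask, "mask")
  coords <- which(mask, arr.ind = TRUE)
  nvox <- nrow(coords)
  if (K < 1) stop("K must be positive", call. = FALSE)
  if (K > nvox) {
    stop(sprintf("K = %d exceeds mask voxel count %d", K, nvox), call. = FALSE)
  }
  dims <- dim(mask)
  labels_arr <- array(0L, dim = dims)
  if (K == 1L) {
    labels_arr[mask] <- 1L
    return(structure(list(labels = labels_arr, sizes = nvox,
                          network_of_node = NA_integer_),
                     class = "parcellation"))
  }
  lab <- with_seed(seed, {
    best <- NULL
    best_cv <- Inf
    xy <- coords + 0.0
    for (s in seq_len(nstart)) {
      km <- tryCatch(
        stats::kmeans(xy, centers = K, iter.max = 100, nstart = 1),
        error = function(e) NULL)
      if (is.null(km)) next
      cv <- stats::sd(tabulate(km$cluster, K)) / mean(tabulate(km$cluster, K))
      if (cv < best_cv) { best_cv <- cv; best <- km$cluster }
    }
    if (is.null(best)) stop("k-means failed on the mask coordinates", call. = FALSE)
    best
  })
  lab <- repair_contiguity(coords, lab, K, dims)
  lab <- balance_sizes(coords, lab, K, dims)
  labels_arr[mask] <- 0L
  labels_arr[cbind(coords)] <- lab
  sizes <- tabulate(lab, K)
  structure(list(labels = labels_arr, sizes = sizes,
                 network_of_node = rep(NA_integer_, K)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d nodes, %d voxels, sizes %d-%d%s\n",
              length(x$sizes), sum(x$sizes), min(x$sizes), max(x$sizes),
              if (all(is.na(x$network_of_node))) "" else ", networks assigned"))
  invisible(x)
}

# reattach non-largest connected fragments of each label to the adjacent
# label with the most contact
repair_contiguity <- function(coords, lab, K, dims) {
  lin_index <- function(cc) (cc[, 3] - 1) * dims[1] * dims[2] +
    (cc[, 2] - 1) * dims[1] + cc[, 1]
  lab_of <- new.env(hash = TRUE, size = nrow(coords))
  lin <- lin_index(coords)
  for (pass in 1:5) {
    for (k in seq_len(nrow(coords))) assign(as.character(lin[k]), lab[k], envir = lab_of)
    changed <- FALSE
    for (node in seq_len(K)) {
      rows <- which(lab == node)
      if (!length(rows)) next
      comp <- connected_components(coords[rows, , drop = FALSE], dims)
      if (max(comp) == 1L) next
      sizes <- tabulate(comp)
      keep <- which.max(sizes)
      for (c_id in setdiff(seq_along(sizes), keep)) {
        frag <- rows[comp == c_id]
        # majority label among neighbors outside the fragment
        votes <- integer(0)
        for (v in frag) {
          for (o in seq_len(6)) {
            nb <- coords[v, ] + neighbor_offsets[o, ]
            if (any(nb < 1) || any(nb > dims)) next
            nlab <- lab_of[[as.character((nb[3] - 1) * dims[1] * dims[2] +
                                           (nb[2] - 1) * dims[1] + nb[1])]]
            if (!is.null(nlab) && nlab != node) votes <- c(votes, nlab)
          }
        }
        if (length(votes)) {
          lab[frag] <- as.integer(names(which.max(table(votes))))
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# move boundary voxels from oversized nodes to adjacent smaller nodes until
# max/min size <= 2 (or the move budget is exhausted)
balance_sizes <- function(coords, lab, K, dims) {
  lin_of <- function(cc) (cc[3] - 1) * dims[1] * dims[2] + (cc[2] - 1) * dims[1] + cc[1]
  budget <- 10L * nrow(coords) %/% max(K, 1L)
  for (iter in seq_len(max(budget, 1L))) {
    sizes <- tabulate(lab, K)
    if (min(sizes) == 0L || max(sizes) <= 2L * min(sizes)) break
    big <- which.max(sizes)
    rows <- which(lab == big)
    lab_env <- new.env(hash = TRUE, size = nrow(coords))
    for (k in seq_len(nrow(coords))) {
      assign(as.character(lin_of(coords[k, ])), lab[k], envir = lab_env)
    }
    moved <- FALSE
    best_target <- NA_integer_; best_row <- NA_integer_; best_size <- Inf
    for (v in rows) {
      for (o in seq_len(6)) {
        nb <- coords[v, ] + neighbor_offsets[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        nlab <- lab_env[[as.character(lin_of(nb))]]
        if (!is.null(nlab) && nlab != big && sizes[nlab] < best_size) {
          best_size <- sizes[nlab]; best_target <- nlab; best_row <- v
        }
      }
    }
    if (!is.na(best_target) && best_size < sizes[big] - 1L) {
      lab[best_row] <- best_target
      moved <- TRUE
    }
    if (!moved) break
  }
  lab
}

#' Assign nodes to functional networks by majority vote
#'
#' Each node receives the majority network label among its voxels in the
#' supplied label volume (e.g. an 11-network white-matter atlas stand-in).
#' Ties go to the lowest label id (logged via `message`).
#'
#' @param parc A [parcellate()] result.
#' @param network_label_volume Integer 3-D array, 0 = unlabeled.
#' @return The `parcellation` with `network_of_node` filled.
#' @export
assign_networks <- function(parc, network_label_volume) {
  stopifnot(inherits(parc, "parcellation"))
  assert_volume(network_label_volume, "network label volume")
  assert_same_grid(parc$labels, network_label_volume)
  K <- length(parc$sizes)
  nets <- integer(K)
  for (node in seq_len(K)) {
    labs <- network_label_volume[parc$labels == node]
    labs <- labs[labs > 0]
    if (!length(labs)) {
      stop(sprintf("node %d overlaps no network labels", node), call. = FALSE)
    }
    tab <- table(labs)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) > 1L) {
      message(sprintf("node %d: network tie among {%s}; lowest id %d used",
                      node, paste(winners, collapse = ", "), min(winners)))
    }
    nets[node] <- min(winners)
  }
  parc$network_of_node <- nets
  parc
}
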