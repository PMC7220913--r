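# Plain-text serialization: cohorts (participant CSV + edge-matrix TSV),
# ground truth and result summaries (JSON), connectome matrices (headerless
# delimited text), volumes (voxel-table TSV with a dims header line).

#' Write a cohort to a directory
#'
#' Writes `participants.csv` (id, gf, age, sex, mean_fd, session) and
#' `edges.tsv` (one row per participant, canonical edge order, id in the
#' first column).
#'
#' @param cohort A `cpm_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  edges <- data.frame(id = cohort$participants$id, cohort$edges,
                      stringsAsFactors = FALSE)
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(list(n_nodes = cohort$n_nodes,
                                   session = cohort$session),
                              auto_unbox = TRUE),
             file.path(dir, "cohort.json"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `participants.csv`, `edges.tsv`,
#'   `cohort.json`.
#' @return A `cpm_cohort`.
#' @export
read_cohort <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  raw <- utils::read.table(file.path(dir, "edges.tsv"), sep = "\t",
                           stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(file.path(dir, "cohort.json"))
  ids <- raw[[1]]
  edges <- as.matrix(raw[, -1, drop = FALSE])
  dimnames(edges) <- NULL
  edges <- edges[match(participants$id, ids), , drop = FALSE]
  new_cohort(participants, edges, meta$n_nodes, meta$session)
}

#' Write ground truth as JSON
#'
#' @param truth A `cpm_ground_truth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "cpm_ground_truth"))
  writeLines(jsonlite::toJSON(list(
    pos_edges = truth$pos_edges, neg_edges = truth$neg_edges,
    effect_r = truth$effect_r, n_nodes = truth$n_nodes,
    external_scale = truth$external_scale,
    external_offset = truth$external_offset,
    latent = as.list(truth$latent), seed = truth$seed
  ), auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Write a feature mask as JSON
#'
#' @param mask A [feature_mask()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_mask <- function(mask, path) {
  stopifnot(inherits(mask, "feature_mask"))
  writeLines(jsonlite::toJSON(unclass(mask), auto_unbox = TRUE), path)
  invisible(path)
}

#' Read a feature mask written by [write_feature_mask()]
#' @param path JSON file.
#' @return A [feature_mask()].
#' @export
read_feature_mask <- function(path) {
  x <- jsonlite::fromJSON(path)
  feature_mask(x$positive_edges, x$negative_edges, x$p_threshold)
}

#' Write a connectivity matrix as headerless delimited text
#' @param m K x K matrix (or `connectome`, whose `z_matrix` is written).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(m, path) {
  if (inherits(m, "connectome")) m <- m$z_matrix
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectome()]
#' @param path Delimited text file (K headerless rows).
#' @return Numeric K x K matrix.
#' @export
read_connectome <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  m
}

#' Write a 3-D volume as a voxel-table TSV
#'
#' First line is a comment `# dims: a b c`; the body has columns x, y, z,
#' value for the nonzero voxels.
#'
#' @param vol 3-D array.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(vol, path) {
  assert_volume(vol)
  idx <- which(vol != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims: %s", paste(dim(vol), collapse = " ")), con)
  utils::write.table(data.frame(idx, value = vol[idx]), con, sep = "\t",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a volume written by [write_volume_table()]
#' @param path Voxel-table TSV.
#' @return 3-D array (zeros where no voxel listed).
#' @export
read_volume_table <- function(path) {
  header <- readLines(path, n = 1)
  dims <- as.integer(strsplit(sub("# dims: ", "", header), " ")[[1]])
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  vol <- array(0, dim = dims)
  vol[as.matrix(tab[, 1:3])] <- tab$value
  vol
}
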