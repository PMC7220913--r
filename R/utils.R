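#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are deterministic without clobbering the
#' session's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Node pairs of the canonical edge ordering
#'
#' Edges are ordered row-major along the upper triangle:
#' (1,2), (1,3), ..., (1,K), (2,3), ..., (K-1,K). All edge vectors, feature
#' masks and ground-truth edge sets in the package use this order.
#'
#' @param n_nodes Number of nodes K.
#' @return Integer matrix with `K(K-1)/2` rows and columns `i`, `j` (i < j).
#' @export
#' @examples
#' edge_nodes(4)
edge_nodes <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes),
              use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' @keywords internal
n_edges_for <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1L) / 2L)

#' @keywords internal
assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
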