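#' Enumerate transformer patch coordinates
#'
#' Each non-overlapping `p x p` patch of the feature grid is one
#' transformer token; its 2D coordinate is its (row, col) index on the
#' patch grid. Enumeration is row-major (column varies fastest), matching
#' the flattening order of the patch embedding.
#'
#' @param grid_h,grid_w spatial dimensions of the (already padded) grid.
#' @param patch_size patch side length `p`; must divide both dimensions.
#' @return `N x 2` integer matrix of 0-based `(row, col)` patch indices,
#'   `N = (grid_h/p) * (grid_w/p)`.
#' @export
patch_coords <- function(grid_h, grid_w, patch_size) {
  if (!is_count(grid_h, 1L) || !is_count(grid_w, 1L) ||
      !is_count(patch_size, 1L))
    stop_resolvst("dimensions and patch_size must be positive integers",
                  "parameter")
  if (grid_h %% patch_size != 0L || grid_w %% patch_size != 0L)
    stop_resolvst(
      "grid dimensions must be divisible by patch_size; pad the grid first (see pad_grid)",
      "contract")
  nh <- grid_h %/% patch_size; nw <- grid_w %/% patch_size
  cbind(row = rep(seq_len(nh) - 1L, each = nw),
        col = rep(seq_len(nw) - 1L, times = nh))
}

#' Gaussian-kernel kNN patch graph
#'
#' Builds the spatial graph the graph module aggregates over. For patch
#' coordinates `p_i`, pairwise Euclidean distances `d_ij = |p_i - p_j|`
#' are mapped through a Gaussian kernel `A_ij = exp(-d_ij^2 / (2 sigma^2))`;
#' only each patch's `k` nearest neighbours are retained (mask `M_ij`,
#' self excluded by default, distance ties broken toward the smaller
#' linear index), and rows are normalized:
#' `Atilde_ij = A_ij M_ij / (sum_j A_ij M_ij + epsilon)`.
#' Every row of the result is non-negative with at most `k` nonzeros and
#' sums to just under 1 (exactly 1 in the limit `epsilon -> 0`). The graph
#' depends only on geometry and is built once per input shape.
#'
#' @param coords `N x 2` matrix of patch coordinates (see [patch_coords()]).
#' @param sigma Gaussian kernel bandwidth in patch-index units (default 1).
#' @param k number of nearest neighbours kept per patch (default 4, the
#'   four lattice neighbours).
#' @param epsilon ridge added to the row-normalization denominator.
#' @param include_self count a patch as its own neighbour (default FALSE:
#'   the distance-0 self weight would dominate the kernel).
#' @return Object of class `"patch_graph"`: list with `coords`,
#'   `adjacency` (dense `N x N`), `sigma`, `k`, `epsilon`.
#' @export
build_adjacency <- function(coords, sigma = 1, k = 4L, epsilon = 1e-8,
                            include_self = FALSE) {
  coords <- as.matrix(coords)
  N <- nrow(coords)
  if (N < 2L) stop_resolvst("need at least 2 patches", "parameter")
  if (!is.numeric(sigma) || sigma <= 0) stop_resolvst("sigma must be > 0", "parameter")
  if (!is.numeric(epsilon) || epsilon <= 0) stop_resolvst("epsilon must be > 0", "parameter")
  if (!is_count(k, 1L) || k >= N)
    stop_resolvst("k must satisfy 1 <= k < N", "parameter")
  d2 <- as.matrix(stats::dist(coords))^2
  A <- exp(-d2 / (2 * sigma^2))
  M <- matrix(0, N, N)
  for (i in seq_len(N)) {
    cand <- seq_len(N)
    if (!include_self) cand <- cand[cand != i]
    ## ties broken by smaller index: order() is stable over the index order
    nn <- cand[order(d2[i, cand])][seq_len(k)]
    M[i, nn] <- 1
  }
  AM <- A * M
  At <- AM / (rowSums(AM) + epsilon)
  structure(list(coords = coords, adjacency = At, sigma = sigma,
                 k = as.integer(k), epsilon = epsilon),
            class = "patch_graph")
}

#' @export
print.patch_graph <- function(x, ...) {
  cat(sprintf("patch_graph: %d patches, k = %d, sigma = %g\n",
              nrow(x$coords), x$k, x$sigma))
  invisible(x)
}

#' One round of neighbour aggregation
#'
#' The message-passing update of the graph module: each patch embedding is
#' replaced by the row-normalized Gaussian-weighted average of its
#' neighbours, `Atilde %*% z`.
#'
#' @param graph a [build_adjacency()] result.
#' @param z `N x D` matrix, one embedding row per patch.
#' @return `N x D` matrix of aggregated embeddings.
#' @export
aggregate_patches <- function(graph, z) {
  stopifnot(inherits(graph, "patch_graph"))
  z <- as.matrix(z)
  if (nrow(z) != nrow(graph$adjacency))
    stop_resolvst("z must have one row per patch", "contract")
  graph$adjacency %*% z
}

#' Export adjacency as a sparse triplet table
#'
#' @param graph a [build_adjacency()] result.
#' @param path optional TSV path; when NULL the data frame is returned only.
#' @return Data frame with 0-based columns `i`, `j` and `weight`, one row
#'   per nonzero edge.
#' @export
adjacency_triplets <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "patch_graph"))
  nz <- which(graph$adjacency > 0, arr.ind = TRUE)
  df <- data.frame(i = nz[, 1L] - 1L, j = nz[, 2L] - 1L,
                   weight = graph$adjacency[nz])
  df <- df[order(df$i, df$j), ]
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
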