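#' Geometric down-sampling of an expression grid
#'
#' Implements the evaluation protocol used to benchmark lattice
#' super-resolution: spots at every second position are retained as the
#' simulated low-resolution measurement and all remaining tissue positions
#' become masked locations whose expression is removed from the input and
#' held out as imputation targets.
#'
#' Two dialects exist, matching the two array geometries:
#' \describe{
#'   \item{square (`downsample_square`)}{retain positions with
#'     `row %% 2 == 0 & col %% 2 == 0` (step size 2 in both axes).}
#'   \item{Visium honeycomb (`downsample_visium`)}{alternating even-odd
#'     rule: retain occupied positions whose row and column are both even.
#'     On the staggered lattice these are exactly the even-parity spots
#'     whose halved indices tile a complete rectangular grid, so the
#'     retained set keeps the section's geometric coverage.}
#' }
#' The retained positions are re-indexed by halving to a
#' `ceiling(H/2) x ceiling(W/2)` grid. Down-sampling is purely geometric:
#' it depends only on the mask, never on expression values.
#'
#' @param g an [expression_grid()] of the matching lattice.
#' @return Object of class `"downsample_result"`: list with `low_res` (an
#'   [expression_grid()]), `masked_positions` (m x 2 integer matrix of
#'   0-based original-grid `(row, col)`), `retained_positions` (same shape),
#'   and `dialect`.
#' @export
downsample_square <- function(g) {
  stopifnot(inherits(g, "expression_grid"))
  if (g$lattice != "square")
    stop_resolvst("downsample_square expects a square-lattice grid",
                  "validation")
  downsample_lattice(g, "square_step2")
}

#' @rdname downsample_square
#' @export
downsample_visium <- function(g) {
  stopifnot(inherits(g, "expression_grid"))
  if (g$lattice != "visium_hex")
    stop_resolvst("downsample_visium expects a visium_hex grid", "validation")
  downsample_lattice(g, "visium_even_odd")
}

downsample_lattice <- function(g, dialect) {
  d <- dim(g$data); G <- d[1L]; H <- d[2L]; W <- d[3L]
  if (H < 2L || W < 2L)
    stop_resolvst("grid too small to down-sample (needs H, W >= 2)",
                  "degenerate")
  occ <- which(g$mask == 1, arr.ind = TRUE)  # 1-based
  if (nrow(occ) == 0L)
    stop_resolvst("grid has an empty tissue mask", "empty")
  r0 <- occ[, 1L] - 1L; c0 <- occ[, 2L] - 1L  # 0-based
  keep <- r0 %% 2L == 0L & c0 %% 2L == 0L
  Hl <- as.integer(ceiling(H / 2)); Wl <- as.integer(ceiling(W / 2))
  data <- array(0, dim = c(G, Hl, Wl))
  mask <- matrix(0L, Hl, Wl)
  for (s in which(keep)) {
    i <- r0[s] %/% 2L + 1L; j <- c0[s] %/% 2L + 1L
    data[, i, j] <- g$data[, occ[s, 1L], occ[s, 2L]]
    mask[i, j] <- 1L
  }
  ## the halved index grid is rectangular for both dialects (the even-even
  ## sublattice of a honeycomb halves to a full square grid)
  low <- expression_grid(data, mask, lattice = "square",
                         origin_offset = g$origin_offset,
                         gene_names = g$gene_names)
  ord <- function(m) m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  masked <- cbind(row = r0[!keep], col = c0[!keep])
  retained <- cbind(row = r0[keep], col = c0[keep])
  if (nrow(masked)) masked <- ord(masked)
  if (nrow(retained)) retained <- ord(retained)
  structure(list(low_res = low, masked_positions = masked,
                 retained_positions = retained, dialect = dialect,
                 full_dim = c(H, W)),
            class = "downsample_result")
}

#' @export
print.downsample_result <- function(x, ...) {
  cat(sprintf(
    "downsample_result (%s): %d retained, %d masked; low-res %d x %d\n",
    x$dialect, nrow(x$retained_positions), nrow(x$masked_positions),
    dim(x$low_res$data)[2L], dim(x$low_res$data)[3L]))
  invisible(x)
}

#' Build a self-supervised training pair
#'
#' Down-samples a full-resolution grid (dialect chosen by its lattice) and
#' pairs the low-resolution result with the original grid as
#' reconstruction target. The model's 2x output of `input` overlays
#' `target` position-for-position: retained spot `(2i, 2j)` sits at
#' low-res cell `(i, j)` and maps back to output position `(2i, 2j)`.
#' `target_mask` is the original tissue mask restricted to the `H x W`
#' window the 2x output covers, so non-tissue positions never contribute
#' to the loss.
#'
#' @param g an [expression_grid()].
#' @return List with `input` (low-res [expression_grid()]), `target`
#'   (original grid), `target_mask` (`H x W` binary), and `downsample`
#'   (the [downsample_square()] result).
#' @export
make_training_pair <- function(g) {
  stopifnot(inherits(g, "expression_grid"))
  ds <- if (g$lattice == "visium_hex") downsample_visium(g)
        else downsample_square(g)
  list(input = ds$low_res, target = g, target_mask = g$mask, downsample = ds)
}
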