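#' Construct an expression grid
#'
#' Dense tensor view of a spatial transcriptomics sample: a `G x H x W`
#' array of expression values plus an `H x W` binary tissue mask (1 =
#' occupied lattice position). Positions with `mask == 0` hold 0. This is
#' the native input representation of the super-resolution network, which
#' treats each gene as a single-channel grayscale image (`G x 1 x H x W`
#' with genes along the batch axis).
#'
#' For the staggered Visium honeycomb the raw `(array_row, array_col)`
#' index pairs are kept as-is on a rectangular grid: half the cells are
#' structurally empty and carried in the mask, which preserves the geometry
#' the even-odd down-sampling protocol needs.
#'
#' @param data numeric array `G x H x W`.
#' @param mask binary `H x W` matrix.
#' @param lattice `"square"` or `"visium_hex"`.
#' @param origin_offset integer pair: the coordinate shift applied so the
#'   minimum row/col maps to (0,0); used to restore original coordinates.
#' @param gene_names optional character vector of length `G`.
#' @return Object of class `"expression_grid"`.
#' @export
expression_grid <- function(data, mask, lattice = "square",
                            origin_offset = c(0L, 0L), gene_names = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop_resolvst("data must be a G x H x W array", "contract")
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(data)[2:3]))
    stop_resolvst("mask dimensions must match data spatial dimensions",
                  "contract")
  if (!all(mask %in% c(0, 1)))
    stop_resolvst("mask must be binary", "validation")
  if (any(!is.finite(data[rep(mask == 1, each = dim(data)[1L])])))
    stop_resolvst("expression must be finite at tissue positions", "validation")
  data[rep(mask == 0, each = dim(data)[1L])] <- 0
  structure(
    list(data = data, mask = mask, lattice = lattice,
         origin_offset = as.integer(origin_offset),
         gene_names = gene_names %||% paste0("gene_", seq_len(dim(data)[1L]))),
    class = "expression_grid")
}

#' @export
print.expression_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "expression_grid: %d genes on %d x %d lattice (%s), %d/%d tissue positions\n",
    d[1L], d[2L], d[3L], x$lattice, sum(x$mask), d[2L] * d[3L]))
  invisible(x)
}

#' @export
dim.expression_grid <- function(x) dim(x$data)

#' Rasterize a spot table onto a dense grid
#'
#' Shifts coordinates so the minimum row/col maps to (0,0) (the shift is
#' recorded in `origin_offset`), then places each spot's expression at its
#' lattice cell. Cells without a spot get mask 0 and value 0.
#'
#' @param x a [spot_table()].
#' @return An [expression_grid()]; `to_grid()` and [from_grid()] are exact
#'   inverses on occupied positions.
#' @export
to_grid <- function(x) {
  stopifnot(inherits(x, "spot_table"))
  r0 <- min(x$array_row); c0 <- min(x$array_col)
  ## honeycomb: keep the equal-parity invariant under the shift (a shift with
  ## odd row+col sum would flip every spot's parity and break the even-odd
  ## down-sampling geometry), so widen the offset by one where needed
  if (x$lattice == "visium_hex" && (r0 + c0) %% 2L == 1L) {
    if (c0 > 0L) c0 <- c0 - 1L else r0 <- r0 - 1L
  }
  r <- x$array_row - r0
  cc <- x$array_col - c0
  H <- max(r) + 1L; W <- max(cc) + 1L
  G <- nrow(x$expr)
  data <- array(0, dim = c(G, H, W))
  mask <- matrix(0L, H, W)
  for (s in seq_along(r)) {
    data[, r[s] + 1L, cc[s] + 1L] <- x$expr[, s]
    mask[r[s] + 1L, cc[s] + 1L] <- 1L
  }
  g <- expression_grid(data, mask, lattice = x$lattice,
                       origin_offset = c(r0, c0), gene_names = x$gene_names)
  if (!is.null(attr(x, "norm"))) attr(g, "norm") <- attr(x, "norm")
  g
}

#' Convert a grid back to a spot table
#'
#' One spot per `mask == 1` position, coordinates un-shifted by
#' `origin_offset`. For a 2x super-resolved grid pass the doubled offset
#' stored by [predict.superres()] so coordinates land on the doubled
#' lattice.
#'
#' @param g an [expression_grid()].
#' @param gene_names optional character vector overriding `g$gene_names`.
#' @return A [spot_table()].
#' @export
from_grid <- function(g, gene_names = NULL) {
  stopifnot(inherits(g, "expression_grid"))
  occ <- which(g$mask == 1, arr.ind = TRUE)
  if (nrow(occ) == 0L)
    stop_resolvst("grid has an empty tissue mask", "empty")
  occ <- occ[order(occ[, 1L], occ[, 2L]), , drop = FALSE]
  G <- dim(g$data)[1L]
  expr <- matrix(0, G, nrow(occ))
  for (s in seq_len(nrow(occ)))
    expr[, s] <- g$data[, occ[s, 1L], occ[s, 2L]]
  ## honeycomb parity survives only when the offset shift has equal parity;
  ## label square otherwise
  lattice <- g$lattice
  ar <- occ[, 1L] - 1L + g$origin_offset[1L]
  ac <- occ[, 2L] - 1L + g$origin_offset[2L]
  if (lattice == "visium_hex" && any(ar %% 2L != ac %% 2L)) lattice <- "square"
  spot_table(expr, ar, ac, lattice = lattice,
             gene_names = gene_names %||% g$gene_names)
}
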