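#' Classical interpolation baselines for masked-spot imputation
#'
#' Predicts gene expression at held-out lattice positions from the
#' retained low-resolution grid using classical interpolators, applied
#' per gene:
#' \describe{
#'   \item{`nearest`}{value of the closest retained spot (Euclidean
#'     distance in original lattice units; ties broken toward the smaller
#'     row-major index).}
#'   \item{`linear`}{bilinear interpolation on the low-resolution grid.}
#'   \item{`cubic`}{bicubic interpolation (separable Catmull-Rom kernel,
#'     `a = -0.5`, linear border extrapolation).}
#'   \item{`nedi`}{new edge-directed interpolation: a 2x upscale whose
#'     interpolation weights are estimated per position by ridge-regularized
#'     least squares on the local covariance of the low-resolution image
#'     (Li & Orchard 2001), with bilinear fallback at borders and
#'     ill-conditioned windows.}
#' }
#' Targets outside the convex hull of the retained lattice (where surface
#' interpolation is undefined) fall back to nearest-neighbour and are
#' flagged in the `outside_hull` attribute. Low-resolution cells without
#' tissue are filled with their nearest retained value before surface
#' interpolation. For the staggered Visium dialect all methods operate on
#' the parity-compressed rectangular sub-grid that the down-sampling
#' produces.
#'
#' @param ds a [downsample_square()] / [downsample_visium()] result.
#' @param method one of `"nearest"`, `"linear"`, `"cubic"`, `"nedi"`.
#' @param targets m x 2 matrix of 0-based original-grid `(row, col)`
#'   positions; defaults to the masked positions of `ds`.
#' @return Numeric matrix, targets in rows and genes in columns, with
#'   attribute `outside_hull` (logical per target).
#' @export
interpolate_baseline <- function(ds, method = c("nearest", "linear", "cubic",
                                                "nedi"),
                                 targets = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "downsample_result"))
  targets <- as.matrix(targets %||% ds$masked_positions)
  low <- ds$low_res
  G <- dim(low$data)[1L]
  ret <- ds$retained_positions
  if (nrow(ret) == 0L)
    stop_resolvst("no retained spots to interpolate from", "degenerate")
  if (method %in% c("linear", "cubic") && nrow(ret) < 4L)
    stop_resolvst("surface interpolation needs at least 4 retained spots",
                  "degenerate")
  n <- nrow(targets)
  out <- matrix(0, n, G)
  colnames(out) <- low$gene_names

  ## low-res fractional coordinates of the targets
  u <- targets[, 1L] / 2; v <- targets[, 2L] / 2
  Hl <- dim(low$data)[2L]; Wl <- dim(low$data)[3L]
  outside <- u < 0 | u > Hl - 1L | v < 0 | v > Wl - 1L

  ## retained values, spots x genes (row-major order of ret)
  retv <- grid_values_at(low, cbind(ret[, 1L] %/% 2L, ret[, 2L] %/% 2L))

  nearest_pred <- function(idx) {
    for (s in idx) {
      d2 <- (ret[, 1L] - targets[s, 1L])^2 + (ret[, 2L] - targets[s, 2L])^2
      out[s, ] <<- retv[which.min(d2), ]   # which.min takes the first tie
    }
  }

  if (method == "nearest") {
    nearest_pred(seq_len(n))
    attr(out, "outside_hull") <- outside
    return(out)
  }

  filled <- fill_missing_cells(low)
  inside <- which(!outside)
  if (method == "linear") {
    for (g in seq_len(G))
      out[inside, g] <- bilinear_at(filled[g, , ], u[inside], v[inside])
  } else if (method == "cubic") {
    for (g in seq_len(G))
      out[inside, g] <- bicubic_at(filled[g, , ], u[inside], v[inside])
  } else {
    for (g in seq_len(G)) {
      up <- nedi_upscale(filled[g, , ])
      for (s in inside)
        out[s, g] <- up[targets[s, 1L] + 1L, targets[s, 2L] + 1L]
    }
  }
  if (any(outside)) nearest_pred(which(outside))
  attr(out, "outside_hull") <- outside
  out
}

## fill low-res cells without tissue with their nearest retained value
fill_missing_cells <- function(low) {
  d <- dim(low$data)
  occ <- which(low$mask == 1, arr.ind = TRUE)
  miss <- which(low$mask == 0, arr.ind = TRUE)
  x <- low$data
  if (nrow(miss) > 0L) {
    for (q in seq_len(nrow(miss))) {
      d2 <- (occ[, 1L] - miss[q, 1L])^2 + (occ[, 2L] - miss[q, 2L])^2
      j <- occ[which.min(d2), ]
      x[, miss[q, 1L], miss[q, 2L]] <- x[, j[1L], j[2L]]
    }
  }
  x
}

## bilinear sample of matrix img at fractional (0-based) positions
bilinear_at <- function(img, u, v) {
  H <- nrow(img); W <- ncol(img)
  i0 <- pmin(pmax(floor(u), 0), H - 2L); fu <- u - i0
  j0 <- pmin(pmax(floor(v), 0), W - 2L); fv <- v - j0
  i0 <- i0 + 1L; j0 <- j0 + 1L
  img[cbind(i0, j0)] * (1 - fu) * (1 - fv) +
    img[cbind(i0, j0 + 1L)] * (1 - fu) * fv +
    img[cbind(i0 + 1L, j0)] * fu * (1 - fv) +
    img[cbind(i0 + 1L, j0 + 1L)] * fu * fv
}

## Catmull-Rom interpolation kernel (4 taps, linear precision)
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

## separable bicubic sample; the border is extended by linear
## extrapolation so the kernel's linear precision holds up to the hull edge
bicubic_at <- function(img, u, v) {
  H <- nrow(img); W <- ncol(img)
  P <- matrix(0, H + 4L, W + 4L)
  P[3:(H + 2L), 3:(W + 2L)] <- img
  for (o in 1:2) {
    P[3L - o, ] <- (1 + o) * P[3L, ] - o * P[4L, ]
    P[H + 2L + o, ] <- (1 + o) * P[H + 2L, ] - o * P[H + 1L, ]
  }
  for (o in 1:2) {
    P[, 3L - o] <- (1 + o) * P[, 3L] - o * P[, 4L]
    P[, W + 2L + o] <- (1 + o) * P[, W + 2L] - o * P[, W + 1L]
  }
  n <- length(u)
  out <- numeric(n)
  i0 <- floor(u); j0 <- floor(v)
  fu <- u - i0; fv <- v - j0
  for (s in seq_len(n)) {
    ri <- i0[s] + (-1:2) + 3L       # indices into the padded image
    cj <- j0[s] + (-1:2) + 3L
    wu <- cubic_kernel(fu[s] - (-1:2))
    wv <- cubic_kernel(fv[s] - (-1:2))
    ## Catmull-Rom weights sum to 1 exactly; no renormalization needed
    out[s] <- drop(wu %*% P[ri, cj] %*% wv)
  }
  out
}

## New edge-directed interpolation, canonical 2x form.
## Phase 1 estimates odd-odd pixels from the 4 diagonal low-res neighbours
## with weights fit by local least squares (window w x w, ridge lambda);
## phase 2 fills the axial positions the same way using axial neighbours.
nedi_upscale <- function(img, window = 4L, lambda = 1e-6) {
  H <- nrow(img); W <- ncol(img)
  up <- matrix(0, 2L * H, 2L * W)
  up[seq(1L, 2L * H, 2L), seq(1L, 2L * W, 2L)] <- img
  half <- window %/% 2L

  solve_weights <- function(C, y) {
    A <- crossprod(C) + diag(lambda * (1 + sum(diag(crossprod(C)))), 4L)
    b <- crossprod(C, y)
    w <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w))) return(NULL)
    w
  }

  ## phase 1 boundary: odd-odd cells beyond the last full diagonal quad
  ## take the mean of their in-range diagonal neighbours
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (i < H && j < W) next
    nb <- img[cbind(pmin(c(i, i, i + 1L, i + 1L), H),
                    pmin(c(j, j + 1L, j, j + 1L), W))]
    up[2L * i, 2L * j] <- mean(nb)
  }

  ## phase 1: odd-odd (between 4 diagonal low-res pixels)
  for (i in seq_len(H - 1L)) for (j in seq_len(W - 1L)) {
    ## training pixels: window around (i, j) with all diagonals in range
    ri <- max(2L, i - half + 1L):min(H - 1L, i + half)
    rj <- max(2L, j - half + 1L):min(W - 1L, j + half)
    tgt <- c(img[i, j], img[i, j + 1L], img[i + 1L, j], img[i + 1L, j + 1L])
    w <- NULL
    if (length(ri) >= 2L && length(rj) >= 2L) {
      cells <- expand.grid(r = ri, s = rj)
      C <- cbind(img[cbind(cells$r - 1L, cells$s - 1L)],
                 img[cbind(cells$r - 1L, cells$s + 1L)],
                 img[cbind(cells$r + 1L, cells$s - 1L)],
                 img[cbind(cells$r + 1L, cells$s + 1L)])
      y <- img[cbind(cells$r, cells$s)]
      w <- solve_weights(C, y)
    }
    up[2L * i, 2L * j] <- if (is.null(w)) mean(tgt) else sum(w * tgt)
  }

  ## phase 2: remaining positions from their 4 axial up-lattice neighbours
  fill_axial <- function(r, c) {
    nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= 2L * H &
          nb[, 2L] >= 1L & nb[, 2L] <= 2L * W
    vals <- up[nb[ok, , drop = FALSE]]
    li <- (r + 1L) %/% 2L; lj <- (c + 1L) %/% 2L   # nearest low-res cell
    ri <- max(2L, li - half + 1L):min(H - 1L, li + half)
    rj <- max(2L, lj - half + 1L):min(W - 1L, lj + half)
    w <- NULL
    if (all(ok) && length(ri) >= 2L && length(rj) >= 2L) {
      cells <- expand.grid(r = ri, s = rj)
      C <- cbind(img[cbind(cells$r - 1L, cells$s)],
                 img[cbind(cells$r + 1L, cells$s)],
                 img[cbind(cells$r, cells$s - 1L)],
                 img[cbind(cells$r, cells$s + 1L)])
      y <- img[cbind(cells$r, cells$s)]
      w <- solve_weights(C, y)
    }
    if (is.null(w) || !all(ok)) mean(vals) else sum(w * up[nb])
  }
  for (r in seq_len(2L * H)) for (c in seq_len(2L * W)) {
    if ((r %% 2L == 1L) == (c %% 2L == 1L)) next  # low-res or phase-1 cell
    up[r, c] <- fill_axial(r, c)
  }
  up
}
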