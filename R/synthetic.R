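#' Simulate a spot-based spatial transcriptomics sample
#'
#' Generates synthetic sections with known spatial structure so every
#' stage of the pipeline is testable without downloads: per-gene smooth
#' spatial fields on a square or honeycomb lattice, optional count noise,
#' and an optional disk-shaped tissue mask. Three field patterns are
#' available, assigned per gene (recycled):
#' \describe{
#'   \item{`gradient`}{a linear field `a r + b c` with random orientation,
#'     scaled to `[0, 1]`; with `noise = "none"` these fields are exactly
#'     linear, so bilinear interpolation reconstructs masked positions
#'     perfectly.}
#'   \item{`gaussian_blob`}{an isotropic Gaussian bump at a random
#'     centre.}
#'   \item{`domain_constant`}{piecewise-constant over the Voronoi domains
#'     of `n_domains` random centres, with well-separated per-domain
#'     levels; the domain labels are returned for cluster-metric tests.}
#' }
#' Noise models: `"gaussian"` adds zero-mean noise of sd `noise_level`
#' (truncated at 0) to the smooth field; `"poisson"` draws counts with
#' mean `field * noise_level` (so `noise_level` is the expected count at
#' field maximum), mimicking sequencing depth.
#'
#' @param lattice `"square"` or `"visium_hex"` (honeycomb: spots occupy
#'   positions with equal row/col parity).
#' @param height,width lattice extent (>= 4).
#' @param n_genes number of genes.
#' @param n_domains number of Voronoi domains.
#' @param patterns character vector of pattern kinds recycled over genes.
#' @param noise `"none"`, `"gaussian"`, or `"poisson"`.
#' @param noise_level see Details above.
#' @param tissue_shape `"full"` (every lattice position) or `"disk"`.
#' @param seed RNG seed; the output is reproducible given the seed.
#' @return List with `table` (a [spot_table()]), `domains` (integer label
#'   per spot), and `fields` (the noise-free `G x H x W` ground-truth
#'   array).
#' @export
simulate_spots <- function(lattice = c("square", "visium_hex"), height = 16L,
                           width = 16L, n_genes = 8L, n_domains = 3L,
                           patterns = c("gradient", "gaussian_blob",
                                        "domain_constant"),
                           noise = c("none", "gaussian", "poisson"),
                           noise_level = 0.1, tissue_shape = c("full", "disk"),
                           seed = 1L) {
  lattice <- match.arg(lattice)
  noise <- match.arg(noise)
  tissue_shape <- match.arg(tissue_shape)
  if (height < 4L || width < 4L)
    stop_resolvst("lattice must be at least 4 x 4", "parameter")
  if (!is_count(n_genes, 1L)) stop_resolvst("n_genes must be >= 1", "parameter")
  set.seed(seed)

  ## occupied lattice positions (0-based)
  pos <- expand.grid(row = seq_len(height) - 1L, col = seq_len(width) - 1L)
  if (lattice == "visium_hex")
    pos <- pos[pos$row %% 2L == pos$col %% 2L, ]
  if (tissue_shape == "disk") {
    rc <- (height - 1) / 2; cc <- (width - 1) / 2
    rad <- min(height, width) / 2 - 0.5
    keep <- (pos$row - rc)^2 + (pos$col - cc)^2 <= rad^2
    pos <- pos[keep, ]
  }
  pos <- pos[order(pos$row, pos$col), ]
  n_spots <- nrow(pos)

  ## domain structure (Voronoi over random centres)
  centers <- cbind(stats::runif(n_domains, 0, height - 1),
                   stats::runif(n_domains, 0, width - 1))
  d2c <- outer(pos$row, centers[, 1L], "-")^2 +
         outer(pos$col, centers[, 2L], "-")^2
  domains <- max.col(-d2c)

  pat <- rep_len(patterns, n_genes)
  fields <- array(0, dim = c(n_genes, height, width))
  expr <- matrix(0, n_genes, n_spots)
  rr <- pos$row; cc_ <- pos$col
  for (g in seq_len(n_genes)) {
    f <- switch(pat[g],
      gradient = {
        th <- stats::runif(1, 0, 2 * pi)
        raw <- cos(th) * rr + sin(th) * cc_
        (raw - min(raw)) / max(max(raw) - min(raw), 1e-12)
      },
      gaussian_blob = {
        ctr <- c(stats::runif(1, 0, height - 1), stats::runif(1, 0, width - 1))
        s <- max(height, width) / 4
        exp(-((rr - ctr[1L])^2 + (cc_ - ctr[2L])^2) / (2 * s^2))
      },
      domain_constant = {
        lev <- sample(seq(0.1, 1, length.out = n_domains))
        lev[domains]
      },
      stop_resolvst(paste0("unknown pattern: ", pat[g]), "parameter"))
    v <- switch(noise,
                none = f,
                gaussian = pmax(f + stats::rnorm(n_spots, 0, noise_level), 0),
                poisson = stats::rpois(n_spots, f * noise_level))
    expr[g, ] <- v
    for (s in seq_len(n_spots))
      fields[g, rr[s] + 1L, cc_[s] + 1L] <- f[s]
  }
  tab <- spot_table(expr, pos$row, pos$col, lattice = lattice,
                    gene_names = paste0("gene_", seq_len(n_genes)))
  list(table = tab, domains = domains, fields = fields)
}

#' Bundle a ready-made down-sampling benchmark case
#'
#' Runs [simulate_spots()], rasterizes to a grid, applies the matching
#' down-sampling dialect, and extracts the held-out truth, yielding
#' everything an imputation benchmark needs.
#'
#' @inheritParams simulate_spots
#' @param ... passed to [simulate_spots()].
#' @return List with `grid` (full-resolution [expression_grid()]),
#'   `downsample` (a [downsample_square()] result), `truth` (matrix,
#'   masked positions x genes), `table`, and `domains`.
#' @export
simulate_eval_case <- function(...) {
  sim <- simulate_spots(...)
  grid <- to_grid(sim$table)
  ds <- if (grid$lattice == "visium_hex") downsample_visium(grid)
        else downsample_square(grid)
  truth <- grid_values_at(grid, ds$masked_positions)
  list(grid = grid, downsample = ds, truth = truth, table = sim$table,
       domains = sim$domains)
}
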