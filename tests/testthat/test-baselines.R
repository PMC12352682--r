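## noiseless linear field on a full square grid: the canonical exactness case
linear_case <- function(H = 8L, W = 8L, a = 1, b = 1, c0 = 0) {
  pos <- expand.grid(row = seq_len(H) - 1L, col = seq_len(W) - 1L)
  f <- a * pos$row + b * pos$col + c0
  t <- spot_table(matrix(f, 1, byrow = TRUE), pos$row, pos$col,
                  lattice = "square")
  downsample_square(to_grid(t))
}

test_that("bilinear interpolation is exact on linear fields", {
  for (ab in list(c(1, 1), c(2, -0.5), c(0.3, 0))) {
    ds <- linear_case(a = ab[1], b = ab[2], c0 = 5)
    pred <- interpolate_baseline(ds, "linear")
    truth <- ab[1] * ds$masked_positions[, 1] +
             ab[2] * ds$masked_positions[, 2] + 5
    inside <- !attr(pred, "outside_hull")
    expect_true(any(inside))
    expect_equal(pred[inside, 1], truth[inside], tolerance = 1e-12)
  }
})

test_that("bilinear at the centre of unit-square corners averages them", {
  ## corners 1, 2, 3, 4 -> centre value 2.5
  expr <- matrix(c(1, 2, 3, 4), 1)
  t <- spot_table(expr, c(0L, 0L, 2L, 2L), c(0L, 2L, 0L, 2L))
  ds <- downsample_square(to_grid(t))
  pred <- interpolate_baseline(ds, "linear", targets = cbind(1L, 1L))
  expect_equal(unname(pred[1, 1]), 2.5)
})

test_that("nearest returns retained values at retained coordinates and breaks ties low", {
  ds <- linear_case()
  ret <- ds$retained_positions
  pred <- interpolate_baseline(ds, "nearest", targets = ret)
  truth <- ret[, 1] + ret[, 2]
  expect_equal(unname(pred[, 1]), truth)
  ## a target equidistant from several retained spots takes the first in
  ## row-major order: (1,1) is sqrt(2)/... from (0,0),(0,2),(2,0),(2,2)
  p <- interpolate_baseline(ds, "nearest", targets = cbind(1L, 1L))
  expect_equal(unname(p[1, 1]), 0)  # value at (0, 0)
})

test_that("cubic has linear precision and reproduces constants", {
  ds <- linear_case(a = 1.5, b = 0.75, c0 = 10)
  pred <- interpolate_baseline(ds, "cubic")
  truth <- 1.5 * ds$masked_positions[, 1] + 0.75 * ds$masked_positions[, 2] + 10
  inside <- !attr(pred, "outside_hull")
  expect_equal(pred[inside, 1], truth[inside], tolerance = 1e-10)
  ## constant field: every method reproduces it everywhere
  dc <- linear_case(a = 0, b = 0, c0 = 3)
  for (m in c("nearest", "linear", "cubic", "nedi")) {
    p <- interpolate_baseline(dc, m)
    ## NEDI's ridge-regularized weights shrink constants by O(lambda)
    tol <- if (m == "nedi") 1e-4 else 1e-10
    expect_equal(unname(p[, 1]), rep(3, nrow(p)), tolerance = tol,
                 label = m)
  }
})

test_that("baselines are deterministic and act gene-wise independently", {
  set.seed(30)
  sim <- simulate_eval_case(height = 10L, width = 10L, n_genes = 3L,
                            noise = "gaussian", noise_level = 0.1, seed = 31)
  for (m in c("nearest", "linear", "cubic", "nedi")) {
    p1 <- interpolate_baseline(sim$downsample, m)
    p2 <- interpolate_baseline(sim$downsample, m)
    expect_identical(p1, p2)
    ## permuting genes permutes predictions
    ds2 <- sim$downsample
    ds2$low_res$data <- ds2$low_res$data[c(3, 1, 2), , , drop = FALSE]
    p3 <- interpolate_baseline(ds2, m)
    expect_equal(unname(p3), unname(p1[, c(3, 1, 2)]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate retained sets raise errors for surface methods", {
  t <- spot_table(matrix(1:2, 1), c(0L, 1L), c(0L, 1L), lattice = "square")
  g <- to_grid(t)
  ds <- downsample_square(g)   # only (0,0) retained
  expect_error(interpolate_baseline(ds, "linear"),
               class = "resolvst_degenerate")
  ## nearest still works
  p <- interpolate_baseline(ds, "nearest")
  expect_equal(unname(p[1, 1]), 1)
})

test_that("NEDI follows oriented edges better than axis-blind averaging", {
  ## a diagonal ridge: NEDI's covariance weights should track the diagonal
  H <- 12L
  pos <- expand.grid(row = seq_len(H) - 1L, col = seq_len(H) - 1L)
  f <- as.numeric(pos$row == pos$col) * 10
  t <- spot_table(matrix(f, 1, byrow = TRUE), pos$row, pos$col,
                  lattice = "square")
  ds <- downsample_square(to_grid(t))
  pr <- interpolate_baseline(ds, "nedi")
  truth <- as.numeric(ds$masked_positions[, 1] == ds$masked_positions[, 2]) * 10
  ## on-diagonal masked odd-odd positions sit between two diagonal
  ## low-res 10s; NEDI should predict clearly above the background
  diag_idx <- which(ds$masked_positions[, 1] == ds$masked_positions[, 2] &
                    ds$masked_positions[, 1] %% 2 == 1 &
                    !attr(pr, "outside_hull"))
  expect_true(length(diag_idx) > 0)
  expect_true(mean(pr[diag_idx, 1]) > 5)
})
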