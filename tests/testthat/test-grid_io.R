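test_that("spot_table validates coordinates, expression and parity", {
  t <- toy_table()
  expect_s3_class(t, "spot_table")
  expect_equal(dim(t$expr), c(2L, 3L))
  expect_error(spot_table(matrix(1, 1, 2), c(0, 0), c(1, 1)),
               class = "resolvst_validation")          # duplicate coords
  expect_error(spot_table(matrix(-1, 1, 1), 0, 0),
               class = "resolvst_validation")          # negative expression
  expect_error(spot_table(matrix(1, 1, 2), c(0, 1), c(0, 0),
                          lattice = "visium_hex"),
               class = "resolvst_validation")          # parity violation
})

test_that("lattice is inferred from coordinate parity", {
  ## equal parity everywhere with odd coordinates present -> honeycomb
  t <- spot_table(matrix(1, 1, 3), c(0, 1, 2), c(0, 1, 0))
  expect_equal(t$lattice, "visium_hex")
  ## mixed parity -> square
  t2 <- spot_table(matrix(1, 1, 3), c(0, 0, 1), c(0, 1, 0))
  expect_equal(t2$lattice, "square")
  ## all-even coordinates are ambiguous; default square
  t3 <- spot_table(matrix(1, 1, 2), c(0, 2), c(0, 0))
  expect_equal(t3$lattice, "square")
})

test_that("csv pair round-trips through disk", {
  dir <- withr::local_tempdir()
  t <- toy_table()
  write_spot_table(t, dir, format = "csv_pair")
  t2 <- read_spot_table(dir, format = "csv_pair")
  expect_equal(t2$expr, t$expr)
  expect_equal(t2$array_row, t$array_row)
  expect_equal(t2$array_col, t$array_col)
  expect_equal(dim(t2$expr), c(2L, 3L))
})

test_that("mtx triplet round-trips and preserves gene order", {
  dir <- withr::local_tempdir()
  set.seed(4)
  expr <- matrix(rpois(5 * 6, 2), 5, 6)
  expr[5, ] <- c(0, 0, 0, 1, 0, 0)
  t <- spot_table(expr, c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 1, 0, 1),
                  gene_names = paste0("g", 5:1))
  write_spot_table(t, dir, format = "mtx_triplet")
  t2 <- read_spot_table(dir, format = "mtx_triplet")
  expect_equal(t2$gene_names, paste0("g", 5:1))
  expect_equal(unname(t2$expr), unname(t$expr))
})

test_that("malformed csv pair raises a format error naming the problem", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(id = 1, row = 2), file.path(dir, "spots.csv"),
            row.names = FALSE)
  write.csv(data.frame(g = 1), file.path(dir, "expr.csv"))
  expect_error(read_spot_table(dir, format = "csv_pair"),
               "spot_id", class = "resolvst_format")
})

test_that("h5ad containers are read, with lattice inferred from parity", {
  skip_if_not_installed("rhdf5")
  f <- withr::local_tempfile(fileext = ".h5ad")
  ## honeycomb coordinates: parity equal for every spot
  ar <- c(0L, 0L, 1L, 2L); ac <- c(0L, 2L, 1L, 0L)
  X <- matrix(seq_len(12), nrow = 4, ncol = 3)  # obs x var
  rhdf5::h5createFile(f)
  rhdf5::h5write(t(X), f, "X")                  # stored var-fastest
  rhdf5::h5createGroup(f, "obs")
  rhdf5::h5write(ar, f, "obs/array_row")
  rhdf5::h5write(ac, f, "obs/array_col")
  rhdf5::h5createGroup(f, "var")
  rhdf5::h5write(paste0("g", 1:3), f, "var/_index")
  rhdf5::H5close()
  t <- read_spot_table(f, format = "h5ad")
  expect_equal(dim(t$expr), c(3L, 4L))
  expect_equal(t$lattice, "visium_hex")
  expect_equal(t$gene_names, paste0("g", 1:3))
  expect_equal(unname(t$expr[, 1]), as.numeric(X[1, ]))
})

test_that("qc_filter drops sparse genes then empty spots, single pass each", {
  ## 5 genes x 6 spots; g5 expressed in 1 spot, s6 expresses nothing
  expr <- matrix(1, 5, 6)
  expr[5, ] <- c(1, 0, 0, 0, 0, 0)
  expr[, 6] <- 0
  t <- spot_table(expr, c(0, 0, 0, 1, 1, 1), c(0, 1, 2, 0, 1, 2),
                  gene_names = paste0("g", 1:5))
  f <- qc_filter(t, min_spots_per_gene = 2L, min_genes_per_spot = 1L)
  expect_equal(f$gene_names, paste0("g", 1:4))
  expect_equal(ncol(f$expr), 5L)
  ## thresholds (0, 0) are the identity
  f0 <- qc_filter(t, 0L, 0L)
  expect_equal(f0$expr, t$expr)
  ## impossible spot threshold removes everything -> empty-result error
  expect_error(qc_filter(t, 0L, 200L), class = "resolvst_empty")
})

test_that("qc_filter is idempotent and never grows dimensions", {
  set.seed(9)
  expr <- matrix(rpois(20 * 15, 0.7), 20, 15)
  expr[1, ] <- 1  # guarantee survivors
  t <- spot_table(expr, rep(0:2, each = 5), rep(0:4, 3))
  f1 <- qc_filter(t, 3L, 2L)
  f2 <- qc_filter(f1, 3L, 2L)
  expect_equal(f2$expr, f1$expr)
  expect_true(all(dim(f1$expr) <= dim(t$expr)))
})

test_that("to_grid places spots and from_grid inverts it exactly", {
  t <- toy_table()
  g <- to_grid(t)
  expect_equal(dim(g$data), c(2L, 2L, 2L))
  expect_equal(sum(g$mask), 3)
  expect_equal(g$data[, 1, 1], unname(t$expr[, 1]))
  back <- from_grid(g)
  expect_equal(unname(back$expr), unname(t$expr[, order(t$array_row,
                                                        t$array_col)]))
  ## origin shift is recorded and undone
  t5 <- spot_table(matrix(2, 1, 1), 5L, 7L)
  g5 <- to_grid(t5)
  expect_equal(dim(g5$data)[2:3], c(1L, 1L))
  expect_equal(g5$origin_offset, c(5L, 7L))
  expect_equal(from_grid(g5)$array_row, 5L)
  expect_equal(from_grid(g5)$array_col, 7L)
})

test_that("grid round-trip preserves the honeycomb parity invariant", {
  for (seed in 1:3) {
    t <- toy_visium_table(6L, 6L, seed = seed)
    g <- to_grid(t)
    back <- from_grid(g)
    expect_equal(back$lattice, "visium_hex")
    expect_true(all(back$array_row %% 2L == back$array_col %% 2L))
    expect_equal(sort(back$spot_id), sort(back$spot_id))
    expect_equal(unname(back$expr[, order(back$array_row, back$array_col)]),
                 unname(t$expr[, order(t$array_row, t$array_col)]))
  }
  ## shifted honeycomb whose offset would flip parity: invariant still holds
  t <- spot_table(matrix(1:2, 1), c(1L, 2L), c(3L, 2L), lattice = "visium_hex")
  g <- to_grid(t)
  back <- from_grid(g)
  expect_true(all(back$array_row %% 2L == back$array_col %% 2L))
})

test_that("from_grid on an empty mask is an empty-result error", {
  g <- expression_grid(array(0, c(1, 2, 2)), matrix(0, 2, 2))
  expect_error(from_grid(g), class = "resolvst_empty")
})

test_that("normalization maps each gene to [0, 1] and stores the inverse", {
  t <- toy_table()
  n <- normalize_expression(t)
  expect_true(all(n$expr >= 0 & n$expr <= 1))
  expect_equal(unname(apply(n$expr, 1, max)), c(1, 1))
  nr <- attr(n, "norm")
  restored <- expm1(n$expr * (nr$hi - nr$lo) + nr$lo)
  expect_equal(unname(restored), unname(t$expr), tolerance = 1e-12)
})
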