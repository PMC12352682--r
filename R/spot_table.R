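#' Construct a spot table
#'
#' The spot table is the package's tabular representation of a spot-based
#' spatial transcriptomics sample: integer array coordinates per spot plus a
#' genes-by-spots expression matrix. Two lattice dialects are supported:
#' `"square"` (classic ST arrays, ~100 micron spacing) and `"visium_hex"`
#' (staggered Visium honeycomb, ~55 micron spacing), the latter constrained so
#' that `array_row` and `array_col` have equal parity for every spot.
#'
#' @param expr numeric matrix, genes in rows, spots in columns; non-negative.
#' @param array_row,array_col integer vectors (0-based) of lattice coordinates,
#'   one entry per spot.
#' @param spot_id optional character vector of spot identifiers; defaults to
#'   `colnames(expr)` or `spot_1 ... spot_n`.
#' @param lattice `"square"`, `"visium_hex"`, or `"auto"` to infer from the
#'   coordinate parities (all-equal parity implies a honeycomb).
#' @param gene_names optional character vector; defaults to `rownames(expr)`.
#'
#' @return An object of class `"spot_table"`: a list with elements `spot_id`,
#'   `array_row`, `array_col`, `lattice`, `expr`, `gene_names`.
#' @seealso [read_spot_table()], [qc_filter()], [to_grid()]
#' @export
spot_table <- function(expr, array_row, array_col, spot_id = NULL,
                       lattice = c("auto", "square", "visium_hex"),
                       gene_names = NULL) {
  lattice <- match.arg(lattice)
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  n_spots <- ncol(expr)
  if (length(array_row) != n_spots || length(array_col) != n_spots)
    stop_resolvst("array_row/array_col length must equal ncol(expr)", "validation")
  array_row <- as.integer(array_row)
  array_col <- as.integer(array_col)
  if (anyNA(array_row) || anyNA(array_col) ||
      any(array_row < 0L) || any(array_col < 0L))
    stop_resolvst("array coordinates must be non-negative integers", "validation")
  if (anyDuplicated(paste(array_row, array_col)))
    stop_resolvst("duplicate (array_row, array_col) coordinates", "validation")
  if (any(!is.finite(expr)) || any(expr < 0))
    stop_resolvst("expression values must be finite and non-negative", "validation")
  gene_names <- gene_names %||% rownames(expr) %||%
    paste0("gene_", seq_len(nrow(expr)))
  spot_id <- spot_id %||% colnames(expr) %||% paste0("spot_", seq_len(n_spots))
  if (lattice == "auto") lattice <- infer_lattice(array_row, array_col)
  if (lattice == "visium_hex" &&
      any(array_row %% 2L != array_col %% 2L))
    stop_resolvst("visium_hex requires equal row/col parity for every spot",
                  "validation")
  rownames(expr) <- gene_names
  colnames(expr) <- spot_id
  structure(
    list(spot_id = as.character(spot_id), array_row = array_row,
         array_col = array_col, lattice = lattice, expr = expr,
         gene_names = as.character(gene_names)),
    class = "spot_table")
}

## honeycomb iff every spot has equal row/col parity AND at least one odd
## coordinate is present (an all-even table is a plain square grid)
infer_lattice <- function(array_row, array_col) {
  if (length(array_row) > 0L &&
      all(array_row %% 2L == array_col %% 2L) &&
      any(array_row %% 2L == 1L))
    "visium_hex" else "square"
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d genes x %d spots, lattice = %s\n",
              nrow(x$expr), ncol(x$expr), x$lattice))
  cat(sprintf("  array rows %d..%d, cols %d..%d\n",
              min(x$array_row), max(x$array_row),
              min(x$array_col), max(x$array_col)))
  invisible(x)
}

#' @export
dim.spot_table <- function(x) dim(x$expr)

#' Read a spot table from disk
#'
#' Three on-disk layouts are understood:
#' \describe{
#'   \item{`csv_pair`}{a directory (or the `spots.csv` path itself) holding
#'     `spots.csv` with columns `spot_id,array_row,array_col` and `expr.csv`,
#'     a genes-by-spots matrix with gene names in the first column and spot
#'     ids as header.}
#'   \item{`mtx_triplet`}{a directory with `matrix.mtx` (genes x spots),
#'     `genes.tsv` (one gene per line) and `barcodes.tsv` with columns
#'     `barcode,array_row,array_col` (tab-separated, no header).}
#'   \item{`h5ad`}{an AnnData container with `obs` columns `array_row` and
#'     `array_col`; requires the `rhdf5` package. `X` may be dense or CSR/CSC
#'     sparse and is transposed to genes x spots.}
#' }
#'
#' @param path file or directory path (see Details per format).
#' @param format one of `"auto"`, `"csv_pair"`, `"mtx_triplet"`, `"h5ad"`.
#' @param lattice lattice dialect, `"auto"` to infer from coordinate parity.
#' @return A [spot_table()].
#' @export
read_spot_table <- function(path, format = c("auto", "csv_pair", "mtx_triplet",
                                             "h5ad"),
                            lattice = "auto") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.h5ad$", path)) "h5ad"
    else if (dir.exists(path) && file.exists(file.path(path, "matrix.mtx")))
      "mtx_triplet"
    else "csv_pair"
  }
  switch(format,
         csv_pair = read_csv_pair(path, lattice),
         mtx_triplet = read_mtx_triplet(path, lattice),
         h5ad = read_h5ad(path, lattice))
}

read_csv_pair <- function(path, lattice) {
  dir <- if (dir.exists(path)) path else dirname(path)
  spots_f <- file.path(dir, "spots.csv")
  expr_f <- file.path(dir, "expr.csv")
  for (f in c(spots_f, expr_f))
    if (!file.exists(f))
      stop_resolvst(paste0("missing file: ", f), "format")
  spots <- utils::read.csv(spots_f, stringsAsFactors = FALSE)
  need <- c("spot_id", "array_row", "array_col")
  if (!all(need %in% names(spots)))
    stop_resolvst(paste0("spots.csv must have columns ",
                         paste(need, collapse = ", "), "; missing: ",
                         paste(setdiff(need, names(spots)), collapse = ", ")),
                  "format")
  expr <- utils::read.csv(expr_f, row.names = 1, check.names = FALSE)
  expr <- as.matrix(expr)
  if (ncol(expr) != nrow(spots))
    stop_resolvst("expr.csv columns do not match spots.csv rows (field: spot count)",
                  "format")
  spot_table(expr, spots$array_row, spots$array_col,
             spot_id = spots$spot_id, lattice = lattice)
}

read_mtx_triplet <- function(path, lattice) {
  mtx_f <- file.path(path, "matrix.mtx")
  genes_f <- file.path(path, "genes.tsv")
  bc_f <- file.path(path, "barcodes.tsv")
  for (f in c(mtx_f, genes_f, bc_f))
    if (!file.exists(f))
      stop_resolvst(paste0("missing file: ", f), "format")
  m <- as.matrix(Matrix::readMM(mtx_f))
  genes <- utils::read.delim(genes_f, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  bc <- utils::read.delim(bc_f, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bc) < 3L)
    stop_resolvst("barcodes.tsv needs columns barcode, array_row, array_col",
                  "format")
  if (nrow(m) != length(genes))
    stop_resolvst("matrix.mtx rows do not match genes.tsv (field: gene count)",
                  "format")
  if (ncol(m) != nrow(bc))
    stop_resolvst("matrix.mtx cols do not match barcodes.tsv (field: spot count)",
                  "format")
  spot_table(m, bc[[2L]], bc[[3L]], spot_id = bc[[1L]],
             lattice = lattice, gene_names = genes)
}

read_h5ad <- function(path, lattice) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop_resolvst("reading h5ad requires the rhdf5 package", "format")
  if (!file.exists(path)) stop_resolvst(paste0("missing file: ", path), "format")
  h5 <- rhdf5::h5ls(path)
  read_vec <- function(name) {
    v <- rhdf5::h5read(path, name)
    ## categorical columns are stored as codes + categories
    if (is.list(v) && all(c("codes", "categories") %in% names(v)))
      v <- v$categories[v$codes + 1L]
    as.vector(v)
  }
  obs_col <- function(col) {
    if (any(h5$group == "/obs" & h5$name == col))
      return(read_vec(paste0("obs/", col)))
    stop_resolvst(paste0("h5ad file lacks obs column '", col, "'"), "format")
  }
  array_row <- as.integer(obs_col("array_row"))
  array_col <- as.integer(obs_col("array_col"))
  x_is_group <- any(h5$group == "/" & h5$name == "X" & h5$otype == "H5I_GROUP")
  if (x_is_group) {
    dat <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    attrs <- rhdf5::h5readAttributes(path, "X")
    shp <- as.integer(attrs$shape)  # (n_obs, n_var)
    enc <- attrs[["encoding-type"]] %||% "csr_matrix"
    if (grepl("csr", enc)) {
      m <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = dat,
                                dims = c(shp[2L], shp[1L]))  # genes x spots
    } else {
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = dat,
                                dims = c(shp[1L], shp[2L]))
      m <- Matrix::t(m)
    }
    expr <- as.matrix(m)
  } else {
    x <- rhdf5::h5read(path, "X")   # h5 column-major gives n_var x n_obs
    expr <- as.matrix(x)
    if (ncol(expr) != length(array_row) && nrow(expr) == length(array_row))
      expr <- t(expr)
  }
  var_index <- tryCatch(read_vec("var/_index"),
                        error = function(e) tryCatch(read_vec("var/index"),
                                                     error = function(e) NULL))
  obs_index <- tryCatch(read_vec("obs/_index"), error = function(e) NULL)
  spot_table(expr, array_row, array_col, spot_id = obs_index,
             lattice = lattice, gene_names = var_index)
}

#' Write a spot table to disk
#'
#' Inverse of [read_spot_table()] for the `csv_pair` and `mtx_triplet`
#' layouts (see that help page for the file conventions).
#'
#' @param x a [spot_table()].
#' @param path directory to write into (created if absent).
#' @param format `"csv_pair"` or `"mtx_triplet"`.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(x, path, format = c("csv_pair", "mtx_triplet")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "spot_table"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (format == "csv_pair") {
    utils::write.csv(data.frame(spot_id = x$spot_id, array_row = x$array_row,
                                array_col = x$array_col),
                     file.path(path, "spots.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(x$expr), file.path(path, "expr.csv"),
                     row.names = TRUE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$expr, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(x$gene_names, file.path(path, "genes.tsv"))
    utils::write.table(data.frame(x$spot_id, x$array_row, x$array_col),
                       file.path(path, "barcodes.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Quality-control filtering of genes and spots
#'
#' Removes genes expressed (value > 0) in fewer than `min_spots_per_gene`
#' spots, then spots with fewer than `min_genes_per_spot` detected genes.
#' The gene filter is applied first and each filter runs exactly once (no
#' iteration to a fixed point), matching the common single-pass convention.
#' Default thresholds suit small classic-ST sections (a few hundred
#' spots); denser Visium sections typically use `(10, 200)`.
#'
#' @param x a [spot_table()].
#' @param min_spots_per_gene keep genes with a positive value in at least
#'   this many spots.
#' @param min_genes_per_spot keep spots with at least this many genes
#'   positive (counted after the gene filter).
#' @return A filtered [spot_table()].
#' @export
qc_filter <- function(x, min_spots_per_gene = 20L, min_genes_per_spot = 10L) {
  stopifnot(inherits(x, "spot_table"))
  if (!is_count(min_spots_per_gene) || !is_count(min_genes_per_spot))
    stop_resolvst("thresholds must be non-negative integers", "parameter")
  keep_g <- rowSums(x$expr > 0) >= min_spots_per_gene
  if (!any(keep_g))
    stop_resolvst("qc_filter removed all genes", "empty")
  expr <- x$expr[keep_g, , drop = FALSE]
  keep_s <- colSums(expr > 0) >= min_genes_per_spot
  if (!any(keep_s))
    stop_resolvst("qc_filter removed all spots", "empty")
  spot_table(expr[, keep_s, drop = FALSE],
             x$array_row[keep_s], x$array_col[keep_s],
             spot_id = x$spot_id[keep_s], lattice = x$lattice,
             gene_names = x$gene_names[keep_g])
}

#' Log and per-gene min-max normalization
#'
#' Applies `log1p` then scales each gene linearly to `[0, 1]` across spots
#' (constant genes map to 0). This is the default transform applied before
#' network training; it is exposed as an explicit step because raw-count
#' normalization ahead of grid models is a modelling choice, not a fixed
#' part of the data format. The per-gene `(min, max)` of the log scale is
#' recorded in `attr(, "norm")` so predictions can be mapped back.
#'
#' @param x a [spot_table()] or [expression_grid()].
#' @param log1p apply `log1p` first (set `FALSE` for data already on log
#'   scale).
#' @return Object of the same class with transformed expression values.
#' @export
normalize_expression <- function(x, log1p = TRUE) {
  if (inherits(x, "spot_table")) {
    e <- x$expr
    if (log1p) e <- log1p(e)
    lo <- apply(e, 1L, min)
    hi <- apply(e, 1L, max)
    rng <- pmax(hi - lo, .Machine$double.eps)
    x$expr <- (e - lo) / rng
    x$expr[hi == lo, ] <- 0
    attr(x, "norm") <- list(lo = lo, hi = hi, log1p = log1p)
    return(x)
  }
  if (inherits(x, "expression_grid")) {
    G <- dim(x$data)[1L]
    occ <- x$mask == 1
    lo <- hi <- numeric(G)
    for (g in seq_len(G)) {
      img <- x$data[g, , ]
      if (log1p) img <- log1p(img)
      v <- img[occ]
      lo[g] <- min(v); hi[g] <- max(v)
      rng <- max(hi[g] - lo[g], .Machine$double.eps)
      img <- (img - lo[g]) / rng
      if (hi[g] == lo[g]) img[] <- 0
      img[!occ] <- 0
      x$data[g, , ] <- img
    }
    attr(x, "norm") <- list(lo = lo, hi = hi, log1p = log1p)
    return(x)
  }
  stop_resolvst("normalize_expression expects a spot_table or expression_grid",
                "contract")
}
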