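#' Gene-wise Pearson correlation report
#'
#' Computes, for every gene, the Pearson correlation between true and
#' predicted expression across the evaluated spots, plus the median as the
#' summary statistic. Genes with zero variance in either vector have an
#' undefined correlation; they are flagged `NA`, counted in
#' `n_undefined`, and excluded from the median.
#'
#' @param truth,pred numeric matrices, spots in rows and genes in columns,
#'   identical shapes, at least 2 spots.
#' @param method label recorded in the report.
#' @return Object of class `"evaluation_report"`: list with
#'   `per_gene_pcc` (named vector, `NA` where undefined), `median_pcc`,
#'   `n_spots_evaluated`, `n_undefined`, `method`.
#' @export
genewise_pcc <- function(truth, pred, method = "unnamed") {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (!all(dim(truth) == dim(pred)))
    stop_resolvst("truth and pred must have identical dimensions", "contract")
  if (nrow(truth) < 2L)
    stop_resolvst("need at least 2 spots to correlate", "parameter")
  G <- ncol(truth)
  pcc <- numeric(G)
  for (g in seq_len(G)) {
    st <- stats::sd(truth[, g]); sp <- stats::sd(pred[, g])
    pcc[g] <- if (st == 0 || sp == 0) NA_real_
              else stats::cor(truth[, g], pred[, g])
  }
  names(pcc) <- colnames(truth) %||% paste0("gene_", seq_len(G))
  structure(list(per_gene_pcc = pcc,
                 median_pcc = stats::median(pcc, na.rm = TRUE),
                 n_spots_evaluated = nrow(truth),
                 n_undefined = sum(is.na(pcc)),
                 method = method),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report [%s]: %d genes over %d spots; median PCC %.4f",
    x$method, length(x$per_gene_pcc), x$n_spots_evaluated, x$median_pcc))
  if (x$n_undefined > 0L)
    cat(sprintf(" (%d undefined)", x$n_undefined))
  cat("\n")
  invisible(x)
}

#' Silhouette coefficient
#'
#' Internal clustering-quality metric: for each point `i`, `a(i)` is the
#' mean distance to the other members of its cluster and `b(i)` the
#' smallest mean distance to any other cluster; the silhouette of `i` is
#' `(b - a) / max(a, b)` and the coefficient is the mean over points.
#' Values near 1 indicate compact, well-separated clusters. Distances are
#' Euclidean. Singletons get silhouette 0 (the conventional choice for a
#' width that is otherwise undefined).
#'
#' @param embeddings `N x d` numeric matrix.
#' @param labels length-`N` cluster assignment (>= 2 distinct values).
#' @return The silhouette coefficient, in `[-1, 1]`.
#' @export
silhouette_score <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  labels <- as.vector(labels)
  if (length(labels) != nrow(embeddings))
    stop_resolvst("labels must match embedding rows", "contract")
  if (length(unique(labels)) < 2L)
    stop_resolvst("silhouette needs at least 2 clusters", "parameter")
  D <- as.matrix(stats::dist(embeddings))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(unique(labels[!own]),
                    function(l) mean(D[i, labels == l]), numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' Internal clustering-quality metric: with `S_i` the mean distance of
#' cluster `i`'s members to their centroid and `D_ij` the distance between
#' centroids, the index is the mean over clusters of
#' `max_{j != i} (S_i + S_j) / D_ij`. Lower is better; zero-scatter
#' point-clusters give 0. Distances are Euclidean.
#'
#' @inheritParams silhouette_score
#' @return Non-negative real.
#' @export
davies_bouldin <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  labels <- as.vector(labels)
  if (length(labels) != nrow(embeddings))
    stop_resolvst("labels must match embedding rows", "contract")
  cl <- unique(labels)
  K <- length(cl)
  if (K < 2L)
    stop_resolvst("Davies-Bouldin needs at least 2 clusters", "parameter")
  centroids <- t(vapply(cl, function(l)
    colMeans(embeddings[labels == l, , drop = FALSE]),
    numeric(ncol(embeddings))))
  S <- vapply(seq_len(K), function(i) {
    pts <- embeddings[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, centroids[i, ])^2)))
  }, numeric(1L))
  Dc <- as.matrix(stats::dist(centroids))
  if (any(Dc[upper.tri(Dc)] == 0))
    stop_resolvst("coincident cluster centroids", "degenerate")
  r <- vapply(seq_len(K), function(i)
    max(vapply(setdiff(seq_len(K), i),
               function(j) (S[i] + S[j]) / Dc[i, j], numeric(1L))),
    numeric(1L))
  mean(r)
}

#' Cluster the imputed expression and score the spatial domains
#'
#' Convenience pipeline for the clustering evaluation: PCA of the
#' spots x genes matrix (the embedding space is a modelling choice;
#' principal components of the imputed expression are the package
#' default), k-means clustering, then [silhouette_score()] and
#' [davies_bouldin()] on the embedding.
#'
#' @param expr spots x genes matrix.
#' @param k number of clusters (>= 2).
#' @param n_pcs number of principal components retained.
#' @param labels optional precomputed labels; skips the k-means step.
#' @param seed seed for k-means restarts.
#' @return List of class `"cluster_metrics"`: `silhouette`,
#'   `davies_bouldin`, `labels`, `embedding`, `n_clusters`.
#' @export
cluster_metrics <- function(expr, k = 4L, n_pcs = 10L, labels = NULL,
                            seed = 1L) {
  expr <- as.matrix(expr)
  n_pcs <- min(n_pcs, ncol(expr), nrow(expr) - 1L)
  emb <- stats::prcomp(expr, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                              drop = FALSE]
  if (is.null(labels)) {
    if (!is_count(k, 2L))
      stop_resolvst("k must be an integer >= 2", "parameter")
    set.seed(seed)
    labels <- stats::kmeans(emb, centers = k, nstart = 10L)$cluster
  }
  structure(list(silhouette = silhouette_score(emb, labels),
                 davies_bouldin = davies_bouldin(emb, labels),
                 labels = labels, embedding = emb,
                 n_clusters = length(unique(labels))),
            class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf("cluster_metrics: K = %d, silhouette %.4f, Davies-Bouldin %.4f\n",
              x$n_clusters, x$silhouette, x$davies_bouldin))
  invisible(x)
}
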