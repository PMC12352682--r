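## fixtures and independent oracles used across the suite

## tiny deterministic spot table: 2 genes x 3 spots on a square lattice
toy_table <- function() {
  expr <- matrix(c(1, 0,
                   2, 5,
                   0, 3), nrow = 2)
  spot_table(expr, array_row = c(0L, 0L, 1L), array_col = c(0L, 1L, 0L),
             lattice = "square", gene_names = c("gA", "gB"))
}

## honeycomb table on equal-parity positions of a h x w window
toy_visium_table <- function(h = 4L, w = 4L, seed = 1L) {
  set.seed(seed)
  pos <- expand.grid(row = seq_len(h) - 1L, col = seq_len(w) - 1L)
  pos <- pos[pos$row %% 2L == pos$col %% 2L, ]
  expr <- matrix(stats::runif(3L * nrow(pos)), nrow = 3L)
  spot_table(expr, pos$row, pos$col, lattice = "visium_hex")
}

## full-tissue square grid with reproducible values
toy_grid <- function(G = 2L, H = 4L, W = 4L, seed = 1L) {
  set.seed(seed)
  expression_grid(array(stats::runif(G * H * W), dim = c(G, H, W)),
                  matrix(1L, H, W), lattice = "square")
}

## small network configuration that keeps tests fast
tiny_config <- function(...) {
  args <- list(cnn_channels = c(4L, 4L), embed_dim = 16L, n_heads = 2L,
               n_blocks = 2L, patch_size = 2L, mlp_ratio = 2L)
  do.call(superres_config, utils::modifyList(args, list(...)))
}

## brute-force Eq-style masked loss: explicit triple loop over k, i, j
masked_mse_oracle <- function(pred, target, mask) {
  G <- dim(pred)[1L]; H <- dim(pred)[3L]; W <- dim(pred)[4L]
  total <- 0; nvalid <- 0
  for (k in 0:3) for (i in 0:(H - 1L)) for (j in 0:(W - 1L)) {
    mk <- mask[2L * i + k %/% 2L + 1L, 2L * j + k %% 2L + 1L]
    nvalid <- nvalid + mk
    for (g in seq_len(G)) {
      y <- target[g, 2L * i + k %/% 2L + 1L, 2L * j + k %% 2L + 1L]
      total <- total + mk * (pred[g, k + 1L, i + 1L, j + 1L] - y)^2
    }
  }
  total / (4 * nvalid * G)
}

## brute-force silhouette from the definition
silhouette_oracle <- function(emb, labels) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  d <- function(i, j) sqrt(sum((emb[i, ] - emb[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0L) { s[i] <- 0; next }
    a <- mean(vapply(same, function(j) d(i, j), numeric(1L)))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      o <- which(labels == l)
      b <- min(b, mean(vapply(o, function(j) d(i, j), numeric(1L))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## brute-force Davies-Bouldin from the definition
davies_bouldin_oracle <- function(emb, labels) {
  emb <- as.matrix(emb)
  cl <- unique(labels)
  K <- length(cl)
  cen <- lapply(cl, function(l) colMeans(emb[labels == l, , drop = FALSE]))
  S <- vapply(seq_len(K), function(i) {
    pts <- emb[labels == cl[i], , drop = FALSE]
    mean(apply(pts, 1L, function(p) sqrt(sum((p - cen[[i]])^2))))
  }, numeric(1L))
  r <- numeric(K)
  for (i in seq_len(K)) {
    best <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      Dij <- sqrt(sum((cen[[i]] - cen[[j]])^2))
      best <- max(best, (S[i] + S[j]) / Dij)
    }
    r[i] <- best
  }
  mean(r)
}

## explicit-loop single-head attention oracle over one gene's tokens
attention_oracle <- function(Z, Wq, bq, Wk, bk, Wv, bv, Wo, bo) {
  N <- nrow(Z); D <- ncol(Z)
  Q <- Z %*% Wq + matrix(bq, N, D, byrow = TRUE)
  K <- Z %*% Wk + matrix(bk, N, D, byrow = TRUE)
  V <- Z %*% Wv + matrix(bv, N, D, byrow = TRUE)
  out <- matrix(0, N, D)
  for (i in seq_len(N)) {
    sc <- numeric(N)
    for (j in seq_len(N)) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(D)
    w <- exp(sc - max(sc)); w <- w / sum(w)
    for (j in seq_len(N)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out %*% Wo + matrix(bo, N, D, byrow = TRUE)
}
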