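## Internal layer primitives with hand-written backward passes.
##
## Data layouts (fixed throughout the network code):
##  - image stacks: matrix V of shape (H*W*C) x G, one column per gene,
##    feature index = r + (c-1)*H + (ch-1)*H*W (R column-major of (H, W, C))
##  - token stacks: matrix Z of shape (G*N) x D, gene-blocked rows, token
##    order row-major over the patch grid (column varies fastest)
## All gradients are exact; test-suite checks them against central finite
## differences on small instances.

.geom_cache <- new.env(parent = emptyenv())

## sparse im2col operator for geometry (H, W, Cin, k, stride, pad).
## Row ordering of the col-space: output position o fastest, then patch
## element e = (dr, dc, ch). With row_major = TRUE output positions are
## enumerated row-major (col fastest) -- used by the patch embedding so
## token order matches patch_coords(); conv layers use R-native ordering.
im2col_op <- function(H, W, Cin, k, stride, pad, row_major = FALSE) {
  key <- paste("i2c", H, W, Cin, k, stride, pad, row_major, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  E <- k * k * Cin
  ho <- rep(seq_len(Ho), times = Wo)          # R-native: row fastest
  wo <- rep(seq_len(Wo), each = Ho)
  if (row_major) {
    ho <- rep(seq_len(Ho), each = Wo)
    wo <- rep(seq_len(Wo), times = Ho)
  }
  M <- Ho * Wo
  ii <- integer(0); jj <- integer(0)
  for (ch in seq_len(Cin)) for (dc in seq_len(k)) for (dr in seq_len(k)) {
    e <- dr + (dc - 1L) * k + (ch - 1L) * k * k
    r <- (ho - 1L) * stride + dr - pad        # 1-based source row
    cc <- (wo - 1L) * stride + dc - pad
    ok <- r >= 1L & r <= H & cc >= 1L & cc <= W
    src <- r[ok] + (cc[ok] - 1L) * H + (ch - 1L) * H * W
    rows <- which(ok) + (e - 1L) * M
    ii <- c(ii, rows); jj <- c(jj, src)
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(M * E, H * W * Cin))
  op <- list(P = P, Pt = Matrix::t(P), Ho = Ho, Wo = Wo, E = E, M = M)
  .geom_cache[[key]] <- op
  op
}

## convolution over a gene stack; returns V layout unless tokens = TRUE,
## in which case the (M*G) x Cout matrix itself is returned (patch embed)
conv_fwd <- function(V, H, W, Cin, Wt, b, k, stride = 1L, pad = 0L,
                     row_major = FALSE, tokens = FALSE) {
  G <- ncol(V)
  op <- im2col_op(H, W, Cin, k, stride, pad, row_major)
  Xcol <- as.matrix(op$P %*% V)                       # (M*E) x G
  X2 <- array(Xcol, dim = c(op$M, op$E, G))
  X2 <- matrix(aperm(X2, c(1L, 3L, 2L)), op$M * G, op$E)  # rows (o, g)
  Y <- X2 %*% Wt
  Y <- sweep(Y, 2L, b, "+")
  out <- if (tokens) Y else {
    Cout <- ncol(Wt)
    matrix(aperm(array(Y, dim = c(op$M, G, Cout)), c(1L, 3L, 2L)),
           op$M * Cout, G)
  }
  list(out = out, cache = list(X2 = X2, op = op, Wt = Wt, G = G,
                               tokens = tokens))
}

conv_bwd <- function(dout, cache) {
  op <- cache$op; G <- cache$G; Cout <- ncol(cache$Wt)
  dY <- if (cache$tokens) dout else
    matrix(aperm(array(dout, dim = c(op$M, Cout, G)), c(1L, 3L, 2L)),
           op$M * G, Cout)
  dWt <- crossprod(cache$X2, dY)
  db <- colSums(dY)
  dX2 <- dY %*% t(cache$Wt)                           # (M*G) x E
  dXcol <- matrix(aperm(array(dX2, dim = c(op$M, G, op$E)), c(1L, 3L, 2L)),
                  op$M * op$E, G)
  dV <- as.matrix(op$Pt %*% dXcol)
  list(dV = dV, dW = dWt, db = db)
}

relu_fwd <- function(x) {
  out <- pmax(x, 0)
  list(out = out, cache = x > 0)
}
relu_bwd <- function(dout, cache) dout * cache

## layer norm over rows (feature dimension = columns)
LN_EPS <- 1e-5
ln_fwd <- function(z, gamma, beta) {
  mu <- rowMeans(z)
  zc <- z - mu
  v <- rowMeans(zc * zc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- zc * inv
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}
ln_bwd <- function(dout, cache) {
  xhat <- cache$xhat; inv <- cache$inv; gamma <- cache$gamma
  D <- ncol(xhat)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, gamma, "*")
  ## standard layer-norm backward (per row)
  dz <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

linear_fwd <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = out, cache = list(x = x, W = W))
}
linear_bwd <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

## multi-head self-attention over a gene-blocked token stack
mhsa_fwd <- function(Z, p, n_genes, n_tokens) {
  D <- ncol(Z)
  H <- p$n_heads; dh <- D %/% H
  scl <- 1 / sqrt(dh)
  Q <- sweep(Z %*% p$Wq, 2L, p$bq, "+")
  K <- sweep(Z %*% p$Wk, 2L, p$bk, "+")
  V <- sweep(Z %*% p$Wv, 2L, p$bv, "+")
  O <- matrix(0, nrow(Z), D)
  att <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    idx <- ((g - 1L) * n_tokens + 1L):(g * n_tokens)
    att[[g]] <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- softmax_rows(Q[idx, cols, drop = FALSE] %*%
                          t(K[idx, cols, drop = FALSE]) * scl)
      O[idx, cols] <- A %*% V[idx, cols, drop = FALSE]
      att[[g]][[h]] <- A
    }
  }
  out <- sweep(O %*% p$Wo, 2L, p$bo, "+")
  list(out = out,
       cache = list(Z = Z, Q = Q, K = K, V = V, O = O, att = att, p = p,
                    scl = scl, n_genes = n_genes, n_tokens = n_tokens,
                    dh = dh, H = H))
}

mhsa_bwd <- function(dout, cache) {
  p <- cache$p; H <- cache$H; dh <- cache$dh; scl <- cache$scl
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- dQ; dV <- dQ
  for (g in seq_len(cache$n_genes)) {
    idx <- ((g - 1L) * cache$n_tokens + 1L):(g * cache$n_tokens)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$att[[g]][[h]]
      dOg <- dO[idx, cols, drop = FALSE]
      Vg <- cache$V[idx, cols, drop = FALSE]
      dA <- dOg %*% t(Vg)
      dV[idx, cols] <- crossprod(A, dOg)
      dS <- A * (dA - rowSums(dA * A)) * scl
      dQ[idx, cols] <- dS %*% cache$K[idx, cols, drop = FALSE]
      dK[idx, cols] <- crossprod(dS, cache$Q[idx, cols, drop = FALSE])
    }
  }
  grads <- list(
    Wq = crossprod(cache$Z, dQ), bq = colSums(dQ),
    Wk = crossprod(cache$Z, dK), bk = colSums(dK),
    Wv = crossprod(cache$Z, dV), bv = colSums(dV),
    Wo = dWo, bo = dbo)
  dZ <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dz = dZ, grads = grads)
}

## block-diagonal adjacency over genes (one graph replicated per gene)
bdiag_adjacency <- function(adjacency, n_genes) {
  A <- Matrix::Matrix(adjacency, sparse = TRUE)
  Ab <- Matrix::bdiag(rep(list(A), n_genes))
  list(A = Ab, At = Matrix::t(Ab))
}
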