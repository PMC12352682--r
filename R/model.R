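#' Network hyperparameter configuration
#'
#' Collects the architecture hyperparameters of the super-resolution
#' network. Defaults are sized so that a full classic-ST section (a few
#' hundred spots) trains in minutes on one CPU core.
#'
#' @param cnn_channels output channels of the two front-end convolution
#'   layers (each 3x3, same padding, ReLU).
#' @param cnn_kernel odd kernel size of both convolutions.
#' @param patch_size side `p` of the non-overlapping patches tokenized by
#'   the transformer; the grid is zero-padded to a multiple of `p`.
#' @param embed_dim token embedding dimension `D`; must be divisible by
#'   `n_heads` and even (for the sinusoidal positional encoding).
#' @param n_heads attention heads `H` (head dimension `D/H`).
#' @param n_blocks transformer blocks, each containing multi-head
#'   self-attention, one graph-aggregation step and an MLP, all with
#'   pre-norm residual connections.
#' @param mlp_ratio hidden width of the block MLP as a multiple of
#'   `embed_dim`.
#' @param gnn_sigma,gnn_k,gnn_epsilon Gaussian-kernel kNN graph parameters
#'   (see [build_adjacency()]); `gnn_k = 4` keeps the four lattice
#'   neighbours of each patch.
#' @param gnn_include_self count a patch among its own neighbours.
#' @param use_gnn,use_pos_encoding ablation switches for the graph step
#'   and the positional encoding.
#' @return A list of class `"superres_config"`.
#' @export
superres_config <- function(cnn_channels = c(32L, 32L), cnn_kernel = 3L,
                            patch_size = 2L, embed_dim = 128L, n_heads = 4L,
                            n_blocks = 4L, mlp_ratio = 2L, gnn_sigma = 1,
                            gnn_k = 4L, gnn_epsilon = 1e-8,
                            gnn_include_self = FALSE, use_gnn = TRUE,
                            use_pos_encoding = TRUE) {
  if (cnn_kernel %% 2L != 1L)
    stop_resolvst("cnn_kernel must be odd (same-padding)", "parameter")
  if (embed_dim %% n_heads != 0L)
    stop_resolvst("embed_dim must be divisible by n_heads", "parameter")
  if (embed_dim %% 2L != 0L)
    stop_resolvst("embed_dim must be even for the sinusoidal encoding",
                  "parameter")
  if (!is_count(patch_size, 1L))
    stop_resolvst("patch_size must be a positive integer", "parameter")
  structure(list(cnn_channels = as.integer(cnn_channels),
                 cnn_kernel = as.integer(cnn_kernel),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 n_blocks = as.integer(n_blocks),
                 mlp_ratio = as.integer(mlp_ratio),
                 gnn_sigma = gnn_sigma, gnn_k = as.integer(gnn_k),
                 gnn_epsilon = gnn_epsilon,
                 gnn_include_self = isTRUE(gnn_include_self),
                 use_gnn = isTRUE(use_gnn),
                 use_pos_encoding = isTRUE(use_pos_encoding)),
            class = "superres_config")
}

#' Initialize network parameters
#'
#' Truncated-normal (sd 0.02, clipped at 2 sd) initialization for all
#' projection weights, zeros for biases (including the sub-pixel head
#' bias), ones/zeros for layer-norm scales/shifts. Fully reproducible
#' given `seed`.
#'
#' @param cfg a [superres_config()].
#' @param seed integer RNG seed.
#' @return Object of class `"network_state"`: list with `params`, `cfg`,
#'   `seed`.
#' @export
init_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "superres_config"))
  set.seed(seed)
  k <- cfg$cnn_kernel; C1 <- cfg$cnn_channels[1L]; C2 <- cfg$cnn_channels[2L]
  D <- cfg$embed_dim; p <- cfg$patch_size; Dh <- D * cfg$mlp_ratio
  mat <- function(nr, nc) matrix(rtruncnorm02(nr * nc), nr, nc)
  params <- list(
    conv1_W = mat(k * k, C1), conv1_b = numeric(C1),
    conv2_W = mat(k * k * C1, C2), conv2_b = numeric(C2),
    pe_W = mat(p * p * C2, D), pe_b = numeric(D),
    head_W = mat(D, 4L * p * p), head_b = numeric(4L * p * p),
    blocks = lapply(seq_len(cfg$n_blocks), function(b) list(
      ln1_g = rep(1, D), ln1_b = numeric(D),
      Wq = mat(D, D), bq = numeric(D), Wk = mat(D, D), bk = numeric(D),
      Wv = mat(D, D), bv = numeric(D), Wo = mat(D, D), bo = numeric(D),
      n_heads = cfg$n_heads,
      ln2_g = rep(1, D), ln2_b = numeric(D),
      Wg = mat(D, D), bg = numeric(D),
      ln3_g = rep(1, D), ln3_b = numeric(D),
      W1 = mat(D, Dh), b1 = numeric(Dh), W2 = mat(Dh, D), b2 = numeric(D))))
  structure(list(params = params, cfg = cfg, seed = as.integer(seed)),
            class = "network_state")
}

#' Sinusoidal positional encoding
#'
#' Absolute positional encoding added to the patch embeddings so the
#' otherwise permutation-invariant self-attention sees the patch order:
#' `PE[pos, 2i] = sin(pos / 10000^(2i/D))` and
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/D))` (0-based `pos` and `i`).
#'
#' @param n_patches number of patch positions `N`.
#' @param embed_dim even embedding dimension `D`.
#' @return `N x D` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(n_patches, embed_dim) {
  if (embed_dim %% 2L != 0L)
    stop_resolvst("embed_dim must be even", "parameter")
  pos <- seq_len(n_patches) - 1L
  i <- seq_len(embed_dim %/% 2L) - 1L
  freq <- 1 / 10000^(2 * i / embed_dim)
  ang <- outer(pos, freq)
  pe <- matrix(0, n_patches, embed_dim)
  pe[, 2L * i + 1L] <- sin(ang)
  pe[, 2L * i + 2L] <- cos(ang)
  pe
}

## zero-pad a (G, H, W) array (bottom/right) to multiples of p
pad_to_patch <- function(x, p) {
  d <- dim(x)
  Hp <- as.integer(ceiling(d[2L] / p) * p)
  Wp <- as.integer(ceiling(d[3L] / p) * p)
  if (Hp == d[2L] && Wp == d[3L]) return(x)
  out <- array(0, dim = c(d[1L], Hp, Wp))
  out[, seq_len(d[2L]), seq_len(d[3L])] <- x
  out
}

## (G, H, W) array -> image-stack matrix (H*W) x G and back
arr_to_stack <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2L, 3L, 1L)), d[2L] * d[3L], d[1L])
}
stack_to_arr <- function(V, H, W, G) {
  aperm(array(V, dim = c(H, W, G)), c(3L, 1L, 2L))
}

## head-output permutation: token matrix ((G*N) x 4p^2) -> (G, 4, Hp, Wp)
head_perm <- function(G, nh, nw, p) {
  key <- paste("hp", G, nh, nw, p, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  N <- nh * nw; Hp <- nh * p
  i <- seq_len(G * N * 4L * p * p)
  t0 <- (i - 1L) %% (G * N)          # 0-based token row
  m0 <- (i - 1L) %/% (G * N)         # 0-based head column
  g0 <- t0 %/% N
  n0 <- t0 %% N
  pr <- n0 %/% nw; pc <- n0 %% nw
  kk <- m0 %/% (p * p)
  rem <- m0 %% (p * p)
  di <- rem %/% p; dj <- rem %% p
  r <- pr * p + di; cc <- pc * p + dj
  perm <- 1L + g0 + kk * G + r * 4L * G + cc * 4L * G * Hp
  .geom_cache[[key]] <- perm
  perm
}

## ---- full forward pass with cache -----------------------------------------

net_forward <- function(x, state, keep_cache = FALSE, graph = NULL) {
  cfg <- state$cfg; par <- state$params
  G <- dim(x)[1L]
  x <- pad_to_patch(x, cfg$patch_size)
  Hp <- dim(x)[2L]; Wp <- dim(x)[3L]
  p <- cfg$patch_size
  nh <- Hp %/% p; nw <- Wp %/% p; N <- nh * nw
  kpad <- (cfg$cnn_kernel - 1L) %/% 2L
  cache <- list(G = G, Hp = Hp, Wp = Wp, N = N, nh = nh, nw = nw)

  ## CNN front-end: two same-padding convolutions with ReLU
  V0 <- arr_to_stack(x)
  c1 <- conv_fwd(V0, Hp, Wp, 1L, par$conv1_W, par$conv1_b, cfg$cnn_kernel,
                 pad = kpad)
  r1 <- relu_fwd(c1$out)
  c2 <- conv_fwd(r1$out, Hp, Wp, cfg$cnn_channels[1L], par$conv2_W,
                 par$conv2_b, cfg$cnn_kernel, pad = kpad)
  r2 <- relu_fwd(c2$out)

  ## patch embedding: p x p convolution with stride p, row-major tokens
  pe <- conv_fwd(r2$out, Hp, Wp, cfg$cnn_channels[2L], par$pe_W, par$pe_b,
                 p, stride = p, row_major = TRUE, tokens = TRUE)
  Z <- pe$out                                   # (G*N) x D
  if (cfg$use_pos_encoding) {
    PE <- positional_encoding(N, cfg$embed_dim)
    Z <- Z + PE[rep(seq_len(N), times = G), ]
  }

  ## spatial patch graph, shared by all blocks; a single patch has no
  ## neighbours, so the graph step degenerates to a no-op there
  gnn_active <- cfg$use_gnn && N >= 2L
  Ab <- NULL
  if (gnn_active) {
    if (is.null(graph))
      graph <- build_adjacency(patch_coords(Hp, Wp, p), sigma = cfg$gnn_sigma,
                               k = min(cfg$gnn_k, N - 1L),
                               epsilon = cfg$gnn_epsilon,
                               include_self = cfg$gnn_include_self)
    Ab <- bdiag_adjacency(graph$adjacency, G)
  }
  cache$gnn_active <- gnn_active

  blocks <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    pb <- par$blocks[[b]]
    bc <- list()
    ## attention sub-layer (pre-norm residual)
    l1 <- ln_fwd(Z, pb$ln1_g, pb$ln1_b)
    at <- mhsa_fwd(l1$out, pb, G, N)
    Z <- Z + at$out
    bc$l1 <- l1$cache; bc$at <- at$cache
    ## graph sub-layer: aggregate neighbours, project, residual
    if (gnn_active) {
      l2 <- ln_fwd(Z, pb$ln2_g, pb$ln2_b)
      agg <- as.matrix(Ab$A %*% l2$out)
      gp <- linear_fwd(agg, pb$Wg, pb$bg)
      Z <- Z + gp$out
      bc$l2 <- l2$cache; bc$agg <- agg; bc$gp <- gp$cache
    }
    ## MLP sub-layer
    l3 <- ln_fwd(Z, pb$ln3_g, pb$ln3_b)
    m1 <- linear_fwd(l3$out, pb$W1, pb$b1)
    ra <- relu_fwd(m1$out)
    m2 <- linear_fwd(ra$out, pb$W2, pb$b2)
    Z <- Z + m2$out
    bc$l3 <- l3$cache; bc$m1 <- m1$cache; bc$ra <- ra$cache; bc$m2 <- m2$cache
    blocks[[b]] <- bc
  }

  ## inverse patch reconstruction: project tokens to 4 p^2 sub-pixel values
  hd <- linear_fwd(Z, par$head_W, par$head_b)
  perm <- head_perm(G, nh, nw, p)
  ch <- array(0, dim = c(G, 4L, Hp, Wp))
  ch[perm] <- as.vector(hd$out)

  if (keep_cache) {
    cache$c1 <- c1$cache; cache$r1 <- r1$cache; cache$c2 <- c2$cache
    cache$r2 <- r2$cache; cache$pe <- pe$cache; cache$blocks <- blocks
    cache$hd <- hd$cache; cache$perm <- perm; cache$Ab <- Ab
    cache$cfg <- cfg
  }
  list(ch = ch, cache = cache, graph = graph)
}

## backward pass: dch is the gradient w.r.t. the (G, 4, Hp, Wp) output
net_backward <- function(dch, state, cache) {
  cfg <- cache$cfg; par <- state$params
  G <- cache$G; N <- cache$N
  dT <- matrix(as.vector(dch)[cache$perm], G * N, ncol(par$head_W))
  gh <- linear_bwd(dT, cache$hd)
  grads <- list(head_W = gh$dW, head_b = gh$db)
  dZ <- gh$dx
  gblocks <- vector("list", cfg$n_blocks)
  for (b in rev(seq_len(cfg$n_blocks))) {
    bc <- cache$blocks[[b]]
    gb <- list()
    ## MLP sub-layer
    g2 <- linear_bwd(dZ, bc$m2)
    gb$W2 <- g2$dW; gb$b2 <- g2$db
    dr <- relu_bwd(g2$dx, bc$ra)
    g1 <- linear_bwd(dr, bc$m1)
    gb$W1 <- g1$dW; gb$b1 <- g1$db
    l3 <- ln_bwd(g1$dx, bc$l3)
    gb$ln3_g <- l3$dgamma; gb$ln3_b <- l3$dbeta
    dZ <- dZ + l3$dz
    ## graph sub-layer
    if (cache$gnn_active) {
      gg <- linear_bwd(dZ, bc$gp)
      gb$Wg <- gg$dW; gb$bg <- gg$db
      dagg <- as.matrix(cache$Ab$At %*% gg$dx)
      l2 <- ln_bwd(dagg, bc$l2)
      gb$ln2_g <- l2$dgamma; gb$ln2_b <- l2$dbeta
      dZ <- dZ + l2$dz
    } else {
      D <- cfg$embed_dim
      gb$Wg <- matrix(0, D, D); gb$bg <- numeric(D)
      gb$ln2_g <- numeric(D); gb$ln2_b <- numeric(D)
    }
    ## attention sub-layer
    ma <- mhsa_bwd(dZ, bc$at)
    gb[names(ma$grads)] <- ma$grads
    l1 <- ln_bwd(ma$dz, bc$l1)
    gb$ln1_g <- l1$dgamma; gb$ln1_b <- l1$dbeta
    dZ <- dZ + l1$dz
    gblocks[[b]] <- gb
  }
  grads$blocks <- gblocks
  ## positional encoding is constant: gradient passes straight through
  gpe <- conv_bwd(dZ, cache$pe)
  grads$pe_W <- gpe$dW; grads$pe_b <- gpe$db
  dr2 <- relu_bwd(gpe$dV, cache$r2)
  gc2 <- conv_bwd(dr2, cache$c2)
  grads$conv2_W <- gc2$dW; grads$conv2_b <- gc2$db
  dr1 <- relu_bwd(gc2$dV, cache$r1)
  gc1 <- conv_bwd(dr1, cache$c1)
  grads$conv1_W <- gc1$dW; grads$conv1_b <- gc1$db
  grads
}

## ---- exported single-stage wrappers (contract surface) ---------------------

#' Convolutional front-end
#'
#' Two stacked same-padding convolutions with ReLU after each, applied to
#' every gene image independently (genes are the batch axis, one input
#' channel). Output spatial dimensions equal the input's.
#'
#' @param x numeric array `G x H x W` (or `G x 1 x H x W`).
#' @param state a [init_network()] state.
#' @return Array `G x C2 x H x W` of non-negative activations.
#' @export
cnn_forward <- function(x, state) {
  stopifnot(inherits(state, "network_state"))
  x <- drop_channel_dim(x)
  if (any(!is.finite(x)))
    stop_resolvst("input must be finite", "validation")
  cfg <- state$cfg
  d <- dim(x); G <- d[1L]; H <- d[2L]; W <- d[3L]
  kpad <- (cfg$cnn_kernel - 1L) %/% 2L
  V0 <- arr_to_stack(x)
  c1 <- relu_fwd(conv_fwd(V0, H, W, 1L, state$params$conv1_W,
                          state$params$conv1_b, cfg$cnn_kernel,
                          pad = kpad)$out)$out
  c2 <- relu_fwd(conv_fwd(c1, H, W, cfg$cnn_channels[1L],
                          state$params$conv2_W, state$params$conv2_b,
                          cfg$cnn_kernel, pad = kpad)$out)$out
  C2 <- cfg$cnn_channels[2L]
  ## (H*W*C2) x G -> (G, C2, H, W)
  aperm(array(c2, dim = c(H, W, C2, G)), c(4L, 3L, 1L, 2L))
}

drop_channel_dim <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) {
    if (d[2L] != 1L)
      stop_resolvst("expected a single input channel", "contract")
    x <- array(x[, 1L, , ], dim = d[c(1L, 3L, 4L)])
  } else if (length(d) != 3L) {
    stop_resolvst("expected a G x H x W or G x 1 x H x W array", "contract")
  }
  x
}

#' Patch embedding
#'
#' Tokenizes a `G x C x H x W` feature map with a `p x p` convolution of
#' stride `p` and flattens to `G x N x D` with patches enumerated
#' row-major, matching [patch_coords()].
#'
#' @param z numeric array `G x C x H x W`, `H` and `W` divisible by the
#'   configured patch size.
#' @param state a [init_network()] state.
#' @return Array `G x N x D`.
#' @export
patch_embed <- function(z, state) {
  stopifnot(inherits(state, "network_state"))
  cfg <- state$cfg
  d <- dim(z)
  if (length(d) != 4L || d[2L] != cfg$cnn_channels[2L])
    stop_resolvst("expected a G x C2 x H x W array", "contract")
  p <- cfg$patch_size
  if (d[3L] %% p != 0L || d[4L] %% p != 0L)
    stop_resolvst("spatial dims must be divisible by patch_size; pad first",
                  "contract")
  G <- d[1L]; H <- d[3L]; W <- d[4L]; C <- d[2L]
  V <- matrix(aperm(z, c(3L, 4L, 2L, 1L)), H * W * C, G)
  tok <- conv_fwd(V, H, W, C, state$params$pe_W, state$params$pe_b, p,
                  stride = p, row_major = TRUE, tokens = TRUE)$out
  N <- (H %/% p) * (W %/% p)
  aperm(array(tok, dim = c(N, G, cfg$embed_dim)), c(2L, 1L, 3L))
}

#' Multi-head self-attention layer
#'
#' Scaled dot-product attention: queries, keys and values are linear
#' projections of the tokens, attention is `softmax(Q K' / sqrt(d_h)) V`
#' per head, and the concatenated heads are projected back to `D`.
#'
#' @param z numeric array `G x N x D` of token embeddings.
#' @param state a [init_network()] state.
#' @param block which transformer block's weights to use (default 1).
#' @return Array `G x N x D`.
#' @export
mhsa <- function(z, state, block = 1L) {
  stopifnot(inherits(state, "network_state"))
  d <- dim(z)
  if (length(d) != 3L || d[3L] != state$cfg$embed_dim)
    stop_resolvst("expected a G x N x D array with configured D", "contract")
  G <- d[1L]; N <- d[2L]
  Z <- matrix(aperm(z, c(2L, 1L, 3L)), G * N, d[3L])
  out <- mhsa_fwd(Z, state$params$blocks[[block]], G, N)$out
  aperm(array(out, dim = c(N, G, d[3L])), c(2L, 1L, 3L))
}

#' One transformer block
#'
#' Pre-norm residual composition: attention, then graph aggregation of the
#' layer-normed tokens (projected back to `D`), then the MLP:
#' `z <- z + MHSA(LN(z))`; `z <- z + Proj(Atilde LN(z))`;
#' `z <- z + MLP(LN(z))`.
#'
#' @param z numeric array `G x N x D`.
#' @param graph a [build_adjacency()] result for the same `N`.
#' @param state a [init_network()] state.
#' @param block block index.
#' @return Array `G x N x D`.
#' @export
transformer_block <- function(z, graph, state, block = 1L) {
  stopifnot(inherits(state, "network_state"))
  d <- dim(z)
  G <- d[1L]; N <- d[2L]
  if (!is.null(graph) && nrow(graph$adjacency) != N)
    stop_resolvst("graph was built for a different number of patches",
                  "contract")
  cfg <- state$cfg
  pb <- state$params$blocks[[block]]
  Z <- matrix(aperm(z, c(2L, 1L, 3L)), G * N, d[3L])
  Z <- Z + mhsa_fwd(ln_fwd(Z, pb$ln1_g, pb$ln1_b)$out, pb, G, N)$out
  if (cfg$use_gnn && !is.null(graph)) {
    Ab <- bdiag_adjacency(graph$adjacency, G)
    zn <- ln_fwd(Z, pb$ln2_g, pb$ln2_b)$out
    Z <- Z + linear_fwd(as.matrix(Ab$A %*% zn), pb$Wg, pb$bg)$out
  }
  zn <- ln_fwd(Z, pb$ln3_g, pb$ln3_b)$out
  Z <- Z + linear_fwd(relu_fwd(linear_fwd(zn, pb$W1, pb$b1)$out)$out,
                      pb$W2, pb$b2)$out
  aperm(array(Z, dim = c(N, G, d[3L])), c(2L, 1L, 3L))
}

#' Full network forward pass
#'
#' Runs the whole architecture on an expression grid (genes as batch,
#' single channel): CNN front-end, patch embedding plus sinusoidal
#' positional encoding, transformer blocks with embedded graph
#' aggregation, and the sub-pixel head. The grid is zero-padded to
#' patch-divisible dimensions internally and the output cropped back.
#'
#' @param g an [expression_grid()] (or a `G x H x W` array).
#' @param state a [init_network()] state.
#' @return Numeric array `G x 4 x H x W` of sub-pixel channel predictions
#'   (see [interleave()] for the channel-to-position contract).
#' @export
network_forward <- function(g, state) {
  stopifnot(inherits(state, "network_state"))
  x <- if (inherits(g, "expression_grid")) g$data else g
  x <- drop_channel_dim(x)
  if (any(!is.finite(x)))
    stop_resolvst("input must be finite", "validation")
  d <- dim(x)
  ch <- net_forward(x, state)$ch
  ch[, , seq_len(d[2L]), seq_len(d[3L]), drop = FALSE]
}
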