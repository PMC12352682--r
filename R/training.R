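#' Tissue-masked multi-channel mean squared error
#'
#' The training loss. The `G x 2H x 2W` target is split into its four
#' sub-pixel channels (see [deinterleave()]) and compared with the
#' predicted channels only where the channel-subsampled tissue mask
#' `M^(k)` is 1:
#' \deqn{L = \frac{1}{4N} \sum_{k=0}^{3} \sum_{i,j} M^{(k)}_{i,j}
#'   (\hat Y^{(k)}_{i,j} - Y^{(k)}_{i,j})^2}
#' with `N = sum(M^(k))` counting valid tissue pixels across all four
#' channels. Note the `1/(4N)` prefactor divides by 4 although `N`
#' already sums over the channels; this printed form is the default, and
#' `loss_norm = "per_pixel"` gives the plain per-valid-pixel mean `1/N`
#' instead (the two differ by an exact factor 4). For a multi-gene tensor
#' the loss is averaged over genes.
#'
#' @param pred numeric array `G x 4 x H x W` of predicted sub-pixel
#'   channels.
#' @param target numeric array `G x 2H x 2W`.
#' @param mask binary `2H x 2W` tissue mask with at least one 1.
#' @param loss_norm `"paper_form"` (the `1/(4N)` prefactor) or
#'   `"per_pixel"`.
#' @return Object of class `"loss_result"`: list with `value`, `n_valid`
#'   (`N` above), and `per_channel` (raw squared-error sums per channel,
#'   summed over genes).
#' @export
masked_mse <- function(pred, target, mask,
                       loss_norm = c("paper_form", "per_pixel")) {
  loss_norm <- match.arg(loss_norm)
  dp <- dim(pred); dt <- dim(target)
  if (length(dp) != 4L || dp[2L] != 4L)
    stop_resolvst("pred must be a G x 4 x H x W array", "contract")
  if (length(dt) != 3L || dt[1L] != dp[1L] ||
      dt[2L] != 2L * dp[3L] || dt[3L] != 2L * dp[4L])
    stop_resolvst("target must be G x 2H x 2W matching pred", "contract")
  if (!all(dim(mask) == dt[2:3]))
    stop_resolvst("mask must be 2H x 2W", "contract")
  m4 <- mask_subsample(mask)
  n_valid <- sum(m4)
  if (n_valid == 0)
    stop_resolvst("mask has no valid tissue pixels (N = 0)", "parameter")
  tch <- deinterleave(target)
  G <- dp[1L]
  sq <- (pred - tch)^2
  per_channel <- numeric(4L)
  for (k in 1:4) {
    mk <- m4[k, , ]
    per_channel[k] <- sum(sweep(
      array(sq[, k, , ], dim = c(G, dp[3L], dp[4L])),
      c(2L, 3L), mk, "*"))
  }
  denom <- if (loss_norm == "paper_form") 4 * n_valid else n_valid
  structure(list(value = sum(per_channel) / (denom * G),
                 n_valid = as.integer(n_valid),
                 per_channel = per_channel,
                 loss_norm = loss_norm),
            class = "loss_result")
}

#' @export
print.loss_result <- function(x, ...) {
  cat(sprintf("masked MSE (%s): %.6g over %d valid tissue pixels\n",
              x$loss_norm, x$value, x$n_valid))
  invisible(x)
}

## gradient of the (gene-averaged) masked loss w.r.t. pred
masked_mse_grad <- function(pred, tch, m4, n_valid, loss_norm, n_genes) {
  denom <- if (loss_norm == "paper_form") 4 * n_valid else n_valid
  diff <- pred - tch
  for (k in 1:4)
    diff[, k, , ] <- sweep(
      array(diff[, k, , ], dim = dim(pred)[c(1L, 3L, 4L)]),
      c(2L, 3L), m4[k, , ], "*")
  2 * diff / (denom * n_genes)
}

## ---- Adam over the nested parameter list -----------------------------------

tree_zero <- function(p) {
  if (is.list(p)) lapply(p, tree_zero)
  else if (is.numeric(p)) p * 0
  else p
}

adam_step <- function(params, grads, m, v, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  rec <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out_p <- p; out_m <- mm; out_v <- vv
      for (nm in names(p)) {
        if (!is.numeric(p[[nm]]) && !is.list(p[[nm]])) next
        r <- rec(p[[nm]], g[[nm]], mm[[nm]], vv[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    if (weight_decay > 0) g <- g + weight_decay * p
    mm <- beta1 * mm + (1 - beta1) * g
    vv <- beta2 * vv + (1 - beta2) * g * g
    mhat <- mm / (1 - beta1^t)
    vhat <- vv / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
  }
  rec(params, grads, m, v)
}

#' Train the super-resolution network on one tissue section
#'
#' Self-supervised training on a single down-sampled/original grid pair
#' (see [make_training_pair()]): the low-resolution grid is the input and
#' the original grid the reconstruction target, scored by [masked_mse()]
#' over the original tissue mask. Training runs full-batch (all genes) for
#' a fixed number of epochs with the Adam optimizer; everything is
#' deterministic given `seed`.
#'
#' Most users should call [superres()], which wraps normalization, pair
#' construction, training and bookkeeping; this function is the bare
#' engine.
#'
#' @param pair a [make_training_pair()] result.
#' @param cfg a [superres_config()].
#' @param epochs number of epochs (>= 1); 500 matches the reference
#'   protocol for real sections, smaller values suffice for synthetic
#'   smoke cases.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty coefficient added to gradients.
#' @param seed RNG seed for parameter initialization.
#' @param loss_norm see [masked_mse()].
#' @param state optional pre-initialized [init_network()] state (overrides
#'   `seed`).
#' @param verbose print the loss every 50 epochs.
#' @return List with `state` (trained [init_network()] state), `loss_trace`
#'   (per-epoch loss), `graph` (the patch graph used), and `n_valid`.
#' @export
train_network <- function(pair, cfg = superres_config(), epochs = 500L,
                          lr = 1e-3, weight_decay = 0, seed = 1L,
                          loss_norm = c("paper_form", "per_pixel"),
                          state = NULL, verbose = FALSE) {
  loss_norm <- match.arg(loss_norm)
  if (!is_count(epochs, 1L))
    stop_resolvst("epochs must be a positive integer", "parameter")
  x <- pair$input$data
  G <- dim(x)[1L]
  p <- cfg$patch_size
  Hp <- as.integer(ceiling(dim(x)[2L] / p) * p)
  Wp <- as.integer(ceiling(dim(x)[3L] / p) * p)
  ## pad target/mask into the 2x window of the (padded) model output
  tfull <- pair$target$data; mfull <- pair$target_mask
  t2 <- array(0, dim = c(G, 2L * Hp, 2L * Wp))
  t2[, seq_len(dim(tfull)[2L]), seq_len(dim(tfull)[3L])] <- tfull
  m2 <- matrix(0L, 2L * Hp, 2L * Wp)
  m2[seq_len(nrow(mfull)), seq_len(ncol(mfull))] <- mfull
  tch <- deinterleave(t2)
  m4 <- mask_subsample(m2)
  n_valid <- sum(m4)
  if (n_valid == 0)
    stop_resolvst("target mask has no tissue pixels", "parameter")

  state <- state %||% init_network(cfg, seed = seed)
  m <- tree_zero(state$params)
  v <- tree_zero(state$params)
  graph <- NULL
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- net_forward(x, state, keep_cache = TRUE, graph = graph)
    graph <- fw$graph
    diff <- fw$ch - tch
    sq <- 0
    for (k in 1:4)
      sq <- sq + sum(sweep(array(diff[, k, , ]^2, dim = c(G, Hp, Wp)),
                           c(2L, 3L), m4[k, , ], "*"))
    denom <- if (loss_norm == "paper_form") 4 * n_valid else n_valid
    loss <- sq / (denom * G)
    if (!is.finite(loss))
      stop_resolvst(paste0("training diverged (non-finite loss at epoch ",
                           ep, ")"), "training")
    loss_trace[ep] <- loss
    dch <- masked_mse_grad(fw$ch, tch, m4, n_valid, loss_norm, G)
    grads <- net_backward(dch, state, fw$cache)
    upd <- adam_step(state$params, grads, m, v, ep, lr,
                     weight_decay = weight_decay)
    state$params <- upd$p; m <- upd$m; v <- upd$v
    if (verbose && (ep %% 50L == 0L || ep == 1L))
      message(sprintf("epoch %4d  loss %.6g", ep, loss))
  }
  list(state = state, loss_trace = loss_trace, graph = graph,
       n_valid = n_valid)
}

#' Enhance a grid to double resolution
#'
#' Runs the trained network on an expression grid and interleaves the four
#' predicted sub-pixel channels into a `2H x 2W` grid. Every original
#' position `(r, c)` maps to output position `(2r, 2c)` (0-based); the
#' output mask is the 2x nearest-neighbour expansion of the input tissue
#' mask, so positions outside the original tissue boundary are zeroed and
#' excluded from any downstream evaluation.
#'
#' @param g an [expression_grid()].
#' @param state a trained [init_network()] state.
#' @return An [expression_grid()] with doubled spatial dimensions and
#'   doubled `origin_offset` (coordinates live on the doubled lattice).
#' @export
enhance <- function(g, state) {
  stopifnot(inherits(g, "expression_grid"), inherits(state, "network_state"))
  ch <- network_forward(g, state)
  y <- interleave(ch)
  mask2 <- g$mask[rep(seq_len(nrow(g$mask)), each = 2L),
                  rep(seq_len(ncol(g$mask)), each = 2L)]
  expression_grid(y, mask2, lattice = g$lattice,
                  origin_offset = 2L * g$origin_offset,
                  gene_names = g$gene_names)
}
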