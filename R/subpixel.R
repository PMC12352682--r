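#' Sub-pixel channel interleaving
#'
#' The network predicts four spatially offset sub-pixel channels per
#' low-resolution cell; `interleave()` rearranges a `G x 4 x H x W` tensor
#' into the `G x 2H x 2W` super-resolved map using the fixed channel ->
#' offset table (0-based coordinates):
#' channel 0 -> `(2i, 2j)`, 1 -> `(2i, 2j+1)`, 2 -> `(2i+1, 2j)`,
#' 3 -> `(2i+1, 2j+1)`. `deinterleave()` is its exact inverse; both are
#' pure index shuffles (bit-exact, no arithmetic).
#'
#' @param ch numeric array `G x 4 x H x W`.
#' @return `interleave()`: array `G x 2H x 2W`.
#' @export
interleave <- function(ch) {
  d <- dim(ch)
  if (length(d) != 4L || d[2L] != 4L)
    stop_resolvst("expected a G x 4 x H x W array", "contract")
  G <- d[1L]; H <- d[3L]; W <- d[4L]
  out <- array(vector(typeof(ch), 1L), dim = c(G, 2L * H, 2L * W))
  odd_r <- seq(1L, 2L * H, 2L); evn_r <- odd_r + 1L
  odd_c <- seq(1L, 2L * W, 2L); evn_c <- odd_c + 1L
  out[, odd_r, odd_c] <- ch[, 1L, , ]   # k = 0 -> (2i,   2j)
  out[, odd_r, evn_c] <- ch[, 2L, , ]   # k = 1 -> (2i,   2j+1)
  out[, evn_r, odd_c] <- ch[, 3L, , ]   # k = 2 -> (2i+1, 2j)
  out[, evn_r, evn_c] <- ch[, 4L, , ]   # k = 3 -> (2i+1, 2j+1)
  out
}

#' @rdname interleave
#' @param y numeric array `G x 2H x 2W` with even spatial dimensions.
#' @return `deinterleave()`: array `G x 4 x H x W`.
#' @export
deinterleave <- function(y) {
  d <- dim(y)
  if (length(d) != 3L)
    stop_resolvst("expected a G x 2H x 2W array", "contract")
  if (d[2L] %% 2L != 0L || d[3L] %% 2L != 0L)
    stop_resolvst("spatial dimensions must be even", "contract")
  G <- d[1L]; H <- d[2L] %/% 2L; W <- d[3L] %/% 2L
  ch <- array(vector(typeof(y), 1L), dim = c(G, 4L, H, W))
  odd_r <- seq(1L, 2L * H, 2L); evn_r <- odd_r + 1L
  odd_c <- seq(1L, 2L * W, 2L); evn_c <- odd_c + 1L
  ch[, 1L, , ] <- y[, odd_r, odd_c, drop = FALSE]
  ch[, 2L, , ] <- y[, odd_r, evn_c, drop = FALSE]
  ch[, 3L, , ] <- y[, evn_r, odd_c, drop = FALSE]
  ch[, 4L, , ] <- y[, evn_r, evn_c, drop = FALSE]
  ch
}

#' Down-sample a tissue mask into the four sub-pixel channels
#'
#' Splits a `2H x 2W` binary mask `M` into the 4-channel form used by the
#' masked loss: `M^(k)[i, j] = M[2i + floor(k/2), 2j + (k mod 2)]`
#' (0-based). Conserves the total count of ones, and
#' `interleave(mask_subsample(M))` reproduces `M`.
#'
#' @param m binary matrix with even dimensions.
#' @return Binary array `4 x H x W`.
#' @export
mask_subsample <- function(m) {
  m <- as.matrix(m)
  d <- dim(m)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L)
    stop_resolvst("mask dimensions must be even", "contract")
  y <- array(m, dim = c(1L, d[1L], d[2L]))
  ch <- deinterleave(y)
  array(ch, dim = c(4L, d[1L] %/% 2L, d[2L] %/% 2L))
}
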