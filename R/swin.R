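# Shifted-window multi-head self-attention: the fundamental unit of the
# network.  Token grids are 3-d arrays [rows, cols, channels]; windows are
# stored as a 3-d array [N^2 tokens, n_windows, channels] so that per-head
# attention over all windows can be evaluated with a handful of vectorised
# array operations instead of a loop over windows.
#
# Coordinate conventions: window order is row-major over the window grid and
# token order within a window is row-major (index t = r*N + c, 0-based).

.swin_cache <- new.env(parent = emptyenv())

# Permutation sending the column-major flattening of an H x W grid to
# [token within window, window] order; cached per (H, W, N).
window_order <- function(H, W, N) {
  key <- paste(H, W, N, sep = "x")
  ord <- .swin_cache[[key]]
  if (!is.null(ord)) return(ord)
  nWr <- H %/% N; nWc <- W %/% N
  # t fastest, then window (row-major over window grid)
  g <- expand.grid(t = 0:(N * N - 1), w = 0:(nWr * nWc - 1))
  r <- g$t %/% N; cc <- g$t %% N
  wr <- g$w %/% nWc; wc <- g$w %% nWc
  row <- wr * N + r; col <- wc * N + cc
  ord <- col * H + row + 1L
  .swin_cache[[key]] <- ord
  ord
}

check_divisible <- function(H, W, N) {
  if (H %% N != 0)
    stop("token grid height (", H, ") is not divisible by window size ", N)
  if (W %% N != 0)
    stop("token grid width (", W, ") is not divisible by window size ", N)
}

#' Partition a token grid into non-overlapping windows
#'
#' Splits an `H x W x C` token grid into `(H/N)*(W/N)` square windows of
#' `N^2` tokens each.  Windows are ordered row-major over the window grid
#' and tokens row-major within a window, so `out[, w, ]` is the
#' `N^2 x C` token matrix of window `w`.
#'
#' @param grid 3-d array `[rows, cols, channels]` of token features
#' @param N window side length, in tokens
#' @return 3-d array `[N^2, n_windows, channels]`
#' @seealso [window_reverse()]
#' @export
window_partition <- function(grid, N) {
  d <- dim(grid)
  check_divisible(d[1], d[2], N)
  ord <- window_order(d[1], d[2], N)
  m <- matrix(grid, d[1] * d[2], d[3])
  array(m[ord, , drop = FALSE], c(N * N, d[1] %/% N * (d[2] %/% N), d[3]))
}

#' Reassemble windows into a token grid
#'
#' Exact inverse of [window_partition()].
#'
#' @param windows array `[N^2, n_windows, channels]`
#' @param H,W token-grid resolution to restore
#' @return 3-d array `[H, W, channels]`
#' @export
window_reverse <- function(windows, H, W) {
  d <- dim(windows)
  N <- as.integer(sqrt(d[1]))
  ord <- window_order(H, W, N)
  m <- matrix(0, H * W, d[3])
  m[ord, ] <- matrix(windows, d[1] * d[2], d[3])
  array(m, c(H, W, d[3]))
}

#' Cyclically shift a token grid
#'
#' Toroidal roll of the grid by `s` positions along both spatial axes
#' (content at (r, c) moves to ((r+s) mod H, (c+s) mod W)).  Used to
#' implement shifted-window attention: shifting by `-floor(N/2)` before
#' partitioning displaces the window boundaries by half a window.
#'
#' @param grid 3-d array `[rows, cols, channels]`
#' @param s integer displacement (negative rolls up/left); `s = 0` is the
#'   identity
#' @return shifted grid, same shape
#' @export
cyclic_shift <- function(grid, s) {
  if (s == 0) return(grid)
  d <- dim(grid)
  ri <- ((seq_len(d[1]) - 1 - s) %% d[1]) + 1
  ci <- ((seq_len(d[2]) - 1 - s) %% d[2]) + 1
  grid[ri, ci, , drop = FALSE]
}

# ---- relative position bias -------------------------------------------------

# Index map sending each ordered token pair of an N x N window to a row of
# the (2N-1)^2 relative-offset bias table.  Depends only on N.  Returned as
# an N^2 x N^2 integer matrix in [key, query] orientation, matching the
# [key, query, window] score layout used below.
relative_position_index <- function(N) {
  key <- paste0("rpi", N)
  idx <- .swin_cache[[key]]
  if (!is.null(idx)) return(idx)
  t_ <- 0:(N * N - 1)  # token t = r*N + c (row-major)
  r <- t_ %/% N; cc <- t_ %% N
  dr <- outer(r, r, `-`)   # dr[i, j] = r_i - r_j, i = query, j = key
  dc <- outer(cc, cc, `-`)
  idx <- (dr + N - 1) * (2 * N - 1) + (dc + N - 1) + 1L  # [query, key]
  storage.mode(idx) <- "integer"
  .swin_cache[[key]] <- idx
  idx
}

init_relative_bias <- function(N, heads, sd = 0.02) {
  matrix(trunc_normal((2 * N - 1)^2 * heads, sd), (2 * N - 1)^2, heads)
}

# ---- shifted-window attention mask -----------------------------------------

#' Additive attention mask for shifted-window attention
#'
#' After the cyclic shift, border windows contain tokens that wrapped around
#' from the opposite side of the image.  This mask forbids attention between
#' tokens that were not neighbours before the shift, by adding a large
#' negative constant to the corresponding score entries (0 elsewhere).
#'
#' @param resolution integer vector `(H, W)` of the token grid
#' @param N window size
#' @param displacement shift magnitude, must satisfy `0 <= displacement < N`
#' @return array `[N^2, N^2, n_windows]` of 0 / -1e9 entries, `[key, query]`
#'   oriented (the mask is symmetric so orientation does not matter)
#' @export
shifted_window_attention_mask <- function(resolution, N, displacement) {
  H <- resolution[1]; W <- resolution[2]
  check_divisible(H, W, N)
  if (displacement >= N || displacement < 0)
    stop("shift displacement must lie in [0, window size); got ", displacement)
  T2 <- N * N
  nW <- (H %/% N) * (W %/% N)
  if (displacement == 0) return(array(0, c(T2, T2, nW)))
  # label each token of the *shifted* grid by the contiguous region it came
  # from; bands end at H-N and H-displacement
  band <- function(n) {
    v <- integer(n)
    v[(n - N + 1):n] <- 1L
    v[(n - displacement + 1):n] <- 2L
    v
  }
  lab <- outer(band(H) * 3L, band(W), `+`)  # H x W region labels
  labw <- window_partition(array(lab, c(H, W, 1)), N)[, , 1, drop = FALSE]
  dim(labw) <- c(T2, nW)
  mask <- array(0, c(T2, T2, nW))
  for (w in seq_len(nW)) {
    l <- labw[, w]
    mask[, , w] <- ifelse(outer(l, l, `!=`), -1e9, 0)
  }
  mask
}

# ---- core attention (Eq-style scaled dot product with bias) ----------------

#' Windowed multi-head self-attention on explicit Q, K, V
#'
#' Computes `softmax(Q K' / sqrt(d) + bias + mask) V` independently per head:
#' the scaled-dot-product attention used inside every window.  `Q`, `K`, `V`
#' are `N^2 x d` matrices (single head) or `N^2 x d x heads` arrays; `bias`
#' and `mask` are `N^2 x N^2` additive score terms (`bias` may be per-head,
#' `N^2 x N^2 x heads`).  Rows of the softmax sum to one, so every output
#' row is a convex combination of rows of `V`.
#'
#' @param Q,K,V query/key/value matrices or per-head arrays
#' @param bias optional additive relative-position bias, `bias[i, j]` added
#'   to the score of query i attending to key j
#' @param mask optional additive mask (0 or large-negative entries)
#' @return array shaped like `V`
#' @export
msa <- function(Q, K, V, bias = NULL, mask = NULL) {
  one <- is.matrix(Q)
  if (one) { Q <- array(Q, c(dim(Q), 1)); K <- array(K, c(dim(K), 1)); V <- array(V, c(dim(V), 1)) }
  if (!all(dim(Q) == dim(K)) || dim(V)[1] != dim(Q)[1] || dim(V)[3] != dim(Q)[3])
    stop("Q, K, V shapes do not conform")
  d <- dim(Q)[2]
  heads <- dim(Q)[3]
  T2 <- dim(Q)[1]
  dv <- dim(V)[2]
  out <- array(0, dim(V))
  for (h in seq_len(heads)) {
    Qh <- matrix(Q[, , h], T2, d); Kh <- matrix(K[, , h], T2, d)
    Vh <- matrix(V[, , h], T2, dv)
    S <- tcrossprod(Qh, Kh) / sqrt(d)
    if (!is.null(bias)) S <- S + (if (length(dim(bias)) == 3) bias[, , h] else bias)
    if (!is.null(mask)) S <- S + mask
    S <- S - apply(S, 1, max)  # numeric stabilisation, row-wise
    P <- exp(S)
    P <- P / rowSums(P)
    out[, , h] <- P %*% Vh
  }
  if (one) out <- matrix(out[, , 1], T2, dv)
  out
}

# ---- full attention layer (QKV projection, all windows batched) ------------

init_window_attention <- function(C, heads, N) {
  list(qkv = init_linear(C, 3 * C),
       proj = init_linear(C, C),
       bias_table = init_relative_bias(N, heads))
}

# x: [H, W, C] token grid.  p: layer params.  N window, shift displacement,
# heads count.  mask: [T, T, nW] or NULL.  Returns out grid + cache.
# The softmax(QK' + B + M)V kernel and its adjoint are compiled (attn_core_*).
window_attention_fwd <- function(x, p, N, heads, shift = 0, mask = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  if (C %% heads != 0) stop("channels not divisible by head count")
  dh <- C %/% heads
  scale <- 1 / sqrt(dh)
  xs <- cyclic_shift(x, -shift)
  xw <- window_partition(xs, N)          # [T, nW, C]
  T2 <- dim(xw)[1]; nW <- dim(xw)[2]
  X <- matrix(xw, T2 * nW, C)
  qkv <- X %*% p$qkv$W + rep(p$qkv$b, each = T2 * nW)
  rpi <- relative_position_index(N)      # [query, key]
  M <- if (is.null(mask)) array(0, c(1, 1, 1)) else mask
  caches <- vector("list", heads)
  O <- matrix(0, T2 * nW, C)
  as_cube <- function(m) aperm(array(m, c(T2, nW, dh)), c(1, 3, 2))
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    q <- as_cube(qkv[, cols, drop = FALSE]) * scale
    k <- as_cube(qkv[, C + cols, drop = FALSE])
    v <- as_cube(qkv[, 2 * C + cols, drop = FALSE])
    B <- matrix(p$bias_table[rpi, h], T2, T2)
    res <- attn_core_fwd(q, k, v, B, M)
    O[, cols] <- matrix(aperm(res$O, c(1, 3, 2)), T2 * nW, dh)
    caches[[h]] <- list(q = q, k = k, v = v, P = res$P)
  }
  pr <- linear_fwd(O, p$proj)
  out <- window_reverse(array(pr$out, c(T2, nW, C)), H, W)
  out <- cyclic_shift(out, shift)
  list(out = out,
       cache = list(X = X, O = O, heads = caches,
                    H = H, W = W, C = C, N = N, T2 = T2, nW = nW,
                    dh = dh, scale = scale, shift = shift, rpi = rpi))
}

window_attention_bwd <- function(dy, cache, p) {
  H <- cache$H; W <- cache$W; C <- cache$C; N <- cache$N
  T2 <- cache$T2; nW <- cache$nW; dh <- cache$dh
  heads <- length(cache$heads)
  dy <- cyclic_shift(dy, -cache$shift)
  dY <- matrix(window_partition(dy, N), T2 * nW, C)
  bp <- linear_bwd(dY, cache$O, p$proj)
  dO <- bp$dx
  dqkv <- matrix(0, T2 * nW, 3 * C)
  dbias <- matrix(0, nrow(p$bias_table), heads)
  uncube <- function(a) matrix(aperm(a, c(1, 3, 2)), T2 * nW, dh)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    hc <- cache$heads[[h]]
    dOh <- aperm(array(dO[, cols, drop = FALSE], c(T2, nW, dh)), c(1, 3, 2))
    res <- attn_core_bwd(dOh, hc$P, hc$q, hc$k, hc$v)
    # bias gradient: scatter-add window-summed score grads by relative offset
    acc <- rowsum(as.vector(res$dB), as.vector(cache$rpi))
    dbias[as.integer(rownames(acc)), h] <- acc
    dqkv[, cols] <- uncube(res$dQ) * cache$scale
    dqkv[, C + cols] <- uncube(res$dK)
    dqkv[, 2 * C + cols] <- uncube(res$dV)
  }
  gqkv <- list(W = crossprod(cache$X, dqkv), b = colSums(dqkv))
  dX <- tcrossprod(dqkv, p$qkv$W)
  dx <- window_reverse(array(dX, c(T2, nW, C)), H, W)
  dx <- cyclic_shift(dx, cache$shift)
  list(dx = dx,
       grads = list(qkv = gqkv, proj = bp$grads, bias_table = dbias))
}

# ---- Swin transformer block -------------------------------------------------

init_swin_block <- function(C, heads, N, mlp_ratio = 4) {
  list(ln1 = init_layernorm(C),
       attn = init_window_attention(C, heads, N),
       ln2 = init_layernorm(C),
       mlp = init_mlp(C, mlp_ratio))
}

#' One Swin transformer block
#'
#' Pre-norm residual block: `x + (S)W-MSA(LN(x))` followed by
#' `x + MLP(LN(x))`.  `mode = "W"` uses regular window attention;
#' `mode = "SW"` shifts the window grid by `floor(N/2)` (with the wrap-around
#' mask) so successive blocks exchange information across window borders.
#' Output resolution and channel count always equal the input's.
#'
#' @param x token grid `[H, W, C]`
#' @param p block parameters from the model constructor
#' @param N window size
#' @param heads number of attention heads
#' @param mode `"W"` or `"SW"`
#' @param mask precomputed additive mask for SW mode (computed on the fly if
#'   omitted)
#' @return token grid of identical shape
#' @export
swin_block <- function(x, p, N, heads, mode = c("W", "SW"), mask = NULL) {
  mode <- match.arg(mode)
  swin_block_fwd(x, p, N, heads, mode, mask)$out
}

swin_block_fwd <- function(x, p, N, heads, mode = "W", mask = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  # windows never larger than the grid: clamp and drop the shift when the
  # whole grid fits in a single window
  Nc <- min(N, H, W)
  shift <- if (mode == "SW" && Nc < min(H, W)) Nc %/% 2L else 0L
  if (shift > 0 && is.null(mask))
    mask <- shifted_window_attention_mask(c(H, W), Nc, shift)
  if (shift == 0) mask <- NULL
  xm <- matrix(x, H * W, C)
  l1 <- layernorm_fwd(xm, p$ln1)
  at <- window_attention_fwd(array(l1$out, d), p$attn, Nc, heads, shift, mask)
  x1 <- xm + matrix(at$out, H * W, C)
  l2 <- layernorm_fwd(x1, p$ln2)
  mo <- mlp_fwd(l2$out, p$mlp)
  out <- x1 + mo$out
  list(out = array(out, d),
       cache = list(l1 = l1$cache, at = at$cache, l2 = l2$cache,
                    mlp = mo$cache, dims = d))
}

swin_block_bwd <- function(dy, cache, p) {
  d <- cache$dims
  dym <- matrix(dy, d[1] * d[2], d[3])
  mb <- mlp_bwd(dym, cache$mlp, p$mlp)
  lb2 <- layernorm_bwd(mb$dx, cache$l2, p$ln2)
  dx1 <- dym + lb2$dx
  ab <- window_attention_bwd(array(dx1, d), cache$at, p$attn)
  lb1 <- layernorm_bwd(matrix(ab$dx, d[1] * d[2], d[3]), cache$l1, p$ln1)
  dx <- dx1 + lb1$dx
  list(dx = array(dx, d),
       grads = list(ln1 = lb1$grads, attn = ab$grads,
                    ln2 = lb2$grads, mlp = mb$grads))
}
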