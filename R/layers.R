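# Elementary differentiable layers.
#
# The package ships its own small compute engine: every layer is a pair of
# functions, a forward pass that returns its output together with a cache,
# and a backward pass that turns the gradient of the loss w.r.t. the output
# into gradients w.r.t. the input and the layer parameters.  Token tensors
# are kept as plain double matrices (tokens x channels) so that all heavy
# lifting happens inside BLAS matrix products.

# ---- initialisation ---------------------------------------------------------

#' Truncated-normal weight initialisation
#'
#' Draws from N(0, sd^2) truncated at +/- 2 sd, the convention used to
#' initialise attention and projection weights in hierarchical vision
#' transformers when no pretrained weights are loaded.
#'
#' @param n number of values to draw
#' @param sd standard deviation before truncation
#' @return numeric vector of length `n`
#' @keywords internal
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

init_linear <- function(d_in, d_out, bias = TRUE, sd = 0.02) {
  p <- list(W = matrix(trunc_normal(d_in * d_out, sd), d_in, d_out))
  if (bias) p$b <- numeric(d_out)
  p
}

init_layernorm <- function(d) {
  list(g = rep(1, d), b = numeric(d))
}

# ---- linear -----------------------------------------------------------------

linear_fwd <- function(x, p) {
  y <- x %*% p$W
  if (!is.null(p$b)) y <- y + rep(p$b, each = nrow(x))
  list(out = y, cache = x)
}

linear_bwd <- function(dy, cache, p) {
  g <- list(W = crossprod(cache, dy))
  if (!is.null(p$b)) g$b <- colSums(dy)
  list(dx = tcrossprod(dy, p$W), grads = g)
}

# ---- layer normalisation ----------------------------------------------------

# Normalises each token (row) over its channel dimension; eps = 1e-5.
layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  n <- nrow(x)
  y <- xhat * rep(p$g, each = n) + rep(p$b, each = n)
  list(out = y, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(dy, cache, p) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dxhat <- dy * rep(p$g, each = n)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx,
       grads = list(g = colSums(dy * xhat), b = colSums(dy)))
}

# ---- GELU -------------------------------------------------------------------

# tanh approximation (the form used in transformer implementations):
# gelu(x) = 0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3)))
gelu_fwd <- function(x) {
  cst <- sqrt(2 / pi)
  u <- tanh(cst * (x + 0.044715 * x^3))
  list(out = 0.5 * x * (1 + u), cache = list(x = x, u = u))
}

gelu_bwd <- function(dy, cache) {
  cst <- sqrt(2 / pi)
  x <- cache$x; u <- cache$u
  dy * (0.5 * (1 + u) + 0.5 * x * (1 - u^2) * cst * (1 + 3 * 0.044715 * x^2))
}

# ---- two-layer MLP with GELU ------------------------------------------------

init_mlp <- function(d, ratio = 4) {
  hidden <- as.integer(round(d * ratio))
  list(fc1 = init_linear(d, hidden), fc2 = init_linear(hidden, d))
}

mlp_fwd <- function(x, p) {
  f1 <- linear_fwd(x, p$fc1)
  g1 <- gelu_fwd(f1$out)
  f2 <- linear_fwd(g1$out, p$fc2)
  list(out = f2$out, cache = list(f1 = f1$cache, g1 = g1$cache, f2 = f2$cache))
}

mlp_bwd <- function(dy, cache, p) {
  b2 <- linear_bwd(dy, cache$f2, p$fc2)
  dg <- gelu_bwd(b2$dx, cache$g1)
  b1 <- linear_bwd(dg, cache$f1, p$fc1)
  list(dx = b1$dx, grads = list(fc1 = b1$grads, fc2 = b2$grads))
}

# ---- recursive parameter-tree helpers --------------------------------------

# Parameters, gradients and optimiser state all share one nested-list shape;
# these walkers apply an operation leaf-wise (leaves are numeric arrays).
ptree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(ptree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

ptree_zeros_like <- function(p) ptree_map(function(x) x * 0, p)

ptree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  ptree_map(`+`, a, b)
}

ptree_count <- function(p) {
  if (is.list(p)) sum(vapply(p, ptree_count, numeric(1))) else length(p)
}
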