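# Independent reference implementations used as oracles.  These are written
# with explicit elementwise loops, deliberately sharing no code with the
# package's vectorised / compiled paths.

# scaled-dot-product attention, one head, elementwise evaluation
oracle_attention <- function(Q, K, V, B = NULL, M = NULL) {
  n <- nrow(Q); d <- ncol(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(d)) acc <- acc + Q[i, k] * K[j, k]
      s[j] <- acc / sqrt(d)
      if (!is.null(B)) s[j] <- s[j] + B[i, j]
      if (!is.null(M)) s[j] <- s[j] + M[i, j]
    }
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# maximum bipartite matching size between predicted and true points within
# `radius`, by exhaustive recursion (feasible for <= 8 points per side)
oracle_max_matching <- function(pred, gt, radius) {
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) return(0L)
  ok <- outer(seq_len(np), seq_len(ng), function(i, j)
    sqrt((pred$x[i] - gt$x[j])^2 + (pred$y[i] - gt$y[j])^2) <= radius)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1, used, count + 1L)
      used[j] <- FALSE
    }
    recurse(i + 1, used, count)
  }
  recurse(1L, logical(ng), 0L)
  best
}

# a token grid whose entries encode their own (row, col, channel) position;
# double storage with exactly-representable integral values, so identity
# round trips can be asserted bitwise
indexed_grid <- function(H, W, C) {
  array(as.numeric(seq_len(H * W * C)), c(H, W, C))
}

# tiny model configuration used across architecture tests
tiny_config <- function(input = 32, C = 8) {
  model_config(input_size = input, embed_dim = C, num_heads = c(2, 2, 2, 2),
               window_size = 4, depths = c(2, 2, 2, 2),
               decoder_depths = c(2, 2, 2), bottleneck_depth = 2)
}
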