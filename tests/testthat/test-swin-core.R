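# Window partitioning, cyclic shifts, shifted-window masking and the
# attention computation itself.

test_that("window partitioning produces the expected window counts", {
  g <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  w <- window_partition(g, 4)
  expect_equal(dim(w), c(16, 4, 3))           # 4 windows of 16 tokens

  # enumeration oracle: count distinct (window-row, window-col) cells
  H <- 56; N <- 7
  cells <- unique(expand.grid(r = (0:(H - 1)) %/% N, c = (0:(H - 1)) %/% N))
  g2 <- array(0, c(56, 56, 1))
  expect_equal(dim(window_partition(g2, 7))[2], nrow(cells))
  expect_equal(nrow(cells), 64)
})

test_that("partition/reverse and shift/unshift are exact inverses", {
  g <- indexed_grid(14, 14, 3)
  expect_identical(window_reverse(window_partition(g, 7), 14, 14), g)

  for (s in c(-3, -1, 0, 2, 5)) {
    expect_identical(cyclic_shift(cyclic_shift(g, s), -s), g)
  }
  expect_identical(cyclic_shift(g, 0), g)
})

test_that("cyclic shift follows roll semantics", {
  g <- array(0, c(4, 4, 1))
  g[1, 1, 1] <- 1                              # marked token at (0, 0)
  gs <- cyclic_shift(g, -1)
  expect_equal(which(gs[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 4, col = 4))            # lands at (3, 3)
})

test_that("non-divisible resolutions are rejected with the offending axis", {
  g <- array(0, c(10, 8, 1))
  expect_error(window_partition(g, 4), "height.*10")
  expect_error(window_partition(array(0, c(8, 10, 1)), 4), "width.*10")
})

test_that("shifted-window mask matches the region-label oracle", {
  expect_equal(shifted_window_attention_mask(c(8, 8), 4, 0),
               array(0, c(16, 16, 4)))
  expect_error(shifted_window_attention_mask(c(8, 8), 4, 4), "displacement")

  H <- 8; N <- 4; s <- 2
  mask <- shifted_window_attention_mask(c(H, H), N, s)
  # oracle: a token of the shifted grid at (rr, cc) originated at
  # ((rr + s) mod H, (cc + s) mod H); two tokens of one window may attend
  # iff neither coordinate wrapped differently between them
  wrap <- function(rr) ((rr + s) %% H) - rr    # constant within a region
  for (w in seq_len(dim(mask)[3])) {
    wr <- (w - 1) %/% (H / N); wc <- (w - 1) %% (H / N)
    for (i in 1:(N * N)) for (j in 1:(N * N)) {
      ri <- wr * N + (i - 1) %/% N; ci <- wc * N + (i - 1) %% N
      rj <- wr * N + (j - 1) %/% N; cj <- wc * N + (j - 1) %% N
      allowed <- wrap(ri) == wrap(rj) && wrap(ci) == wrap(cj)
      expect_equal(mask[i, j, w] == 0, allowed)
    }
  }
})

test_that("interior windows are unaffected by the shift mask", {
  # 12x12 grid, N = 4: window (1,1) (0-based) is interior after a shift of 2
  mask <- shifted_window_attention_mask(c(12, 12), 4, 2)
  interior <- 5  # row-major index of window (1, 1) + 1
  expect_true(all(mask[, , interior] == 0))
  set.seed(1)
  Q <- matrix(rnorm(32), 16, 2); K <- matrix(rnorm(32), 16, 2)
  V <- matrix(rnorm(32), 16, 2)
  expect_equal(msa(Q, K, V, mask = mask[, , interior]), msa(Q, K, V))
})

test_that("msa has softmax structure: uniform and single-token cases", {
  V <- matrix(rnorm(8), 4, 2)
  zero <- matrix(0, 4, 2)
  out <- msa(zero, zero, V)                    # uniform attention
  expect_equal(out, matrix(rep(colMeans(V), each = 4), 4, 2))

  v1 <- matrix(c(3, -1), 1, 2)
  expect_equal(msa(matrix(1, 1, 2), matrix(2, 1, 2), v1), v1)
})

test_that("msa and the compiled attention core match a brute-force oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(c(2, 4, 9), 1); d <- sample(2:4, 1)
    Q <- matrix(rnorm(n * d), n, d); K <- matrix(rnorm(n * d), n, d)
    V <- matrix(rnorm(n * d), n, d)
    B <- matrix(rnorm(n * n), n, n)
    ref <- oracle_attention(Q, K, V, B)
    got <- msa(Q, K, V, bias = B)
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-5)
    # same instance through the compiled batched kernel (one window)
    cc <- swincount:::attn_core_fwd(array(Q / sqrt(d), c(n, d, 1)),
                                    array(K, c(n, d, 1)),
                                    array(V, c(n, d, 1)),
                                    B, array(0, c(1, 1, 1)))
    expect_lt(max(abs(cc$O[, , 1] - ref)) / max(abs(ref)), 1e-5)
    expect_equal(rowSums(cc$P[, , 1]), rep(1, n), tolerance = 1e-6)
  }
})

test_that("attention rows are convex weights for random layer inputs", {
  set.seed(7)
  p <- swincount:::init_window_attention(8, 2, 4)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  fw <- swincount:::window_attention_fwd(x, p, 4, 2, shift = 2,
    mask = shifted_window_attention_mask(c(8, 8), 4, 2))
  for (h in 1:2) {
    Psums <- apply(fw$cache$heads[[h]]$P, c(1, 3), sum)
    expect_equal(as.vector(Psums), rep(1, length(Psums)), tolerance = 1e-6)
  }
})

test_that("swin blocks preserve resolution and channels", {
  set.seed(3)
  for (cfgi in list(c(H = 8, C = 8, heads = 2, N = 4),
                    c(H = 12, C = 6, heads = 3, N = 4),
                    c(H = 14, C = 4, heads = 2, N = 7))) {
    p <- swincount:::init_swin_block(cfgi["C"], cfgi["heads"], cfgi["N"])
    x <- array(rnorm(cfgi["H"]^2 * cfgi["C"]), c(cfgi["H"], cfgi["H"],
                                                 cfgi["C"]))
    for (mode in c("W", "SW")) {
      y <- swin_block(x, p, cfgi["N"], cfgi["heads"], mode)
      expect_equal(dim(y), dim(x))
      expect_true(all(is.finite(y)))
    }
  }
})

test_that("a block with zeroed projection outputs is the identity", {
  set.seed(4)
  p <- swincount:::init_swin_block(8, 2, 4)
  p$attn$proj$W[] <- 0; p$attn$proj$b[] <- 0
  p$mlp$fc2$W[] <- 0; p$mlp$fc2$b[] <- 0
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  expect_equal(swin_block(x, p, 4, 2, "W"), x)
})

test_that("window attention commutes with whole-window translations", {
  # rolling the input by exactly one window size permutes windows, so the
  # unshifted block output rolls identically
  set.seed(5)
  p <- swincount:::init_swin_block(6, 2, 4)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  y <- swin_block(x, p, 4, 2, "W")
  ys <- swin_block(cyclic_shift(x, 4), p, 4, 2, "W")
  expect_equal(ys, cyclic_shift(y, 4), tolerance = 1e-12)
})

test_that("relative position bias machinery has the contracted shapes", {
  for (N in c(4, 7)) {
    idx <- swincount:::relative_position_index(N)
    expect_equal(dim(idx), c(N^2, N^2))
    expect_true(all(idx >= 1 & idx <= (2 * N - 1)^2))
    # depends only on N: identical on recomputation
    expect_identical(idx, swincount:::relative_position_index(N))
    tab <- swincount:::init_relative_bias(N, 3)
    expect_equal(dim(tab), c((2 * N - 1)^2, 3))
    B <- matrix(tab[idx, 2], N^2, N^2)
    expect_equal(dim(B), c(N^2, N^2))
  }
})
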