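# Patch embedding, merging/expanding, skip fusion, the density head, and
# whole-model shape invariants.

test_that("patch partition flattens 4x4x3 blocks losslessly", {
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  tok <- patch_partition(img)
  expect_equal(dim(tok), c(56, 56, 48))        # 4 * 4 * 3 = 48

  small <- array(runif(4 * 4 * 3), c(4, 4, 3))
  one <- patch_partition(small)
  expect_equal(dim(one), c(1, 1, 48))
  expect_equal(sort(as.vector(one)), sort(as.vector(small)))

  expect_identical(patch_unpartition(tok), img)
  expect_error(patch_partition(array(0, c(30, 30, 3))), "resize")
})

test_that("space/depth rearranges use the fixed 2x2 block order", {
  g <- array(1:4, c(2, 2, 1))                  # g[r, c] column-major
  flat <- swincount:::space_to_depth(g, 2)
  # blocks ordered top-left, top-right, bottom-left, bottom-right
  expect_equal(as.vector(flat), c(g[1, 1, 1], g[1, 2, 1], g[2, 1, 1],
                                  g[2, 2, 1]))
  big <- indexed_grid(8, 6, 5)
  expect_identical(swincount:::depth_to_space(swincount:::space_to_depth(big, 2), 2), big)
  # pure permutation of values
  expect_identical(sort(as.vector(swincount:::space_to_depth(big, 2))),
                   sort(as.vector(big)))
})

test_that("linear embedding changes only the channel dimension", {
  tok <- array(rnorm(8 * 8 * 48), c(8, 8, 48))
  m <- matrix(tok, 64, 48)
  ident <- list(W = diag(48))
  expect_equal(swincount:::linear_fwd(m, ident)$out, m)
  proj <- swincount:::init_linear(48, 96)
  out <- swincount:::linear_fwd(m, proj)$out
  expect_equal(dim(out), c(64, 96))
  zero <- list(W = matrix(0, 48, 96), b = numeric(96))
  expect_true(all(swincount:::linear_fwd(m, zero)$out == 0))
})

test_that("patch merging halves resolution and doubles channels", {
  set.seed(1)
  g <- array(rnorm(56 * 56 * 4), c(56, 56, 4))
  out <- patch_merging(g)
  expect_equal(dim(out), c(28, 28, 8))
  expect_equal(prod(dim(out)[1:2]), 3136 / 4)  # token count divided by 4
  expect_error(patch_merging(array(0, c(7, 7, 4))), "even")
})

test_that("patch expanding doubles resolution and halves channels", {
  set.seed(2)
  g <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  out <- patch_expanding(g)
  expect_equal(dim(out), c(16, 16, 4))
  # merging then expanding restores the (resolution, channels) signature
  merged <- patch_merging(g)
  expect_equal(dim(patch_expanding(merged)), dim(g))
})

test_that("skip fusion keeps the decoder feature size", {
  set.seed(3)
  dec <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  enc <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  out <- skip_fuse(dec, enc)
  expect_equal(dim(out), dim(dec))
  expect_error(skip_fuse(dec, array(0, c(4, 4, 6))), "mismatch")
  # zero encoder branch + identity-block reduction returns the decoder
  p <- list(red = list(W = rbind(diag(6), matrix(0, 6, 6)), b = numeric(6)))
  expect_equal(skip_fuse(dec, enc * 0, p), dec)
})

test_that("density head restores full resolution, nonnegative and finite", {
  set.seed(4)
  g <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  d <- density_head(g)
  expect_equal(dim(d), c(32, 32))
  expect_true(all(d >= 0))
  for (seed in 1:20) {
    set.seed(seed)
    gg <- array(rnorm(8 * 8 * 8, sd = 3), c(8, 8, 8))
    expect_true(all(is.finite(density_head(gg))))
  }
})

test_that("model config validates divisibility up front", {
  expect_error(model_config(input_size = 100), "divisible by 32")
  expect_error(model_config(depths = c(2, 2)), "4 encoder entries")
  expect_error(model_config(embed_dim = 10, num_heads = c(3, 3, 3, 3)),
               "not divisible by its head count")
})

test_that("the assembled model maps an image to a full-resolution map", {
  m <- swintunet(tiny_config(32), seed = 5)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  d1 <- swintunet_forward(img, m)
  expect_equal(dim(d1), c(32, 32))
  expect_true(all(d1 >= 0))
  expect_identical(d1, swintunet_forward(img, m))  # bit-for-bit

  expect_error(swintunet_forward(array(0, c(64, 64, 3)), m), "resize")
})

test_that("encoder/decoder stage signature follows C, 2C, 4C, 8C", {
  cfg <- tiny_config(64, C = 8)
  m <- swintunet(cfg, seed = 6)
  p <- m$params
  # qkv weight of stage s acts on C * 2^(s-1) channels
  for (s in 1:4)
    expect_equal(nrow(p$enc[[s]]$blocks[[1]]$attn$qkv$W), 8 * 2^(s - 1))
  expect_equal(nrow(p$bottleneck$blocks[[1]]$attn$qkv$W), 64)  # 8C at H/32
  # decoder mirrors the encoder: 4C, 2C, C
  for (ds in 1:3)
    expect_equal(nrow(p$dec[[ds]]$blocks[[1]]$attn$qkv$W), 8 * 2^(3 - ds))
  # exactly three skip fusions
  expect_equal(length(p$dec), 3)
  for (ds in 1:3)
    expect_equal(dim(p$dec[[ds]]$fuse$red$W),
                 c(2 * 8 * 2^(3 - ds), 8 * 2^(3 - ds)))
})

test_that("parameter count is a pure function of the configuration", {
  m1 <- swintunet(tiny_config(32), seed = 1)
  m2 <- swintunet(tiny_config(32), seed = 99)
  expect_equal(n_parameters(m1), n_parameters(m2))
  expect_equal(n_parameters(m1), 295177)       # frozen regression value
  expect_equal(n_parameters(swintunet(model_config(), seed = 1)), 41350069)
})

test_that("checkpoints round-trip parameters, config and history", {
  m <- swintunet(tiny_config(32), seed = 7)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  path <- withr::local_tempfile(fileext = ".rds")
  hist <- data.frame(epoch = 1, loss = 0.5)
  save_checkpoint(m, path, history = hist)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_checkpoint(path)
  expect_identical(swintunet_forward(img, m), swintunet_forward(img, m2))
  expect_equal(attr(m2, "history"), hist)
  manifest <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(manifest$n_parameters, n_parameters(m))
})
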