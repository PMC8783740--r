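# Full encoder-decoder assembly: patch embedding, four encoder stages with
# patch merging, a bottleneck, a mirrored decoder with patch expanding and
# skip connections, and a density-map head that restores full resolution.

#' Model configuration
#'
#' Collects every architecture hyperparameter.  The input is split into
#' `patch_size x patch_size` patches (so a 3-channel image yields
#' `patch_size^2 * 3`-dimensional raw tokens, 48 by default), embedded to
#' `embed_dim` channels, and processed at resolutions H/4, H/8, H/16, H/32
#' with channel counts C, 2C, 4C, 8C.  Defaults follow the tiny variant of
#' the hierarchical shifted-window transformer family: C = 96, two blocks
#' per stage, heads (3, 6, 12, 24), window 7.
#'
#' @param input_size integer length-2 `(H, W)` in pixels; both divisible by 32
#' @param patch_size side of the square patch partition (4)
#' @param embed_dim embedding channels C
#' @param depths encoder blocks per stage (4 entries)
#' @param decoder_depths decoder blocks per stage (3 entries, H/16, H/8, H/4)
#' @param bottleneck_depth blocks between encoder and decoder at H/32
#' @param num_heads attention heads per stage (4 entries); stage channels
#'   must be divisible by the stage's head count
#' @param window_size attention window side N, in tokens
#' @param mlp_ratio hidden expansion of the block MLPs
#' @param density_scale the head emits `softplus(z) / density_scale`; with
#'   the default 100, typical per-pixel densities (around 0.04 at a kernel
#'   peak) correspond to pre-rectifier activations of order 1, keeping the
#'   rectifier out of its vanishing-gradient tail.  The output is a true
#'   density map regardless of the value
#' @return object of class `swin_model_config`
#' @export
model_config <- function(input_size = c(224, 224), patch_size = 4,
                         embed_dim = 96, depths = c(2, 2, 2, 2),
                         decoder_depths = c(2, 2, 2), bottleneck_depth = 2,
                         num_heads = c(3, 6, 12, 24), window_size = 7,
                         mlp_ratio = 4, density_scale = 100) {
  if (length(input_size) == 1) input_size <- c(input_size, input_size)
  if (any(input_size %% 32 != 0))
    stop("input_size must be divisible by 32 (four halvings after the ",
         patch_size, "x", patch_size, " patch partition); got ",
         paste(input_size, collapse = "x"))
  if (length(depths) != 4) stop("depths must have 4 encoder entries")
  if (length(decoder_depths) != 3) stop("decoder_depths must have 3 entries")
  if (length(num_heads) != 4) stop("num_heads must have 4 entries")
  for (s in 1:4) {
    Cs <- embed_dim * 2^(s - 1)
    if (Cs %% num_heads[s] != 0)
      stop("stage ", s, " channels (", Cs, ") not divisible by its head ",
           "count (", num_heads[s], ")")
  }
  structure(list(input_size = as.integer(input_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 depths = as.integer(depths),
                 decoder_depths = as.integer(decoder_depths),
                 bottleneck_depth = as.integer(bottleneck_depth),
                 num_heads = as.integer(num_heads),
                 window_size = as.integer(window_size),
                 mlp_ratio = mlp_ratio,
                 density_scale = density_scale),
            class = "swin_model_config")
}

#' @export
print.swin_model_config <- function(x, ...) {
  cat("Model configuration\n")
  cat("  input  ", paste(x$input_size, collapse = " x "), " px, patch ",
      x$patch_size, ", window ", x$window_size, "\n", sep = "")
  cat("  embed C =", x$embed_dim, " heads", paste(x$num_heads, collapse = "/"),
      "\n")
  cat("  depths ", paste(x$depths, collapse = "-"), " | bottleneck ",
      x$bottleneck_depth, " | decoder ",
      paste(x$decoder_depths, collapse = "-"), "\n", sep = "")
  invisible(x)
}

# ---- space-to-depth rearranges ---------------------------------------------

# out[r, c, (p1*P + p2)*C + ch] = x[P*r + p1, P*c + p2, ch]  (0-based);
# channel blocks ordered top-left, top-right, bottom-left, bottom-right.
space_to_depth <- function(x, P) {
  d <- dim(x)
  if (any(d[1:2] %% P != 0))
    stop("resolution ", d[1], "x", d[2], " not divisible by ", P)
  out <- array(0, c(d[1] %/% P, d[2] %/% P, d[3] * P * P))
  for (p1 in 0:(P - 1)) for (p2 in 0:(P - 1)) {
    blk <- p1 * P + p2
    out[, , (blk * d[3] + 1):((blk + 1) * d[3])] <-
      x[seq(p1 + 1, d[1], P), seq(p2 + 1, d[2], P), , drop = FALSE]
  }
  out
}

depth_to_space <- function(x, P) {
  d <- dim(x)
  if (d[3] %% (P * P) != 0)
    stop("channel count ", d[3], " not divisible by ", P * P)
  C <- d[3] %/% (P * P)
  out <- array(0, c(d[1] * P, d[2] * P, C))
  for (p1 in 0:(P - 1)) for (p2 in 0:(P - 1)) {
    blk <- p1 * P + p2
    out[seq(p1 + 1, d[1] * P, P), seq(p2 + 1, d[2] * P, P), ] <-
      x[, , (blk * C + 1):((blk + 1) * C), drop = FALSE]
  }
  out
}

#' Partition an image into non-overlapping patch tokens
#'
#' Splits an `H x W x 3` image into `patch_size`-square patches and flattens
#' each into one token, giving an `H/P x W/P` grid of `P*P*3`-dimensional
#' tokens (48 for the default P = 4).  The operation is lossless:
#' [patch_unpartition()] restores the image bit-exactly.
#'
#' @param image numeric array `[H, W, 3]`
#' @param patch_size patch side P
#' @return token grid `[H/P, W/P, P*P*3]`
#' @export
patch_partition <- function(image, patch_size = 4) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("expected a 3-channel image array [H, W, 3]")
  if (any(d[1:2] %% patch_size != 0))
    stop("image size ", d[1], "x", d[2], " not divisible by patch size ",
         patch_size, "; resize the image first")
  space_to_depth(image, patch_size)
}

#' Inverse of [patch_partition()]
#' @param tokens token grid from [patch_partition()]
#' @param patch_size patch side used to build the tokens
#' @return image array `[H, W, 3]`
#' @export
patch_unpartition <- function(tokens, patch_size = 4) {
  depth_to_space(tokens, patch_size)
}

# ---- functional layer wrappers (exported module surface) --------------------

init_patch_merging <- function(K) {
  list(ln = init_layernorm(4 * K),
       red = list(W = matrix(trunc_normal(4 * K * 2 * K), 4 * K, 2 * K)))
}

patch_merging_fwd <- function(x, p) {
  d <- dim(x)
  if (any(d[1:2] %% 2 != 0))
    stop("patch merging needs an even resolution; got ", d[1], "x", d[2])
  y <- space_to_depth(x, 2)
  m <- matrix(y, length(y) / (4 * d[3]), 4 * d[3])
  ln <- layernorm_fwd(m, p$ln)
  red <- linear_fwd(ln$out, p$red)
  list(out = array(red$out, c(d[1] %/% 2, d[2] %/% 2, 2 * d[3])),
       cache = list(ln = ln$cache, red = red$cache, dims = d))
}

patch_merging_bwd <- function(dy, cache, p) {
  d <- cache$dims
  dm <- matrix(dy, prod(d[1:2]) / 4, 2 * d[3])
  rb <- linear_bwd(dm, cache$red, p$red)
  lb <- layernorm_bwd(rb$dx, cache$ln, p$ln)
  dx <- depth_to_space(array(lb$dx, c(d[1] %/% 2, d[2] %/% 2, 4 * d[3])), 2)
  list(dx = dx, grads = list(ln = lb$grads, red = rb$grads))
}

#' Merge 2x2 token groups (downsample by two, double the channels)
#'
#' Concatenates the features of each 2x2 group of adjacent tokens (in fixed
#' order top-left, top-right, bottom-left, bottom-right) into 4K channels,
#' normalises, and projects linearly to 2K.  Token count drops by 4.
#'
#' @param grid token grid `[R, R, K]`, R even
#' @param params parameters from the model constructor; a fresh random set
#'   is drawn if omitted
#' @return token grid `[R/2, R/2, 2K]`
#' @export
patch_merging <- function(grid, params = NULL) {
  if (is.null(params)) params <- init_patch_merging(dim(grid)[3])
  patch_merging_fwd(grid, params)$out
}

init_patch_expanding <- function(K, P = 2) {
  if ((2 * K) %% (P * P) != 0)
    stop("cannot expand ", K, " channels with factor ", P,
         ": doubled channel count not divisible by ", P * P)
  list(up = list(W = matrix(trunc_normal(K * 2 * K), K, 2 * K)),
       ln = init_layernorm(2 * K %/% (P * P)))
}

patch_expanding_fwd <- function(x, p, P = 2) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:2]), d[3])
  up <- linear_fwd(m, p$up)
  z <- depth_to_space(array(up$out, c(d[1], d[2], 2 * d[3])), P)
  dz <- dim(z)
  ln <- layernorm_fwd(matrix(z, prod(dz[1:2]), dz[3]), p$ln)
  list(out = array(ln$out, dz),
       cache = list(up = up$cache, ln = ln$cache, dims = d, dz = dz, P = P))
}

patch_expanding_bwd <- function(dy, cache, p) {
  d <- cache$dims; dz <- cache$dz
  lb <- layernorm_bwd(matrix(dy, prod(dz[1:2]), dz[3]), cache$ln, p$ln)
  dzarr <- space_to_depth(array(lb$dx, dz), cache$P)
  ub <- linear_bwd(matrix(dzarr, prod(d[1:2]), 2 * d[3]), cache$up, p$up)
  list(dx = array(ub$dx, d), grads = list(up = ub$grads, ln = lb$grads))
}

#' Expand tokens (upsample by two, halve the channels)
#'
#' Linearly doubles the channel dimension (K to 2K), then rearranges a 2x2
#' spatial factor out of the channels, doubling the resolution and leaving
#' K/2 channels.
#'
#' @param grid token grid `[R, R, K]`
#' @param params parameters from the model constructor (fresh random set if
#'   omitted)
#' @return token grid `[2R, 2R, K/2]`
#' @export
patch_expanding <- function(grid, params = NULL) {
  if (is.null(params)) params <- init_patch_expanding(dim(grid)[3])
  patch_expanding_fwd(grid, params)$out
}

init_skip_fuse <- function(K) {
  list(red = init_linear(2 * K, K))
}

skip_fuse_fwd <- function(dec, enc, p) {
  dd <- dim(dec)
  if (!all(dd == dim(enc)))
    stop("skip fusion resolution/channel mismatch: decoder ",
         paste(dd, collapse = "x"), " vs encoder ",
         paste(dim(enc), collapse = "x"))
  n <- prod(dd[1:2])
  cat2 <- cbind(matrix(dec, n, dd[3]), matrix(enc, n, dd[3]))
  red <- linear_fwd(cat2, p$red)
  list(out = array(red$out, dd), cache = list(red = red$cache, dims = dd))
}

skip_fuse_bwd <- function(dy, cache, p) {
  dd <- cache$dims
  n <- prod(dd[1:2])
  rb <- linear_bwd(matrix(dy, n, dd[3]), cache$red, p$red)
  list(ddec = array(rb$dx[, 1:dd[3]], dd),
       denc = array(rb$dx[, (dd[3] + 1):(2 * dd[3])], dd),
       grads = list(red = rb$grads))
}

#' Fuse decoder features with an encoder skip connection
#'
#' Channel-concatenates the upsampled decoder features with same-resolution
#' encoder features (2K channels) and projects back to the decoder's K
#' channels, so the fused output keeps the upsampled features' size.
#'
#' @param decoder_grid,encoder_grid token grids of identical shape
#' @param params parameters from the model constructor (fresh random set if
#'   omitted)
#' @return token grid shaped like `decoder_grid`
#' @export
skip_fuse <- function(decoder_grid, encoder_grid, params = NULL) {
  if (is.null(params)) params <- init_skip_fuse(dim(decoder_grid)[3])
  skip_fuse_fwd(decoder_grid, encoder_grid, params)$out
}

init_density_head <- function(C, P = 4) {
  list(finalup = list(W = matrix(trunc_normal(C * P * P * C), C, P * P * C)),
       ln = init_layernorm(C),
       proj = init_linear(C, 1))
}

density_head_fwd <- function(x, p, P = 4, density_scale = 100) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:2]), d[3])
  up <- linear_fwd(m, p$finalup)
  z <- depth_to_space(array(up$out, c(d[1], d[2], P * P * d[3])), P)
  dz <- dim(z)
  ln <- layernorm_fwd(matrix(z, prod(dz[1:2]), dz[3]), p$ln)
  pr <- linear_fwd(ln$out, p$proj)
  # smooth rectifier: softplus keeps the map nonnegative without the dead
  # zone a hard cutoff would create under sparse targets; dividing by the
  # density scale maps order-1 activations to realistic per-pixel densities
  zz <- pr$out
  out <- matrix((pmax(zz, 0) + log1p(exp(-abs(zz)))) / density_scale,
                dz[1], dz[2])
  sig <- 1 / (1 + exp(-zz))
  list(out = out,
       cache = list(up = up$cache, ln = ln$cache, pr = pr$cache, sig = sig,
                    dims = d, dz = dz, P = P, scale = density_scale))
}

density_head_bwd <- function(dy, cache, p) {
  d <- cache$dims; dz <- cache$dz
  dpr <- matrix(as.vector(dy) * as.vector(cache$sig) / cache$scale,
                prod(dz[1:2]), 1)
  pb <- linear_bwd(dpr, cache$pr, p$proj)
  lb <- layernorm_bwd(pb$dx, cache$ln, p$ln)
  dzarr <- space_to_depth(array(lb$dx, dz), cache$P)
  ub <- linear_bwd(matrix(dzarr, prod(d[1:2]), cache$P^2 * d[3]),
                   cache$up, p$finalup)
  list(dx = array(ub$dx, d),
       grads = list(finalup = ub$grads, ln = lb$grads, proj = pb$grads))
}

#' Density-map head
#'
#' Expands the final H/4-resolution decoder features back to the full input
#' resolution (a 4x patch expansion), then linearly projects each pixel's
#' features to a single channel and applies a smooth rectifier (softplus),
#' producing the nonnegative density map whose integral estimates the tree
#' count.
#'
#' @param grid final decoder token grid `[H/4, W/4, C]`
#' @param params parameters from the model constructor (fresh random set if
#'   omitted)
#' @param density_scale see [model_config()]
#' @return density map matrix `[H, W]`, all entries `>= 0`
#' @export
density_head <- function(grid, params = NULL, density_scale = 100) {
  if (is.null(params)) params <- init_density_head(dim(grid)[3])
  density_head_fwd(grid, params, 4, density_scale)$out
}

# ---- model constructor ------------------------------------------------------

stage_channels <- function(cfg, s) cfg$embed_dim * 2L^(s - 1L)

#' Construct a density-counting shifted-window transformer U-Net
#'
#' Initialises all parameters (truncated-normal weights, unit LayerNorm
#' gains) for the configured architecture.  The returned model is a plain
#' list of parameter arrays plus its configuration and can be trained with
#' [train_swintunet()] or applied with [swintunet_forward()].
#'
#' @param config a [model_config()]
#' @param seed optional integer seed for reproducible initialisation
#' @return object of class `swintunet`
#' @export
swintunet <- function(config = model_config(), seed = NULL) {
  if (!inherits(config, "swin_model_config")) stop("config must come from model_config()")
  if (!is.null(seed)) set.seed(seed)
  C <- config$embed_dim
  N <- config$window_size
  raw <- config$patch_size^2 * 3L
  p <- list(embed = init_linear(raw, C))
  p$enc <- lapply(1:4, function(s) {
    K <- stage_channels(config, s)
    st <- list(blocks = lapply(seq_len(config$depths[s]), function(b)
      init_swin_block(K, config$num_heads[s], N, config$mlp_ratio)))
    if (s < 4) st$merge <- init_patch_merging(K)
    st
  })
  p$bottleneck <- list(blocks = lapply(seq_len(config$bottleneck_depth),
    function(b) init_swin_block(stage_channels(config, 4),
                                config$num_heads[4], N, config$mlp_ratio)))
  p$dec <- lapply(1:3, function(ds) {
    s <- 4 - ds                       # encoder stage this level mirrors
    K <- stage_channels(config, s)
    list(expand = init_patch_expanding(2 * K),
         fuse = init_skip_fuse(K),
         blocks = lapply(seq_len(config$decoder_depths[ds]), function(b)
           init_swin_block(K, config$num_heads[s], N, config$mlp_ratio)))
  })
  p$head <- init_density_head(C, config$patch_size)
  structure(list(config = config, params = p), class = "swintunet")
}

#' @export
print.swintunet <- function(x, ...) {
  cat("Shifted-window transformer U-Net for density counting\n")
  print(x$config)
  cat("  parameters:", format(n_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param model a [swintunet()] model
#' @return integer parameter count
#' @export
n_parameters <- function(model) ptree_count(model$params)

# cached SW-attention mask per (resolution, window, shift)
mask_cached <- function(H, W, N, shift) {
  if (shift == 0) return(NULL)
  key <- paste("mask", H, W, N, shift, sep = "_")
  m <- .swin_cache[[key]]
  if (is.null(m)) {
    m <- shifted_window_attention_mask(c(H, W), N, shift)
    .swin_cache[[key]] <- m
  }
  m
}

# run a sequence of blocks, alternating W / SW attention
run_blocks_fwd <- function(x, blocks, heads, N) {
  caches <- vector("list", length(blocks))
  d <- dim(x)
  Nc <- min(N, d[1], d[2])
  for (b in seq_along(blocks)) {
    mode <- if (b %% 2 == 1) "W" else "SW"
    shift <- if (mode == "SW" && Nc < min(d[1], d[2])) Nc %/% 2L else 0L
    mask <- mask_cached(d[1], d[2], Nc, shift)
    fw <- swin_block_fwd(x, blocks[[b]], N, heads, mode, mask)
    x <- fw$out
    caches[[b]] <- fw$cache
  }
  list(out = x, caches = caches)
}

run_blocks_bwd <- function(dy, caches, blocks) {
  grads <- vector("list", length(blocks))
  for (b in rev(seq_along(blocks))) {
    bk <- swin_block_bwd(dy, caches[[b]], blocks[[b]])
    dy <- bk$dx
    grads[[b]] <- bk$grads
  }
  list(dx = dy, grads = grads)
}

# full forward pass; keep = TRUE retains every cache for backprop
swintunet_fwd <- function(model, image, keep = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- dim(image)
  if (is.matrix(image)) stop("expected a 3-channel image array [H, W, 3]")
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2])
    stop("image is ", d[1], "x", d[2], " but the model expects ",
         cfg$input_size[1], "x", cfg$input_size[2],
         "; resize with resize_image()")
  cc <- list()
  tok <- patch_partition(image, cfg$patch_size)
  td <- dim(tok)
  emb <- linear_fwd(matrix(tok, prod(td[1:2]), td[3]), p$embed)
  x <- array(emb$out, c(td[1], td[2], cfg$embed_dim))
  if (keep) cc$embed <- emb$cache
  if (keep) cc$tokdim <- td
  enc_feats <- list(); enc_caches <- list(); merge_caches <- list()
  for (s in 1:4) {
    rb <- run_blocks_fwd(x, p$enc[[s]]$blocks, cfg$num_heads[s],
                         cfg$window_size)
    x <- rb$out
    if (keep) enc_caches[[s]] <- rb$caches
    if (s < 4) {
      enc_feats[[s]] <- x
      mg <- patch_merging_fwd(x, p$enc[[s]]$merge)
      x <- mg$out
      if (keep) merge_caches[[s]] <- mg$cache
    }
  }
  bb <- run_blocks_fwd(x, p$bottleneck$blocks, cfg$num_heads[4],
                       cfg$window_size)
  x <- bb$out
  if (keep) cc$bottleneck <- bb$caches
  dec_caches <- list()
  for (ds in 1:3) {
    s <- 4 - ds
    ex <- patch_expanding_fwd(x, p$dec[[ds]]$expand)
    fu <- skip_fuse_fwd(ex$out, enc_feats[[s]], p$dec[[ds]]$fuse)
    rb <- run_blocks_fwd(fu$out, p$dec[[ds]]$blocks, cfg$num_heads[s],
                         cfg$window_size)
    x <- rb$out
    if (keep) dec_caches[[ds]] <- list(ex = ex$cache, fu = fu$cache,
                                       blocks = rb$caches)
  }
  hd <- density_head_fwd(x, p$head, cfg$patch_size, cfg$density_scale)
  if (keep) {
    cc$enc <- enc_caches; cc$merge <- merge_caches; cc$dec <- dec_caches
    cc$head <- hd$cache
  }
  list(out = hd$out, cache = if (keep) cc else NULL)
}

swintunet_bwd <- function(dpred, cache, model) {
  cfg <- model$config
  p <- model$params
  g <- list()
  hb <- density_head_bwd(dpred, cache$head, p$head)
  g$head <- hb$grads
  dy <- hb$dx
  g$dec <- vector("list", 3)
  denc <- vector("list", 3)  # gradients flowing into encoder skips
  for (ds in 3:1) {
    s <- 4 - ds
    dcc <- cache$dec[[ds]]
    rb <- run_blocks_bwd(dy, dcc$blocks, p$dec[[ds]]$blocks)
    fb <- skip_fuse_bwd(rb$dx, dcc$fu, p$dec[[ds]]$fuse)
    eb <- patch_expanding_bwd(fb$ddec, dcc$ex, p$dec[[ds]]$expand)
    denc[[s]] <- fb$denc
    g$dec[[ds]] <- list(expand = eb$grads, fuse = fb$grads, blocks = rb$grads)
    dy <- eb$dx
  }
  bb <- run_blocks_bwd(dy, cache$bottleneck, p$bottleneck$blocks)
  g$bottleneck <- list(blocks = bb$grads)
  dy <- bb$dx
  g$enc <- vector("list", 4)
  for (s in 4:1) {
    if (s < 4) {
      mb <- patch_merging_bwd(dy, cache$merge[[s]], p$enc[[s]]$merge)
      dy <- mb$dx + denc[[s]]
    }
    rb <- run_blocks_bwd(dy, cache$enc[[s]], p$enc[[s]]$blocks)
    dy <- rb$dx
    g$enc[[s]] <- if (s < 4) list(blocks = rb$grads, merge = mb$grads)
                  else list(blocks = rb$grads)
  }
  td <- cache$tokdim
  ebk <- linear_bwd(matrix(dy, prod(td[1:2]), cfg$embed_dim), cache$embed,
                    p$embed)
  g$embed <- ebk$grads
  # reorder to match the parameter tree layout
  list(grads = g[c("embed", "enc", "bottleneck", "dec", "head")])
}

#' Run the model on one image
#'
#' Deterministic forward pass producing the predicted density map at the
#' input resolution.  The image must already match the configured input
#' size; use [resize_image()] otherwise.
#'
#' @param image array `[H, W, 3]` with values in `[0, 1]`
#' @param model a [swintunet()] model
#' @return nonnegative density map matrix `[H, W]`
#' @export
swintunet_forward <- function(image, model) {
  swintunet_fwd(model, image, keep = FALSE)$out
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is written with R's native serialisation and contains the
#' parameters, the configuration and (optionally) the training history; a
#' human-readable JSON manifest with the configuration and parameter count
#' is written alongside as `<path>.json`.
#'
#' @param model a [swintunet()] model
#' @param path file path for the checkpoint (e.g. `model.rds`)
#' @param history optional training history to embed
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  obj <- list(format = "swincount-checkpoint", version = 1L,
              config = unclass(model$config), params = model$params,
              history = history)
  saveRDS(obj, path)
  manifest <- list(format = obj$format, version = obj$version,
                   config = unclass(model$config),
                   n_parameters = n_parameters(model))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "swincount-checkpoint"))
    stop("not a model checkpoint: ", path)
  cfg <- do.call(model_config, obj$config)
  m <- structure(list(config = cfg, params = obj$params), class = "swintunet")
  attr(m, "history") <- obj$history
  m
}
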