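# Parametric orchard-image simulator.  Emulates very-high-resolution RGB
# tiles of olive plantations: many small, bright-tipped, roughly circular
# crowns on soil-toned ground, each trailing an offset shadow, in regular,
# jittered or clustered (closely planted) layouts, plus non-tree bright
# distractor objects.  Every image carries exact ground-truth center points
# and tight crown bounding boxes.  Output is fully determined by the seed.

#' Specification of a synthetic orchard image
#'
#' @param image_size side length in pixels (square tile; default 512, the
#'   native size the model pipeline later resizes from)
#' @param layout `"grid"` (regular planting), `"jittered"` (grid with
#'   random displacement), or `"clustered"` (tight clumps of closely
#'   planted trees around jittered-grid anchor trees)
#' @param tree_count number of trees, or a `(min, max)` range sampled per
#'   image; `NULL` fills the whole planting lattice
#' @param spacing planting distance between lattice positions, px
#' @param jitter maximum random displacement as a fraction of `spacing`
#' @param crown_radius `(min, max)` crown radius range, px
#' @param shadow_offset `(dx, dy)` shadow displacement, px
#' @param shadow_opacity shadow darkening strength in `[0, 1]`
#' @param soil mean background RGB (soil tone)
#' @param noise_sd pixel noise standard deviation
#' @param distractor_count number of bright non-tree objects (absent from
#'   the ground truth)
#' @param rotation planting-lattice rotation, degrees
#' @param cluster_size trees per clump for the clustered layout
#' @param seed integer; fully determines the rendered image
#' @return list of class `orchard_spec`
#' @export
orchard_spec <- function(image_size = 512, layout = c("jittered", "grid",
                                                      "clustered"),
                         tree_count = NULL, spacing = 32, jitter = 0.2,
                         crown_radius = c(5, 9), shadow_offset = c(3, 3),
                         shadow_opacity = 0.45,
                         soil = c(0.62, 0.54, 0.42), noise_sd = 0.02,
                         distractor_count = 2, rotation = 0,
                         cluster_size = 3, seed = 1) {
  layout <- match.arg(layout)
  if (length(crown_radius) == 1) crown_radius <- rep(crown_radius, 2)
  if (diff(crown_radius) < 0 || crown_radius[1] <= 0)
    stop("crown_radius must be a nonempty positive range")
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(image_size = as.integer(image_size), layout = layout,
                 tree_count = tree_count, spacing = spacing, jitter = jitter,
                 crown_radius = crown_radius, shadow_offset = shadow_offset,
                 shadow_opacity = shadow_opacity, soil = soil,
                 noise_sd = noise_sd,
                 distractor_count = as.integer(distractor_count),
                 rotation = rotation, cluster_size = as.integer(cluster_size),
                 seed = as.integer(seed)),
            class = "orchard_spec")
}

# evaluate `expr` under the spec's private RNG stream, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# planting positions (x, y), 0-based, possibly rotated about the tile center
orchard_positions <- function(spec) {
  sz <- spec$image_size
  margin <- spec$crown_radius[2] + 2
  lo <- margin; hi <- sz - 1 - margin
  anchors <- expand.grid(x = seq(lo, hi, by = spec$spacing),
                         y = seq(lo, hi, by = spec$spacing))
  if (spec$rotation != 0) {
    th <- spec$rotation * pi / 180
    cx <- (sz - 1) / 2
    x0 <- anchors$x - cx; y0 <- anchors$y - cx
    anchors$x <- cx + cos(th) * x0 - sin(th) * y0
    anchors$y <- cx + sin(th) * x0 + cos(th) * y0
    inside <- anchors$x >= lo & anchors$x <= hi &
              anchors$y >= lo & anchors$y <= hi
    anchors <- anchors[inside, , drop = FALSE]
  }
  n_req <- spec$tree_count
  if (!is.null(n_req) && length(n_req) == 2)
    n_req <- sample(n_req[1]:n_req[2], 1)
  jit <- spec$jitter * spec$spacing
  if (spec$layout == "clustered") {
    n_anchor <- max(1, ceiling((if (is.null(n_req)) nrow(anchors) else n_req) /
                                 spec$cluster_size))
    if (n_anchor > nrow(anchors))
      stop("infeasible packing: ", n_anchor, " clumps requested but only ",
           nrow(anchors), " lattice positions fit at spacing ", spec$spacing)
    anchors <- anchors[sample.int(nrow(anchors), n_anchor), , drop = FALSE]
    rr <- spec$crown_radius
    pts <- do.call(rbind, lapply(seq_len(nrow(anchors)), function(i) {
      k <- spec$cluster_size
      ang <- stats::runif(k, 0, 2 * pi)
      rad <- stats::runif(k, 0.8, 1.6) * mean(rr)  # crowns touch/overlap
      data.frame(x = anchors$x[i] + c(0, cos(ang[-1]) * rad[-1]),
                 y = anchors$y[i] + c(0, sin(ang[-1]) * rad[-1]))
    }))
    lo2 <- spec$crown_radius[1] + 1
    pts$x <- pmin(pmax(pts$x, lo2), spec$image_size - 1 - lo2)
    pts$y <- pmin(pmax(pts$y, lo2), spec$image_size - 1 - lo2)
    if (!is.null(n_req)) pts <- pts[seq_len(min(n_req, nrow(pts))), ,
                                    drop = FALSE]
    return(pts)
  }
  if (!is.null(n_req)) {
    if (n_req > nrow(anchors))
      stop("infeasible packing: ", n_req, " trees requested but only ",
           nrow(anchors), " lattice positions fit at spacing ", spec$spacing)
    anchors <- anchors[sample.int(nrow(anchors), n_req), , drop = FALSE]
  }
  if (spec$layout == "jittered" && jit > 0) {
    anchors$x <- anchors$x + stats::runif(nrow(anchors), -jit, jit)
    anchors$y <- anchors$y + stats::runif(nrow(anchors), -jit, jit)
  }
  anchors
}

# draw one radially shaded disc; `col` at the bright tip fading to
# `col * edge_dim` at the rim, alpha-blended onto img
draw_disc <- function(img, cx, cy, r, col, edge_dim = 0.55, tip = 0.35,
                      alpha = 1) {
  sz <- dim(img)[1]
  rows <- max(0, floor(cy - r)):min(sz - 1, ceiling(cy + r))
  cols <- max(0, floor(cx - r)):min(sz - 1, ceiling(cx + r))
  # bright tip offset toward the upper-left (sun side)
  dy <- outer(rows - (cy - tip * r), rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - (cx - tip * r))
  d0 <- sqrt(outer((rows - cy)^2, rep(1, length(cols))) +
             outer(rep(1, length(rows)), (cols - cx)^2))
  inside <- d0 <= r
  shade <- 1 - (1 - edge_dim) * pmin(1, sqrt(dx^2 + dy^2) / r)
  a <- inside * alpha
  for (ch in 1:3) {
    blk <- img[rows + 1, cols + 1, ch]
    img[rows + 1, cols + 1, ch] <- blk * (1 - a) + col[ch] * shade * a
  }
  img
}

darken_ellipse <- function(img, cx, cy, rx, ry, strength) {
  sz <- dim(img)[1]
  rows <- max(0, floor(cy - ry)):min(sz - 1, ceiling(cy + ry))
  cols <- max(0, floor(cx - rx)):min(sz - 1, ceiling(cx + rx))
  d <- outer(((rows - cy) / ry)^2, rep(1, length(cols))) +
       outer(rep(1, length(rows)), ((cols - cx) / rx)^2)
  a <- (d <= 1) * strength
  for (ch in 1:3)
    img[rows + 1, cols + 1, ch] <- img[rows + 1, cols + 1, ch] * (1 - a)
  img
}

#' Render one synthetic orchard image
#'
#' Produces the RGB tile together with its exact ground truth: the center
#' point of every rendered crown and a tight bounding box per crown.
#' Distractor objects are rendered but never appear in the ground truth.
#' The output is a pure function of the spec (including its seed).
#'
#' @param spec an [orchard_spec()]
#' @return list with `image` (`[S, S, 3]` array in `[0, 1]`), `points`
#'   (data frame `x, y`), `boxes` (data frame `x1, y1, ..., x4, y4`), and
#'   `crown_mask` (logical matrix marking tree-crown pixels only)
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "orchard_spec"))
  with_seed(spec$seed, {
    sz <- spec$image_size
    img <- array(rep(spec$soil, each = sz * sz), c(sz, sz, 3))
    # low-frequency soil mottling + pixel noise
    gx <- matrix(rep(seq(0, 1, length.out = sz), sz), sz)
    mot <- 0.05 * sin(2 * pi * gx * stats::runif(1, 1, 3) +
                      stats::runif(1, 0, 2 * pi)) *
           sin(2 * pi * t(gx) * stats::runif(1, 1, 3))
    img <- img + array(rep(mot, 3), c(sz, sz, 3))
    img <- img + array(stats::rnorm(sz * sz * 3, 0, spec$noise_sd),
                       c(sz, sz, 3))
    pts <- orchard_positions(spec)
    radii <- stats::runif(nrow(pts), spec$crown_radius[1],
                          spec$crown_radius[2])
    # distractors: bright grey-white blobs (buildings, rock, machinery)
    if (spec$distractor_count > 0) {
      for (i in seq_len(spec$distractor_count)) {
        dx <- stats::runif(1, 10, sz - 10); dy <- stats::runif(1, 10, sz - 10)
        dr <- stats::runif(1, 3, 10)
        dcol <- rep(stats::runif(1, 0.75, 0.95), 3)
        img <- draw_disc(img, dx, dy, dr, dcol, edge_dim = 0.8, tip = 0)
      }
    }
    # shadows first (so crowns overdraw them), then crowns
    if (nrow(pts) > 0) {
      for (i in seq_len(nrow(pts)))
        img <- darken_ellipse(img,
                              pts$x[i] + spec$shadow_offset[1],
                              pts$y[i] + spec$shadow_offset[2],
                              radii[i] * 1.1, radii[i] * 0.8,
                              spec$shadow_opacity)
      crown_mask <- matrix(FALSE, sz, sz)
      for (i in seq_len(nrow(pts))) {
        g <- stats::runif(1, 0.30, 0.45)
        col <- c(g * 0.75, g, g * 0.55)  # olive green-grey
        img <- draw_disc(img, pts$x[i], pts$y[i], radii[i], col)
        rows <- max(0, floor(pts$y[i] - radii[i])):
                min(sz - 1, ceiling(pts$y[i] + radii[i]))
        cols <- max(0, floor(pts$x[i] - radii[i])):
                min(sz - 1, ceiling(pts$x[i] + radii[i]))
        d0 <- outer((rows - pts$y[i])^2, rep(1, length(cols))) +
              outer(rep(1, length(rows)), (cols - pts$x[i])^2)
        crown_mask[rows + 1, cols + 1] <-
          crown_mask[rows + 1, cols + 1] | (d0 <= radii[i]^2)
      }
    } else crown_mask <- matrix(FALSE, sz, sz)
    img <- pmin(pmax(img, 0), 1)
    boxes <- if (nrow(pts) > 0)
      data.frame(x1 = pts$x - radii, y1 = pts$y - radii,
                 x2 = pts$x + radii, y2 = pts$y - radii,
                 x3 = pts$x + radii, y3 = pts$y + radii,
                 x4 = pts$x - radii, y4 = pts$y + radii)
    else data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                    y2 = numeric(), x3 = numeric(), y3 = numeric(),
                    x4 = numeric(), y4 = numeric())
    list(image = img, points = data.frame(x = pts$x, y = pts$y),
         boxes = boxes, crown_mask = crown_mask)
  })
}

#' Generate a dataset of synthetic orchard tiles on disk
#'
#' Renders `n_images` tiles from per-image variations of `spec` (each image
#' gets its own seed derived from the master seed), writes them as PNG,
#' writes all center-point annotations to one CSV in the package's
#' annotation dialect, and records everything in a JSON manifest with
#' disjoint train/test splits.
#'
#' @param spec template [orchard_spec()]; its `seed` is the master seed
#' @param n_images number of tiles
#' @param split named fractions, e.g. `c(train = 0.8, test = 0.2)`
#' @param out_dir destination directory
#' @param force overwrite a non-empty `out_dir`
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`)
#' @export
generate_dataset <- function(spec, n_images, split = c(train = 0.8,
                                                       test = 0.2),
                             out_dir, force = FALSE) {
  stopifnot(n_images >= 1)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory ", out_dir, " is not empty; use force = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1, n_images))
  entries <- vector("list", n_images)
  ann <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- spec; si$seed <- seeds[i]
    out <- generate_image(si)
    fname <- sprintf("orchard_%04d.png", i)
    write_orchard_image(out$image, file.path(out_dir, fname))
    entries[[i]] <- list(image = fname, seed = seeds[i],
                         count = nrow(out$points))
    if (nrow(out$points) > 0)
      ann[[i]] <- data.frame(image = fname, x = out$points$x,
                             y = out$points$y)
  }
  annotations <- do.call(rbind, ann[!vapply(ann, is.null, logical(1))])
  if (is.null(annotations))
    annotations <- data.frame(image = character(), x = numeric(),
                              y = numeric())
  write_annotations(annotations, file.path(out_dir, "annotations.csv"))
  # disjoint splits, in order (sizes rounded, remainder to the first split)
  sizes <- floor(split * n_images)
  sizes[1] <- n_images - sum(sizes[-1])
  idx <- seq_len(n_images)
  splits <- list()
  for (k in seq_along(split)) {
    take <- idx[seq_len(sizes[k])]
    idx <- setdiff(idx, take)
    splits[[names(split)[k]]] <- vapply(entries[take], `[[`, "", "image")
  }
  manifest <- list(master_seed = spec$seed,
                   spec = unclass(spec)[setdiff(names(spec), "seed")],
                   n_images = n_images,
                   total_count = sum(vapply(entries, `[[`, 0, "count")),
                   images = entries, splits = splits,
                   annotations = "annotations.csv")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
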