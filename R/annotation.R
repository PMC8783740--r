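# Annotation handling: bounding-box to centroid reduction, point-annotation
# I/O, and rendering of point sets into density-map supervision targets.
#
# Coordinate convention used throughout the package: 0-based, x = column,
# y = row, pixel-center (the center of the top-left pixel is (0, 0)).

#' Centroid of a four-vertex bounding box
#'
#' Reduces a box to its annotation point: the mean of the four vertices,
#' `(mean(x_i), mean(y_i))`.  For an axis-aligned rectangle this is the
#' geometric center.  Defined for degenerate boxes too (a repeated vertex
#' simply yields that vertex).
#'
#' @param box 4 x 2 numeric matrix of vertices (columns x, y), or a length-8
#'   vector `x1, y1, x2, y2, x3, y3, x4, y4`
#' @return named numeric vector `c(x, y)`
#' @export
box_to_centroid <- function(box) {
  if (!is.matrix(box) && is.numeric(box) && length(box) == 8)
    box <- matrix(box, 4, 2, byrow = TRUE)
  if (!is.matrix(box) || nrow(box) != 4 || ncol(box) != 2)
    stop("box must be a 4x2 vertex matrix or a length-8 vector")
  if (!all(is.finite(box))) stop("box vertices must be finite")
  c(x = mean(box[, 1]), y = mean(box[, 2]))
}

#' Density-target rendering configuration
#'
#' @param kernel_sigma Gaussian kernel bandwidth in pixels; default 2 px,
#'   matching small tree crowns at 224 x 224
#' @param truncation_radius kernel support radius in pixels; must be at
#'   least `3 * kernel_sigma` (default exactly that, rounded up)
#' @return list with class `density_target_config`
#' @export
density_target_config <- function(kernel_sigma = 2,
                                  truncation_radius = ceiling(3 * kernel_sigma)) {
  if (kernel_sigma <= 0) stop("kernel_sigma must be positive")
  if (truncation_radius < 3 * kernel_sigma)
    stop("truncation_radius must be at least 3 * kernel_sigma")
  structure(list(kernel_sigma = kernel_sigma,
                 truncation_radius = as.integer(ceiling(truncation_radius))),
            class = "density_target_config")
}

# Peak value of one rendered unit-mass kernel (used as the default
# peak-detection threshold reference).
density_kernel_peak <- function(cfg = density_target_config()) {
  r <- cfg$truncation_radius
  g <- outer((-r):r, (-r):r, function(a, b)
    exp(-(a^2 + b^2) / (2 * cfg$kernel_sigma^2)))
  max(g) / sum(g)
}

#' Render a point set into a density-map target
#'
#' Places one truncated Gaussian kernel at each annotated center.  Every
#' kernel is renormalised to unit mass over the pixels that fall inside the
#' image, including kernels cropped by the border, so the map's sum equals
#' the number of points and counting by integration is exact by
#' construction.
#'
#' @param points data frame with numeric columns `x`, `y` (0-based,
#'   pixel-center); an empty frame yields an all-zero map
#' @param shape integer `(H, W)` of the target map
#' @param cfg a [density_target_config()]
#' @return `H x W` density matrix with `sum == nrow(points)`
#' @export
points_to_density <- function(points, shape, cfg = density_target_config()) {
  H <- shape[1]; W <- shape[2]
  dmap <- matrix(0, H, W)
  if (is.null(points) || nrow(points) == 0) return(dmap)
  if (any(points$x < -0.5 | points$x > W - 0.5 |
          points$y < -0.5 | points$y > H - 0.5))
    stop("points outside image bounds; clamp or filter before rendering")
  r <- cfg$truncation_radius
  s2 <- 2 * cfg$kernel_sigma^2
  for (i in seq_len(nrow(points))) {
    px <- points$x[i]; py <- points$y[i]
    rows <- max(0, floor(py) - r):min(H - 1, ceiling(py) + r)
    cols <- max(0, floor(px) - r):min(W - 1, ceiling(px) + r)
    k <- outer(rows - py, cols - px, function(a, b) {
      d2 <- a^2 + b^2
      ifelse(d2 <= r^2, exp(-d2 / s2), 0)
    })
    tot <- sum(k)
    if (tot > 0)
      dmap[rows + 1, cols + 1] <- dmap[rows + 1, cols + 1] + k / tot
  }
  dmap
}

# ---- annotation file I/O ----------------------------------------------------

point_cols <- c("image", "x", "y")
box_cols <- c("image", paste0(rep(c("x", "y"), 4), rep(1:4, each = 2)))

validate_annotation_frame <- function(df, path) {
  if (nrow(df) == 0) return(df)
  num <- setdiff(names(df), "image")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) | is.na(df[[cn]]))
    if (length(bad))
      stop("malformed annotation in ", path, ": non-numeric '", cn,
           "' at data row ", bad[1], " (file line ", bad[1] + 1, ")")
    df[[cn]] <- v
  }
  df
}

#' Read annotations from CSV or JSON
#'
#' Two dialects are accepted, recognised by their fields: point files
#' (`image, x, y`) and box files (`image, x1, y1, ..., x4, y4`).  JSON files
#' hold an array of objects with the same fields.  Coordinates are 0-based
#' pixel-center; x is the column, y the row.  If `image_size` is supplied,
#' points outside the bounds are clamped with a warning.
#'
#' @param path `.csv` or `.json` annotation file
#' @param image_size optional `(H, W)` used to clamp out-of-bounds points
#' @return data frame of points (class `point_set`) or of boxes
#'   (class `box_set`)
#' @export
read_annotations <- function(path, image_size = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0) df <- data.frame(image = character(),
                                          x = numeric(), y = numeric())
    df <- as.data.frame(df)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(image = "character"))
  }
  df <- validate_annotation_frame(df, path)
  if (all(box_cols %in% names(df))) {
    class(df) <- c("box_set", class(df))
    return(df)
  }
  if (!all(point_cols %in% names(df)))
    stop("unrecognised annotation fields in ", path, ": expected ",
         "image,x,y or image,x1,y1,...,x4,y4")
  if (!is.null(image_size) && nrow(df) > 0) {
    H <- image_size[1]; W <- image_size[2]
    out <- df$x < 0 | df$x > W - 1 | df$y < 0 | df$y > H - 1
    if (any(out)) {
      warning(sum(out), " point(s) outside image bounds were clamped")
      df$x <- pmin(pmax(df$x, 0), W - 1)
      df$y <- pmin(pmax(df$y, 0), H - 1)
    }
  }
  class(df) <- c("point_set", class(df))
  df
}

#' Write annotations to CSV or JSON
#'
#' Inverse of [read_annotations()]: `write_annotations()` followed by
#' [read_annotations()] reproduces the frame.
#'
#' @param annotations a point or box data frame
#' @param path destination `.csv` or `.json` path
#' @return `path`, invisibly
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations)
  class(df) <- "data.frame"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Convert a box annotation frame to centroid points
#'
#' Applies [box_to_centroid()] row-wise.
#'
#' @param boxes data frame with columns `image, x1, y1, ..., x4, y4`
#' @return point data frame (`image, x, y`), class `point_set`
#' @export
boxes_to_points <- function(boxes) {
  xs <- as.matrix(boxes[, paste0("x", 1:4)])
  ys <- as.matrix(boxes[, paste0("y", 1:4)])
  df <- data.frame(image = boxes$image,
                   x = rowMeans(xs), y = rowMeans(ys))
  class(df) <- c("point_set", class(df))
  df
}
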