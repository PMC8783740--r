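# Training: paired image/point augmentation, density-MSE loss, and the SGD
# loop (momentum 0.9, weight decay 1e-4, step decay) over synthetic or
# user-provided datasets.

#' Training configuration
#'
#' Defaults follow the counting recipe: SGD with momentum 0.9 and weight
#' decay 1e-4, images resized to the model input size, and random flip /
#' right-angle rotation / scale augmentation applied jointly to pixels and
#' point annotations.  The learning rate decays once, by `lr_decay`, at
#' `lr_decay_at` of the way through training.
#'
#' @param learning_rate SGD learning rate
#' @param epochs passes over the training set
#' @param momentum SGD momentum
#' @param weight_decay L2 weight decay added to every gradient
#' @param augment named probabilities for `flip`, `rotate` (right-angle)
#'   and `scale`
#' @param scale_range multiplicative scale-jitter range
#' @param sigma density-target kernel bandwidth, px (at model resolution)
#' @param lr_decay_at fraction of epochs after which the rate is decayed
#' @param lr_decay decay factor
#' @param val_every evaluate pooled estimation error on the validation set
#'   every this many epochs (0 disables)
#' @param seed RNG seed for shuffling and augmentation
#' @param verbose print one line per epoch
#' @return list of class `train_config`
#' @export
train_config <- function(learning_rate = 1e-2, epochs = 10, momentum = 0.9,
                         weight_decay = 1e-4,
                         augment = c(flip = 0.5, rotate = 0.5, scale = 0.0),
                         scale_range = c(0.9, 1.1), sigma = 2,
                         lr_decay_at = 0.75, lr_decay = 0.1, val_every = 0,
                         seed = 1, verbose = TRUE) {
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 momentum = momentum, weight_decay = weight_decay,
                 augment = augment, scale_range = scale_range, sigma = sigma,
                 lr_decay_at = lr_decay_at, lr_decay = lr_decay,
                 val_every = as.integer(val_every), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

rot90cw <- function(img) {
  H <- dim(img)[1]
  aperm(img, c(2, 1, 3))[, rev(seq_len(H)), , drop = FALSE]
}

#' Jointly augment an image and its point annotations
#'
#' Applies horizontal/vertical flips, right-angle rotations and scale
#' jitter; point coordinates undergo exactly the spatial map applied to the
#' pixels, and points pushed outside the frame by scaling are dropped.
#' With all probabilities zero (or `rotate` drawing k = 0 and scale 1) the
#' pair is returned unchanged.
#'
#' @param image array `[H, W, 3]`
#' @param points data frame `x, y` (0-based pixel-center)
#' @param probs named probabilities (`flip`, `rotate`, `scale`)
#' @param scale_range range for the scale factor
#' @return list `(image, points)`
#' @export
augment_pair <- function(image, points,
                         probs = c(flip = 0.5, rotate = 0.5, scale = 0),
                         scale_range = c(0.9, 1.1)) {
  d <- dim(image); H <- d[1]; W <- d[2]
  if (stats::runif(1) < probs[["flip"]]) {       # horizontal flip
    image <- image[, rev(seq_len(W)), , drop = FALSE]
    points$x <- W - 1 - points$x
  }
  if (stats::runif(1) < probs[["flip"]]) {       # vertical flip
    image <- image[rev(seq_len(H)), , , drop = FALSE]
    points$y <- H - 1 - points$y
  }
  if (stats::runif(1) < probs[["rotate"]]) {     # k quarter turns clockwise
    k <- sample(0:3, 1)
    for (i in seq_len(k)) {
      image <- rot90cw(image)
      new_x <- dim(image)[2] - 1 - points$y  # (x', y') = (H-1-y, x)
      points$y <- points$x
      points$x <- new_x
    }
  }
  if (stats::runif(1) < probs[["scale"]]) {
    s <- stats::runif(1, scale_range[1], scale_range[2])
    Hs <- max(8, round(H * s)); Ws <- max(8, round(W * s))
    scaled <- resize_image(image, c(Hs, Ws))
    points <- rescale_points(points, c(H, W), c(Hs, Ws))
    bg <- apply(image, 3, stats::median)
    canvas <- array(rep(bg, each = H * W), c(H, W, 3))
    r0 <- (Hs - H) %/% 2; c0 <- (Ws - W) %/% 2   # center crop / pad
    if (s >= 1) {
      canvas <- scaled[r0 + seq_len(H), c0 + seq_len(W), , drop = FALSE]
      points$x <- points$x - c0; points$y <- points$y - r0
    } else {
      canvas[-r0 + seq_len(Hs), -c0 + seq_len(Ws), ] <- scaled
      points$x <- points$x - c0; points$y <- points$y - r0
    }
    image <- canvas
    keep <- points$x >= 0 & points$x <= W - 1 &
            points$y >= 0 & points$y <= H - 1
    points <- points[keep, , drop = FALSE]
  }
  list(image = image, points = points)
}

#' Mean-squared density loss
#'
#' Mean squared pixel-wise difference between predicted and target density
#' maps; zero if and only if the maps are identical.
#'
#' @param pred,target density matrices of equal shape
#' @return scalar loss
#' @export
density_loss <- function(pred, target) {
  if (!all(dim(pred) == dim(target)))
    stop("prediction and target shapes differ: ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(target), collapse = "x"))
  mean((pred - target)^2)
}

density_loss_grad <- function(pred, target) {
  2 * (pred - target) / length(pred)
}

# load one dataset sample (from a generate_dataset() directory) and prepare
# it at model resolution
load_sample <- function(dir, fname, annotations, input_size) {
  img <- read_orchard_image(file.path(dir, fname))
  pts <- annotations[annotations$image == fname, c("x", "y"), drop = FALSE]
  from <- dim(img)[1:2]
  if (!all(from == input_size)) {
    img <- resize_image(img, input_size)
    pts <- rescale_points(pts, from, input_size)
    pts$x <- pmin(pmax(pts$x, 0), input_size[2] - 1)
    pts$y <- pmin(pmax(pts$y, 0), input_size[1] - 1)
  }
  list(image = img, points = pts)
}

# resolve a dataset argument into a list of (image, points) samples:
# either a directory produced by generate_dataset() (+ split name) or an
# in-memory list of such samples
resolve_samples <- function(data, split, input_size) {
  if (is.character(data)) {
    manifest <- jsonlite::fromJSON(file.path(data, "manifest.json"),
                                   simplifyDataFrame = FALSE)
    ann <- read_annotations(file.path(data, manifest$annotations))
    files <- unlist(manifest$splits[[split]])
    if (length(files) == 0) stop("split '", split, "' is empty")
    lapply(files, function(f) load_sample(data, f, ann, input_size))
  } else {
    lapply(data, function(s) {
      from <- dim(s$image)[1:2]
      if (!all(from == input_size)) {
        s$points <- rescale_points(s$points, from, input_size)
        s$image <- resize_image(s$image, input_size)
      }
      s
    })
  }
}

sgd_update <- function(params, grads, state, lr, momentum, wd) {
  if (is.null(state)) state <- ptree_zeros_like(params)
  state <- ptree_map(function(v, g, p) momentum * v + g + wd * p,
                     state, grads, params)
  params <- ptree_map(function(p, v) p - lr * v, params, state)
  list(params = params, state = state)
}

#' Train the model on (image, density-target) pairs
#'
#' Stochastic gradient descent with momentum over single-image steps: each
#' training image is augmented, its point annotations are rendered into a
#' unit-mass Gaussian density target, and the mean-squared density loss is
#' backpropagated through the full network.  With a validation set, pooled
#' estimation error is tracked and the parameters with the best value are
#' restored at the end.  The loop is fully seeded and aborts with
#' diagnostics if the loss turns non-finite.
#'
#' @param model a [swintunet()] model
#' @param data either the directory written by [generate_dataset()] or a
#'   list of `list(image =, points =)` samples
#' @param cfg a [train_config()]
#' @param val_data optional validation set (same forms as `data`; with a
#'   dataset directory, its `"test"` split is used)
#' @param split split name to train on when `data` is a directory
#' @return list of class `swincount_fit`: `model`, `history` (data frame
#'   of per-epoch loss / learning rate / validation EE), `config`
#' @export
train_swintunet <- function(model, data, cfg = train_config(),
                            val_data = NULL, split = "train") {
  input_size <- model$config$input_size
  samples <- resolve_samples(data, split, input_size)
  val <- if (!is.null(val_data))
    resolve_samples(val_data, "test", input_size)
  dcfg <- density_target_config(kernel_sigma = cfg$sigma)
  dsc <- model$config$density_scale
  if (is.null(dsc)) dsc <- 1
  set.seed(cfg$seed)
  state <- NULL
  best <- list(ee = Inf, params = model$params)
  hist <- data.frame()
  n <- length(samples)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate *
      if (epoch > cfg$lr_decay_at * cfg$epochs) cfg$lr_decay else 1
    ord <- sample.int(n)
    tot <- 0
    for (i in ord) {
      s <- samples[[i]]
      aug <- augment_pair(s$image, s$points, cfg$augment, cfg$scale_range)
      target <- points_to_density(aug$points, input_size, dcfg)
      fw <- swintunet_fwd(model, aug$image, keep = TRUE)
      # optimise on density-scale-multiplied maps (see model_config());
      # identical minimiser, far better-conditioned gradients
      l <- density_loss(fw$out * dsc, target * dsc)
      if (!is.finite(l))
        stop("non-finite loss at epoch ", epoch, ", sample ", i,
             " (lr = ", lr, "); reduce the learning rate")
      tot <- tot + l
      bk <- swintunet_bwd(density_loss_grad(fw$out, target) * dsc^2,
                          fw$cache, model)
      upd <- sgd_update(model$params, bk$grads, state, lr, cfg$momentum,
                        cfg$weight_decay)
      model$params <- upd$params
      state <- upd$state
    }
    val_ee <- NA_real_
    if (!is.null(val) && cfg$val_every > 0 &&
        (epoch %% cfg$val_every == 0 || epoch == cfg$epochs)) {
      val_ee <- pooled_count_ee(model, val)
      if (val_ee < best$ee) best <- list(ee = val_ee, params = model$params)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = tot / n, lr = lr,
                                   val_ee = val_ee))
    if (cfg$verbose)
      message(sprintf("epoch %3d  loss %.3e  lr %.1e%s", epoch, tot / n, lr,
                      if (is.na(val_ee)) "" else sprintf("  val EE %.1f%%",
                                                         val_ee)))
  }
  if (is.finite(best$ee)) model$params <- best$params
  structure(list(model = model, history = hist, config = cfg),
            class = "swincount_fit")
}

# pooled |sum(NE) - sum(NA)| / sum(NA) * 100 over a sample list
pooled_count_ee <- function(model, samples) {
  ne <- 0; na <- 0
  for (s in samples) {
    ne <- ne + sum(swintunet_fwd(model, s$image)$out)
    na <- na + nrow(s$points)
  }
  estimation_error(round(ne), na)
}

#' Predicted tree count for one image
#'
#' Resizes the image to the model input if needed, runs the forward pass
#' and integrates the density map.
#'
#' @param image array `[H, W, 3]`
#' @param model a [swintunet()] model
#' @return integer count estimate
#' @export
predict_count <- function(image, model) {
  input_size <- model$config$input_size
  if (!all(dim(image)[1:2] == input_size))
    image <- resize_image(image, input_size)
  count_from_density(swintunet_forward(image, model))
}
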