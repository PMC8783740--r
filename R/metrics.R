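# Counting and detection evaluation: density-integral count readout, peak
# localisation with greedy point matching, and the four counting metrics
# (overall accuracy, omission / commission error rates, estimation error).

#' Count estimate from a density map
#'
#' The estimated count NE is the rounded spatial integral of the predicted
#' density map.
#'
#' @param d nonnegative density matrix
#' @return integer count
#' @export
count_from_density <- function(d) {
  if (any(d < 0))
    stop("density map contains negative values; the head contract requires ",
         "a nonnegative map")
  as.integer(round(sum(d)))
}

# Local-maximum peak extraction with non-maximum suppression: candidate
# pixels exceed `threshold` and are maximal in their 3x3 neighbourhood;
# candidates are then accepted in decreasing order of value, suppressing
# any candidate within `radius` of an accepted peak.
find_density_peaks <- function(d, threshold, radius) {
  H <- nrow(d); W <- ncol(d)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- d
  ismax <- d >= threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & (d >= pad[2:(H + 1) + dr, 2:(W + 1) + dc])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(x = numeric(), y = numeric(),
                                        value = numeric()))
  cand <- data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1,
                     value = d[idx])
  cand <- cand[order(-cand$value), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1 || all((cand$x[keep] - cand$x[i])^2 +
                      (cand$y[keep] - cand$y[i])^2 >= radius^2)) {
      keep[i] <- TRUE
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

# Greedy nearest-pair matching: all (peak, truth) pairs within `radius` are
# sorted by distance and accepted while both endpoints are unmatched.
greedy_match <- function(pred, gt, radius) {
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0 || ng == 0) return(0L)
  dx <- outer(pred$x, gt$x, `-`)
  dy <- outer(pred$y, gt$y, `-`)
  dist <- sqrt(dx^2 + dy^2)
  pairs <- which(dist <= radius, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0L)
  pairs <- pairs[order(dist[pairs]), , drop = FALSE]
  pused <- logical(np); gused <- logical(ng)
  m <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!pused[i] && !gused[j]) {
      pused[i] <- TRUE; gused[j] <- TRUE; m <- m + 1L
    }
  }
  m
}

#' Localise predicted trees and match them to ground truth
#'
#' Extracts peaks from the predicted density map (local maxima above
#' `peak_threshold`, at least `radius` apart) and greedily matches them to
#' ground-truth points within `radius`, each truth point used at most once.
#' Unmatched truth points are omissions (Nm); unmatched peaks are false
#' detections (Nf).
#'
#' @param pred predicted density matrix
#' @param gt data frame of ground-truth points (`x`, `y`)
#' @param radius match radius in pixels (default 4 at 224 x 224)
#' @param peak_threshold minimum peak height; defaults to half the peak
#'   value of a unit-mass target kernel under `cfg`
#' @param cfg [density_target_config()] used only for the default threshold
#' @return a `count_summary` list with fields `NA_` (actual), `NE`
#'   (number of peaks), `Nm`, `Nf`, `matched`
#' @export
localize_and_match <- function(pred, gt, radius = 4, peak_threshold = NULL,
                               cfg = density_target_config()) {
  if (radius <= 0) stop("match radius must be positive")
  if (is.null(peak_threshold))
    peak_threshold <- 0.5 * density_kernel_peak(cfg)
  peaks <- find_density_peaks(pred, peak_threshold, radius)
  m <- greedy_match(peaks, gt, radius)
  count_summary(NA_ = nrow(gt), NE = nrow(peaks),
                Nm = nrow(gt) - m, Nf = nrow(peaks) - m)
}

#' Detection count summary
#'
#' Bundles the four counts the metrics are built from: `NA_` actual trees,
#' `NE` estimated trees, `Nm` omitted (missed) trees, `Nf` false
#' detections.
#'
#' @param NA_ actual count
#' @param NE estimated count
#' @param Nm omitted count, `Nm <= NA_`
#' @param Nf false-detection count
#' @return list of class `count_summary`
#' @export
count_summary <- function(NA_, NE, Nm, Nf) {
  stopifnot(NA_ >= 0, NE >= 0, Nm >= 0, Nf >= 0)
  if (Nm > NA_) stop("omissions (", Nm, ") cannot exceed actual count (",
                     NA_, ")")
  structure(list(NA_ = as.integer(NA_), NE = as.integer(NE),
                 Nm = as.integer(Nm), Nf = as.integer(Nf),
                 matched = as.integer(NA_ - Nm)),
            class = "count_summary")
}

check_na <- function(NA_) {
  if (NA_ <= 0)
    stop("metrics are undefined for an actual count of zero")
}

#' Overall accuracy: NE / NA x 100
#' @param NE estimated count
#' @param NA_ actual count, must be positive
#' @return percentage
#' @export
overall_accuracy <- function(NE, NA_) {
  check_na(NA_)
  NE / NA_ * 100
}

#' Omission error rate: Nm / NA x 100 (missed trees)
#' @param Nm omitted-tree count
#' @param NA_ actual count, must be positive
#' @return percentage
#' @export
omission_error <- function(Nm, NA_) {
  check_na(NA_)
  Nm / NA_ * 100
}

#' Commission error rate: Nf / NA x 100 (false detections)
#' @param Nf false-detection count
#' @param NA_ actual count, must be positive
#' @return percentage
#' @export
commission_error <- function(Nf, NA_) {
  check_na(NA_)
  Nf / NA_ * 100
}

#' Estimation error: |NE - NA| / NA x 100
#'
#' The relative count deviation.  The absolute value is reported (an over-
#' and an under-count of equal size are the same error); the signed value
#' is available from [metric_report()] as `ee_signed`.
#'
#' @param NE estimated count
#' @param NA_ actual count, must be positive
#' @return percentage
#' @export
estimation_error <- function(NE, NA_) {
  check_na(NA_)
  abs(NE - NA_) / NA_ * 100
}

#' Full metric report from a count summary
#'
#' @param s a [count_summary()]
#' @return list of class `metric_report` with `oa`, `oer`, `cer`, `ee`
#'   (percentages, unrounded) plus the signed estimation error `ee_signed`
#'   and the underlying counts
#' @export
metric_report <- function(s) {
  structure(list(oa = overall_accuracy(s$NE, s$NA_),
                 oer = omission_error(s$Nm, s$NA_),
                 cer = commission_error(s$Nf, s$NA_),
                 ee = estimation_error(s$NE, s$NA_),
                 ee_signed = (s$NE - s$NA_) / s$NA_ * 100,
                 counts = s),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  s <- x$counts
  cat(sprintf("counts: NA=%d NE=%d missed=%d false=%d\n",
              s$NA_, s$NE, s$Nm, s$Nf))
  cat(sprintf("OA %.2f%%  OER %.1f%%  CER %.2f%%  EE %.2f%%\n",
              x$oa, x$oer, x$cer, x$ee))
  invisible(x)
}

#' Evaluate predictions against annotations
#'
#' For every image, the estimated count NE is read out by integrating its
#' predicted density map, and missed / false detections are obtained by
#' peak localisation and matching.  Counts are pooled over all images
#' before the percentage metrics are applied (the per-image metrics are
#' also returned).
#'
#' @param predictions named list of predicted density matrices, one per
#'   image
#' @param annotations point data frame (`image, x, y`) covering the same
#'   images
#' @param radius match radius in pixels
#' @param peak_threshold see [localize_and_match()]
#' @param cfg [density_target_config()] for the default threshold
#' @param out_csv optional path: write the per-image table as CSV
#' @param out_json optional path: write the pooled summary as JSON
#' @return list with `pooled` (a [metric_report()]) and `per_image`
#'   (data frame)
#' @export
evaluate <- function(predictions, annotations, radius = 4,
                     peak_threshold = NULL, cfg = density_target_config(),
                     out_csv = NULL, out_json = NULL) {
  keys_p <- names(predictions)
  keys_a <- unique(annotations$image)
  if (!setequal(keys_p, keys_a)) {
    miss_p <- setdiff(keys_a, keys_p); miss_a <- setdiff(keys_p, keys_a)
    stop("prediction/annotation keys differ.",
         if (length(miss_p)) paste0(" Missing predictions: ",
                                    paste(miss_p, collapse = ", "), "."),
         if (length(miss_a)) paste0(" Missing annotations: ",
                                    paste(miss_a, collapse = ", "), "."))
  }
  rows <- lapply(keys_p, function(k) {
    gt <- annotations[annotations$image == k, , drop = FALSE]
    dmap <- predictions[[k]]
    s <- localize_and_match(dmap, gt, radius, peak_threshold, cfg)
    ne_int <- count_from_density(dmap)
    data.frame(image = k, NA_ = s$NA_, NE = ne_int, NE_peaks = s$NE,
               Nm = s$Nm, Nf = s$Nf,
               oa = if (s$NA_ > 0) overall_accuracy(ne_int, s$NA_) else NA,
               oer = if (s$NA_ > 0) omission_error(s$Nm, s$NA_) else NA,
               cer = if (s$NA_ > 0) commission_error(s$Nf, s$NA_) else NA,
               ee = if (s$NA_ > 0) estimation_error(ne_int, s$NA_) else NA)
  })
  per_image <- do.call(rbind, rows)
  pooled <- metric_report(count_summary(NA_ = sum(per_image$NA_),
                                        NE = sum(per_image$NE),
                                        Nm = sum(per_image$Nm),
                                        Nf = sum(per_image$Nf)))
  if (!is.null(out_csv))
    utils::write.csv(per_image, out_csv, row.names = FALSE)
  if (!is.null(out_json))
    jsonlite::write_json(list(pooled = pooled[c("oa", "oer", "cer", "ee",
                                                "ee_signed")],
                              counts = unclass(pooled$counts)),
                         out_json, auto_unbox = TRUE, digits = NA)
  list(pooled = pooled, per_image = per_image)
}
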