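# Nucleus localisation: pluggable detectors over overlapping patches,
# duplicate merging within a 4 px radius, and distance-thresholded F1
# evaluation (< 3.3 um between predicted and true centroids).

#' Detector contract
#'
#' A nucleus detector is any object with a [detect_boxes()] method
#' returning, for a `slide_patch`, a data.frame of axis-aligned boxes
#' `x0, y0, x1, y1` (patch-local pixels) with a `score` in `[0, 1]`.
#' The package ships two implementations: [oracle_detector()], which
#' reads ground truth with configurable jitter/drop (for pipeline
#' tests), and [blob_detector()], a trainable classical intensity
#' detector (dark-blob thresholding + connected components).
#'
#' @param detector a detector object.
#' @param patch a `slide_patch`.
#' @return data.frame with columns `x0, y0, x1, y1, score`.
#' @export
detect_boxes <- function(detector, patch) UseMethod("detect_boxes")

#' Ground-truth oracle detector
#'
#' Returns boxes around the true nuclei falling inside each patch,
#' optionally jittered (Gaussian, `jitter_px`) and thinned (each
#' nucleus dropped with probability `drop`).  Jitter and drops are
#' deterministic per patch origin under `seed`, so repeated iteration
#' over the same slide yields identical output.
#'
#' @param truth data.frame with nucleus columns `x`, `y` (rescaled frame).
#' @param jitter_px standard deviation of coordinate jitter.
#' @param drop per-nucleus drop probability.
#' @param seed RNG seed (only used when jitter or drop is nonzero).
#' @param box_px box side length.
#' @return a `nucleus_detector`.
#' @export
oracle_detector <- function(truth, jitter_px = 0, drop = 0, seed = 1L,
                            box_px = 20) {
  structure(list(truth = truth, jitter_px = jitter_px, drop = drop,
                 seed = as.integer(seed), box_px = box_px),
            class = c("oracle_detector", "nucleus_detector"))
}

#' @export
detect_boxes.oracle_detector <- function(detector, patch) {
  ox <- patch$origin[1]; oy <- patch$origin[2]
  w <- patch$size[1]; h <- patch$size[2]
  t <- detector$truth
  sel <- t$x >= ox & t$x < ox + w & t$y >= oy & t$y < oy + h
  x <- t$x[sel] - ox; y <- t$y[sel] - oy
  if (length(x) > 0 && (detector$jitter_px > 0 || detector$drop > 0)) {
    patch_seed <- (detector$seed + 7919 * ox + 104729 * oy) %% 2147483647
    jit <- with_seed(patch_seed, {
      keep <- stats::runif(length(x)) >= detector$drop
      list(keep = keep,
           dx = stats::rnorm(length(x), 0, detector$jitter_px),
           dy = stats::rnorm(length(x), 0, detector$jitter_px))
    })
    x <- (x + jit$dx)[jit$keep]
    y <- (y + jit$dy)[jit$keep]
    x <- clamp(x, 0, w - 1e-9); y <- clamp(y, 0, h - 1e-9)
  }
  r <- detector$box_px / 2
  data.frame(x0 = x - r, y0 = y - r, x1 = x + r, y1 = y + r,
             score = rep(1, length(x)))
}

#' Classical intensity blob detector
#'
#' Detects nuclei as connected components of pixels darker than
#' `threshold` (mean over RGB), with component area restricted to
#' `[min_area_px, max_area_px]`.  Centroids are darkness-weighted for
#' sub-pixel accuracy; the score is the component's mean darkness.
#'
#' Components touching the patch border are discarded: the overlap of
#' the tiling guarantees every nucleus appears whole in at least one
#' patch, and truncated blobs would yield displaced centroids.
#'
#' @param threshold grey-level threshold (0..255) below which a pixel
#'   is nucleus candidate.
#' @param min_area_px,max_area_px component area bounds in pixels.
#' @return a `nucleus_detector`.
#' @export
blob_detector <- function(threshold = 215, min_area_px = 40,
                          max_area_px = Inf) {
  structure(list(threshold = threshold, min_area_px = min_area_px,
                 max_area_px = max_area_px),
            class = c("blob_detector", "nucleus_detector"))
}

#' @export
detect_boxes.blob_detector <- function(detector, patch) {
  px <- patch$pixels
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  mask <- gray < detector$threshold
  empty <- data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), score = numeric(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask))))
  W <- nrow(lab)  # first dim of the transposed matrix is x
  idx <- which(lab > 0)
  ids <- lab[idx]
  xs <- (idx - 1) %% W
  ys <- (idx - 1) %/% W
  dark <- 1 - t(gray)[idx] / 255
  area <- tabulate(ids)
  wsum <- vapply(split(dark, ids), sum, numeric(1))
  cx <- vapply(split(xs * dark, ids), sum, numeric(1)) / wsum
  cy <- vapply(split(ys * dark, ids), sum, numeric(1)) / wsum
  mdark <- wsum / area[as.integer(names(wsum))]
  a <- area[as.integer(names(wsum))]
  H <- ncol(lab)
  border_ids <- unique(c(lab[1, ], lab[W, ], lab[, 1], lab[, H]))
  touches_border <- as.integer(names(wsum)) %in% border_ids
  keep <- a >= detector$min_area_px & a <= detector$max_area_px &
    !touches_border
  if (!any(keep)) return(empty)
  r <- sqrt(a[keep] / pi)
  data.frame(x0 = cx[keep] - r, y0 = cy[keep] - r,
             x1 = cx[keep] + r, y1 = cy[keep] + r,
             score = clamp(mdark[keep], 0, 1))
}

#' Run nucleus detection across a slide
#'
#' Tiles the slide with overlapping patches, skips background patches,
#' converts per-patch boxes to centroids in the global rescaled frame,
#' pools them and merges overlap duplicates.
#'
#' @param handle a `slide_handle`.
#' @param detector a `nucleus_detector`.
#' @inheritParams patch_origins
#' @inheritParams read_patch
#' @param radius_px duplicate-merge radius (see [merge_duplicates()]).
#' @param origins optional origin subset (resume support).
#' @param dedup apply duplicate merging (default TRUE).
#' @return data.frame of nucleus predictions `x`, `y`, `confidence`.
#' @export
run_detection <- function(handle, detector, width = 1600, height = 1200,
                          overlap = 200, target_mpp = HISTOCELL_MPP,
                          radius_px = 4, origins = NULL, dedup = TRUE) {
  patches <- iter_patches(handle, width, height, overlap, target_mpp,
                          origins = origins)
  out <- lapply(patches, function(p) {
    if (is_background(p)) return(NULL)
    boxes <- tryCatch(detect_boxes(detector, p), error = function(e) {
      stopf("detector failed on patch at origin (%d, %d): %s",
            p$origin[1], p$origin[2], conditionMessage(e))
    })
    if (nrow(boxes) == 0) return(NULL)
    data.frame(x = (boxes$x0 + boxes$x1) / 2 + p$origin[1],
               y = (boxes$y0 + boxes$y1) / 2 + p$origin[2],
               confidence = clamp(boxes$score, 0, 1))
  })
  preds <- do.call(rbind, out)
  if (is.null(preds)) {
    preds <- data.frame(x = numeric(0), y = numeric(0),
                        confidence = numeric(0))
  }
  if (dedup) preds <- merge_duplicates(preds, radius_px) else preds
}

#' Merge duplicate nucleus predictions
#'
#' Greedy pass in descending confidence (ties: lower y, then lower x):
#' a prediction is kept iff no already-kept prediction lies within
#' Euclidean distance strictly less than `radius_px`.  Survivors are
#' therefore pairwise at least `radius_px` apart.
#'
#' @param preds data.frame with `x`, `y`, `confidence`.
#' @param radius_px merge radius in rescaled pixels.
#' @return the kept predictions, in kept order.
#' @export
merge_duplicates <- function(preds, radius_px = 4) {
  n <- nrow(preds)
  if (n <= 1) return(preds)
  ord <- order(-preds$confidence, preds$y, preds$x)
  x <- preds$x[ord]; y <- preds$y[ord]
  kept <- logical(n)
  kx <- numeric(n); ky <- numeric(n); nk <- 0L
  r2 <- radius_px^2
  for (i in seq_len(n)) {
    if (nk > 0) {
      d2 <- (kx[1:nk] - x[i])^2 + (ky[1:nk] - y[i])^2
      if (min(d2) < r2) next
    }
    nk <- nk + 1L
    kx[nk] <- x[i]; ky[nk] <- y[i]
    kept[i] <- TRUE
  }
  preds[ord[kept], , drop = FALSE]
}

#' Evaluate detection with distance-thresholded F1
#'
#' Matches predictions to ground-truth points one-to-one on the
#' bipartite graph of pairs closer than `max_dist_um` (strict), taking
#' a maximum-cardinality matching and, among those, one of minimum
#' total distance.  `F1 = 2TP / (2TP + FP + FN)`.
#'
#' @param preds,truth data.frames with `x`, `y` in rescaled pixels.
#' @param max_dist_um match threshold in micrometres.
#' @param mpp micrometres per pixel of the coordinate frame.
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn` and
#'   `matching` (data.frame `pred`, `truth`, `dist_um`).
#' @export
evaluate_detection <- function(preds, truth, max_dist_um = 3.3,
                               mpp = HISTOCELL_MPP) {
  if (max_dist_um <= 0) stopf("max_dist_um must be > 0")
  np <- nrow(preds); nt <- nrow(truth)
  empty_match <- data.frame(pred = integer(0), truth = integer(0),
                            dist_um = numeric(0))
  if (np == 0 || nt == 0) {
    tp <- 0L
    return(list(precision = if (np == 0 && nt == 0) 1 else 0,
                recall = if (nt == 0) 1 else 0,
                f1 = if (np == 0 && nt == 0) 1 else 0,
                tp = tp, fp = np, fn = nt, matching = empty_match))
  }
  d_um <- sqrt(outer(preds$x, truth$x, "-")^2 +
               outer(preds$y, truth$y, "-")^2) * mpp
  allowed <- which(d_um < max_dist_um, arr.ind = TRUE)
  if (nrow(allowed) == 0) {
    tp <- 0L
  } else {
    dists <- d_um[allowed]
    big <- sum(dists) + 1
    g <- igraph::make_bipartite_graph(
      types = c(rep(FALSE, np), rep(TRUE, nt)),
      edges = as.vector(t(cbind(allowed[, 1], np + allowed[, 2]))))
    m <- igraph::max_bipartite_match(g, weights = big - dists)
    matched_pred <- which(!is.na(m$matching[seq_len(np)]))
    matched_truth <- m$matching[matched_pred] - np
    tp <- length(matched_pred)
    if (tp > 0) {
      empty_match <- data.frame(
        pred = matched_pred, truth = matched_truth,
        dist_um = d_um[cbind(matched_pred, matched_truth)])
    }
  }
  fp <- np - tp; fn <- nt - tp
  list(precision = tp / np, recall = tp / nt,
       f1 = 2 * tp / (2 * tp + fp + fn),
       tp = tp, fp = fp, fn = fn, matching = empty_match)
}

#' Train (calibrate) the classical blob detector
#'
#' The trainable parameters are the grey threshold and minimum
#' component area.  Each epoch evaluates one candidate setting from a
#' seeded search sequence on the validation patches and records its F1;
#' the setting with the best validation F1 is returned (argmax over the
#' per-epoch log), mirroring best-validation-model selection.
#'
#' @param dataset list with elements `train` and `val`, each a list of
#'   `list(patch = <slide_patch>, centroids = <data.frame x, y>)`
#'   (patch-local coordinates).
#' @param schedule list with `epochs` (candidate evaluations; 0 returns
#'   the initial detector unchanged) and optional `seed`,
#'   `thresholds`, `min_areas` candidate grids.
#' @param mpp micrometres per pixel for F1 evaluation.
#' @return a `blob_detector` with attributes `log` (per-epoch data.frame
#'   `epoch`, `threshold`, `min_area`, `val_f1`) and `best_epoch`.
#' @export
train_detector <- function(dataset, schedule = list(epochs = 10),
                           mpp = HISTOCELL_MPP) {
  if (length(dataset$val) == 0 && (schedule$epochs %||% 0) > 0) {
    stopf("empty validation dataset")
  }
  epochs <- schedule$epochs %||% 10
  det <- blob_detector()
  if (epochs == 0) {
    attr(det, "log") <- data.frame(epoch = integer(0), threshold = numeric(0),
                                   min_area = numeric(0), val_f1 = numeric(0))
    return(det)
  }
  thresholds <- schedule$thresholds %||% seq(150, 240, by = 10)
  min_areas <- schedule$min_areas %||% c(10, 30, 100, 300, 600)
  grid <- expand.grid(threshold = thresholds, min_area = min_areas)
  ord <- with_seed(schedule$seed %||% 1L, sample.int(nrow(grid)))
  grid <- grid[ord[seq_len(min(epochs, nrow(grid)))], , drop = FALSE]
  log <- data.frame(epoch = seq_len(nrow(grid)),
                    threshold = grid$threshold, min_area = grid$min_area,
                    val_f1 = NA_real_)
  for (e in seq_len(nrow(grid))) {
    cand <- blob_detector(grid$threshold[e], grid$min_area[e])
    log$val_f1[e] <- validation_f1(cand, dataset$val, mpp)
  }
  best <- which.max(log$val_f1)
  det <- blob_detector(log$threshold[best], log$min_area[best])
  attr(det, "log") <- log
  attr(det, "best_epoch") <- best
  det
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validation_f1 <- function(detector, val, mpp) {
  tp <- fp <- fn <- 0L
  for (item in val) {
    boxes <- detect_boxes(detector, item$patch)
    preds <- data.frame(x = (boxes$x0 + boxes$x1) / 2,
                        y = (boxes$y0 + boxes$y1) / 2)
    ev <- evaluate_detection(preds, item$centroids, mpp = mpp)
    tp <- tp + ev$tp; fp <- fp + ev$fp; fn <- fn + ev$fn
  }
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}
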