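# Cell classification: nucleus-centred crops, H&E stain augmentation,
# inverse-frequency oversampling, a trainable classifier with a 64-d
# penultimate embedding, and syncytial-knot post-processing.

#' Crop a nucleus-centred image
#'
#' Extracts the rescaled-frame window
#' `[x - size/2, x + size/2) x [y - size/2, y + size/2)`; area outside
#' the slide is filled with constant 255 (white), so the output raster
#' is always `size x size x 3`.
#'
#' @param handle a `slide_handle`.
#' @param x,y nucleus centre in rescaled pixels.
#' @param size_px crop side length (default 200).
#' @inheritParams read_patch
#' @return a `slide_patch`.
#' @export
crop_cell_image <- function(handle, x, y, size_px = 200,
                            target_mpp = HISTOCELL_MPP) {
  dims <- rescaled_dims(handle, target_mpp)
  if (x < 0 || y < 0 || x >= dims[1] || y >= dims[2]) {
    stopf("nucleus (%.1f, %.1f) outside slide bounds %d x %d",
          x, y, dims[1], dims[2])
  }
  read_patch(handle, round(x) - size_px %/% 2, round(y) - size_px %/% 2,
             size_px, size_px, target_mpp)
}

# Normalised H&E optical-density stain vectors (haematoxylin, eosin).
he_stain_matrix <- function() {
  m <- rbind(c(0.650, 0.704, 0.286),
             c(0.072, 0.990, 0.105))
  m / sqrt(rowSums(m^2))
}

#' H&E stain augmentation
#'
#' Deconvolves the image into a two-channel haematoxylin/eosin stain
#' space (fixed stain matrix), multiplies each stain concentration
#' channel by a factor drawn uniformly from `[1 - alpha, 1 + alpha]`
#' and shifts it by a uniform `[-beta, beta]` offset, then recomposes
#' and clips to `[0, 255]`.  The deconvolution residual (the component
#' of optical density outside the two-stain plane) is preserved, so
#' `alpha = beta = 0` is an identity up to floating-point round-trip.
#'
#' @param image a `slide_patch` or H x W x 3 array (0..255).
#' @param alpha multiplicative jitter half-width (>= 0).
#' @param beta additive jitter half-width in OD units (>= 0).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return augmented raster of the same shape (array in, array out).
#' @export
stain_augment <- function(image, alpha = 0.15, beta = 0.15, seed = NULL) {
  if (alpha < 0 || beta < 0) stopf("alpha and beta must be >= 0")
  px <- if (inherits(image, "slide_patch")) image$pixels else image
  dm <- dim(px)
  M <- he_stain_matrix()
  od <- -log((matrix(px, ncol = 3) + 1) / 256)
  pinv <- t(M) %*% solve(M %*% t(M))
  conc <- od %*% pinv                 # N x 2 stain concentrations
  resid <- od - conc %*% M
  jit <- with_seed(seed, list(u = stats::runif(2, 1 - alpha, 1 + alpha),
                              v = stats::runif(2, -beta, beta)))
  conc2 <- sweep(sweep(conc, 2, jit$u, "*"), 2, jit$v, "+")
  od2 <- conc2 %*% M + resid
  out <- clamp(256 * exp(-od2) - 1, 0, 255)
  out <- array(out, dm)
  if (inherits(image, "slide_patch")) {
    image$pixels <- out
    image
  } else out
}

#' Inverse-frequency oversampling weights
#'
#' `weight(item) = 1 / count(class(item))`: under weighted sampling
#' with replacement, expected class frequencies are uniform over the
#' classes present.  Weights are reported unnormalised (any common
#' rescaling is equivalent downstream).
#'
#' @param labels character/factor vector of class labels.
#' @return numeric weight per item.
#' @export
balance_by_oversampling <- function(labels) {
  if (length(labels) == 0) stopf("empty labels")
  counts <- table(labels)
  as.numeric(1 / counts[as.character(labels)])
}

# Downsampled RGB features for the classifier: input_px x input_px x 3,
# scaled to [0, 1].
crop_features <- function(crops, input_px) {
  t(vapply(crops, function(cr) {
    px <- if (inherits(cr, "slide_patch")) cr$pixels else cr
    if (dim(px)[1] != input_px) px <- resample_rgb(px, input_px, input_px)
    as.vector(px) / 255
  }, numeric(input_px * input_px * 3)))
}

#' Train the cell classifier
#'
#' A single-hidden-layer softmax network (64 hidden units by default)
#' over a PCA projection of downsampled RGB crop features; the
#' hidden-layer activations are the per-cell 64-d embedding.  The PCA
#' front-end keeps the optimiser's weight count small while the hidden
#' layer provides the embedding width.  Training uses inverse-frequency
#' case weights (oversampling), optional per-epoch H&E stain
#' augmentation, and keeps the epoch with the best validation accuracy.
#'
#' @param dataset list with `train` and `val`, each
#'   `list(crops = <list of rasters>, labels = <character>)`; every class
#'   present in validation must be present in training.
#' @param schedule list: `epochs` (default 8; 0 returns the randomly
#'   initialised classifier), `maxit` optimiser iterations per epoch
#'   (default 40), `hidden` (default 64), `input_px` (default 12),
#'   `pca_dim` (default 24), `augment` (default TRUE), `alpha`, `beta`,
#'   `seed`.
#' @return object of class `cell_classifier` with fields `net`,
#'   `classes`, `input_px`, `log` (per-epoch validation accuracy) and
#'   `best_epoch`.
#' @export
train_cell_classifier <- function(dataset, schedule = list()) {
  epochs <- schedule$epochs %||% 8
  maxit <- schedule$maxit %||% 40
  hidden <- schedule$hidden %||% 64
  input_px <- schedule$input_px %||% 12
  pca_dim <- schedule$pca_dim %||% 24
  augment <- schedule$augment %||% TRUE
  alpha <- schedule$alpha %||% 0.15
  beta <- schedule$beta %||% 0.15
  seed <- schedule$seed %||% 1L

  classes <- sort(unique(dataset$train$labels))
  if (length(setdiff(unique(dataset$val$labels), classes)) > 0) {
    stopf("validation contains classes absent from training")
  }
  Xtr0 <- crop_features(dataset$train$crops, input_px)
  ytr <- factor(dataset$train$labels, levels = classes)
  yval <- factor(dataset$val$labels, levels = classes)
  w <- balance_by_oversampling(as.character(ytr))
  w <- w / mean(w)
  yind <- nnet::class.ind(ytr)

  pca_dim <- min(pca_dim, nrow(Xtr0) - 1L, ncol(Xtr0))
  pca <- stats::prcomp(Xtr0, center = TRUE, scale. = FALSE,
                       rank. = pca_dim)
  project <- function(X) {
    sweep(X, 2, pca$center) %*% pca$rotation
  }
  Xval <- project(crop_features(dataset$val$crops, input_px))

  d <- pca_dim
  nw <- (d + 1) * hidden + (hidden + 1) * length(classes)
  wts <- with_seed(seed, stats::runif(nw, -0.5, 0.5))
  log <- data.frame(epoch = integer(0), val_accuracy = numeric(0))
  best <- list(wts = wts, acc = -Inf, epoch = 0L)
  seeds <- derive_seeds(seed, max(1, epochs))

  for (e in seq_len(epochs)) {
    Xtr <- Xtr0
    if (augment && (alpha > 0 || beta > 0)) {
      aug_seeds <- derive_seeds(seeds[e], nrow(Xtr0))
      for (i in seq_len(nrow(Xtr0))) {
        r <- array(Xtr0[i, ] * 255, c(input_px, input_px, 3))
        Xtr[i, ] <- as.vector(stain_augment(r, alpha, beta,
                                            seed = aug_seeds[i])) / 255
      }
    }
    fit <- with_seed(seeds[e],
      nnet::nnet(project(Xtr), yind, size = hidden, softmax = TRUE,
                 Wts = wts, weights = w, maxit = maxit, decay = 5e-4,
                 MaxNWts = nw + 1, trace = FALSE))
    wts <- fit$wts
    pv <- predict(fit, Xval)
    acc <- mean(classes[max.col(pv, ties.method = "first")] ==
                as.character(yval))
    log <- rbind(log, data.frame(epoch = e, val_accuracy = acc))
    if (acc > best$acc) best <- list(wts = wts, acc = acc, epoch = e)
  }
  final_wts <- if (epochs > 0) best$wts else wts
  net <- with_seed(seed,
    nnet::nnet(project(Xtr0), yind, size = hidden, softmax = TRUE,
               Wts = final_wts, weights = w, maxit = 0, decay = 5e-4,
               MaxNWts = nw + 1, trace = FALSE))
  structure(list(net = net, classes = classes, input_px = input_px,
                 hidden = hidden, pca_center = pca$center,
                 pca_rotation = pca$rotation, log = log,
                 best_epoch = if (epochs > 0) best$epoch else 0L),
            class = "cell_classifier")
}

#' Classify crops with a trained cell classifier
#'
#' @param classifier a `cell_classifier`.
#' @param crops list of crop rasters / `slide_patch`es.
#' @return list with `label` (character), `probs` (n x K matrix, rows
#'   sum to 1) and `embedding` (n x hidden matrix of penultimate-layer
#'   activations).
#' @export
predict_cells <- function(classifier, crops) {
  X <- crop_features(crops, classifier$input_px)
  X <- sweep(X, 2, classifier$pca_center) %*% classifier$pca_rotation
  probs <- predict(classifier$net, X)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(X))
  colnames(probs) <- classifier$classes
  d <- ncol(X); nh <- classifier$hidden
  W1 <- matrix(classifier$net$wts[seq_len((d + 1) * nh)], nrow = d + 1)
  emb <- 1 / (1 + exp(-(cbind(1, X) %*% W1)))
  list(label = classifier$classes[max.col(probs, ties.method = "first")],
       probs = probs, embedding = unname(emb))
}

#' Ground-truth oracle cell classifier
#'
#' Labels each nucleus with the class of the nearest ground-truth
#' nucleus; probabilities put mass `1 - eps` on the true class, and the
#' embedding is a fixed seeded 64-d class prototype.  Used to exercise
#' downstream stages without training.
#'
#' @param truth data.frame with `x`, `y`, `cell_class`.
#' @param classes class universe (default: classes present in truth).
#' @param embed_dim embedding dimension (default 64).
#' @param eps probability mass spread over non-true classes.
#' @param seed seed for the class prototypes.
#' @return an `oracle_cell_classifier`.
#' @export
oracle_cell_classifier <- function(truth, classes = NULL, embed_dim = 64,
                                   eps = 0.05, seed = 1L) {
  if (is.null(classes)) classes <- sort(unique(truth$cell_class))
  protos <- with_seed(seed,
    matrix(stats::rnorm(length(classes) * embed_dim), length(classes)))
  rownames(protos) <- classes
  structure(list(truth = truth, classes = classes, protos = protos,
                 eps = eps),
            class = "oracle_cell_classifier")
}

#' Classify all nuclei of a slide
#'
#' Crops a `size_px` image around every nucleus, classifies it, and
#' applies syncytial-knot post-processing.  Output order follows input
#' order (up to knot-cluster removals).
#'
#' @param handle a `slide_handle`.
#' @param nuclei data.frame of nucleus predictions (`x`, `y`,
#'   optionally `confidence`).
#' @param classifier a `cell_classifier` or `oracle_cell_classifier`.
#' @param size_px crop size.
#' @inheritParams read_patch
#' @param knot_radius_px,knot_min_neighbours see [knot_postprocess()];
#'   set `postprocess = FALSE` to skip.
#' @param postprocess apply [knot_postprocess()] (default TRUE).
#' @return a `cell_predictions` object: list with `nuclei` (data.frame
#'   `x`, `y`, `confidence`), `label`, `probs`, `embedding`.
#' @export
classify_cells <- function(handle, nuclei, classifier, size_px = 200,
                           target_mpp = HISTOCELL_MPP,
                           knot_radius_px = 50, knot_min_neighbours = 4,
                           postprocess = TRUE) {
  n <- nrow(nuclei)
  if (is.null(nuclei$confidence)) nuclei$confidence <- rep(1, n)
  if (n == 0) {
    classes <- if (inherits(classifier, "oracle_cell_classifier"))
      classifier$classes else classifier$classes
    out <- structure(list(nuclei = nuclei, label = character(0),
                          probs = matrix(numeric(0), 0, length(classes),
                                         dimnames = list(NULL, classes)),
                          embedding = matrix(numeric(0), 0, 0)),
                     class = "cell_predictions")
    return(out)
  }
  if (inherits(classifier, "oracle_cell_classifier")) {
    idx <- vapply(seq_len(n), function(i) {
      which.min((classifier$truth$x - nuclei$x[i])^2 +
                (classifier$truth$y - nuclei$y[i])^2)
    }, integer(1))
    label <- classifier$truth$cell_class[idx]
    K <- length(classifier$classes)
    probs <- matrix(classifier$eps / (K - 1), n, K,
                    dimnames = list(NULL, classifier$classes))
    if (K == 1) probs[] <- 1
    probs[cbind(seq_len(n), match(label, classifier$classes))] <-
      if (K == 1) 1 else 1 - classifier$eps
    emb <- classifier$protos[label, , drop = FALSE]
    rownames(emb) <- NULL
  } else {
    crops <- lapply(seq_len(n), function(i) {
      crop_cell_image(handle, nuclei$x[i], nuclei$y[i], size_px, target_mpp)
    })
    pr <- predict_cells(classifier, crops)
    label <- pr$label; probs <- pr$probs; emb <- pr$embedding
  }
  preds <- structure(list(nuclei = nuclei, label = label, probs = probs,
                          embedding = emb),
                     class = "cell_predictions")
  if (postprocess) {
    preds <- knot_postprocess(preds, knot_radius_px, knot_min_neighbours)
  }
  preds
}

#' @exportS3Method base::print
print.cell_predictions <- function(x, ...) {
  cat(sprintf("<cell_predictions> %d cells, %d classes\n",
              nrow(x$nuclei), ncol(x$probs)))
  print(table(x$label))
  invisible(x)
}

subset_cell_predictions <- function(preds, keep) {
  structure(list(nuclei = preds$nuclei[keep, , drop = FALSE],
                 label = preds$label[keep],
                 probs = preds$probs[keep, , drop = FALSE],
                 embedding = preds$embedding[keep, , drop = FALSE]),
            class = "cell_predictions")
}

#' Syncytial-knot post-processing
#'
#' Single pass over the original prediction set, using only
#' syncytial-knot predictions.  For each knot, the count of *other*
#' knots within Euclidean distance `<= radius_px` is computed.  Knots
#' with fewer than `min_neighbours` such neighbours are relabelled as
#' syncytiotrophoblast (their knot probability mass is moved to the
#' syncytiotrophoblast column so the label stays the argmax).  The
#' remaining knots are processed in descending neighbour count (ties:
#' lower y, then lower x): each centre not already removed keeps a
#' single syncytial-knot point and removes its in-radius knot
#' neighbours.  Non-knot predictions are untouched.
#'
#' @param preds a `cell_predictions` object.
#' @param radius_px neighbourhood radius (inclusive boundary).
#' @param min_neighbours relabel threshold.
#' @param knot_class,sync_class class names used.
#' @return the filtered/relabelled `cell_predictions`.
#' @export
knot_postprocess <- function(preds, radius_px = 50, min_neighbours = 4,
                             knot_class = "syncytial_knot",
                             sync_class = "syncytiotrophoblast") {
  kn <- which(preds$label == knot_class)
  if (length(kn) == 0) return(preds)
  x <- preds$nuclei$x[kn]; y <- preds$nuclei$y[kn]
  m <- length(kn)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  within <- d2 <= radius_px^2
  diag(within) <- FALSE
  cnt <- rowSums(within)

  relabel <- cnt < min_neighbours
  removed <- logical(m)
  centres <- which(!relabel)
  centres <- centres[order(-cnt[centres], y[centres], x[centres])]
  for (c0 in centres) {
    if (removed[c0]) next
    nb <- which(within[c0, ] & !relabel)
    removed[nb] <- TRUE
    removed[c0] <- FALSE
  }

  if (any(relabel)) {
    ridx <- kn[relabel]
    preds$label[ridx] <- sync_class
    if (sync_class %in% colnames(preds$probs)) {
      kc <- match(knot_class, colnames(preds$probs))
      sc <- match(sync_class, colnames(preds$probs))
      preds$probs[ridx, sc] <- preds$probs[ridx, sc] + preds$probs[ridx, kc]
      preds$probs[ridx, kc] <- 0
    }
  }
  keep <- rep(TRUE, nrow(preds$nuclei))
  keep[kn[removed]] <- FALSE
  subset_cell_predictions(preds, keep)
}

# Rank-based (Mann-Whitney) area under the ROC curve with tie handling.
binary_auc <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# Average precision (area under the precision-recall curve), computed
# over the score-ranked list with ties grouped.
average_precision <- function(scores, positive) {
  np <- sum(positive)
  if (np == 0) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; p <- positive[ord]
  groups <- cumsum(!duplicated(s))
  tp_g <- tapply(as.numeric(p), groups, sum)
  n_g <- tapply(rep(1, length(p)), groups, sum)
  tp <- cumsum(tp_g); nsel <- cumsum(n_g)
  prec <- tp / nsel
  rec <- tp / np
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Evaluate cell classification
#'
#' @param labels predicted labels.
#' @param truth true labels.
#' @param probs n x K probability matrix with class column names.
#' @param k top-k accuracy level (default 2).
#' @return list with `accuracy`, `topk_accuracy`, `macro_roc_auc`
#'   (mean one-vs-rest AUC over classes present in truth),
#'   `confusion` (counts, truth rows), `per_class` (precision/recall).
#' @export
evaluate_cells <- function(labels, truth, probs, k = 2) {
  if (length(labels) != length(truth)) stopf("length mismatch")
  classes <- colnames(probs)
  acc <- mean(labels == truth)
  ord <- t(apply(probs, 1, function(p) order(-p, seq_along(p))))
  topk <- mean(vapply(seq_along(truth), function(i) {
    match(truth[i], classes) %in% ord[i, seq_len(min(k, ncol(probs)))]
  }, logical(1)))
  present <- intersect(classes, unique(truth))
  aucs <- vapply(present, function(cl) {
    binary_auc(probs[, cl], truth == cl)
  }, numeric(1))
  conf <- table(factor(truth, levels = classes),
                factor(labels, levels = classes))
  per_class <- data.frame(
    class = classes,
    precision = vapply(classes, function(cl) {
      denom <- sum(labels == cl)
      if (denom == 0) NA_real_ else sum(labels == cl & truth == cl) / denom
    }, numeric(1)),
    recall = vapply(classes, function(cl) {
      denom <- sum(truth == cl)
      if (denom == 0) NA_real_ else sum(labels == cl & truth == cl) / denom
    }, numeric(1)),
    row.names = NULL)
  list(accuracy = acc, topk_accuracy = topk,
       macro_roc_auc = mean(aucs, na.rm = TRUE),
       confusion = conf, per_class = per_class)
}
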