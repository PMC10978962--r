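# Inductive tissue classification: a sample-and-aggregate (GraphSAGE-mean)
# message-passing network over the whole-slide cell graph, trained with
# inverse-frequency weighted cross entropy, neighbour sampling during
# training, and best-validation-accuracy model selection on a k = 8
# intersection graph evaluated without sampling.

#' GNN configuration
#'
#' The `desk` profile (default) is sized for laptop-scale synthetic
#' graphs; the `paper` profile carries the full-scale defaults (16
#' layers, 256 hidden units, 2000 epochs, lr 0.001, batch 200,
#' neighbour sample 400).
#'
#' @param profile "desk" or "paper".
#' @param layers,hidden,epochs,lr,batch_nodes,neighbour_sample,val_every,seed
#'   overrides for individual fields.
#' @return list of class `gnn_config`.
#' @export
gnn_config <- function(profile = c("desk", "paper"), layers = NULL,
                       hidden = NULL, epochs = NULL, lr = NULL,
                       batch_nodes = NULL, neighbour_sample = NULL,
                       val_every = NULL, seed = 1L) {
  profile <- match.arg(profile)
  base <- if (profile == "paper") {
    list(layers = 16L, hidden = 256L, epochs = 2000L, lr = 0.001,
         batch_nodes = 200L, neighbour_sample = 400L, val_every = 25L)
  } else {
    list(layers = 4L, hidden = 64L, epochs = 200L, lr = 0.01,
         batch_nodes = 200L, neighbour_sample = 400L, val_every = 10L)
  }
  ov <- list(layers = layers, hidden = hidden, epochs = epochs, lr = lr,
             batch_nodes = batch_nodes, neighbour_sample = neighbour_sample,
             val_every = val_every)
  for (f in names(ov)) if (!is.null(ov[[f]])) base[[f]] <- ov[[f]]
  stopifnot(base$layers >= 1, base$hidden >= 1, base$epochs >= 0,
            base$lr > 0, base$batch_nodes >= 1, base$neighbour_sample >= 1)
  base$profile <- profile
  base$seed <- as.integer(seed)
  structure(base, class = "gnn_config")
}

#' Inverse-frequency class weights for the loss
#'
#' `weight(c) = 1 / count(c)`, normalised to mean 1 over the classes
#' present; with balanced labels all weights are exactly 1 and the
#' weighted cross entropy coincides with the unweighted one.
#'
#' @param labels integer or factor class labels.
#' @param n_classes class universe size (default: max label).
#' @return numeric weight vector of length `n_classes` (absent classes
#'   get weight 0).
#' @export
class_weights <- function(labels, n_classes = max(as.integer(labels))) {
  if (length(labels) == 0) stopf("empty labels")
  cnt <- tabulate(as.integer(labels), nbins = n_classes)
  w <- ifelse(cnt > 0, 1 / cnt, 0)
  w / mean(w[cnt > 0])
}

new_gnn_params <- function(d_in, hidden, layers, n_classes, seed) {
  with_seed(seed, {
    dims <- c(d_in, rep(hidden, layers))
    p <- list(W_self = vector("list", layers),
              W_neigh = vector("list", layers),
              b = vector("list", layers))
    for (l in seq_len(layers)) {
      sc <- sqrt(2 / dims[l])
      p$W_self[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sc),
                              dims[l], dims[l + 1])
      p$W_neigh[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sc),
                               dims[l], dims[l + 1])
      p$b[[l]] <- numeric(dims[l + 1])
    }
    p$W_out <- matrix(stats::rnorm(hidden * n_classes, 0, sqrt(2 / hidden)),
                      hidden, n_classes)
    p$b_out <- numeric(n_classes)
    p
  })
}

# Forward pass.  A is the row-normalised neighbour-mean operator
# (self-loops included); keep_cache retains pre-activations for backprop.
gnn_forward <- function(params, X, A, keep_cache = FALSE) {
  L <- length(params$W_self)
  H <- X
  cache <- if (keep_cache) list(H = vector("list", L + 1)) else NULL
  if (keep_cache) cache$H[[1]] <- H
  for (l in seq_len(L)) {
    M <- as.matrix(A %*% H)
    pre <- H %*% params$W_self[[l]] + M %*% params$W_neigh[[l]]
    pre <- sweep(pre, 2, params$b[[l]], "+")
    H <- pmax(pre, 0)
    if (keep_cache) {
      cache$M <- c(cache$M, list(M))
      cache$pre <- c(cache$pre, list(pre))
      cache$H[[l + 1]] <- H
    }
  }
  logits <- sweep(H %*% params$W_out, 2, params$b_out, "+")
  list(logits = logits, cache = cache)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

gnn_backward <- function(params, A, cache, G_logits) {
  L <- length(params$W_self)
  g <- list(W_self = vector("list", L), W_neigh = vector("list", L),
            b = vector("list", L))
  H_L <- cache$H[[L + 1]]
  g$W_out <- t(H_L) %*% G_logits
  g$b_out <- colSums(G_logits)
  G <- G_logits %*% t(params$W_out)
  At <- Matrix::t(A)
  for (l in rev(seq_len(L))) {
    G <- G * (cache$pre[[l]] > 0)
    g$W_self[[l]] <- t(cache$H[[l]]) %*% G
    g$W_neigh[[l]] <- t(cache$M[[l]]) %*% G
    g$b[[l]] <- colSums(G)
    if (l > 1) {
      G <- G %*% t(params$W_self[[l]]) +
        as.matrix(At %*% (G %*% t(params$W_neigh[[l]])))
    }
  }
  g
}

# Flatten/unflatten parameter lists for the Adam update.
flatten_params <- function(p) {
  unlist(list(unlist(p$W_self), unlist(p$W_neigh), unlist(p$b),
              as.vector(p$W_out), p$b_out))
}

apply_flat <- function(p, flat) {
  i <- 0L
  take <- function(n) {
    v <- flat[i + seq_len(n)]
    i <<- i + n
    v
  }
  for (l in seq_along(p$W_self)) {
    p$W_self[[l]][] <- take(length(p$W_self[[l]]))
  }
  for (l in seq_along(p$W_neigh)) {
    p$W_neigh[[l]][] <- take(length(p$W_neigh[[l]]))
  }
  for (l in seq_along(p$b)) p$b[[l]][] <- take(length(p$b[[l]]))
  p$W_out[] <- take(length(p$W_out))
  p$b_out[] <- take(length(p$b_out))
  p
}

#' Weighted cross-entropy loss
#'
#' Mean over items of `w[y_i] * (-log p_i[y_i])`.  With uniform weights
#' this equals the unweighted cross entropy.
#'
#' @param probs n x K probability matrix.
#' @param y integer labels.
#' @param w per-class weights (default uniform).
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probs, y, w = rep(1, ncol(probs))) {
  p <- pmax(probs[cbind(seq_along(y), y)], 1e-12)
  mean(w[y] * (-log(p)))
}

#' Train the tissue GNN
#'
#' Trains the sample-and-aggregate node classifier with neighbour
#' sampling (uniform without replacement, capped at
#' `neighbour_sample` per node, resampled each epoch), a `batch_nodes`
#' subsample of training nodes per step, and inverse-frequency weighted
#' cross entropy, optimised with Adam.  Model selection follows the
#' validation protocol: highest validation accuracy computed *without*
#' neighbourhood sampling on a k = 8 intersection graph built from the
#' same nodes.  Inference (and the test graph) uses the k = 5 graph.
#'
#' @param graph a `cell_graph` with `labels` and `masks` (logical
#'   `train` and `val`).
#' @param config a [gnn_config()].
#' @param n_classes number of tissue classes (default: max label).
#' @return object of class `tissue_gnn`: `params`, `config`,
#'   `n_classes`, `feat_center`/`feat_scale`, `log` (per-evaluation
#'   validation accuracy), `best_epoch`.
#' @export
train_tissue_gnn <- function(graph, config = gnn_config(),
                             n_classes = max(graph$labels)) {
  if (is.null(graph$labels) || is.null(graph$masks)) {
    stopf("graph needs labels and train/val masks")
  }
  train_idx <- which(graph$masks$train)
  if (length(train_idx) == 0) stopf("no labelled training nodes")
  val_idx <- which(graph$masks$val)
  y <- as.integer(graph$labels)

  ctr <- colMeans(graph$features[train_idx, , drop = FALSE])
  scl <- apply(graph$features[train_idx, , drop = FALSE], 2, stats::sd)
  scl[scl < 1e-8] <- 1
  X <- sweep(sweep(graph$features, 2, ctr), 2, scl, "/")

  params <- new_gnn_params(ncol(X), config$hidden, config$layers,
                           n_classes, config$seed)
  model <- structure(list(params = params, config = config,
                          n_classes = n_classes, feat_center = ctr,
                          feat_scale = scl,
                          log = data.frame(epoch = integer(0),
                                           val_accuracy = numeric(0)),
                          best_epoch = 0L),
                     class = "tissue_gnn")
  if (config$epochs == 0) return(model)

  w <- class_weights(y[train_idx], n_classes)
  # validation graph: k = 8 intersection over the same nodes, full
  # neighbourhoods (no sampling)
  A_val <- NULL
  if (length(val_idx) > 0) {
    g8 <- build_graph(graph$coords, NULL, k = 8)
    A_val <- graph_mean_operator(g8)
  }

  flat <- flatten_params(params)
  m_t <- numeric(length(flat)); v_t <- numeric(length(flat))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(flat = flat, acc = -Inf, epoch = 0L)
  seeds <- derive_seeds(config$seed, config$epochs)
  log <- model$log

  for (e in seq_len(config$epochs)) {
    A_s <- graph_mean_operator(graph, sample_size = config$neighbour_sample,
                               seed = seeds[e])
    batch <- with_seed(seeds[e] + 1L, {
      if (length(train_idx) <= config$batch_nodes) train_idx
      else sample(train_idx, config$batch_nodes)
    })
    fw <- gnn_forward(params, X, A_s, keep_cache = TRUE)
    P <- softmax_rows(fw$logits)
    G <- matrix(0, nrow(P), ncol(P))
    Yb <- matrix(0, length(batch), n_classes)
    Yb[cbind(seq_along(batch), y[batch])] <- 1
    G[batch, ] <- (P[batch, , drop = FALSE] - Yb) *
      (w[y[batch]] / length(batch))
    grads <- gnn_backward(params, A_s, fw$cache, G)
    gflat <- flatten_params(grads)
    m_t <- beta1 * m_t + (1 - beta1) * gflat
    v_t <- beta2 * v_t + (1 - beta2) * gflat^2
    mhat <- m_t / (1 - beta1^e); vhat <- v_t / (1 - beta2^e)
    flat <- flat - config$lr * mhat / (sqrt(vhat) + eps)
    params <- apply_flat(params, flat)

    if (length(val_idx) > 0 &&
        (e %% config$val_every == 0 || e == config$epochs)) {
      pv <- gnn_forward(params, X, A_val)$logits
      acc <- mean(max.col(pv[val_idx, , drop = FALSE],
                          ties.method = "first") == y[val_idx])
      log <- rbind(log, data.frame(epoch = e, val_accuracy = acc))
      if (acc > best$acc) best <- list(flat = flat, acc = acc, epoch = e)
    }
  }
  if (best$epoch > 0) params <- apply_flat(params, best$flat)
  model$params <- params
  model$log <- log
  model$best_epoch <- if (best$epoch > 0) best$epoch else config$epochs
  model
}

#' Predict tissue classes for every node
#'
#' Full-neighbourhood (no sampling) deterministic inference on the
#' graph as given.
#'
#' @param graph a `cell_graph` whose feature dimension matches the
#'   model.
#' @param model a `tissue_gnn`.
#' @param tissue_names optional class names for the output.
#' @return list with `label` (integer class per node, or names if
#'   given) and `probs` (n x K matrix).
#' @export
predict_tissues <- function(graph, model, tissue_names = NULL) {
  if (ncol(graph$features) != length(model$feat_center)) {
    stopf("feature dimension %d does not match model (%d)",
          ncol(graph$features), length(model$feat_center))
  }
  X <- sweep(sweep(graph$features, 2, model$feat_center), 2,
             model$feat_scale, "/")
  A <- graph_mean_operator(graph)
  logits <- gnn_forward(model$params, X, A)$logits
  probs <- softmax_rows(logits)
  lab <- max.col(probs, ties.method = "first")
  if (!is.null(tissue_names)) {
    colnames(probs) <- tissue_names
    lab <- tissue_names[lab]
  }
  list(label = lab, probs = probs)
}

#' Evaluate tissue classification
#'
#' Accuracy, top-2/top-3 accuracy, macro ROC AUC, per-class PR-AUC
#' (average precision over the one-vs-rest precision-recall curve) and
#' the row-proportion confusion matrix (each truth row normalised by
#' its sample count).
#'
#' @param labels predicted labels (integer or names matching `probs`
#'   columns).
#' @param truth true labels.
#' @param probs n x K probability matrix.
#' @return list with `accuracy`, `top2_accuracy`, `top3_accuracy`,
#'   `macro_roc_auc`, `pr_auc` (per class), `confusion_prop`.
#' @export
evaluate_tissues <- function(labels, truth, probs) {
  if (length(labels) != length(truth)) stopf("length mismatch")
  K <- ncol(probs)
  classes <- colnames(probs)
  if (is.null(classes)) {
    classes <- as.character(seq_len(K))
    colnames(probs) <- classes
  }
  labels <- as.character(labels); truth <- as.character(truth)
  ord <- t(apply(probs, 1, function(p) order(-p, seq_along(p))))
  topk <- function(k) {
    mean(vapply(seq_along(truth), function(i) {
      match(truth[i], classes) %in% ord[i, seq_len(min(k, K))]
    }, logical(1)))
  }
  present <- intersect(classes, unique(truth))
  aucs <- vapply(present, function(cl) binary_auc(probs[, cl], truth == cl),
                 numeric(1))
  prauc <- vapply(classes, function(cl) {
    if (!cl %in% present) return(NA_real_)
    average_precision(probs[, cl], truth == cl)
  }, numeric(1))
  conf <- table(factor(truth, levels = classes),
                factor(labels, levels = classes))
  rs <- rowSums(conf)
  conf_prop <- sweep(unclass(conf), 1, ifelse(rs == 0, 1, rs), "/")
  list(accuracy = mean(labels == truth),
       top2_accuracy = topk(2), top3_accuracy = topk(3),
       macro_roc_auc = mean(aucs, na.rm = TRUE),
       pr_auc = prauc, confusion_prop = conf_prop)
}
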