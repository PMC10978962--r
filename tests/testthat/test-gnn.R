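# GNN tissue classification: loss weights, message passing mechanics,
# and evaluation metrics.

path_graph <- function(n, d = 3) {
  g <- structure(list(coords = cbind(seq_len(n), 0),
                      features = matrix(0, n, d),
                      edges = cbind(seq_len(n - 1), 2:n),
                      n = n, k = 1, labels = NULL, masks = NULL),
                 class = "cell_graph")
  g
}

test_that("class weights are inverse-frequency with mean one", {
  expect_equal(class_weights(rep(1:3, each = 10)), rep(1, 3))
  expect_equal(class_weights(c(rep(1, 75), rep(2, 25))), c(0.5, 1.5))
  expect_equal(class_weights(rep(1, 9), n_classes = 1), 1)
  expect_error(class_weights(integer(0)), "empty")
})

test_that("uniformly weighted cross entropy equals the unweighted loss", {
  set.seed(41)
  probs <- matrix(runif(30), 10, 3)
  probs <- probs / rowSums(probs)
  y <- sample(1:3, 10, TRUE)
  expect_equal(weighted_cross_entropy(probs, y, rep(1, 3)),
               mean(-log(probs[cbind(1:10, y)])), tolerance = 1e-6)
  # reweighting changes the loss when classes are imbalanced
  expect_false(isTRUE(all.equal(
    weighted_cross_entropy(probs, y, c(2, 0.5, 0.5)),
    weighted_cross_entropy(probs, y))))
})

test_that("zero-epoch training returns an initialised model, empty log", {
  g <- generate_synthetic_cell_graph(80, 2, class_sep = 2, seed = 21)
  g$masks <- list(train = rep(TRUE, g$n), val = rep(FALSE, g$n),
                  test = rep(FALSE, g$n))
  m <- train_tissue_gnn(g, gnn_config(epochs = 0, seed = 3))
  expect_equal(nrow(m$log), 0)
  expect_equal(m$best_epoch, 0L)
  pr <- predict_tissues(g, m)
  expect_equal(length(pr$label), g$n)
  expect_error(train_tissue_gnn(
    structure(list(labels = NULL, masks = NULL), class = "cell_graph")),
    "labels")
})

test_that("the receptive field is bounded by the number of layers", {
  n <- 9
  g <- path_graph(n)
  g$features <- matrix(rnorm(n * 3), n, 3)
  g$labels <- rep(1:2, length.out = n)
  g$masks <- list(train = rep(TRUE, n), val = rep(FALSE, n))
  m <- train_tissue_gnn(g, gnn_config(layers = 2, hidden = 8, epochs = 3,
                                      seed = 5))
  base <- predict_tissues(g, m)$probs
  # perturb node 9's features: nodes 1..6 are > 2 hops away on the path
  g2 <- g
  g2$features[9, ] <- g2$features[9, ] + 100
  pert <- predict_tissues(g2, m)$probs
  expect_equal(pert[1:6, ], base[1:6, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pert[9, ], base[9, ])))
})

test_that("inference is deterministic and permutation equivariant", {
  g <- generate_synthetic_cell_graph(150, 3, class_sep = 3, seed = 22)
  g$masks <- list(train = rep(TRUE, g$n), val = rep(FALSE, g$n))
  m <- train_tissue_gnn(g, gnn_config(epochs = 10, seed = 6))
  p1 <- predict_tissues(g, m)
  p2 <- predict_tissues(g, m)
  expect_identical(p1$probs, p2$probs)

  perm <- sample(g$n)
  inv <- order(perm)
  gp <- g
  gp$coords <- g$coords[perm, ]
  gp$features <- g$features[perm, ]
  remap <- inv[g$edges]
  dim(remap) <- dim(g$edges)
  gp$edges <- remap
  pp <- predict_tissues(gp, m)
  expect_equal(pp$probs[inv, ], p1$probs, tolerance = 1e-10)
})

test_that("an analytic one-hot model recovers labels exactly", {
  # features are one-hot tissue labels; a single layer with identity
  # self-weights and zero neighbour weights must echo them
  n <- 30; K <- 3
  set.seed(44)
  labels <- sample(seq_len(K), n, TRUE)
  feats <- diag(K)[labels, ]
  g <- build_graph(rand_points(n, seed = 45), feats, k = 5)
  params <- list(W_self = list(10 * diag(K)),
                 W_neigh = list(matrix(0, K, K)),
                 b = list(numeric(K)),
                 W_out = 10 * diag(K), b_out = numeric(K))
  model <- structure(list(params = params,
                          config = gnn_config(layers = 1, hidden = K),
                          n_classes = K,
                          feat_center = numeric(K),
                          feat_scale = rep(1, K)),
                     class = "tissue_gnn")
  pr <- predict_tissues(g, model)
  expect_equal(pr$label, labels)

  # single node: prediction from its own features via the self-loop
  g1 <- build_graph(matrix(c(0, 0), 1, 2), matrix(c(0, 1, 0), 1, 3))
  expect_equal(predict_tissues(g1, model)$label, 2L)

  # feature-dimension mismatch is caught
  gbad <- build_graph(rand_points(5, seed = 1), matrix(0, 5, 7))
  expect_error(predict_tissues(gbad, model), "dimension")
})

test_that("tissue metrics match hand-computed values", {
  probs <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.2, 0.2, 0.6))
  colnames(probs) <- c("a", "b", "c")
  ev <- evaluate_tissues(c("a", "b", "c"), c("a", "b", "c"), probs)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$top2_accuracy, 1)
  expect_equal(ev$top3_accuracy, 1)
  expect_equal(ev$macro_roc_auc, 1)
  expect_equal(unname(ev$pr_auc), rep(1, 3))
  expect_equal(unname(diag(ev$confusion_prop)), rep(1, 3))

  # 6-item binary average precision, hand-enumerated:
  # scores ranked 0.9(+) 0.8(-) 0.7(+) 0.6(+) 0.4(-) 0.2(-)
  # AP = (1/3)*(1/1) + (1/3)*(2/3) + (1/3)*(3/4) = 0.80555...
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  pos <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  probs6 <- cbind(a = scores, b = 1 - scores)
  truth6 <- ifelse(pos, "a", "b")
  ev6 <- evaluate_tissues(truth6, truth6, probs6)
  expect_equal(unname(ev6$pr_auc["a"]), 1 / 3 + 2 / 9 + 1 / 4,
               tolerance = 1e-12)

  # confusion rows are proportions relative to per-class sample counts
  ev7 <- evaluate_tissues(c("a", "a", "b", "b"), c("a", "a", "a", "b"),
                          cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1)))
  expect_equal(unname(ev7$confusion_prop["a", ]), c(2 / 3, 1 / 3))
})
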