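# Cell crops, stain augmentation, oversampling, classification and
# syncytial-knot post-processing.

test_that("cell crops are centred, fixed-size and white-padded", {
  h <- test_slide()$handle
  p <- crop_cell_image(h, 100, 100, size_px = 200)
  expect_equal(p$origin, c(x = 0, y = 0))
  expect_equal(dim(p$pixels), c(200, 200, 3))

  # near the corner: out-of-slide area filled with 255
  p2 <- crop_cell_image(h, 10, 10, size_px = 200)
  expect_equal(p2$origin, c(x = -90, y = -90))
  expect_true(all(p2$pixels[, 1:90, ] == 255))
  expect_true(all(p2$pixels[1:90, , ] == 255))
  expect_equal(dim(p2$pixels), c(200, 200, 3))

  expect_error(crop_cell_image(h, -5, 10), "outside")
  expect_error(crop_cell_image(h, 10, 1e5), "outside")
})

test_that("stain augmentation is an identity at zero and bounded always", {
  img <- test_slide()$slide$pixels[1:80, 1:80, , drop = FALSE]
  expect_lte(max(abs(stain_augment(img, 0, 0) - img)), 2)

  a1 <- stain_augment(img, 0.2, 0.2, seed = 7)
  a2 <- stain_augment(img, 0.2, 0.2, seed = 7)
  expect_identical(a1, a2)
  expect_false(identical(a1, stain_augment(img, 0.2, 0.2, seed = 8)))

  expect_equal(dim(a1), dim(img))
  expect_true(min(a1) >= 0 && max(a1) <= 255)
  expect_error(stain_augment(img, -0.1, 0), ">= 0")

  # mid-gray image stays within the analytic range implied by the jitter
  gray <- array(128, c(10, 10, 3))
  for (s in 1:5) {
    out <- stain_augment(gray, 0.2, 0, seed = s)
    expect_true(all(out >= 0 & out <= 255))
    # multiplicative-only jitter at alpha=0.2 moves OD by at most 20%
    od_in <- -log((128 + 1) / 256)
    expect_lte(max(abs(-log((out + 1) / 256) - od_in)), 0.25 * od_in + 0.02)
  }
})

test_that("oversampling weights equalise class frequencies", {
  w <- balance_by_oversampling(c(rep("A", 90), rep("B", 10)))
  expect_equal(w[100] / w[1], 9)
  expect_true(all(balance_by_oversampling(rep("A", 5)) ==
                  balance_by_oversampling(rep("A", 5))[1]))
  expect_error(balance_by_oversampling(character(0)), "empty")

  labels <- c(rep("A", 50), rep("B", 25), rep("C", 25))
  w <- balance_by_oversampling(labels)
  set.seed(3)
  draws <- sample(labels, 1e5, replace = TRUE, prob = w)
  expect_equal(as.numeric(table(draws) / 1e5), rep(1 / 3, 3),
               tolerance = 0.03)
  # scale invariance
  expect_equal(w / sum(w), (w * 17) / sum(w * 17))
})

test_that("knot post-processing relabels isolates and collapses clusters", {
  mk <- function(df) {
    K <- c("syncytial_knot", "syncytiotrophoblast", "fibroblast")
    probs <- matrix(0.05, nrow(df), 3, dimnames = list(NULL, K))
    probs[cbind(seq_len(nrow(df)), match(df$label, K))] <- 0.9
    structure(list(nuclei = data.frame(x = df$x, y = df$y, confidence = 1),
                   label = df$label, probs = probs,
                   embedding = matrix(0, nrow(df), 4)),
              class = "cell_predictions")
  }
  # isolated knot -> syncytiotrophoblast
  iso <- mk(data.frame(x = 0, y = 0, label = "syncytial_knot"))
  out <- knot_postprocess(iso)
  expect_equal(out$label, "syncytiotrophoblast")
  expect_equal(which.max(out$probs[1, ]), 2L, ignore_attr = TRUE)

  # 6 knots within a 50 px disc -> one survivor
  ang <- seq(0, 2 * pi, length.out = 6)[-6]
  clus <- mk(data.frame(x = c(0, 20 * cos(ang)), y = c(0, 20 * sin(ang)),
                        label = "syncytial_knot"))
  out <- knot_postprocess(clus)
  expect_equal(sum(out$label == "syncytial_knot"), 1)
  expect_equal(nrow(out$nuclei), 1)

  # non-knot predictions untouched
  mixed <- mk(data.frame(x = c(0, 5, 10), y = 0, label = "fibroblast"))
  expect_identical(knot_postprocess(mixed)$label, mixed$label)

  # random configurations against the direct rule restatement
  set.seed(23)
  for (trial in 1:20) {
    n <- sample(3:20, 1)
    df <- data.frame(x = runif(n, 0, 150), y = runif(n, 0, 150),
                     label = sample(c("syncytial_knot", "fibroblast"),
                                    n, TRUE, prob = c(0.7, 0.3)))
    out <- knot_postprocess(mk(df), radius_px = 50, min_neighbours = 4)
    exp <- oracle_knot(df)
    expect_equal(out$label, exp$label[exp$keep])
    expect_equal(out$nuclei$x, df$x[exp$keep])
    # knot count never increases; non-knot counts preserved
    expect_lte(sum(out$label == "syncytial_knot"),
               sum(df$label == "syncytial_knot"))
    expect_equal(sum(out$label == "fibroblast"),
                 sum(df$label == "fibroblast"))
  }
})

test_that("a desk-scale classifier separates synthetic cell classes", {
  ts <- test_slide()
  truth <- ts$slide$truth$nuclei
  crops <- lapply(seq_len(nrow(truth)), function(i) {
    crop_cell_image(ts$handle, truth$x[i], truth$y[i], size_px = 64)
  })
  sp <- split_dataset(nrow(truth), ratios = c(0.7, 0.3, 0), seed = 4)
  ds <- list(train = list(crops = crops[sp$train],
                          labels = truth$cell_class[sp$train]),
             val = list(crops = crops[sp$val],
                        labels = truth$cell_class[sp$val]))
  cls <- train_cell_classifier(ds, schedule = list(epochs = 4, seed = 5))
  expect_gte(max(cls$log$val_accuracy), 0.9)
  expect_equal(cls$best_epoch, which.max(cls$log$val_accuracy))

  pr <- predict_cells(cls, crops[sp$val])
  expect_equal(ncol(pr$embedding), 64)
  expect_true(all(abs(rowSums(pr$probs) - 1) < 1e-6))
  expect_true(all(is.finite(pr$embedding)))

  # 0 epochs returns the randomly initialised classifier
  c0 <- train_cell_classifier(ds, schedule = list(epochs = 0, seed = 5))
  expect_equal(nrow(c0$log), 0)
  expect_equal(c0$best_epoch, 0L)

  # validation class absent from training is an error
  bad <- list(train = ds$train,
              val = list(crops = ds$val$crops,
                         labels = rep("leucocyte", length(sp$val))))
  expect_error(train_cell_classifier(bad, schedule = list(epochs = 1)),
               "absent")
})

test_that("oracle cell classification round-trips ground truth", {
  ts <- test_slide()
  truth <- ts$slide$truth$nuclei
  oc <- oracle_cell_classifier(truth, classes = cell_taxonomy()$class[1:4])
  nuc <- data.frame(x = truth$x, y = truth$y, confidence = 1)
  cp <- classify_cells(ts$handle, nuc, oc, postprocess = FALSE)
  expect_equal(cp$label, truth$cell_class)
  expect_true(all(abs(rowSums(cp$probs) - 1) < 1e-6))
  expect_equal(ncol(cp$embedding), 64)
  expect_equal(cp$label,
               colnames(cp$probs)[max.col(cp$probs, ties.method = "first")])

  empty <- classify_cells(ts$handle, nuc[0, ], oc)
  expect_equal(length(empty$label), 0)
})

test_that("cell metrics match hand-computed cases", {
  # perfect predictions
  probs <- diag(3); colnames(probs) <- c("a", "b", "c")
  ev <- evaluate_cells(c("a", "b", "c"), c("a", "b", "c"), probs)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$macro_roc_auc, 1)
  # top-k with k = number of classes is always 1
  ev2 <- evaluate_cells(c("a", "a", "a"), c("a", "b", "c"), probs, k = 3)
  expect_equal(ev2$topk_accuracy, 1)

  # hand-counted binary AUC: 4 items, scores 0.9 0.8 | 0.4 0.1 -> AUC 1;
  # swapping one pair -> 3 of 4 concordant pairs -> 0.75
  p1 <- cbind(a = c(0.9, 0.8, 0.4, 0.1), b = c(0.1, 0.2, 0.6, 0.9))
  tr <- c("a", "a", "b", "b")
  expect_equal(evaluate_cells(tr, tr, p1)$macro_roc_auc, 1)
  p2 <- p1[c(1, 3, 2, 4), ]
  expect_equal(evaluate_cells(tr, tr, p2)$macro_roc_auc, 0.75)

  # agreement with an independent ROC implementation
  set.seed(31)
  scores <- runif(40)
  labs <- sample(c("x", "y"), 40, TRUE)
  mine <- evaluate_cells(labs, labs, cbind(x = scores, y = 1 - scores))
  ref <- suppressMessages(pROC::auc(pROC::roc(labs == "x", scores,
                                              quiet = TRUE)))
  # macro AUC averages the two symmetric one-vs-rest AUCs
  expect_equal(mine$macro_roc_auc, as.numeric(ref), tolerance = 1e-10)

  expect_error(evaluate_cells(c("a"), c("a", "b"), probs), "mismatch")
})
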