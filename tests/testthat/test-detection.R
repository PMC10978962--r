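# Nucleus detection, duplicate merging and distance-thresholded F1.

test_that("duplicate merge keeps the higher-confidence member", {
  one <- data.frame(x = 5, y = 5, confidence = 0.7)
  expect_identical(merge_duplicates(one), one)

  two <- data.frame(x = c(0, 3), y = c(0, 0), confidence = c(0.9, 0.8))
  kept <- merge_duplicates(two, radius_px = 4)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)

  chain <- data.frame(x = c(0, 3, 6), y = 0, confidence = c(0.9, 0.8, 0.7))
  kept <- merge_duplicates(chain, radius_px = 4)
  expect_equal(sort(kept$x), c(0, 6))

  # distance exactly equal to the radius is kept (strict inequality)
  border <- data.frame(x = c(0, 4), y = c(0, 0), confidence = c(0.9, 0.8))
  expect_equal(nrow(merge_duplicates(border, radius_px = 4)), 2)
})

test_that("duplicate merge is idempotent, order-free and matches the rule", {
  set.seed(42)
  for (trial in 1:25) {
    n <- sample(2:20, 1)
    preds <- data.frame(x = runif(n, 0, 30), y = runif(n, 0, 30),
                        confidence = runif(n))
    kept <- merge_duplicates(preds, radius_px = 4)
    # survivors pairwise >= radius apart
    if (nrow(kept) > 1) {
      d <- as.matrix(dist(kept[, c("x", "y")]))
      expect_true(all(d[upper.tri(d)] >= 4))
    }
    # idempotent
    expect_equal(merge_duplicates(kept, 4), kept)
    # permutation invariant (as a set)
    perm <- preds[sample(n), ]
    kept2 <- merge_duplicates(perm, 4)
    expect_setequal(paste(kept$x, kept$y), paste(kept2$x, kept2$y))
    # equals the direct rule restatement
    expect_setequal(paste(kept$x, kept$y),
                    paste(preds$x[oracle_dedup(preds, 4)],
                          preds$y[oracle_dedup(preds, 4)]))
  }
})

test_that("detection F1 applies the strict micrometre threshold", {
  t1 <- data.frame(x = 0, y = 0)
  # at mpp = 1 the threshold is 3.3 um = 3.3 px
  expect_equal(evaluate_detection(data.frame(x = 3.2, y = 0), t1,
                                  mpp = 1)$f1, 1)
  expect_equal(evaluate_detection(data.frame(x = 3.4, y = 0), t1,
                                  mpp = 1)$f1, 0)
  # exact boundary excluded (strict <)
  expect_equal(evaluate_detection(data.frame(x = 3.3, y = 0), t1,
                                  mpp = 1)$f1, 0)

  p <- data.frame(x = c(1, 2, 10), y = 0)
  expect_equal(evaluate_detection(p, p)$f1, 1)
  expect_equal(evaluate_detection(p[0, ], p)$f1, 0)
  expect_error(evaluate_detection(p, p, max_dist_um = 0), "> 0")
})

test_that("matching equals the exhaustive optimum on small instances", {
  set.seed(11)
  for (trial in 1:60) {
    np <- sample(1:7, 1); nt <- sample(1:7, 1)
    pd <- data.frame(x = runif(np, 0, 10), y = runif(np, 0, 10))
    td <- data.frame(x = runif(nt, 0, 10), y = runif(nt, 0, 10))
    dmat <- sqrt(outer(pd$x, td$x, "-")^2 + outer(pd$y, td$y, "-")^2)
    ev <- evaluate_detection(pd, td, max_dist_um = 3.3, mpp = 1)
    opt <- oracle_matching(pd, td, dmat, 3.3)
    expect_equal(ev$tp, opt$card)
    expect_equal(sum(ev$matching$dist_um), opt$cost, tolerance = 1e-9)
  }
})

test_that("F1 is translation invariant and monotone in the threshold", {
  set.seed(12)
  pd <- data.frame(x = runif(15, 0, 50), y = runif(15, 0, 50))
  td <- data.frame(x = runif(12, 0, 50), y = runif(12, 0, 50))
  base <- evaluate_detection(pd, td, mpp = 1)
  shifted <- evaluate_detection(transform(pd, x = x + 100, y = y - 30),
                                transform(td, x = x + 100, y = y - 30),
                                mpp = 1)
  expect_equal(base$f1, shifted$f1)
  f1s <- vapply(c(0.5, 1, 2, 4, 8),
                function(d) evaluate_detection(pd, td, d, mpp = 1)$f1,
                numeric(1))
  expect_true(!is.unsorted(f1s))
})

test_that("oracle detection round-trips ground truth across patches", {
  ts <- test_slide()
  det <- oracle_detector(ts$slide$truth$nuclei)
  preds <- run_detection(ts$handle, det, width = 400, height = 300,
                         overlap = 100)
  truth <- ts$slide$truth$nuclei
  expect_equal(nrow(preds), nrow(truth))
  ev <- evaluate_detection(preds, truth)
  expect_equal(ev$f1, 1)
  expect_true(all(ev$matching$dist_um / 0.1109 < 1))  # within 1 px

  # a nucleus seen by two overlapping patches survives exactly once
  in_band <- truth[truth$x > 300 & truth$x < 400, ]
  if (nrow(in_band) > 0) {
    hits <- sapply(seq_len(nrow(in_band)), function(i) {
      sum(abs(preds$x - in_band$x[i]) < 1 & abs(preds$y - in_band$y[i]) < 1)
    })
    expect_true(all(hits == 1))
  }

  # blank slide yields nothing
  blank <- generate_synthetic_slide(
    synthetic_slide_config(width_px = 420, height_px = 320,
                           nucleus_density = 0, seed = 3L))
  bpath <- file.path(tempdir(), "blank.png")
  write_synthetic_slide(blank, bpath)
  expect_equal(nrow(run_detection(open_slide(bpath),
                                  oracle_detector(blank$truth$nuclei),
                                  width = 420, height = 320,
                                  overlap = 100)), 0)
})

test_that("detector calibration selects the best-validation epoch", {
  ts <- test_slide()
  patches <- iter_patches(ts$handle, width = 300, height = 250, overlap = 50)
  items <- lapply(patches, function(p) {
    tr <- ts$slide$truth$nuclei
    sel <- tr$x >= p$origin[1] & tr$x < p$origin[1] + 300 &
      tr$y >= p$origin[2] & tr$y < p$origin[2] + 250
    list(patch = p, centroids = data.frame(x = tr$x[sel] - p$origin[1],
                                           y = tr$y[sel] - p$origin[2]))
  })
  ds <- list(train = items[1:4], val = items[5:length(items)])

  d0 <- train_detector(ds, schedule = list(epochs = 0))
  expect_equal(nrow(attr(d0, "log")), 0)
  expect_equal(d0$threshold, blob_detector()$threshold)

  dt <- train_detector(ds, schedule = list(epochs = 12, seed = 2))
  log <- attr(dt, "log")
  expect_equal(nrow(log), 12)
  expect_equal(attr(dt, "best_epoch"), which.max(log$val_f1))
  expect_equal(dt$threshold, log$threshold[which.max(log$val_f1)])
  expect_gte(max(log$val_f1), 0.8)

  # end-to-end with the calibrated detector
  preds <- run_detection(ts$handle, dt, width = 400, height = 300,
                         overlap = 100)
  expect_gte(evaluate_detection(preds, ts$slide$truth$nuclei)$f1, 0.8)
})
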