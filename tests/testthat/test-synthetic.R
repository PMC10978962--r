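# Synthetic slide and cell-graph generators.

test_that("slide generation is reproducible and density-calibrated", {
  cfg <- synthetic_slide_config(width_px = 500, height_px = 400, seed = 5L)
  s1 <- generate_synthetic_slide(cfg)
  s2 <- generate_synthetic_slide(cfg)
  expect_identical(s1$pixels, s2$pixels)
  expect_identical(s1$truth$nuclei, s2$truth$nuclei)

  # zero density -> blank slide, all patches background
  s0 <- generate_synthetic_slide(
    synthetic_slide_config(width_px = 500, height_px = 400,
                           nucleus_density = 0, seed = 5L))
  expect_equal(nrow(s0$truth$nuclei), 0)
  expect_true(is_background(s0$pixels))

  # 1 mm^2 at 1 um/px, 500 / mm^2 -> Poisson count within +-20%
  s500 <- generate_synthetic_slide(
    synthetic_slide_config(width_px = 1000, height_px = 1000, mpp = 1,
                           nucleus_density = 500, min_sep_px = 5,
                           seed = 99L))
  expect_gte(nrow(s500$truth$nuclei), 400)
  expect_lte(nrow(s500$truth$nuclei), 600)
})

test_that("rendered blob centroids sit on the stored coordinates", {
  cfg <- synthetic_slide_config(width_px = 1000, height_px = 800,
                                nucleus_density = 1000, min_sep_px = 130,
                                seed = 17L)
  sl <- generate_synthetic_slide(cfg)
  nuc <- sl$truth$nuclei
  expect_gt(nrow(nuc), 2)
  gray <- (sl$pixels[, , 1] + sl$pixels[, , 2] + sl$pixels[, , 3]) / 3
  dark <- pmax(cfg$bg_value - gray, 0)
  for (i in seq_len(nrow(nuc))) {
    # intensity centroid inside a window around the stored coordinate
    x0 <- round(nuc$x[i]); y0 <- round(nuc$y[i]); w <- 40
    xs <- max(0, x0 - w):min(cfg$width_px - 1, x0 + w)
    ys <- max(0, y0 - w):min(cfg$height_px - 1, y0 + w)
    win <- dark[ys + 1, xs + 1]
    cx <- sum(outer(rep(1, length(ys)), xs) * win) / sum(win)
    cy <- sum(outer(ys, rep(1, length(xs))) * win) / sum(win)
    expect_lt(sqrt((cx - nuc$x[i])^2 + (cy - nuc$y[i])^2), 2)
  }
})

test_that("every nucleus carries the label of its containing region", {
  sl <- test_slide()$slide
  nuc <- sl$truth$nuclei
  for (reg in sl$truth$regions) {
    inside <- point_in_polygon(nuc$x, nuc$y, reg$polygon)
    expect_true(all(nuc$tissue_class[inside] == reg$tissue_class))
  }
})

test_that("GeoJSON annotations round-trip", {
  ts <- test_slide()
  geo <- paste0(tools::file_path_sans_ext(ts$path), "_annotations.geojson")
  ann <- read_annotations_geojson(geo)
  expect_equal(nrow(ann$nuclei), nrow(ts$slide$truth$nuclei))
  expect_equal(ann$nuclei$cell_class, ts$slide$truth$nuclei$cell_class)
  expect_equal(ann$nuclei$x, ts$slide$truth$nuclei$x, tolerance = 1e-9)
  expect_equal(length(ann$regions), length(ts$slide$truth$regions))
  expect_equal(ann$regions[[1]]$tissue_class,
               ts$slide$truth$regions[[1]]$tissue_class)
})

test_that("synthetic cell graphs are reproducible and class-separable", {
  g1 <- generate_synthetic_cell_graph(300, 3, class_sep = 4, seed = 8L)
  g2 <- generate_synthetic_cell_graph(300, 3, class_sep = 4, seed = 8L)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$features, g2$features)
  expect_error(generate_synthetic_cell_graph(100, 3, class_sep = -1), ">= 0")

  # separable case: a linear classifier on features alone is near-perfect
  g <- generate_synthetic_cell_graph(2000, 3, class_sep = 10, seed = 9L)
  tr <- seq_len(1000); te <- 1001:2000
  fit <- nnet::multinom(y ~ ., trace = FALSE, MaxNWts = 5000,
                        data = data.frame(y = factor(g$labels[tr]),
                                          g$features[tr, 1:10]))
  pred <- predict(fit, newdata = data.frame(g$features[te, 1:10]))
  expect_gte(mean(pred == g$labels[te]), 0.99)

  # null case: features carry no label signal beyond class frequencies
  g0 <- generate_synthetic_cell_graph(5000, 3, class_sep = 0, seed = 10L)
  fit0 <- nnet::multinom(y ~ ., trace = FALSE, MaxNWts = 5000,
                         data = data.frame(y = factor(g0$labels[1:2500]),
                                           g0$features[1:2500, 1:10]))
  pred0 <- predict(fit0, newdata = data.frame(g0$features[2501:5000, 1:10]))
  chance <- max(table(g0$labels[2501:5000])) / 2500
  expect_lte(mean(pred0 == g0$labels[2501:5000]), chance + 0.05)
})

test_that("dataset splits use largest-remainder rounding and partition", {
  s <- split_dataset(100, seed = 1)
  expect_equal(lengths(s), c(train = 70L, val = 15L, test = 15L))
  s20 <- split_dataset(20, seed = 2)
  expect_equal(lengths(s20), c(train = 14L, val = 3L, test = 3L))
  sdeg <- split_dataset(3, ratios = c(1, 0, 0), seed = 3)
  expect_equal(sort(sdeg$train), 1:3)
  expect_equal(length(sdeg$val), 0)
  expect_error(split_dataset(0), "empty")
  expect_error(split_dataset(10, ratios = c(0.5, 0.2, 0.2)), "sum to 1")

  for (n in c(1, 7, 33, 101)) {
    sp <- split_dataset(n, seed = n)
    all_idx <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(anyDuplicated(all_idx), 0)
  }
})
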