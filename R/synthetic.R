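# Synthetic histology fixtures: slides with nucleus blobs organised into
# contiguous tissue regions, plus synthetic cell graphs.  These emulate the
# statistical structure the pipeline assumes -- localized class-dependent
# nuclei on a pale background, spatial tissue organisation, per-tissue cell
# mixtures -- without attempting photorealistic histology.

#' Configuration for a synthetic slide
#'
#' @param width_px,height_px raster size in pixels.
#' @param mpp micrometres per pixel of the generated raster.
#' @param n_cell_classes number of cell classes used (first `n` of
#'   [cell_taxonomy()]), at most 11.
#' @param cell_class_names which taxonomy classes the fixture uses
#'   (default: the first `n_cell_classes`); override to e.g. exclude
#'   syncytial knots when downstream post-processing should be a no-op.
#' @param n_tissue_classes number of tissue regions classes (first `n` of
#'   [tissue_taxonomy()]), at most 9.
#' @param nucleus_density expected nuclei per square millimetre.
#' @param min_sep_px minimum separation between nucleus centres in pixels;
#'   default corresponds to 7 micrometres at `mpp`.
#' @param class_appearance data.frame with one row per cell class:
#'   `radius_um`, `r`, `g`, `b` (0..255 blob colour), `ecc` (axis ratio).
#' @param class_mixture matrix `n_tissue_classes x n_cell_classes`; each
#'   row a categorical distribution of cell classes within that tissue.
#' @param bg_value pale background grey value (0..255).
#' @param seed integer RNG seed; the whole slide is reproducible from it.
#' @return list of class `synthetic_slide_config`.
#' @export
synthetic_slide_config <- function(width_px = 1200, height_px = 900,
                                   mpp = HISTOCELL_MPP,
                                   n_cell_classes = 4, n_tissue_classes = 3,
                                   cell_class_names = NULL,
                                   nucleus_density = 4000,
                                   min_sep_px = NULL,
                                   class_appearance = NULL,
                                   class_mixture = NULL,
                                   bg_value = 248,
                                   seed = 1L) {
  stopifnot(n_cell_classes >= 1, n_cell_classes <= 11,
            n_tissue_classes >= 1, n_tissue_classes <= 9,
            nucleus_density >= 0, mpp > 0)
  if (is.null(min_sep_px)) min_sep_px <- 7 / mpp
  if (min_sep_px <= 0) stopf("min_sep_px must be > 0")
  if (is.null(cell_class_names)) {
    cell_class_names <- cell_taxonomy()$class[seq_len(n_cell_classes)]
  }
  stopifnot(length(cell_class_names) == n_cell_classes,
            all(cell_class_names %in% cell_taxonomy()$class))
  if (is.null(class_appearance)) {
    class_appearance <- default_class_appearance(11)[
      match(cell_class_names, cell_taxonomy()$class), , drop = FALSE]
  }
  if (is.null(class_mixture)) {
    class_mixture <- default_class_mixture(n_tissue_classes, n_cell_classes)
  }
  if (any(abs(rowSums(class_mixture) - 1) > 1e-9)) {
    stopf("class_mixture rows must sum to 1")
  }
  structure(list(width_px = width_px, height_px = height_px, mpp = mpp,
                 cell_class_names = cell_class_names,
                 n_cell_classes = n_cell_classes,
                 n_tissue_classes = n_tissue_classes,
                 nucleus_density = nucleus_density,
                 min_sep_px = min_sep_px,
                 class_appearance = class_appearance,
                 class_mixture = class_mixture,
                 bg_value = bg_value, seed = as.integer(seed)),
            class = "synthetic_slide_config")
}

# Distinct, dark, haematoxylin-like appearances: hue/size/eccentricity vary
# by class so an image classifier can separate them.
default_class_appearance <- function(n) {
  base <- data.frame(
    radius_um = c(3.2, 2.4, 2.0, 3.6, 2.8, 3.0, 2.2, 3.4, 2.6, 3.8, 2.1),
    r = c(70, 120, 50, 90, 140, 60, 110, 40, 150, 80, 100),
    g = c(40, 60, 30, 100, 70, 90, 40, 60, 90, 30, 110),
    b = c(140, 160, 100, 150, 110, 170, 130, 120, 100, 160, 180),
    ecc = c(1.0, 1.4, 1.0, 1.8, 2.2, 1.0, 1.5, 1.2, 1.0, 1.6, 1.1)
  )
  base[seq_len(n), , drop = FALSE]
}

# Each tissue concentrates on a few dominant cell classes (70/20/10 split
# over a rotating window), mimicking distinct per-tissue cell mixtures.
default_class_mixture <- function(n_tissue, n_cell) {
  m <- matrix(0, n_tissue, n_cell)
  for (t in seq_len(n_tissue)) {
    i1 <- ((t - 1) %% n_cell) + 1
    i2 <- (t %% n_cell) + 1
    m[t, i1] <- m[t, i1] + 0.7
    m[t, i2] <- m[t, i2] + 0.2
    m[t, ] <- m[t, ] + 0.1 / n_cell
  }
  m / rowSums(m)
}

#' Generate a synthetic slide with ground truth
#'
#' Places nuclei by Poisson-disk style rejection sampling (expected count
#' `density x area`, minimum separation `min_sep_px`), partitions the
#' slide into contiguous tissue regions by a seeded Voronoi tessellation,
#' draws each nucleus' cell class from its tissue's mixture, and renders
#' nuclei as dark anisotropic Gaussian blobs with class-dependent colour,
#' size and eccentricity on a pale background.
#'
#' @param config a [synthetic_slide_config()].
#' @return list of class `synthetic_slide` with `pixels` (H x W x 3,
#'   0..255), `truth` (list: `nuclei` data.frame with `x`, `y`,
#'   `cell_class`, `tissue_class`; `regions` list of polygons with a
#'   tissue class each), and `config`.
#' @export
generate_synthetic_slide <- function(config) {
  stopifnot(inherits(config, "synthetic_slide_config"))
  with_seed(config$seed, {
    W <- config$width_px; H <- config$height_px
    area_mm2 <- (W * config$mpp / 1000) * (H * config$mpp / 1000)
    n_target <- stats::rpois(1, config$nucleus_density * area_mm2)

    margin <- max(config$class_appearance$radius_um) / config$mpp * 3 + 1
    margin <- min(margin, W / 4, H / 4)
    pts <- place_poisson_disk(n_target, W, H, margin, config$min_sep_px)

    seeds <- cbind(stats::runif(config$n_tissue_classes, 0, W),
                   stats::runif(config$n_tissue_classes, 0, H))
    regions <- voronoi_regions(seeds, W, H)
    tissue_names <- tissue_taxonomy()$class[seq_len(config$n_tissue_classes)]
    cell_names <- config$cell_class_names
    for (i in seq_along(regions)) regions[[i]]$tissue_class <- tissue_names[i]

    if (nrow(pts) > 0) {
      tl <- nearest_seed(pts, seeds)
      cc <- vapply(tl, function(t) {
        sample.int(config$n_cell_classes, 1, prob = config$class_mixture[t, ])
      }, integer(1))
      nuclei <- data.frame(x = pts[, 1], y = pts[, 2],
                           cell_class = cell_names[cc],
                           tissue_class = tissue_names[tl],
                           stringsAsFactors = FALSE)
    } else {
      nuclei <- data.frame(x = numeric(0), y = numeric(0),
                           cell_class = character(0),
                           tissue_class = character(0))
    }

    pixels <- render_slide(nuclei, match(nuclei$cell_class, cell_names),
                           config)
    structure(list(pixels = pixels,
                   truth = list(nuclei = nuclei, regions = regions,
                                seeds = seeds),
                   config = config),
              class = "synthetic_slide")
  })
}

place_poisson_disk <- function(n_target, W, H, margin, min_sep) {
  if (n_target == 0) return(matrix(numeric(0), 0, 2))
  acc <- matrix(NA_real_, n_target, 2)
  n_acc <- 0L
  attempts <- 0L
  max_attempts <- 200L * n_target
  while (n_acc < n_target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stopf("cannot place %d nuclei with min separation %.1f px (placed %d)",
            n_target, min_sep, n_acc)
    }
    p <- c(stats::runif(1, margin, W - margin),
           stats::runif(1, margin, H - margin))
    if (n_acc > 0) {
      d2 <- (acc[1:n_acc, 1] - p[1])^2 + (acc[1:n_acc, 2] - p[2])^2
      if (min(d2) < min_sep^2) next
    }
    n_acc <- n_acc + 1L
    acc[n_acc, ] <- p
  }
  acc
}

nearest_seed <- function(pts, seeds) {
  d <- outer(pts[, 1], seeds[, 1], "-")^2 + outer(pts[, 2], seeds[, 2], "-")^2
  max.col(-d, ties.method = "first")
}

render_slide <- function(nuclei, class_idx, config) {
  W <- config$width_px; H <- config$height_px
  px <- array(config$bg_value, c(H, W, 3))
  if (nrow(nuclei) == 0) return(px)
  app <- config$class_appearance
  for (i in seq_len(nrow(nuclei))) {
    a <- app[class_idx[i], ]
    r_px <- a$radius_um / config$mpp
    theta <- stats::runif(1, 0, pi)
    px <- render_blob(px, nuclei$x[i], nuclei$y[i], r_px, a$ecc, theta,
                      c(a$r, a$g, a$b))
  }
  px
}

# Paint one anisotropic Gaussian blob; the kernel is symmetric about
# (cx, cy) so the rendered intensity centroid coincides with the stored
# nucleus coordinate.
render_blob <- function(px, cx, cy, radius, ecc, theta, colour) {
  H <- dim(px)[1]; W <- dim(px)[2]
  ext <- ceiling(radius * max(1, ecc) * 2.5)
  x0 <- max(0, floor(cx - ext)); x1 <- min(W - 1, ceiling(cx + ext))
  y0 <- max(0, floor(cy - ext)); y1 <- min(H - 1, ceiling(cy + ext))
  if (x1 < x0 || y1 < y0) return(px)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  s_major <- radius * sqrt(ecc) / 1.6
  s_minor <- radius / sqrt(ecc) / 1.6
  wgt <- exp(-0.5 * ((u / s_major)^2 + (v / s_minor)^2))
  wgt[wgt < 0.01] <- 0
  ry <- ys + 1; rx <- xs + 1
  for (ch in 1:3) {
    old <- px[ry, rx, ch]
    px[ry, rx, ch] <- old + wgt * (colour[ch] - old)
  }
  px
}

# Voronoi cell polygons clipped to the slide rectangle, by successive
# half-plane (Sutherland-Hodgman) clipping against each bisector.
voronoi_regions <- function(seeds, W, H) {
  n <- nrow(seeds)
  lapply(seq_len(n), function(i) {
    poly <- matrix(c(0, 0, W, 0, W, H, 0, H), ncol = 2, byrow = TRUE)
    for (j in seq_len(n)) {
      if (j == i) next
      mid <- (seeds[i, ] + seeds[j, ]) / 2
      nrm <- seeds[j, ] - seeds[i, ]   # keep side where (p-mid).nrm <= 0
      poly <- clip_halfplane(poly, mid, nrm)
      if (nrow(poly) == 0) break
    }
    list(polygon = poly, seed = seeds[i, ])
  })
}

clip_halfplane <- function(poly, q, nrm) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  d <- (poly[, 1] - q[1]) * nrm[1] + (poly[, 2] - q[2]) * nrm[2]
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- d[i] <= 1e-12; pj_in <- d[j] <= 1e-12
    if (pi_in) out <- rbind(out, poly[i, ])
    if (pi_in != pj_in) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Point-in-polygon test (ray casting)
#'
#' @param x,y point coordinates (vectorised).
#' @param poly polygon vertex matrix (n x 2), implicitly closed.
#' @return logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    # boundary tolerance: points essentially on the edge count as inside
    on_edge <- abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi)) < 1e-9 &
      x >= pmin(xi, xj) - 1e-9 & x <= pmax(xi, xj) + 1e-9 &
      y >= pmin(yi, yj) - 1e-9 & y <= pmax(yi, yj) + 1e-9
    inside <- inside | on_edge
    j <- i
  }
  inside
}

#' Write a synthetic slide to disk
#'
#' Writes the raster as PNG with a JSON micrometres-per-pixel sidecar,
#' and the ground truth as a QuPath-style GeoJSON FeatureCollection
#' (Point features with `classification$name` for nuclei, Polygon
#' features for tissue regions).
#'
#' @param slide a `synthetic_slide`.
#' @param path output PNG path; `<path>.json` and
#'   `<stem>_annotations.geojson` are written alongside.
#' @return invisibly, the paths written.
#' @export
write_synthetic_slide <- function(slide, path) {
  png::writePNG(slide$pixels / 255, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(mpp_x = slide$config$mpp,
                            mpp_y = slide$config$mpp),
                       sidecar, auto_unbox = TRUE, digits = NA)
  geo <- paste0(tools::file_path_sans_ext(path), "_annotations.geojson")
  write_annotations_geojson(slide$truth, geo)
  invisible(c(image = path, mpp = sidecar, annotations = geo))
}

#' @rdname write_synthetic_slide
#' @param truth ground-truth list (`nuclei` data.frame, `regions` list).
#' @export
write_annotations_geojson <- function(truth, path) {
  feats <- list()
  nuc <- truth$nuclei
  if (!is.null(nuc) && nrow(nuc) > 0) {
    for (i in seq_len(nrow(nuc))) {
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(nuc$x[i], nuc$y[i])),
        properties = list(objectType = "annotation",
                          classification = list(name = nuc$cell_class[i])))
    }
  }
  for (reg in truth$regions) {
    if (is.null(reg$polygon) || nrow(reg$polygon) < 3) next
    ring <- rbind(reg$polygon, reg$polygon[1, , drop = FALSE])
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(unname(
                        lapply(seq_len(nrow(ring)),
                               function(i) unname(ring[i, ]))))),
      properties = list(objectType = "annotation",
                        classification = list(name = reg$tissue_class)))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read QuPath-style GeoJSON annotations
#'
#' @param path GeoJSON file with Point (nucleus) and/or Polygon (tissue
#'   region) features carrying `classification$name`.
#' @return list with `nuclei` data.frame (`x`, `y`, `cell_class`) and
#'   `regions` list (polygon matrix + `tissue_class`).
#' @export
read_annotations_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  nuclei <- list(); regions <- list()
  for (f in doc$features) {
    cls <- f$properties$classification$name
    if (is.null(cls)) cls <- NA_character_
    if (identical(f$geometry$type, "Point")) {
      xy <- unlist(f$geometry$coordinates)
      nuclei[[length(nuclei) + 1]] <- data.frame(
        x = xy[1], y = xy[2], cell_class = cls, stringsAsFactors = FALSE)
    } else if (identical(f$geometry$type, "Polygon")) {
      ring <- f$geometry$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, unlist))
      # drop the closing vertex
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ]
      regions[[length(regions) + 1]] <- list(polygon = m, tissue_class = cls)
    }
  }
  nuclei <- if (length(nuclei)) do.call(rbind, nuclei) else
    data.frame(x = numeric(0), y = numeric(0), cell_class = character(0))
  list(nuclei = nuclei, regions = regions)
}

#' Generate a synthetic labelled cell graph
#'
#' Nodes are uniform over a rectangle partitioned into contiguous tissue
#' regions (seeded Voronoi); node features are drawn from per-tissue
#' Gaussians (unit variance) whose means are pairwise `class_sep` apart.
#' With `class_sep = 0` the features carry no label information.
#'
#' @param n_nodes number of nodes (`>= n_tissue_classes`).
#' @param n_tissue_classes number of tissue classes.
#' @param feature_dim node feature dimension (default 64).
#' @param class_sep pairwise Euclidean distance between per-tissue
#'   feature means; must be `>= 0`.
#' @param seed RNG seed.
#' @param width,height extent of the coordinate rectangle.
#' @param k neighbour count for graph construction (default 5).
#' @param n_regions number of contiguous regions (default
#'   `3 * n_tissue_classes`); each region carries one tissue class, and
#'   classes cycle over regions so every class occupies several
#'   disjoint regions (which makes leakage-free held-out-region splits
#'   possible).
#' @return a `cell_graph` (see [build_graph()]) with `labels`
#'   (integer tissue class per node), `tissue_names`, `regions` (Voronoi
#'   polygons, each with `tissue_class`), and `region_id` per node.
#' @export
generate_synthetic_cell_graph <- function(n_nodes, n_tissue_classes = 3,
                                          feature_dim = 64, class_sep = 4,
                                          seed = 1L, width = 1000,
                                          height = 1000, k = 5,
                                          n_regions = 3 * n_tissue_classes) {
  if (class_sep < 0) stopf("class_sep must be >= 0")
  stopifnot(n_nodes >= n_tissue_classes, n_regions >= n_tissue_classes)
  with_seed(seed, {
    # region seeds on a jittered grid so region areas are comparable --
    # held-out regions must be large relative to the GNN receptive field
    gr <- ceiling(sqrt(n_regions)); gc <- ceiling(n_regions / gr)
    cell_w <- width / gc; cell_h <- height / gr
    centers <- expand.grid(cx = (seq_len(gc) - 0.5) * cell_w,
                           cy = (seq_len(gr) - 0.5) * cell_h)
    centers <- centers[seq_len(n_regions), ]
    seeds <- cbind(centers$cx + stats::runif(n_regions, -0.2, 0.2) * cell_w,
                   centers$cy + stats::runif(n_regions, -0.2, 0.2) * cell_h)
    region_class <- sample(rep_len(seq_len(n_tissue_classes), n_regions))
    coords <- cbind(stats::runif(n_nodes, 0, width),
                    stats::runif(n_nodes, 0, height))
    region_id <- nearest_seed(coords, seeds)
    labels <- region_class[region_id]
    mu <- matrix(0, n_tissue_classes, feature_dim)
    for (t in seq_len(n_tissue_classes)) {
      mu[t, t] <- class_sep / sqrt(2)
    }
    feats <- mu[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_nodes * feature_dim), n_nodes, feature_dim)
    g <- build_graph(coords, feats, k = k)
    g$labels <- labels
    g$region_id <- region_id
    g$tissue_names <- tissue_taxonomy()$class[seq_len(n_tissue_classes)]
    g$regions <- voronoi_regions(seeds, width, height)
    for (i in seq_along(g$regions)) {
      g$regions[[i]]$tissue_class <- g$tissue_names[region_class[i]]
    }
    g
  })
}

#' Random train/validation/test split
#'
#' Sizes are the largest-remainder rounding of `ratios * n`; the
#' partition is exhaustive and disjoint, with membership randomised
#' under `seed`.
#'
#' @param items a vector/list to split (or a single integer count).
#' @param ratios length-3 numeric summing to 1.
#' @param seed RNG seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(items, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  n <- if (length(items) == 1 && is.numeric(items)) as.integer(items)
       else length(items)
  if (n < 1) stopf("empty items")
  if (abs(sum(ratios) - 1) > 1e-9) stopf("ratios must sum to 1")
  base <- floor(ratios * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- ratios * n - base
    add <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  idx <- with_seed(seed, sample.int(n))
  list(train = sort(idx[seq_len(base[1])]),
       val = sort(idx[seq_len(base[2]) + base[1]]),
       test = sort(idx[seq_len(base[3]) + base[1] + base[2]]))
}
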