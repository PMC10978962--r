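# Whole-slide cell graph: nodes are cells (coordinates + embeddings), edges
# are the intersection of symmetrised k-nearest-neighbour edges with the
# Delaunay triangulation, plus one self-loop per node.  The Delaunay term
# caps spurious long-range edges while kNN keeps the graph locally dense,
# limiting edges that cross tissue boundaries.

#' Symmetrised k-nearest-neighbour edges
#'
#' Undirected edge \{i, j\} is present iff j is among i's k nearest
#' neighbours (Euclidean) or i is among j's.  Distance ties are broken
#' by node index.
#'
#' @param coords n x 2 coordinate matrix.
#' @param k neighbour count.
#' @return m x 2 integer matrix of undirected edges with `i < j`.
#' @export
knn_edges <- function(coords, k) {
  n <- nrow(coords)
  if (n < 2) return(matrix(integer(0), 0, 2))
  k <- min(k, n - 1)
  pairs <- matrix(integer(0), 0, 2)
  chunk <- max(1L, as.integer(2e6 / n))
  rows <- vector("list", ceiling(n / chunk))
  ci <- 1L
  for (start in seq(1L, n, by = chunk)) {
    end <- min(n, start + chunk - 1L)
    d2 <- outer(coords[start:end, 1], coords[, 1], "-")^2 +
          outer(coords[start:end, 2], coords[, 2], "-")^2
    sub <- matrix(integer(0), (end - start + 1L) * k, 2)
    r <- 0L
    for (ii in seq_len(end - start + 1L)) {
      i <- start + ii - 1L
      ord <- order(d2[ii, ], seq_len(n))
      nb <- setdiff(ord, i)[seq_len(k)]
      sub[r + seq_len(k), ] <- cbind(i, nb)
      r <- r + k
    }
    rows[[ci]] <- sub
    ci <- ci + 1L
  }
  e <- do.call(rbind, rows)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique_edges(e)
}

unique_edges <- function(e) {
  if (nrow(e) == 0) return(matrix(integer(0), 0, 2))
  key <- (e[, 1] - 1) * (max(e[, 2]) + 1) + e[, 2]
  e <- e[!duplicated(key), , drop = FALSE]
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Delaunay triangulation edges (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation in the plane.  Returns `NULL`
#' for degenerate inputs (fewer than 3 points, or all points collinear),
#' for which no triangulation exists.
#'
#' @param coords n x 2 coordinate matrix with finite entries.
#' @return m x 2 integer edge matrix (`i < j`), or `NULL` if degenerate.
#' @export
delaunay_edges <- function(coords) {
  n <- nrow(coords)
  if (n < 3 || all_collinear(coords)) return(NULL)

  # super-triangle comfortably containing every point
  cx <- mean(range(coords[, 1])); cy <- mean(range(coords[, 2]))
  d <- max(diff(range(coords[, 1])), diff(range(coords[, 2])), 1) * 100
  P <- rbind(coords,
             c(cx - 3 * d, cy - d), c(cx + 3 * d, cy - d), c(cx, cy + 3 * d))
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  cap <- 4L * n + 16L
  tri <- matrix(NA_integer_, cap, 3)
  cc <- matrix(NA_real_, cap, 3)  # circumcenter x, y, radius^2
  alive <- logical(cap)
  tri[1, ] <- c(s1, s2, s3)
  cc[1, ] <- circumcircle(P[s1, ], P[s2, ], P[s3, ])
  alive[1] <- TRUE
  ntri <- 1L

  for (p in seq_len(n)) {
    px <- P[p, 1]; py <- P[p, 2]
    act <- which(alive[seq_len(ntri)])
    inb <- (cc[act, 1] - px)^2 + (cc[act, 2] - py)^2 <=
      cc[act, 3] * (1 + 1e-12) + 1e-9
    bad <- act[inb]
    if (length(bad) == 0) next  # numerically outside everything; skip
    # cavity boundary = edges of bad triangles used exactly once
    ev <- rbind(tri[bad, c(1, 2), drop = FALSE],
                tri[bad, c(2, 3), drop = FALSE],
                tri[bad, c(1, 3), drop = FALSE])
    a <- pmin(ev[, 1], ev[, 2]); b <- pmax(ev[, 1], ev[, 2])
    key <- (a - 1) * (n + 4) + b
    tb <- table(key)
    once <- as.numeric(names(tb)[tb == 1])
    alive[bad] <- FALSE
    for (kk in once) {
      b2 <- ((kk - 1) %% (n + 4)) + 1
      a2 <- ((kk - 1) %/% (n + 4)) + 1
      ntri <- ntri + 1L
      if (ntri > cap) {
        cap2 <- cap * 2L
        tri <- rbind(tri, matrix(NA_integer_, cap2 - cap, 3))
        cc <- rbind(cc, matrix(NA_real_, cap2 - cap, 3))
        alive <- c(alive, logical(cap2 - cap))
        cap <- cap2
      }
      tri[ntri, ] <- c(a2, b2, p)
      cc[ntri, ] <- circumcircle(P[a2, ], P[b2, ], P[p, ])
      alive[ntri] <- TRUE
    }
  }

  keep <- which(alive[seq_len(ntri)])
  tt <- tri[keep, , drop = FALSE]
  tt <- tt[apply(tt, 1, function(v) all(v <= n)), , drop = FALSE]
  if (nrow(tt) == 0) return(matrix(integer(0), 0, 2))
  e <- rbind(tt[, c(1, 2), drop = FALSE], tt[, c(2, 3), drop = FALSE],
             tt[, c(1, 3), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique_edges(e)
}

all_collinear <- function(coords, tol = 1e-9) {
  n <- nrow(coords)
  if (n <= 2) return(TRUE)
  v <- sweep(coords[-1, , drop = FALSE], 2, coords[1, ])
  base <- v[which.max(rowSums(v^2)), ]
  if (sum(base^2) < tol) return(TRUE)
  cross <- abs(v[, 1] * base[2] - v[, 2] * base[1])
  all(cross < tol * sqrt(sum(base^2)))
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

#' Build the whole-slide cell graph
#'
#' Edge set = `sym(kNN_k)` intersected with the Delaunay triangulation,
#' plus one self-loop per node.  For degenerate inputs (n < 3 or all
#' points collinear), where no triangulation exists, the Delaunay term
#' is taken as the complete graph so the edge set reduces to
#' `sym(kNN_k)` plus self-loops.
#'
#' @param coords n x 2 matrix of node coordinates (rescaled-frame px).
#' @param features optional n x d node feature matrix (cell embeddings).
#' @param k neighbour count (5 for the training/inference graph; 8 for
#'   the validation graph).
#' @param labels optional integer tissue label per node.
#' @return object of class `cell_graph`: `coords`, `features`, `edges`
#'   (undirected pairs `i < j`, self-loops implicit), `n`, `k`,
#'   `labels`, `masks`.
#' @export
build_graph <- function(coords, features = NULL, k = 5, labels = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stopf("need at least one node")
  if (any(!is.finite(coords))) stopf("non-finite coordinates")
  kn <- knn_edges(coords, k)
  del <- delaunay_edges(coords)
  edges <- if (is.null(del)) kn else intersect_edges(kn, del)
  structure(list(coords = coords, features = features, edges = edges,
                 n = nrow(coords), k = k, labels = labels, masks = NULL),
            class = "cell_graph")
}

intersect_edges <- function(e1, e2) {
  if (nrow(e1) == 0 || nrow(e2) == 0) return(matrix(integer(0), 0, 2))
  m <- max(e1[, 2], e2[, 2]) + 1
  k1 <- (e1[, 1] - 1) * m + e1[, 2]
  k2 <- (e2[, 1] - 1) * m + e2[, 2]
  e1[k1 %in% k2, , drop = FALSE]
}

#' Edge list of a cell graph
#'
#' @param graph a `cell_graph`.
#' @param self_loops include the n self-loops (default TRUE).
#' @return integer matrix of undirected edges.
#' @export
graph_edges <- function(graph, self_loops = TRUE) {
  e <- graph$edges
  if (self_loops) e <- rbind(e, cbind(seq_len(graph$n), seq_len(graph$n)))
  e
}

#' @exportS3Method base::print
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d nodes, %d undirected edges (+%d self-loops), k=%d\n",
              x$n, nrow(x$edges), x$n, x$k))
  if (!is.null(x$features)) {
    cat(sprintf("  features: %d-d\n", ncol(x$features)))
  }
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d classes\n", length(unique(x$labels))))
  }
  invisible(x)
}

# Row-normalised sparse adjacency (neighbour-mean operator) including
# self-loops; optionally with per-node neighbour subsampling.
graph_mean_operator <- function(graph, sample_size = NULL, seed = NULL) {
  n <- graph$n
  e <- graph$edges
  ii <- c(e[, 1], e[, 2], seq_len(n))
  jj <- c(e[, 2], e[, 1], seq_len(n))
  if (!is.null(sample_size)) {
    keep <- with_seed(seed, {
      unlist(lapply(split(seq_along(ii), ii), function(idx) {
        if (length(idx) <= sample_size) idx
        else sample(idx, sample_size)
      }), use.names = FALSE)
    })
    ii <- ii[keep]; jj <- jj[keep]
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  Matrix::Diagonal(x = 1 / deg) %*% A
}

#' Region-based dataset split with leakage report
#'
#' Assigns every node to the split of its containing region polygon and
#' reports potential leakage: the number of graph edges crossing split
#' boundaries and the minimum hop distance from validation/test nodes
#' to any training node.  Region-based splitting keeps held-out nodes
#' outside the training nodes' receptive fields when regions are far
#' apart relative to the GNN depth.
#'
#' @param graph a `cell_graph`.
#' @param regions list of regions (`polygon` matrix, as produced by the
#'   synthetic generator or read from GeoJSON).
#' @param assignment character vector, one of "train"/"val"/"test" per
#'   region.
#' @return list with `masks` (logical `train`, `val`, `test`) and
#'   `leakage` (`crossing_edges`, `min_hop_val_test_to_train`).
#' @export
split_by_region <- function(graph, regions, assignment) {
  stopifnot(length(regions) == length(assignment),
            all(assignment %in% c("train", "val", "test")))
  n <- graph$n
  node_split <- rep(NA_character_, n)
  for (r in seq_along(regions)) {
    inside <- point_in_polygon(graph$coords[, 1], graph$coords[, 2],
                               regions[[r]]$polygon)
    node_split[is.na(node_split) & inside] <- assignment[r]
  }
  if (!is.null(graph$labels) && anyNA(node_split)) {
    stopf("%d labelled node(s) fall in no region polygon",
          sum(is.na(node_split)))
  }
  masks <- list(train = !is.na(node_split) & node_split == "train",
                val = !is.na(node_split) & node_split == "val",
                test = !is.na(node_split) & node_split == "test")
  e <- graph$edges
  crossing <- if (nrow(e) == 0) 0L else
    sum(node_split[e[, 1]] != node_split[e[, 2]], na.rm = TRUE)
  min_hop <- NA_real_
  held <- which(masks$val | masks$test)
  trn <- which(masks$train)
  if (length(held) > 0 && length(trn) > 0) {
    ig <- igraph::graph_from_edgelist(e, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    dmat <- igraph::distances(ig, v = held, to = trn)
    min_hop <- suppressWarnings(min(dmat))
  }
  list(masks = masks,
       leakage = list(crossing_edges = crossing,
                      min_hop_val_test_to_train = min_hop))
}
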