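# Independent brute-force oracles used to cross-check the package's
# geometric and matching algorithms.  These deliberately share no code
# with the implementations they verify.

# Delaunay edge oracle via the empty-circumcircle characterisation:
# {i, j} is a Delaunay edge iff some circumcircle through i, j and a
# third point contains no other point strictly inside.
oracle_delaunay_edges <- function(coords, eps = 1e-7) {
  n <- nrow(coords)
  x <- coords[, 1]; y <- coords[, 2]
  out <- vector("list", n * (n - 1) / 2)
  m <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]
      others <- setdiff(seq_len(n), c(i, j))
      cx <- x[others]; cy <- y[others]
      # circumcentres of (i, j, k) for every third point k, vectorised
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      ok <- abs(d) > 1e-12
      if (!any(ok)) next
      a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
      ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
      uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
      r2 <- (ax - ux)^2 + (ay - uy)^2
      # a circle is empty iff no point lies strictly inside it (points
      # on the circle, including i, j, k themselves, do not count)
      inside <- outer(x, ux, "-")^2 + outer(y, uy, "-")^2 <
        rep(r2 - eps * (1 + r2), each = n)
      empty <- colSums(inside) == 0
      if (any(empty & ok)) {
        m <- m + 1L
        out[[m]] <- c(i, j)
      }
    }
  }
  if (m == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, out[seq_len(m)])
}

# All-pairs kNN by full sort, symmetrised by union; ties by index.
oracle_knn_edges <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1)
  out <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    d <- sqrt((coords[, 1] - coords[i, 1])^2 +
              (coords[, 2] - coords[i, 2])^2)
    ord <- order(d, seq_len(n))
    nb <- ord[ord != i][seq_len(k)]
    out <- rbind(out, cbind(pmin(i, nb), pmax(i, nb)))
  }
  unique(out[order(out[, 1], out[, 2]), , drop = FALSE])
}

edge_key <- function(e) {
  if (nrow(e) == 0) return(character(0))
  sort(paste(e[, 1], e[, 2]))
}

# Exhaustive maximum-cardinality / minimum-total-distance matching over
# pairs with distance strictly below the threshold.  Recursion over
# predictions, feasible for <= 7 points per side.
oracle_matching <- function(pd, td, dist, thr) {
  np <- nrow(dist); nt <- ncol(dist)
  best <- list(card = -1L, cost = Inf)
  recurse <- function(i, used, card, cost) {
    if (i > np) {
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12)) {
        best <<- list(card = card, cost = cost)
      }
      return(invisible())
    }
    # option: leave prediction i unmatched
    recurse(i + 1L, used, card, cost)
    for (j in seq_len(nt)) {
      if (!used[j] && dist[i, j] < thr) {
        used[j] <- TRUE
        recurse(i + 1L, used, card + 1L, cost + dist[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nt), 0L, 0)
  best
}

# Direct restatement of the duplicate-merge rule: greedy in descending
# confidence (ties lower y then x), keep iff no kept point strictly
# within radius.
oracle_dedup <- function(preds, radius) {
  ord <- order(-preds$confidence, preds$y, preds$x)
  kept <- list()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (sqrt((preds$x[i] - preds$x[k])^2 +
               (preds$y[i] - preds$y[k])^2) < radius) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept[[length(kept) + 1]] <- i
  }
  unlist(kept)
}

# Direct restatement of the syncytial-knot rule on an (x, y, label)
# data.frame; returns the expected output labels and kept flags.
oracle_knot <- function(df, radius = 50, min_nb = 4,
                        knot = "syncytial_knot",
                        sync = "syncytiotrophoblast") {
  kn <- which(df$label == knot)
  keep <- rep(TRUE, nrow(df))
  label <- df$label
  if (length(kn) == 0) return(list(label = label, keep = keep))
  cnt <- sapply(kn, function(i) {
    sum(sqrt((df$x[kn] - df$x[i])^2 + (df$y[kn] - df$y[i])^2) <= radius) - 1
  })
  relabel <- cnt < min_nb
  label[kn[relabel]] <- sync
  removed <- rep(FALSE, length(kn))
  centres <- which(!relabel)
  centres <- centres[order(-cnt[centres], df$y[kn][centres],
                           df$x[kn][centres])]
  for (c0 in centres) {
    if (removed[c0]) next
    for (j in which(!relabel)) {
      if (j != c0 &&
          sqrt((df$x[kn[j]] - df$x[kn[c0]])^2 +
               (df$y[kn[j]] - df$y[kn[c0]])^2) <= radius) {
        removed[j] <- TRUE
      }
    }
    removed[c0] <- FALSE
  }
  keep[kn[removed]] <- FALSE
  list(label = label, keep = keep)
}
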