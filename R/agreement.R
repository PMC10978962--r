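# Inter-rater agreement: Cohen's kappa, per-class (binarised) kappa,
# majority vote with "unclear"/"not listed" handling, and the
# PR-AUC-versus-kappa regression.

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` computed from each rater's marginal label
#' frequencies.  When `p_e = 1` (both raters constant and identical),
#' kappa is 1.
#'
#' @param a,b equal-length label vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  if (length(a) == 0) stopf("empty labels")
  a <- as.character(a); b <- as.character(b)
  lev <- union(a, b)
  n <- length(a)
  po <- mean(a == b)
  pa <- table(factor(a, levels = lev)) / n
  pb <- table(factor(b, levels = lev)) / n
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  if (abs(1 - pe) < 1e-15) return(1)
  (po - pe) / (1 - pe)
}

#' Per-class kappa across raters
#'
#' Binarises every rater's labels to class-vs-rest and averages the
#' pairwise Cohen's kappa over all rater pairs.  A class used by no
#' rater has no defined binarised agreement and is reported as `NA`.
#'
#' @param labels items x raters matrix or data.frame of labels.
#' @param class the class to binarise on.
#' @return mean pairwise kappa, or `NA` if the class is absent.
#' @export
per_class_kappa <- function(labels, class) {
  labels <- as.matrix(labels)
  if (ncol(labels) < 2) stopf("need at least 2 raters")
  if (!any(labels == class)) return(NA_real_)
  bin <- matrix(ifelse(labels == class, class, ".rest"),
                nrow = nrow(labels))
  pairs <- utils::combn(ncol(bin), 2)
  ks <- apply(pairs, 2, function(pr) cohens_kappa(bin[, pr[1]], bin[, pr[2]]))
  mean(ks)
}

#' Mean pairwise kappa over all raters
#'
#' The headline multi-rater agreement reported by this package: the
#' unweighted mean of Cohen's kappa over all rater pairs.
#'
#' @param labels items x raters matrix or data.frame.
#' @return mean pairwise kappa.
#' @export
mean_pairwise_kappa <- function(labels) {
  labels <- as.matrix(labels)
  if (ncol(labels) < 2) stopf("need at least 2 raters")
  pairs <- utils::combn(ncol(labels), 2)
  mean(apply(pairs, 2, function(pr) {
    cohens_kappa(labels[, pr[1]], labels[, pr[2]])
  }))
}

#' Per-item majority vote
#'
#' "unclear" and "not listed" votes are excluded; the winner is the
#' strict plurality of the remaining votes.  Ties, or items with no
#' remaining votes, yield `NA`.
#'
#' @param labels items x raters matrix or data.frame.
#' @param exclude vote values excluded before counting.
#' @return character vector of majority labels (`NA` where undefined).
#' @export
majority_vote <- function(labels,
                          exclude = c("unclear", "not_listed",
                                      "not listed")) {
  labels <- as.matrix(labels)
  if (ncol(labels) < 2) stopf("need at least 2 raters")
  apply(labels, 1, function(v) {
    v <- v[!v %in% exclude & !is.na(v)]
    if (length(v) == 0) return(NA_character_)
    tb <- sort(table(v), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) return(NA_character_)
    names(tb)[1]
  })
}

#' Confusion of rater labels against the majority label
#'
#' For items with a defined majority label, tabulates how each rater's
#' vote (including "unclear"/"not listed") distributes against that
#' majority, as row proportions.
#'
#' @inheritParams majority_vote
#' @return matrix of row proportions (majority label x vote).
#' @export
majority_confusion <- function(labels,
                               exclude = c("unclear", "not_listed",
                                           "not listed")) {
  labels <- as.matrix(labels)
  mv <- majority_vote(labels, exclude)
  keep <- !is.na(mv)
  maj <- rep(mv[keep], times = ncol(labels))
  votes <- as.vector(labels[keep, , drop = FALSE])
  tb <- table(majority = maj, vote = votes)
  sweep(unclass(tb), 1, pmax(rowSums(tb), 1), "/")
}

#' Regression of model PR-AUC on inter-rater kappa
#'
#' Ordinary least squares of per-class model PR-AUC on per-class
#' pathologist kappa; `R^2` is the squared Pearson correlation (0 when
#' the response is constant).
#'
#' @param pr_auc,kappa paired per-class values (>= 3 pairs).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
correlate_prauc_kappa <- function(pr_auc, kappa) {
  ok <- is.finite(pr_auc) & is.finite(kappa)
  pr_auc <- pr_auc[ok]; kappa <- kappa[ok]
  if (length(pr_auc) < 3) stopf("need at least 3 paired values")
  if (stats::sd(kappa) == 0) stopf("zero variance in kappa")
  fit <- stats::lm(pr_auc ~ kappa)
  r2 <- if (stats::sd(pr_auc) == 0) 0 else stats::cor(pr_auc, kappa)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}
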