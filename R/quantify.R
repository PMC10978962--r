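# Slide-level quantification: per-class counts, proportions, occupied
# tissue area (non-overlapping grid patches containing at least one
# nucleus), per-mm^2 densities, literature-range flags, and group
# comparison with Welch's t-test under Bonferroni correction.

#' Summarise a slide's predictions
#'
#' Proportions are class counts over the total; occupied area is the
#' number of non-overlapping grid patches containing at least one
#' nucleus prediction times the patch area in mm^2 (patch area =
#' `(W * mpp / 1000) * (H * mpp / 1000)`); densities divide counts by
#' that area.
#'
#' @param cell_preds a `cell_predictions` object (or a data.frame with
#'   `x`, `y`, `label`).
#' @param tissue_labels optional per-cell tissue labels (same length).
#' @param mpp micrometres per pixel of the coordinate frame.
#' @param area_patch_px grid patch size `c(width, height)` in pixels
#'   for area estimation (defaults to the tiling patch).
#' @param cell_classes,tissue_classes class universes for the count
#'   vectors (defaults: full taxonomies).
#' @param slide_id identifier stored in the summary.
#' @return object of class `slide_summary`.
#' @export
summarise_slide <- function(cell_preds, tissue_labels = NULL,
                            mpp = HISTOCELL_MPP,
                            area_patch_px = c(1600, 1200),
                            cell_classes = cell_taxonomy()$class,
                            tissue_classes = tissue_taxonomy()$class,
                            slide_id = "slide") {
  if (inherits(cell_preds, "cell_predictions")) {
    xy <- cell_preds$nuclei
    labels <- cell_preds$label
  } else {
    xy <- cell_preds
    labels <- cell_preds$label
  }
  n <- nrow(xy)
  cell_counts <- table(factor(labels, levels = cell_classes))
  tissue_counts <- table(factor(tissue_labels, levels = tissue_classes))

  patch_area_mm2 <- (area_patch_px[1] * mpp / 1000) *
    (area_patch_px[2] * mpp / 1000)
  if (n > 0) {
    gx <- floor(xy$x / area_patch_px[1])
    gy <- floor(xy$y / area_patch_px[2])
    occupied <- nrow(unique(cbind(gx, gy)))
  } else {
    occupied <- 0L
  }
  area_mm2 <- occupied * patch_area_mm2
  stopifnot(!(n > 0 && area_mm2 == 0))

  prop <- function(cnt) {
    tot <- sum(cnt)
    if (tot == 0) as.numeric(cnt) else as.numeric(cnt) / tot
  }
  dens <- function(cnt) {
    if (area_mm2 == 0) rep(0, length(cnt)) else as.numeric(cnt) / area_mm2
  }
  structure(list(
    slide_id = slide_id,
    total_nuclei = n,
    cell_counts = stats::setNames(as.integer(cell_counts), cell_classes),
    tissue_counts = stats::setNames(as.integer(tissue_counts),
                                    tissue_classes),
    occupied_area_mm2 = area_mm2,
    occupied_patches = occupied,
    cell_proportions = stats::setNames(prop(cell_counts), cell_classes),
    tissue_proportions = stats::setNames(prop(tissue_counts),
                                         tissue_classes),
    cell_densities = stats::setNames(dens(cell_counts), cell_classes),
    tissue_densities = stats::setNames(dens(tissue_counts), tissue_classes),
    total_density = if (area_mm2 == 0) 0 else n / area_mm2
  ), class = "slide_summary")
}

#' @exportS3Method base::print
print.slide_summary <- function(x, ...) {
  cat(sprintf("<slide_summary> %s: %d nuclei over %.3f mm^2 (%.0f / mm^2)\n",
              x$slide_id, x$total_nuclei, x$occupied_area_mm2,
              x$total_density))
  invisible(x)
}

#' Literature ranges for healthy term placenta tissue proportions
#'
#' Expected percentage ranges: terminal villi 30-60, mature
#' intermediate villi 17-32, stem villi 9-25, fibrin below 10,
#' avascular villi below 2.5.
#'
#' @return data.frame with `class`, `low_pct`, `high_pct`.
#' @export
expected_tissue_ranges <- function() {
  data.frame(
    class = c("terminal_villi", "mature_intermediate_villi", "stem_villi",
              "fibrin", "avascular_villi"),
    low_pct = c(30, 17, 9, 0, 0),
    high_pct = c(60, 32, 25, 10, 2.5),
    stringsAsFactors = FALSE)
}

#' Flag tissue proportions against expected ranges
#'
#' Bounds are inclusive: a proportion exactly on a range limit is
#' in-range.
#'
#' @param summary a `slide_summary`.
#' @param ranges data.frame as [expected_tissue_ranges()].
#' @return data.frame `class`, `proportion_pct`, `flag`
#'   ("in" / "below" / "above").
#' @export
check_expected_ranges <- function(summary, ranges = expected_tissue_ranges()) {
  if (any(ranges$low_pct > ranges$high_pct)) stopf("invalid ranges")
  pct <- summary$tissue_proportions[ranges$class] * 100
  flag <- ifelse(pct < ranges$low_pct, "below",
                 ifelse(pct > ranges$high_pct, "above", "in"))
  data.frame(class = ranges$class, proportion_pct = as.numeric(pct),
             flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch's two-sample t-test
#'
#' Two-sided test not assuming equal variances:
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom.  When both groups have zero
#' variance and equal means, `p = 1` by convention.
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stopf("non-finite values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  se2 <- va + vb
  if (se2 == 0) {
    return(list(t = 0, df = na + nb - 2, p = 1))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Compare two slide groups variable by variable
#'
#' Runs a two-sided Welch's t-test per variable and applies Bonferroni
#' correction within the variable family tested here
#' (`p_adj = min(1, m p)` with `m` the number of variables).
#'
#' @param summariesA,summariesB lists of `slide_summary` objects (at
#'   least 2 slides each).
#' @param variables character vector of variables; each is either a
#'   summary scalar (e.g. `"total_density"`) or `"<field>.<class>"`
#'   (e.g. `"tissue_proportions.fibrin"`,
#'   `"cell_densities.leucocyte"`).
#' @param alpha significance level after correction.
#' @param correction "bonferroni" or "none".
#' @return data.frame `variable`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `p_adjusted`, `significant`.
#' @export
compare_groups <- function(summariesA, summariesB, variables,
                           alpha = 0.05, correction = "bonferroni") {
  stopifnot(length(summariesA) >= 2, length(summariesB) >= 2)
  extract <- function(s, v) {
    val <- if (v %in% names(s)) {
      s[[v]]  # flat column name (e.g. from a summaries CSV)
    } else {
      parts <- strsplit(v, ".", fixed = TRUE)[[1]]
      if (length(parts) == 1) s[[parts[1]]] else s[[parts[1]]][[parts[2]]]
    }
    if (is.null(val)) stopf("variable '%s' missing from summary", v)
    as.numeric(val)
  }
  rows <- lapply(variables, function(v) {
    a <- vapply(summariesA, extract, numeric(1), v)
    b <- vapply(summariesB, extract, numeric(1), v)
    tt <- welch_t_test(a, b)
    data.frame(variable = v, mean_a = mean(a), mean_b = mean(b),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (correction == "bonferroni") {
    stats::p.adjust(out$p, method = "bonferroni")
  } else out$p
  out$significant <- out$p_adjusted <= alpha
  out
}

#' Write slide summaries as a CSV table
#'
#' @param summaries list of `slide_summary` objects.
#' @param path output CSV path (optional).
#' @return data.frame, one row per slide, invisibly written to `path`.
#' @export
summaries_to_table <- function(summaries, path = NULL) {
  rows <- lapply(summaries, function(s) {
    row <- data.frame(slide_id = s$slide_id, total_nuclei = s$total_nuclei,
                      occupied_area_mm2 = s$occupied_area_mm2,
                      total_density = s$total_density)
    for (f in c("cell_proportions", "tissue_proportions",
                "cell_densities", "tissue_densities")) {
      v <- s[[f]]
      names(v) <- paste(f, names(v), sep = ".")
      row <- cbind(row, as.data.frame(as.list(v), check.names = FALSE))
    }
    row
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
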