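# End-to-end orchestration: tile -> detect -> dedup -> classify ->
# knot-postprocess -> build cell graph -> GNN inference -> summarise,
# with optional persistence and pause/resume.

#' Pipeline configuration
#'
#' @param detector a `nucleus_detector`.
#' @param classifier a `cell_classifier` or `oracle_cell_classifier`.
#' @param gnn_model optional trained `tissue_gnn`; when `NULL` the
#'   tissue stage is skipped.
#' @param tissue_names tissue class names for GNN outputs.
#' @param width,height,overlap tiling geometry.
#' @param target_mpp working resolution.
#' @param radius_px duplicate-merge radius.
#' @param crop_px cell crop size.
#' @param knot_radius_px,knot_min_neighbours knot post-processing.
#' @param k graph neighbour count.
#' @param area_patch_px grid patch for occupied-area estimation.
#' @param seed run seed (logged).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(detector, classifier, gnn_model = NULL,
                            tissue_names = NULL,
                            width = 1600, height = 1200, overlap = 200,
                            target_mpp = HISTOCELL_MPP, radius_px = 4,
                            crop_px = 200, knot_radius_px = 50,
                            knot_min_neighbours = 4, k = 5,
                            area_patch_px = c(width, height), seed = 1L) {
  structure(list(detector = detector, classifier = classifier,
                 gnn_model = gnn_model, tissue_names = tissue_names,
                 width = width, height = height, overlap = overlap,
                 target_mpp = target_mpp, radius_px = radius_px,
                 crop_px = crop_px, knot_radius_px = knot_radius_px,
                 knot_min_neighbours = knot_min_neighbours, k = k,
                 area_patch_px = area_patch_px, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Hash only the parameters that determine results, not model objects
# (closures serialise unstably); model identity is the caller's concern.
pipeline_config_hash_fields <- function(config) {
  config[c("width", "height", "overlap", "target_mpp", "radius_px",
           "crop_px", "knot_radius_px", "knot_min_neighbours", "k",
           "area_patch_px", "seed")]
}

#' Run the full pipeline on one slide
#'
#' Stages: tile, detect (+ dedup), classify (+ knot post-processing),
#' build the cell graph from nucleus coordinates and embeddings, GNN
#' tissue inference, summarise.  With a `store`, per-patch detection
#' batches are persisted as they complete and the run resumes from the
#' ledger; any stage error aborts with the stage name.
#'
#' @param handle a `slide_handle`.
#' @param config a [pipeline_config()].
#' @param store optional [results_store()] directory path or object.
#' @param max_patches process at most this many remaining patches (for
#'   deliberate interruption in tests); `Inf` = all.
#' @return list with `summary` (a `slide_summary`), `nuclei`,
#'   `cell_preds`, `tissue` (labels + probs or `NULL`), `graph`.
#' @export
run_pipeline <- function(handle, config, store = NULL, max_patches = Inf) {
  if (is.character(store)) {
    store <- results_store(store, pipeline_config_hash_fields(config),
                           seed = config$seed)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed on %s: %s", name, handle$path,
            conditionMessage(e))
    })
  }

  # -- detection, patch by patch (resumable) -------------------------------
  nuclei <- stage("detect", {
    if (is.null(store)) {
      run_detection(handle, config$detector, config$width, config$height,
                    config$overlap, config$target_mpp, config$radius_px)
    } else {
      remaining <- resume_run(store, handle, "detect", config$width,
                              config$height, config$overlap,
                              config$target_mpp)
      if (nrow(remaining) > max_patches) {
        remaining <- remaining[seq_len(max_patches), , drop = FALSE]
      }
      for (i in seq_len(nrow(remaining))) {
        org <- remaining[i, ]
        batch <- run_detection(handle, config$detector, config$width,
                               config$height, config$overlap,
                               config$target_mpp, config$radius_px,
                               origins = org, dedup = FALSE)
        record_predictions(store, "detect", batch,
                           c(org$x, org$y))
      }
      left <- resume_run(store, handle, "detect", config$width,
                         config$height, config$overlap, config$target_mpp)
      if (nrow(left) > 0) {
        NULL  # interrupted on purpose; caller resumes later
      } else {
        pooled <- load_predictions(store, "detect")
        if (is.null(pooled)) {
          pooled <- data.frame(x = numeric(0), y = numeric(0),
                               confidence = numeric(0))
        }
        merge_duplicates(pooled, config$radius_px)
      }
    }
  })
  if (is.null(nuclei)) return(invisible(NULL))  # paused

  # -- cell classification -------------------------------------------------
  cell_preds <- stage("classify", {
    classify_cells(handle, nuclei, config$classifier, config$crop_px,
                   config$target_mpp, config$knot_radius_px,
                   config$knot_min_neighbours)
  })
  if (!is.null(store)) {
    record_predictions(store, "classify", cell_preds)
  }

  # -- cell graph + tissue inference ---------------------------------------
  graph <- NULL
  tissue <- NULL
  n_cells <- nrow(cell_preds$nuclei)
  if (n_cells > 0 && !is.null(config$gnn_model)) {
    graph <- stage("graph", {
      build_graph(cbind(cell_preds$nuclei$x, cell_preds$nuclei$y),
                  cell_preds$embedding, k = config$k)
    })
    tissue <- stage("tissue", {
      predict_tissues(graph, config$gnn_model, config$tissue_names)
    })
    if (!is.null(store)) {
      record_predictions(store, "tissue",
                         data.frame(x = cell_preds$nuclei$x,
                                    y = cell_preds$nuclei$y,
                                    label = tissue$label))
    }
  }

  summary <- stage("summarise", {
    summarise_slide(cell_preds, tissue_labels = tissue$label,
                    mpp = config$target_mpp,
                    area_patch_px = config$area_patch_px,
                    slide_id = basename(handle$path))
  })
  list(summary = summary, nuclei = nuclei, cell_preds = cell_preds,
       tissue = tissue, graph = graph)
}
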