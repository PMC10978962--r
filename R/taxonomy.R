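# Fixed cell and tissue taxonomies for term placenta histology.

#' Placental cell taxonomy
#'
#' The 11 cell classes grouped by lineage: four trophoblast types, five
#' villus mesenchymal-derived types, and two non-villus types.
#'
#' @return data.frame with columns `class` and `group`, in fixed order.
#' @export
cell_taxonomy <- function() {
  data.frame(
    class = c("syncytiotrophoblast", "cytotrophoblast", "syncytial_knot",
              "extravillus_trophoblast",
              "fibroblast", "hofbauer_cell", "vascular_endothelial",
              "vascular_myocyte", "mesenchymal_undifferentiated",
              "maternal_decidual", "leucocyte"),
    group = c(rep("trophoblast", 4),
              rep("mesenchymal_derived", 5),
              rep("non_villus", 2)),
    stringsAsFactors = FALSE
  )
}

#' Placental tissue microstructure taxonomy
#'
#' The 9 tissue classes: five chorionic villus types, the two
#' maternal/fetal surfaces, and two pathologic indicators.  The order is
#' fixed so confusion matrices are comparable across runs.
#'
#' @return data.frame with columns `class` and `group`, in fixed order.
#' @export
tissue_taxonomy <- function() {
  data.frame(
    class = c("stem_villi", "anchoring_villi", "mature_intermediate_villi",
              "terminal_villi", "villus_sprouts",
              "chorionic_plate", "basal_plate_septum",
              "fibrin", "avascular_villi"),
    group = c(rep("villi", 5), rep("surface", 2), rep("pathologic", 2)),
    stringsAsFactors = FALSE
  )
}
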