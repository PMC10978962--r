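# File-backed results store with pause/resume.  Run metadata lives in a
# JSON file, bulk prediction batches in per-batch RDS chunk files, and a
# TSV append-only ledger marks patch origins complete *after* their chunk
# is on disk.  A crash between the chunk write and the ledger append
# leaves an unreferenced chunk, which resume ignores -- so interrupted
# runs complete to results identical to uninterrupted ones.

#' Open (or create) a results store
#'
#' @param dir store directory (created if missing).
#' @param config run configuration; its hash guards resume against
#'   changed parameters.
#' @param seed seed recorded in the metadata.
#' @param slide_id slide identifier.
#' @return object of class `results_store`.
#' @export
results_store <- function(dir, config = list(), seed = NA_integer_,
                          slide_id = "slide") {
  dir.create(file.path(dir, "chunks"), recursive = TRUE,
             showWarnings = FALSE)
  meta_path <- file.path(dir, "meta.json")
  hash <- config_hash(config)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!identical(meta$config_hash, hash)) {
      stopf("store %s was created with a different configuration (%s != %s)",
            dir, meta$config_hash, hash)
    }
  } else {
    meta <- list(slide_id = slide_id, config_hash = hash, seed = seed,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  }
  structure(list(dir = dir, meta = meta), class = "results_store")
}

ledger_path <- function(store) file.path(store$dir, "ledger.tsv")

#' Record a prediction batch
#'
#' Appends the batch to the store: the chunk file is written first,
#' then the ledger line referencing it (with the patch origin) is
#' appended.  Only ledger-referenced chunks are ever read back.
#'
#' @param store a `results_store`.
#' @param stage stage name (e.g. "detect", "classify").
#' @param batch any serialisable object (typically a data.frame or
#'   list of arrays).
#' @param origin length-2 patch origin marked complete by this batch;
#'   use the default for whole-slide stages.
#' @return invisibly, the chunk file path.
#' @export
record_predictions <- function(store, stage, batch, origin = c(-1L, -1L)) {
  chunks <- list.files(file.path(store$dir, "chunks"),
                       pattern = paste0("^", stage, "_"))
  fname <- sprintf("%s_%06d.rds", stage, length(chunks) + 1L)
  fpath <- file.path(store$dir, "chunks", fname)
  saveRDS(batch, fpath)
  line <- sprintf("%s\t%s\t%d\t%d\n", stage, fname,
                  as.integer(origin[1]), as.integer(origin[2]))
  cat(line, file = ledger_path(store), append = TRUE)
  invisible(fpath)
}

read_ledger <- function(store) {
  lp <- ledger_path(store)
  if (!file.exists(lp)) {
    return(data.frame(stage = character(0), chunk = character(0),
                      x = integer(0), y = integer(0)))
  }
  utils::read.table(lp, sep = "\t", col.names = c("stage", "chunk", "x", "y"),
                    stringsAsFactors = FALSE)
}

#' Origins already completed for a stage
#'
#' @param store a `results_store`.
#' @param stage stage name.
#' @return data.frame with columns `x`, `y`.
#' @export
completed_origins <- function(store, stage) {
  led <- read_ledger(store)
  led <- led[led$stage == stage & led$x >= 0, c("x", "y")]
  unique(led)
}

#' Load all recorded batches for a stage
#'
#' Reads back, in ledger order, every chunk the ledger references;
#' data.frame batches are row-bound.  Chunks present on disk but not in
#' the ledger (interrupted writes) are ignored.
#'
#' @param store a `results_store`.
#' @param stage stage name.
#' @return combined batches (`NULL` if none).
#' @export
load_predictions <- function(store, stage) {
  led <- read_ledger(store)
  files <- led$chunk[led$stage == stage]
  if (length(files) == 0) return(NULL)
  batches <- lapply(file.path(store$dir, "chunks", files), readRDS)
  if (all(vapply(batches, is.data.frame, logical(1)))) {
    do.call(rbind, batches)
  } else batches
}

#' Remaining tiling origins for a resumable stage
#'
#' Returns exactly the tiling origins not yet marked complete in the
#' ledger; the run configuration must hash-match the one the store was
#' created with (enforced by [results_store()]).
#'
#' @param store a `results_store`.
#' @param handle a `slide_handle`.
#' @param stage stage name.
#' @inheritParams patch_origins
#' @inheritParams read_patch
#' @return data.frame of origins (`x`, `y`) still to process.
#' @export
resume_run <- function(store, handle, stage = "detect", width = 1600,
                       height = 1200, overlap = 200,
                       target_mpp = HISTOCELL_MPP) {
  dims <- rescaled_dims(handle, target_mpp)
  all_org <- patch_origins(dims[1], dims[2], width, height, overlap)
  done <- completed_origins(store, stage)
  if (nrow(done) == 0) return(all_org)
  key_all <- paste(all_org$x, all_org$y)
  key_done <- paste(done$x, done$y)
  all_org[!key_all %in% key_done, , drop = FALSE]
}
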