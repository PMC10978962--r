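# Slide reading, physical-resolution rescaling, and overlapping patch tiling.
#
# All downstream coordinates are 0-based pixel indices in the *rescaled*
# frame (default 0.1109 micrometres per pixel); pixel (0, 0) is the top-left
# corner, x increases rightwards (columns), y downwards (rows).

#' Standard working resolution in micrometres per pixel
#'
#' Every slide is resampled to this physical resolution before any
#' detection or classification, so that models see nuclei at a fixed
#' physical scale regardless of the scanner's native pixel size.
#' @export
HISTOCELL_MPP <- 0.1109

#' Open a slide image
#'
#' Reads a flat PNG or (pyramidal/flat) TIFF raster together with its
#' physical resolution.  Micrometres-per-pixel are taken, in order of
#' priority, from the `mpp` argument, a JSON sidecar file
#' (`<image>.json` or `<stem>.json` with fields `mpp_x`/`mpp_y` or `mpp`),
#' or TIFF resolution tags.  A slide whose resolution cannot be determined
#' is an error: silently assuming a default physical scale would corrupt
#' every downstream measurement.
#'
#' @param path path to a PNG or TIFF image.
#' @param mpp optional explicit micrometres-per-pixel, length 1 or 2
#'   (x, y); overrides any metadata.
#' @return an object of class `slide_handle` with fields `path`,
#'   `width_px`, `height_px`, `native_mpp` (x, y) and `reader_dialect`.
#' @export
open_slide <- function(path, mpp = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stopf("slide file not found: %s", as.character(path)[1])
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
    dialect <- "flat-image"
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    dialect <- "pyramidal-tiff"
  } else {
    stopf("unsupported slide format '.%s' (PNG or TIFF expected)", ext)
  }
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]
  pixels <- raw * 255

  native_mpp <- resolve_mpp(path, raw, mpp)
  structure(list(
    path = path,
    pixels = pixels,
    width_px = dim(pixels)[2],
    height_px = dim(pixels)[1],
    native_mpp = native_mpp,
    reader_dialect = dialect
  ), class = "slide_handle")
}

resolve_mpp <- function(path, raw, mpp) {
  if (!is.null(mpp)) {
    mpp <- as.numeric(mpp)
    if (length(mpp) == 1) mpp <- c(mpp, mpp)
    if (any(!is.finite(mpp)) || any(mpp <= 0)) stopf("mpp must be positive")
    return(mpp)
  }
  for (sidecar in c(paste0(path, ".json"),
                    paste0(tools::file_path_sans_ext(path), ".json"))) {
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (!is.null(meta$mpp_x) && !is.null(meta$mpp_y)) {
        return(c(as.numeric(meta$mpp_x), as.numeric(meta$mpp_y)))
      }
      if (!is.null(meta$mpp)) {
        m <- as.numeric(meta$mpp)
        return(c(m, m))
      }
    }
  }
  # TIFF resolution tags: pixels per unit -> micrometres per pixel.
  xres <- attr(raw, "x.resolution")
  unit <- attr(raw, "resolution.unit")
  if (!is.null(xres) && is.finite(xres) && xres > 0 && !is.null(unit)) {
    um_per_unit <- switch(as.character(unit),
                          "cm" = 1e4, "3" = 1e4, "inch" = 25400, "2" = 25400,
                          NA_real_)
    if (is.finite(um_per_unit)) {
      yres <- attr(raw, "y.resolution")
      if (is.null(yres) || !is.finite(yres) || yres <= 0) yres <- xres
      return(c(um_per_unit / xres, um_per_unit / yres))
    }
  }
  stopf(paste0("micrometres-per-pixel unknown for %s: supply mpp= or a ",
               "JSON sidecar {\"mpp_x\":..., \"mpp_y\":...}"), path)
}

#' @exportS3Method base::print
print.slide_handle <- function(x, ...) {
  cat(sprintf("<slide_handle> %s\n  %d x %d px @ %.4f x %.4f um/px (%s)\n",
              x$path, x$width_px, x$height_px,
              x$native_mpp[1], x$native_mpp[2], x$reader_dialect))
  invisible(x)
}

#' Native-to-target resampling factor
#'
#' @param handle a `slide_handle`.
#' @param target_mpp target micrometres per pixel (default
#'   [HISTOCELL_MPP]).
#' @return numeric length 2: per-axis scale factor
#'   `native_mpp / target_mpp`.  Values above 1 upsample.
#' @export
rescale_factor <- function(handle, target_mpp = HISTOCELL_MPP) {
  if (!is.numeric(target_mpp) || any(target_mpp <= 0)) {
    stopf("target_mpp must be > 0")
  }
  handle$native_mpp / target_mpp
}

# Slide dimensions (width, height) expressed in the rescaled frame.
rescaled_dims <- function(handle, target_mpp = HISTOCELL_MPP) {
  sc <- rescale_factor(handle, target_mpp)
  pmax(1L, as.integer(round(c(handle$width_px, handle$height_px) * sc)))
}

#' Physical extent of a patch in micrometres
#'
#' @param width_px,height_px patch size in pixels.
#' @param mpp micrometres per pixel.
#' @return numeric length 2: (width_um, height_um).
#' @export
patch_extent_um <- function(width_px, height_px, mpp = HISTOCELL_MPP) {
  if (any(c(width_px, height_px) < 0)) stopf("sizes must be non-negative")
  if (mpp <= 0) stopf("mpp must be > 0")
  c(width_px * mpp, height_px * mpp)
}

#' Tiling origins for an overlapping patch grid
#'
#' Origins advance with stride `width - overlap` (`height - overlap`
#' vertically).  The final origin in each axis is clamped to
#' `dim - patch` so that every raster is full-size and every pixel is
#' covered; patches are enumerated row-major.
#'
#' @param slide_width,slide_height slide size in rescaled pixels.
#' @param width,height patch size in pixels.
#' @param overlap overlap between consecutive patches, `0 <= overlap < width`.
#' @return data.frame with 0-based columns `x`, `y`.
#' @export
patch_origins <- function(slide_width, slide_height,
                          width = 1600, height = 1200, overlap = 200) {
  if (overlap < 0 || overlap >= width || overlap >= height) {
    stopf("need 0 <= overlap < patch size")
  }
  ax <- function(dim, p, stride) {
    if (dim <= p) return(0L)
    org <- seq(0L, dim - p, by = stride)
    if (org[length(org)] + p < dim) org <- c(org, dim - p)
    as.integer(org)
  }
  xs <- ax(slide_width, width, width - overlap)
  ys <- ax(slide_height, height, height - overlap)
  data.frame(x = rep(xs, times = length(ys)),
             y = rep(ys, each = length(xs)))
}

#' Read one rescaled patch from a slide
#'
#' Extracts the rescaled-frame window `[x, x + w) x [y, y + h)` by
#' cropping the corresponding native region and resampling it
#' (bilinear) to `w x h`.  Area outside the slide is filled with 255
#' (white background).
#'
#' @param handle a `slide_handle`.
#' @param x,y 0-based origin in the rescaled frame.
#' @param w,h output size in pixels.
#' @inheritParams rescale_factor
#' @return a `slide_patch`: list with `pixels` (h x w x 3 array, 0..255),
#'   `origin` (x, y) and `size` (w, h).
#' @export
read_patch <- function(handle, x, y, w, h, target_mpp = HISTOCELL_MPP) {
  sc <- rescale_factor(handle, target_mpp)
  if (all(abs(sc - 1) < 1e-9)) {
    px <- crop_padded(handle$pixels, x, y, w, h)
  } else {
    nx0 <- floor(x / sc[1]); ny0 <- floor(y / sc[2])
    nw <- max(1L, ceiling(w / sc[1])); nh <- max(1L, ceiling(h / sc[2]))
    native <- crop_padded(handle$pixels, nx0, ny0, nw, nh)
    px <- resample_rgb(native, w, h)
  }
  structure(list(pixels = px, origin = c(x = x, y = y), size = c(w = w, h = h)),
            class = "slide_patch")
}

# Crop [x, x+w) x [y, y+h) from an HxWx3 array, padding out-of-bounds
# area with constant 255.
crop_padded <- function(pixels, x, y, w, h, fill = 255) {
  out <- array(fill, c(h, w, 3))
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  sx0 <- max(0, x); sy0 <- max(0, y)
  sx1 <- min(W, x + w); sy1 <- min(H, y + h)
  if (sx1 > sx0 && sy1 > sy0) {
    out[(sy0 - y + 1):(sy1 - y), (sx0 - x + 1):(sx1 - x), ] <-
      pixels[(sy0 + 1):sy1, (sx0 + 1):sx1, , drop = FALSE]
  }
  out
}

# Bilinear resample of an HxWx3 0..255 array to out_w x out_h.
resample_rgb <- function(pixels, out_w, out_h) {
  img <- EBImage::Image(aperm(pixels / 255, c(2, 1, 3)), colormode = "Color")
  res <- EBImage::resize(img, w = out_w, h = out_h, filter = "bilinear")
  aperm(EBImage::imageData(res), c(2, 1, 3)) * 255
}

#' Iterate overlapping patches over a slide
#'
#' Yields every tiling patch (row-major) at the target resolution.  For
#' the in-memory readers used here the full patch list is materialised;
#' `origins` allows restricting to a subset (e.g. when resuming a run).
#'
#' @inheritParams read_patch
#' @inheritParams patch_origins
#' @param origins optional data.frame of origins (columns `x`, `y`);
#'   default = full grid from [patch_origins()].
#' @return list of `slide_patch` objects.
#' @export
iter_patches <- function(handle, width = 1600, height = 1200, overlap = 200,
                         target_mpp = HISTOCELL_MPP, origins = NULL) {
  dims <- rescaled_dims(handle, target_mpp)
  if (is.null(origins)) {
    origins <- patch_origins(dims[1], dims[2], width, height, overlap)
  }
  lapply(seq_len(nrow(origins)), function(i) {
    read_patch(handle, origins$x[i], origins$y[i],
               min(width, dims[1]), min(height, dims[2]), target_mpp)
  })
}

#' Background-patch filter
#'
#' A patch is background when its mean value over all pixels and
#' channels is above 245 (bare glass) or below 10 (scanner border or
#' pen), and is then excluded from detection.
#'
#' @param patch a `slide_patch` or an H x W x 3 array with values 0..255.
#' @return logical.
#' @export
is_background <- function(patch) {
  px <- if (inherits(patch, "slide_patch")) patch$pixels else patch
  if (length(px) == 0) stopf("empty raster")
  m <- mean(px)
  m > 245 || m < 10
}
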