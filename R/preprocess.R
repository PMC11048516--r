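# Preprocessing: angiogram I/O, digital vasculature map (DVM) extraction,
# ETDRS regionation, binarization.

#' Construct a digital vasculature map (DVM) image
#'
#' A DVM is the grayscale en-face angiogram of one retinal capillary plexus,
#' carrying its physical scan geometry. Intensities must already be normalized
#' to \[0, 1\].
#'
#' @param pixels numeric matrix of intensities in \[0, 1\] (rows = image rows).
#' @param width_mm,height_mm physical scan extent; the standard macular scan
#'   is 3 x 3 mm.
#' @param center_rc fovea center as (row, col), 1-based pixel coordinates.
#'   Defaults to the geometric image center (the device centers the scan on
#'   the fovea).
#' @return object of class `dvm_image` with fields `pixels`, `width_mm`,
#'   `height_mm`, `center_rc` and the derived `pixel_size_mm`.
#' @export
dvm_image <- function(pixels, width_mm = 3, height_mm = width_mm,
                      center_rc = NULL) {
  .assert(is.matrix(pixels) && is.numeric(pixels), "pixels must be a numeric matrix")
  .assert(all(is.finite(pixels)), "pixels must be finite")
  .assert(min(pixels) >= 0 && max(pixels) <= 1,
          "intensities must lie in [0, 1]; normalize first (see extract_dvm)")
  .assert(width_mm > 0 && height_mm > 0, "scan extent must be positive",
          "octacrmb_config_error")
  if (is.null(center_rc)) center_rc <- (dim(pixels) + 1) / 2
  .assert(length(center_rc) == 2 &&
            center_rc[1] >= 1 && center_rc[1] <= nrow(pixels) &&
            center_rc[2] >= 1 && center_rc[2] <= ncol(pixels),
          "center_rc must lie inside the image")
  structure(list(pixels = pixels,
                 width_mm = width_mm, height_mm = height_mm,
                 center_rc = as.numeric(center_rc),
                 pixel_size_mm = width_mm / ncol(pixels)),
            class = "dvm_image")
}

#' @export
print.dvm_image <- function(x, ...) {
  cat(sprintf("<dvm_image> %d x %d px, %.1f x %.1f mm (%.2f um/px), center (%.1f, %.1f)\n",
              nrow(x$pixels), ncol(x$pixels), x$width_mm, x$height_mm,
              x$pixel_size_mm * 1000, x$center_rc[1], x$center_rc[2]))
  invisible(x)
}

#' Read a grayscale angiogram raster
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF export. Color rasters are
#' collapsed by averaging channels.
#'
#' @param path image file path.
#' @return numeric matrix of raw intensities in \[0, 1\].
#' @export
read_angiogram <- function(path) {
  .assert(file.exists(path), sprintf("image file not found: %s", path),
          "octacrmb_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  img
}

#' Extract the digital vasculature map from a device report raster
#'
#' Crops the en-face angiogram panel out of a larger report raster and
#' min-max normalizes it. The crop must be square (within one pixel); the
#' fovea center is taken as the crop center.
#'
#' @param report numeric matrix (a raster as returned by [read_angiogram()]).
#' @param crop_box `c(row, col, height, width)`: 1-based top-left corner and
#'   extent of the crop. Defaults to the full frame.
#' @param width_mm physical width of the cropped scan (default 3 mm).
#' @return a [dvm_image()].
#' @export
extract_dvm <- function(report, crop_box = NULL, width_mm = 3) {
  .assert(is.matrix(report) && is.numeric(report), "report must be a numeric matrix")
  if (is.null(crop_box)) crop_box <- c(1, 1, nrow(report), ncol(report))
  .assert(length(crop_box) == 4, "crop_box must be c(row, col, height, width)")
  r0 <- crop_box[1]; c0 <- crop_box[2]; h <- crop_box[3]; w <- crop_box[4]
  .assert(r0 >= 1 && c0 >= 1 && r0 + h - 1 <= nrow(report) &&
            c0 + w - 1 <= ncol(report),
          "crop_box must lie within the raster", "octacrmb_geometry_error")
  .assert(abs(h - w) <= 1, "crop must be square within 1 pixel",
          "octacrmb_geometry_error")
  px <- report[r0:(r0 + h - 1), c0:(c0 + w - 1), drop = FALSE]
  rng <- range(px)
  .assert(diff(rng) > 0, "constant-intensity crop: not an angiogram",
          "octacrmb_degenerate_image")
  px <- (px - rng[1]) / diff(rng)
  dvm_image(px, width_mm = width_mm)
}

#' ETDRS fovea / parafovea region masks
#'
#' Builds the standard macular regionation used for perfusion analysis: the
#' fovea is the central disc of 1 mm diameter, the parafovea the annulus
#' between the 1 mm and 3 mm diameter circles. Distances are physical,
#' measured between pixel centers.
#'
#' @param dvm a [dvm_image()].
#' @return object of class `region_masks`: logical matrices `fovea_mask`,
#'   `parafovea_mask`, `full_mask`.
#' @export
make_etdrs_masks <- function(dvm) {
  stopifnot(inherits(dvm, "dvm_image"))
  .assert(dvm$pixel_size_mm > 0, "pixel size must be positive",
          "octacrmb_config_error")
  d_mm <- .radius_grid(nrow(dvm$pixels), ncol(dvm$pixels), dvm$center_rc) *
    dvm$pixel_size_mm
  structure(list(fovea_mask = d_mm < 0.5,
                 parafovea_mask = d_mm >= 0.5 & d_mm < 1.5,
                 full_mask = matrix(TRUE, nrow(dvm$pixels), ncol(dvm$pixels))),
            class = "region_masks")
}

#' Construct a binary vessel map
#'
#' Low-level constructor; most users obtain one from [binarize()]. Carries
#' scan geometry so downstream metrics can convert to physical units.
#'
#' @param pixels logical matrix, `TRUE` = vessel.
#' @param pixel_size_mm physical pixel pitch.
#' @param center_rc fovea center (row, col); default geometric center.
#' @param method,threshold_used provenance of the segmentation.
#' @return object of class `binary_vessel_map`.
#' @export
binary_vessel_map <- function(pixels, pixel_size_mm, center_rc = NULL,
                              method = "external", threshold_used = NA_real_) {
  .assert(is.matrix(pixels) && is.logical(pixels), "pixels must be a logical matrix")
  if (is.null(center_rc)) center_rc <- (dim(pixels) + 1) / 2
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm,
                 center_rc = as.numeric(center_rc), method = method,
                 threshold_used = threshold_used),
            class = "binary_vessel_map")
}

#' Binarize a DVM into a vessel map
#'
#' Default method is local mean (adaptive) thresholding: a pixel is vessel if
#' its intensity exceeds the mean over a square window of `local_window_mm`
#' plus `offset`. The local method compensates the slow intensity falloff of
#' OCTA signal with depth and vignetting; global Otsu is available as an
#' alternative. Intensities are min-max renormalized internally, so the
#' local-mean segmentation is invariant to affine intensity rescaling.
#' Connected components smaller than `min_object_px` are removed as speckle.
#'
#' @param dvm a [dvm_image()].
#' @param method `"local_mean"` or `"global_otsu"`.
#' @param local_window_mm adaptive window side (default 0.2 mm).
#' @param offset additive threshold margin above the local mean, on the
#'   normalized intensity scale (default 0.08).
#' @param min_object_px components smaller than this are dropped (default 10;
#'   0 disables).
#' @return a [binary_vessel_map()]; `threshold_used` is the Otsu level for the
#'   global method and the offset for the local method.
#' @export
binarize <- function(dvm, method = c("local_mean", "global_otsu"),
                     local_window_mm = 0.2, offset = 0.08,
                     min_object_px = 10) {
  stopifnot(inherits(dvm, "dvm_image"))
  method <- match.arg(method)
  px <- dvm$pixels
  rng <- range(px)
  .assert(diff(rng) > 0, "uniform image cannot be segmented",
          "octacrmb_degenerate_segmentation")
  px <- (px - rng[1]) / diff(rng)
  if (method == "global_otsu") {
    thr <- EBImage::otsu(EBImage::Image(px), range = c(0, 1))
    vessel <- px > thr
  } else {
    w <- max(3L, round(local_window_mm / dvm$pixel_size_mm))
    if (w %% 2 == 0) w <- w + 1L
    vessel <- px > .box_mean(px, w) + offset
    thr <- offset
  }
  if (min_object_px > 0 && any(vessel)) {
    lab <- EBImage::bwlabel(vessel)
    sz <- tabulate(lab[lab > 0])
    vessel <- matrix(lab > 0 & sz[pmax(lab, 1)] >= min_object_px,
                     nrow(vessel), ncol(vessel))
  }
  frac <- mean(vessel)
  .assert(frac > 0 && frac < 1,
          sprintf("degenerate segmentation: vessel fraction %.3f (method %s)",
                  frac, method),
          "octacrmb_degenerate_segmentation")
  binary_vessel_map(vessel, dvm$pixel_size_mm, dvm$center_rc,
                    method = method, threshold_used = thr)
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %d x %d px, vessel fraction %.3f (%s)\n",
              nrow(x$pixels), ncol(x$pixels), mean(x$pixels), x$method))
  invisible(x)
}

#' Write a logical mask as a PNG image
#' @param mask logical matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
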