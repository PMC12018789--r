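#' @title Object and adaptive-erode segmentation masks
#'
#' @description Brightfield objects appear dark on a bright background. The
#'   object mask is an Otsu threshold of the smoothed contrast map (largest
#'   8-connected component, holes filled). The adaptive-erode refinement cuts
#'   that region at a contrast level set by its threshold parameter; at the
#'   default threshold 95 the cut sits at the half-maximum contrast contour,
#'   the unbiased edge locator under symmetric blur, which is what makes
#'   bead sizes come out right. A deliberately loose "default" mask (a fixed
#'   dilation) emulates the vendor default that overestimates bead size.
#'
#' @name masking
NULL

#' Mask container
#'
#' @param bits logical matrix, same dimensions as the parent image
#' @param kind `"object"`, `"adaptive_erode"` or `"default_loose"`
#' @param pixel_size_um micrometres per pixel
#' @param ae_threshold adaptive-erode threshold (only for that kind)
#' @return an object of class `ifc_mask`
#' @export
ifc_mask <- function(bits, kind, pixel_size_um, ae_threshold = NA_real_) {
  stopifnot(is.matrix(bits), is.logical(bits))
  structure(list(bits = bits, kind = kind, pixel_size_um = pixel_size_um,
                 ae_threshold = ae_threshold), class = "ifc_mask")
}

#' @export
print.ifc_mask <- function(x, ...) {
  cat(sprintf("<ifc_mask kind=%s, %d px foreground, %.3g um/px>\n",
              x$kind, sum(x$bits), x$pixel_size_um))
  invisible(x)
}

#' Estimate image background and a robust contrast scale
#'
#' The background level is the median intensity of a 3-pixel border frame
#' (single-object gallery frames have object-free margins); the contrast
#' scale is the 99th percentile of `|I - background|` over the whole image.
#'
#' @param image an [obj_image]
#' @return list with `background`, `scale` and a `degenerate` flag (`TRUE`
#'   when the image is constant, i.e. scale 0)
#' @export
estimate_background <- function(image) {
  px <- image$pixels
  if (nrow(px) < 16 || ncol(px) < 16) stop("image must be at least 16x16 px")
  nr <- nrow(px); nc <- ncol(px)
  border <- c(px[1:3, ], px[(nr - 2):nr, ], px[, 1:3], px[, (nc - 2):nc])
  bg <- median(border)
  sc <- unname(quantile(abs(px - bg), 0.99))
  list(background = bg, scale = sc, degenerate = sc == 0)
}

.largest_component <- function(bits) {
  lab <- .label8_cpp(bits)
  if (max(lab) == 0) return(bits & FALSE)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

.fill_holes <- function(bits) {
  out <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bits * 1))) > 0
  matrix(out, nrow(bits), ncol(bits))
}

.dilate_px <- function(bits, r) {
  if (r <= 0) return(bits)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = if (r == 1) "box" else "disc")
  out <- EBImage::imageData(EBImage::dilate(EBImage::Image(bits * 1), brush)) > 0
  matrix(out, nrow(bits), ncol(bits))
}

#' Segment the object mask
#'
#' Gaussian-smooths (sigma = 1 px) the contrast map `|I - background|`,
#' thresholds it by Otsu's criterion, keeps the largest 8-connected
#' component and fills holes.
#'
#' @param image an [obj_image]
#' @param min_contrast minimum contrast floor (intensity units); when no
#'   pixel exceeds it the image is treated as empty
#' @param smooth_sigma_px smoothing scale in pixels
#' @return an [ifc_mask] of kind `"object"`
#' @export
object_mask <- function(image, min_contrast = 0.05, smooth_sigma_px = 1) {
  bgst <- estimate_background(image)
  contrast <- abs(image$pixels - bgst$background)
  if (bgst$degenerate || max(contrast) < min_contrast)
    stop(.empty_object_error(image))
  sm <- .gauss_blur(contrast, smooth_sigma_px)
  z <- sm / max(sm)
  th <- EBImage::otsu(EBImage::Image(z), range = c(0, 1))
  bits <- z > th
  if (!any(bits)) stop(.empty_object_error(image))
  bits <- .fill_holes(.largest_component(bits))
  ifc_mask(bits, "object", image$pixel_size_um)
}

.empty_object_error <- function(image) {
  structure(class = c("ifc_empty_object", "error", "condition"),
            list(message = "empty object: no pixel above the contrast floor",
                 call = sys.call(-1)))
}

#' Adaptive-erode refinement of the object mask
#'
#' Computes the normalized contrast `c(p) = |I(p) - background| / scale`
#' (clipped to `[0, 1]`, `scale` from [estimate_background()]) and keeps, of
#' the filled 1-px dilation of the object mask, the pixels with
#' `c(p) >= (100 - threshold) / 10` (level clipped to `[0, 1]`). The default
#' threshold 95 therefore cuts at the half-maximum contrast contour;
#' threshold 100 keeps the whole candidate region. The mask is the connected
#' component containing the object centroid, holes filled. Masks are nested:
#' a lower threshold always gives a subset of a higher one.
#'
#' @param image an [obj_image]
#' @param om the [object_mask()] of the image
#' @param threshold adaptive-erode threshold, in `[50, 100]`
#' @return an [ifc_mask] of kind `"adaptive_erode"`; if the candidate set is
#'   empty, the object mask is returned (as kind `"adaptive_erode"`) with a
#'   warning
#' @export
adaptive_erode_mask <- function(image, om, threshold = 95) {
  stopifnot(inherits(om, "ifc_mask"), om$kind == "object")
  if (threshold < 50 || threshold > 100)
    stop("threshold must be in [50, 100]")
  bgst <- estimate_background(image)
  if (bgst$degenerate) stop("degenerate constant image")
  cmap <- pmin(abs(image$pixels - bgst$background) / bgst$scale, 1)
  level <- min(max((100 - threshold) / 10, 0), 1)
  candidate <- .fill_holes(.dilate_px(om$bits, 1L)) & (cmap >= level)
  if (!any(candidate)) {
    warning("adaptive-erode candidate set empty; falling back to object mask")
    return(ifc_mask(om$bits, "adaptive_erode", om$pixel_size_um, threshold))
  }
  lab <- .label8_cpp(candidate)
  ij <- which(om$bits, arr.ind = TRUE)
  cen <- round(colMeans(ij))
  keep <- lab[cen[1], cen[2]]
  if (keep == 0) {  # centroid outside candidate (e.g. ring): take largest
    tab <- tabulate(lab[lab > 0])
    keep <- which.max(tab)
  }
  bits <- .fill_holes(lab == keep)
  ifc_mask(bits, "adaptive_erode", om$pixel_size_um, threshold)
}

#' Deliberately loose default-style mask
#'
#' A filled morphological dilation of the object mask by `dilation_px`
#' pixels, emulating the looseness of vendor default brightfield masks,
#' which overestimate bead modal size.
#'
#' @param om an [object_mask()]
#' @param dilation_px dilation radius in pixels
#' @return an [ifc_mask] of kind `"default_loose"`
#' @export
default_loose_mask <- function(om, dilation_px = 4L) {
  stopifnot(inherits(om, "ifc_mask"))
  bits <- .fill_holes(.dilate_px(om$bits, as.integer(dilation_px)))
  ifc_mask(bits, "default_loose", om$pixel_size_um)
}

#' Write a mask as a 0/255 PNG alongside a gallery
#'
#' @param mask an [ifc_mask]
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to write masks")
  png::writePNG(mask$bits * 1, path)
  invisible(path)
}
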