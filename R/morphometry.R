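#' @title Size and shape features in micrometres
#'
#' @description The six size features measured on the adaptive-erode mask:
#'   area-equivalent diameter (`2 * sqrt(area / pi)`), bounding-rectangle
#'   height and width (long and short side of the minimum-area rotated
#'   rectangle), best-fit-ellipse major axis (from second central moments),
#'   fold-tolerant length (geodesic diameter of the mask) and maximum
#'   thickness (largest inscribed width, from the Euclidean distance
#'   transform); plus the two gating features, circularity and
#'   elongatedness, whose relative ordering drives doublet removal and
#'   polar/equatorial view sorting.
#'
#' @name morphometry
NULL

.mask_bits <- function(mask) {
  if (inherits(mask, "ifc_mask")) mask$bits else mask
}

#' Mask area in square micrometres
#'
#' @param mask an [ifc_mask] or logical matrix
#' @param pixel_size_um micrometres per pixel (taken from the mask if absent)
#' @return foreground pixel count times `pixel_size_um^2`
#' @export
compute_area <- function(mask, pixel_size_um = mask$pixel_size_um) {
  bits <- .mask_bits(mask)
  if (!any(bits)) stop("empty mask")
  sum(bits) * pixel_size_um^2
}

#' Area-equivalent circular diameter
#'
#' The diameter of the circle with the same area as the object:
#' `2 * sqrt(area / pi)`.
#'
#' @param area_um2 positive area in square micrometres
#' @return diameter in micrometres
#' @export
equivalent_diameter <- function(area_um2) {
  if (any(area_um2 <= 0)) stop("area must be positive")
  2 * sqrt(area_um2 / pi)
}

# boundary pixels: foreground with a 4-neighbour outside the mask (or frame)
.boundary_bits <- function(bits) {
  nr <- nrow(bits); nc <- ncol(bits)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- bits
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  bits & !interior
}

# centres of the boundary pixels; rectangle sides get a +1 px correction
# (centre extents understate physical extent by one pixel; axis-aligned
# rectangles then measure exactly)
.boundary_points <- function(bits) {
  ij <- which(.boundary_bits(bits), arr.ind = TRUE)
  cbind(ij[, 1], ij[, 2])
}

# minimum-area rotated rectangle by rotating calipers over hull edges;
# returns c(long, short) side lengths in pixel units
.min_area_rect <- function(pts) {
  hull <- grDevices::chull(pts)
  P <- pts[hull, , drop = FALSE]
  n <- nrow(P)
  if (n == 1) return(c(0, 0))
  if (n == 2) return(c(sqrt(sum((P[1, ] - P[2, ])^2)), 0))
  best <- c(Inf, Inf, Inf)   # area, side1, side2
  for (k in seq_len(n)) {
    e <- P[k %% n + 1, ] - P[k, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2], u[1])
    p1 <- P %*% u
    p2 <- P %*% v
    s1 <- diff(range(p1)); s2 <- diff(range(p2))
    if (s1 * s2 < best[1]) best <- c(s1 * s2, s1, s2)
  }
  sort(best[2:3], decreasing = TRUE)
}

#' Bounding-rectangle height and width
#'
#' Sides of the minimum-area rotated bounding rectangle of the mask, from
#' rotating calipers over the convex hull of boundary pixel centres plus a
#' one-pixel side correction (so a single pixel measures one pixel on each
#' side and axis-aligned rectangles measure exactly). Height is the longer
#' side, width the shorter.
#'
#' @inheritParams compute_area
#' @return named numeric vector `c(height_um, width_um)`
#' @export
bounding_rect <- function(mask, pixel_size_um = mask$pixel_size_um) {
  bits <- .mask_bits(mask)
  if (!any(bits)) stop("empty mask")
  sides <- (.min_area_rect(.boundary_points(bits)) + 1) * pixel_size_um
  c(height_um = sides[1], width_um = sides[2])
}

#' Major axis of the best-fit ellipse
#'
#' Full length of the major axis of the ellipse with the same second central
#' moments as the mask pixels: `4 * sqrt(largest eigenvalue)` of the
#' pixel-coordinate covariance (population moments, plus the 1/12 per-pixel
#' variance of a unit square).
#'
#' @inheritParams compute_area
#' @return major axis length in micrometres
#' @export
major_axis <- function(mask, pixel_size_um = mask$pixel_size_um) {
  bits <- .mask_bits(mask)
  ij <- which(bits, arr.ind = TRUE)
  if (nrow(ij) < 2) stop("mask must have at least 2 pixels")
  ctr <- sweep(ij, 2, colMeans(ij))
  cv <- crossprod(ctr) / nrow(ij) + diag(1 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] / ev[1] < 1e-6)  # collinear degenerate mask
    return(geodesic_length(mask, pixel_size_um))
  4 * sqrt(ev[1]) * pixel_size_um
}

#' Fold-tolerant object length (geodesic diameter)
#'
#' The longest shortest-path between boundary pixels inside the mask, plus a
#' one-pixel endpoint correction (pixel-centre distances understate physical
#' extent by one pixel). For convex objects this equals the maximum Feret
#' diameter; for folded objects it follows the fold, which is what makes the
#' feature robust for bent or curved particles. Masks up to `exact_limit`
#' pixels are measured exactly over all boundary pairs; larger masks use an
#' iterated farthest-point sweep (error below 2% on convex shapes).
#'
#' @inheritParams compute_area
#' @param exact_limit pixel-count cutoff for the exact all-pairs computation
#' @return length in micrometres
#' @export
geodesic_length <- function(mask, pixel_size_um = mask$pixel_size_um,
                            exact_limit = 20000L) {
  bits <- .mask_bits(mask)
  if (!any(bits)) stop("empty mask")
  res <- .geodesic_diameter_cpp(bits, as.integer(exact_limit))
  (res$diameter + 1) * pixel_size_um
}

#' Maximum thickness (largest inscribed width)
#'
#' Twice the maximum of the Euclidean distance transform of the mask
#' (distance to the nearest background pixel, frame padded), in micrometres.
#' For a rectangle this is its shorter side; for a disk, its diameter.
#'
#' @inheritParams compute_area
#' @return thickness in micrometres
#' @export
thickness_max <- function(mask, pixel_size_um = mask$pixel_size_um) {
  bits <- .mask_bits(mask)
  if (!any(bits)) stop("empty mask")
  nr <- nrow(bits); nc <- ncol(bits)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- bits * 1
  d <- EBImage::distmap(EBImage::Image(pad))
  2 * max(d) * pixel_size_um
}

#' Circularity score
#'
#' Mean boundary-pixel distance to the centroid divided by the standard
#' deviation of that distance (high for circles, low for doublets and
#' irregular shapes), capped at 100. Scale-invariant; only its ordering is
#' used for gating.
#'
#' @inheritParams compute_area
#' @return dimensionless score, `NA` for masks with fewer than 8 boundary
#'   pixels
#' @export
circularity <- function(mask) {
  bits <- .mask_bits(mask)
  ij <- which(bits, arr.ind = TRUE)
  bd <- which(.boundary_bits(bits), arr.ind = TRUE)
  if (nrow(bd) < 8) return(NA_real_)
  ctr <- colMeans(ij)
  r <- sqrt((bd[, 1] - ctr[1])^2 + (bd[, 2] - ctr[2])^2)
  mu <- mean(r); s <- sd(r)
  if (s < mu / 100) 100 else min(mu / s, 100)
}

#' Elongatedness (bounding-rectangle aspect ratio)
#'
#' Height over width of the minimum-area bounding rectangle; 1 for squares
#' and circles, roughly the view aspect for oblate pollen seen equatorially.
#' Used to sort polar from equatorial views.
#'
#' @inheritParams compute_area
#' @return dimensionless ratio `>= 1`
#' @export
elongatedness <- function(mask) {
  hw <- bounding_rect(mask, pixel_size_um = 1)
  unname(hw[1] / max(hw[2], 1e-9))
}

.na_feature_row <- function(object_id, pixel_size_um, status) {
  data.frame(object_id = object_id, area_um2 = NA_real_,
             diameter_um = NA_real_, height_um = NA_real_,
             width_um = NA_real_, major_axis_um = NA_real_,
             length_um = NA_real_, thickness_max_um = NA_real_,
             circularity = NA_real_, elongatedness = NA_real_,
             intensity_ch01 = NA_real_, intensity_ch09 = NA_real_,
             border_touch = NA, pixel_size_um = pixel_size_um,
             status = status, stringsAsFactors = FALSE)
}

#' Extract the full feature record of one object
#'
#' Runs masking (object mask, then adaptive-erode refinement) and computes
#' all size features on the adaptive-erode mask; intensities (summed
#' background-subtracted absorbance) are measured within the object mask.
#' Failed objects are returned as a row with `status` set, never dropped.
#'
#' @param image an [obj_image]
#' @param object_id identifier for the output row
#' @param ae_threshold adaptive-erode threshold (default 95)
#' @param mask_kind which mask to measure size features on:
#'   `"adaptive_erode"` (the calibrated choice) or `"default_loose"` (the
#'   vendor-default emulation used for the overestimation comparison)
#' @param loose_dilation_px dilation radius of the loose mask
#' @return one-row data frame with the FeatureRecord columns and a `status`
#'   column (`"ok"` or an error code)
#' @export
extract_features <- function(image, object_id = "obj00001",
                             ae_threshold = 95,
                             mask_kind = c("adaptive_erode", "default_loose"),
                             loose_dilation_px = 4L) {
  mask_kind <- match.arg(mask_kind)
  px <- image$pixel_size_um
  om <- tryCatch(object_mask(image), ifc_empty_object = function(e) e)
  if (inherits(om, "condition"))
    return(.na_feature_row(object_id, px, "empty_object"))
  mask <- if (mask_kind == "adaptive_erode")
    adaptive_erode_mask(image, om, threshold = ae_threshold)
  else default_loose_mask(om, loose_dilation_px)

  area <- compute_area(mask)
  hw <- bounding_rect(mask)
  bits <- om$bits
  border_touch <- any(bits[1, ]) || any(bits[nrow(bits), ]) ||
    any(bits[, 1]) || any(bits[, ncol(bits)])
  bgst <- estimate_background(image)
  inten <- sum(bgst$background - image$pixels[bits])

  data.frame(object_id = object_id, area_um2 = area,
             diameter_um = equivalent_diameter(area),
             height_um = unname(hw[1]), width_um = unname(hw[2]),
             major_axis_um = major_axis(mask),
             length_um = geodesic_length(mask),
             thickness_max_um = thickness_max(mask),
             circularity = circularity(mask),
             elongatedness = unname(hw[1] / max(hw[2], 1e-9)),
             intensity_ch01 = inten, intensity_ch09 = inten,
             border_touch = border_touch, pixel_size_um = px,
             status = "ok", stringsAsFactors = FALSE)
}

#' Extract features for every object of a gallery
#'
#' @param gallery an `ifc_gallery` (from [render_gallery()] or
#'   [read_gallery()]) or a gallery directory path
#' @inheritParams extract_features
#' @return data frame with one row per object; when the gallery carries a
#'   truth table, its `species_label`, `individual_label` and `year_label`
#'   columns are joined in
#' @export
extract_gallery <- function(gallery, ae_threshold = 95,
                            mask_kind = "adaptive_erode",
                            loose_dilation_px = 4L) {
  if (is.character(gallery)) gallery <- read_gallery(gallery)
  stopifnot(inherits(gallery, "ifc_gallery"))
  rows <- lapply(names(gallery$images), function(id)
    extract_features(gallery$images[[id]], object_id = id,
                     ae_threshold = ae_threshold, mask_kind = mask_kind,
                     loose_dilation_px = loose_dilation_px))
  feats <- do.call(rbind, rows)
  lbl <- intersect(c("object_id", "species_label", "individual_label",
                     "year_label"), names(gallery$truth))
  if (length(lbl) > 1)
    feats <- merge(feats, gallery$truth[, lbl], by = "object_id", sort = TRUE)
  feats[order(feats$object_id), , drop = FALSE]
}
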