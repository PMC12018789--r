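#' @title Synthetic brightfield object galleries with exact ground truth
#'
#' @description Renders per-object brightfield-like images (dark object on a
#'   bright background, Gaussian point-spread blur, additive Gaussian noise)
#'   for the shape classes seen in pollen imaging flow cytometry: calibration
#'   beads, spheroid pollen, oblate pollen in polar or equatorial view,
#'   elongated pollen, saccate (Pinaceae-like) pollen, debris, touching
#'   doublets and frame-cropped objects. Every rendered object carries a
#'   ground-truth record so downstream masking, morphometry and gating can be
#'   tested against known sizes.
#'
#' @name synthetic-gallery
NULL

.SHAPE_CLASSES <- c("bead", "spheroid", "oblate_polar", "oblate_equatorial",
                    "elongated", "saccate", "debris", "doublet", "cropped")

#' Single-object brightfield image container
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`
#' @param pixel_size_um micrometres per pixel edge (0.5 at x40, 1.0 at x20)
#' @param channel_id brightfield channel label, e.g. `"Ch09"`
#' @return an object of class `obj_image`
#' @export
obj_image <- function(pixels, pixel_size_um, channel_id = "Ch09") {
  stopifnot(is.matrix(pixels), is.numeric(pixels), pixel_size_um > 0)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel_id = channel_id), class = "obj_image")
}

#' @export
print.obj_image <- function(x, ...) {
  cat(sprintf("<obj_image %dx%d px, %.3g um/px, channel %s>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel_id))
  invisible(x)
}

#' Specification of one synthetic object
#'
#' @param shape_class one of `r paste0('"', .SHAPE_CLASSES, '"', collapse = ", ")`
#' @param size_um true longest dimension in micrometres
#' @param aspect dimensionless aspect ratio, >= 1
#' @param psf_sigma_um Gaussian blur scale in micrometres
#' @param noise_sd additive Gaussian noise SD in intensity units (image range
#'   is `[0, 1]`)
#' @param background_level background intensity
#' @param contrast object-to-background intensity difference; objects are
#'   dark, i.e. rendered at `background_level - contrast`
#' @return a list of class `synthetic_object_spec`
#' @export
synthetic_object_spec <- function(shape_class, size_um, aspect = 1,
                                  psf_sigma_um = 0.5, noise_sd = 0.02,
                                  background_level = 0.75, contrast = 0.5) {
  shape_class <- match.arg(shape_class, .SHAPE_CLASSES)
  if (!is.numeric(size_um) || size_um <= 0) stop("size_um must be positive")
  if (aspect < 1) stop("aspect must be >= 1")
  if (contrast <= 0 || background_level - contrast < 0)
    stop("contrast must be positive and not exceed background_level")
  structure(list(shape_class = shape_class, size_um = size_um,
                 aspect = aspect, psf_sigma_um = psf_sigma_um,
                 noise_sd = noise_sd, background_level = background_level,
                 contrast = contrast), class = "synthetic_object_spec")
}

# ---- analytic silhouettes -------------------------------------------------

# Each silhouette is an indicator over object-local micrometre coordinates
# (origin at the object centre). Returns list(fun, area_um2 (NA = numeric),
# extent_um = longest dimension).
.make_silhouette <- function(spec, angle = 0) {
  s <- spec$size_um
  a <- spec$aspect
  rot <- function(x, y) {
    if (angle == 0) return(list(x = x, y = y))
    list(x = cos(angle) * x + sin(angle) * y,
         y = -sin(angle) * x + cos(angle) * y)
  }
  disk <- function(cx, cy, r) function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2
  switch(spec$shape_class,
    bead = ,
    spheroid = ,
    cropped = ,
    oblate_polar = list(fun = disk(0, 0, s / 2), area_um2 = pi * (s / 2)^2),
    oblate_equatorial = list(
      fun = function(x, y) {
        p <- rot(x, y)
        (p$x / (s / 2))^2 + (p$y / (s / (2 * a)))^2 <= 1
      },
      area_um2 = pi * (s / 2) * (s / (2 * a))),
    elongated = {
      # capsule: rectangle with semicircular caps, total length s, width s/a
      w <- s / a
      list(fun = function(x, y) {
        p <- rot(x, y)
        ax <- pmin(pmax(p$x, -(s - w) / 2), (s - w) / 2)
        (p$x - ax)^2 + p$y^2 <= (w / 2)^2
      },
      area_um2 = (s - w) * w + pi * (w / 2)^2)
    },
    saccate = {
      # corpus disk diameter d plus two sacci (0.6 d) at +/- 0.55 d; total
      # span along the saccus axis is 1.7 d, so d = s / 1.7
      d <- s / 1.7
      list(fun = function(x, y) {
        p <- rot(x, y)
        disk(0, 0, d / 2)(p$x, p$y) |
          disk(0.55 * d, 0, 0.3 * d)(p$x, p$y) |
          disk(-0.55 * d, 0, 0.3 * d)(p$x, p$y)
      }, area_um2 = NA_real_)
    },
    doublet = {
      # two overlapping pollen profiles; centres 1.8 r apart -> span 3.8 r
      r <- s / 3.8
      list(fun = function(x, y) {
        p <- rot(x, y)
        disk(-0.9 * r, 0, r)(p$x, p$y) | disk(0.9 * r, 0, r)(p$x, p$y)
      }, area_um2 = NA_real_)
    },
    debris = {
      # small irregular blob: three jittered disks
      r0 <- s / 3
      off <- matrix(runif(6, -s / 5, s / 5), ncol = 2)
      rr <- r0 * runif(3, 0.5, 1)
      list(fun = function(x, y) {
        p <- rot(x, y)
        disk(off[1, 1], off[1, 2], rr[1])(p$x, p$y) |
          disk(off[2, 1], off[2, 2], rr[2])(p$x, p$y) |
          disk(off[3, 1], off[3, 2], rr[3])(p$x, p$y)
      }, area_um2 = NA_real_)
    },
    stop("unknown shape_class: ", spec$shape_class))
}

# Rasterize an indicator to per-pixel coverage by 4x4 supersampling.
# centre_um = object centre in frame coordinates (um, origin = frame centre).
.rasterize <- function(fun, nr, nc, pixel_size_um, centre_um = c(0, 0),
                       ss = 4L) {
  px <- pixel_size_um
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss    # subpixel offsets in px units
  xs <- ((seq_len(nc) - (nc + 1) / 2)) * px - centre_um[1]
  ys <- ((seq_len(nr) - (nr + 1) / 2)) * px - centre_um[2]
  cov <- matrix(0, nr, nc)
  for (dx in sub) for (dy in sub) {
    X <- matrix(rep(xs + dx * px, each = nr), nr, nc)
    Y <- matrix(rep(ys + dy * px, times = nc), nr, nc)
    cov <- cov + fun(X, Y)
  }
  cov / ss^2
}

.gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  size <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  out <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(m), k, boundary = "replicate"))
  matrix(out, nrow(m), ncol(m))
}

# Core renderer shared by render_bead / render_pollen.
.render_object <- function(spec, pixel_size_um, object_id = "obj00001",
                           species_label = "species1",
                           individual_label = "ind1", year_label = "y1") {
  px <- pixel_size_um
  if (spec$size_um < 3 * px)
    stop("object size ", spec$size_um, " um is below the resolution limit (",
         3 * px, " um) at ", px, " um/px")
  sil_angle <- if (spec$shape_class %in%
                   c("oblate_equatorial", "elongated", "saccate", "doublet"))
    runif(1, 0, pi) else 0
  sil <- .make_silhouette(spec, angle = sil_angle)

  frame_um <- 1.8 * spec$size_um
  n <- max(16L, as.integer(ceiling(frame_um / px)))
  centre <- runif(2, -px / 2, px / 2)          # subpixel jitter
  if (spec$shape_class == "cropped") {
    # shift the object so it intersects the frame border
    centre[1] <- centre[1] + runif(1, 0.55, 0.75) * spec$size_um
  }
  cov <- .rasterize(sil$fun, n, n, px, centre_um = centre)
  true_area <- if (is.na(sil$area_um2)) {
    # numeric ground truth from a fine uncropped raster of the silhouette
    fine <- .rasterize(sil$fun, 2L * n, 2L * n, px / 2, centre_um = c(0, 0))
    sum(fine) * (px / 2)^2
  } else sil$area_um2

  img <- spec$background_level - spec$contrast * cov
  img <- .gauss_blur(img, spec$psf_sigma_um / px)
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), n, n)
  img <- pmin(pmax(img, 0), 1)

  view <- switch(spec$shape_class, oblate_polar = "polar",
                 oblate_equatorial = "equatorial", "none")
  truth <- data.frame(
    object_id = object_id, shape_class = spec$shape_class,
    true_length_um = spec$size_um, true_area_um2 = true_area,
    true_view = view, species_label = species_label,
    individual_label = individual_label, year_label = year_label,
    pixel_size_um = px, stringsAsFactors = FALSE)
  list(image = obj_image(img, px), truth = truth)
}

#' Render one calibration bead image
#'
#' Renders a single blurred, noise-corrupted disk of known diameter, the
#' synthetic analogue of a NIST-traceable latex sizing bead (the L20 standard
#' has a certified modal diameter of 19.98 um).
#'
#' @param diameter_um true bead diameter (um); must be at least
#'   `3 * pixel_size_um`
#' @param pixel_size_um micrometres per pixel (0.5 at x40, 1.0 at x20)
#' @param psf_sigma_um Gaussian blur scale (um); default one pixel
#' @param noise_sd additive noise SD in intensity units
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so gallery-level seeding stays reproducible)
#' @param object_id identifier recorded in the ground-truth row
#' @return list with elements `image` (an [obj_image]) and `truth`
#'   (one-row ground-truth data frame)
#' @export
#' @examples
#' b <- render_bead(19.98, pixel_size_um = 0.5, seed = 1)
#' dim(b$image$pixels)
render_bead <- function(diameter_um, pixel_size_um = 0.5,
                        psf_sigma_um = pixel_size_um, noise_sd = 0.02,
                        seed = NULL, object_id = "bead00001") {
  if (!is.null(seed)) set.seed(seed)
  spec <- synthetic_object_spec("bead", diameter_um,
                                psf_sigma_um = psf_sigma_um,
                                noise_sd = noise_sd)
  .render_object(spec, pixel_size_um, object_id = object_id,
                 species_label = "bead", individual_label = "bead",
                 year_label = "none")
}

#' Render one synthetic pollen-like object
#'
#' @param spec a [synthetic_object_spec()]
#' @param pixel_size_um micrometres per pixel
#' @param seed optional integer seed
#' @param object_id,species_label,individual_label,year_label labels copied
#'   into the ground-truth record
#' @return list with elements `image` and `truth` as for [render_bead()]
#' @export
render_pollen <- function(spec, pixel_size_um = 0.5, seed = NULL,
                          object_id = "obj00001", species_label = "species1",
                          individual_label = "ind1", year_label = "y1") {
  stopifnot(inherits(spec, "synthetic_object_spec"))
  if (!is.null(seed)) set.seed(seed)
  .render_object(spec, pixel_size_um, object_id = object_id,
                 species_label = species_label,
                 individual_label = individual_label, year_label = year_label)
}

.default_class_params <- function() {
  list(
    bead = list(size = 19.98, aspect = 1, contrast = 0.5),
    spheroid = list(size = 25, aspect = 1, contrast = 0.5),
    oblate_polar = list(size = 30, aspect = 1.6, contrast = 0.5),
    oblate_equatorial = list(size = 30, aspect = 1.6, contrast = 0.5),
    elongated = list(size = 60, aspect = 3, contrast = 0.5),
    saccate = list(size = 68, aspect = 1, contrast = 0.5),
    debris = list(size = 4, aspect = 1, contrast = 0.12),
    doublet = list(size = 28, aspect = 1, contrast = 0.5),
    cropped = list(size = 25, aspect = 1, contrast = 0.5))
}

#' Render a gallery of synthetic objects with a ground-truth table
#'
#' Object class counts are drawn multinomially from `composition`; object
#' sizes are Gaussian around the per-class mean with coefficient of variation
#' `size_cv`; objects are assigned uniformly to `n_individuals` individuals
#' (with Gaussian between-individual size effects) and to `year_labels`
#' (with optional fixed per-year mean shifts). The gallery is capped at
#' `particle_limit` objects, mirroring the instrument's acquisition stop
#' (default 5000 particles).
#'
#' @param n_objects requested number of objects
#' @param composition named fractions over shape classes, summing to 1
#' @param pixel_size_um micrometres per pixel
#' @param seed integer seed; the whole gallery is a deterministic function
#'   of it
#' @param out_dir optional directory; when given, one TIFF per object plus
#'   `truth.csv` are written there (see [write_gallery()])
#' @param species_label species name recorded in the truth table
#' @param n_individuals number of individuals (biological replicates)
#' @param individual_sd_um SD of between-individual mean size effects (um)
#' @param year_labels character vector of acquisition years
#' @param year_effects_um named per-year additive size shifts (um)
#' @param size_mean_um named per-class mean sizes (um); defaults cover the
#'   observed range of anemophilous pollen
#' @param size_cv within-group coefficient of variation of true size
#' @param psf_sigma_um,noise_sd optical blur and noise parameters
#' @param particle_limit acquisition cap on the number of emitted objects
#' @return list of class `ifc_gallery` with elements `images` (list of
#'   [obj_image]), `truth` (data frame) and `dir` (output path or `NULL`)
#' @export
#' @examples
#' g <- render_gallery(20, c(spheroid = 0.8, debris = 0.2), seed = 1)
#' table(g$truth$shape_class)
render_gallery <- function(n_objects, composition = c(spheroid = 1),
                           pixel_size_um = 0.5, seed = 1, out_dir = NULL,
                           species_label = "species1", n_individuals = 1,
                           individual_sd_um = 0.8, year_labels = "y1",
                           year_effects_um = NULL, size_mean_um = NULL,
                           size_cv = 0.08, psf_sigma_um = pixel_size_um,
                           noise_sd = 0.02, particle_limit = 5000) {
  stopifnot(n_objects >= 1, length(composition) >= 1)
  if (is.null(names(composition)) || !all(names(composition) %in% .SHAPE_CLASSES))
    stop("composition must be named by shape classes")
  if (abs(sum(composition) - 1) > 1e-8)
    stop("composition fractions must sum to 1")
  set.seed(seed)
  n <- min(as.integer(n_objects), as.integer(particle_limit))

  counts <- drop(rmultinom(1, n, composition))
  classes <- sample(rep(names(composition), counts))
  pars <- .default_class_params()
  if (!is.null(size_mean_um)) {
    for (cl in names(size_mean_um)) pars[[cl]]$size <- size_mean_um[[cl]]
  }
  ind_labels <- sprintf("ind%02d", seq_len(n_individuals))
  ind_eff <- setNames(rnorm(n_individuals, 0, individual_sd_um), ind_labels)
  yr_eff <- setNames(rep(0, length(year_labels)), year_labels)
  if (!is.null(year_effects_um))
    yr_eff[names(year_effects_um)] <- year_effects_um

  images <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    p <- pars[[cl]]
    ind <- sample(ind_labels, 1)
    yr <- if (length(year_labels) == 1) year_labels else sample(year_labels, 1)
    mu <- p$size +
      if (cl %in% c("debris", "bead")) 0 else ind_eff[[ind]] + yr_eff[[yr]]
    size <- max(3.5 * pixel_size_um, rnorm(1, mu, size_cv * p$size))
    spec <- synthetic_object_spec(cl, size, aspect = p$aspect,
                                  psf_sigma_um = psf_sigma_um,
                                  noise_sd = noise_sd, contrast = p$contrast)
    out <- .render_object(spec, pixel_size_um,
                          object_id = sprintf("obj%05d", i),
                          species_label = species_label,
                          individual_label = ind, year_label = yr)
    images[[i]] <- out$image
    truth[[i]] <- out$truth
  }
  gal <- structure(list(images = setNames(images, sprintf("obj%05d", seq_len(n))),
                        truth = do.call(rbind, truth), dir = out_dir),
                   class = "ifc_gallery")
  if (!is.null(out_dir)) write_gallery(gal, out_dir)
  gal
}

#' @export
print.ifc_gallery <- function(x, ...) {
  cat(sprintf("<ifc_gallery: %d objects, %.3g um/px>\n",
              length(x$images), x$truth$pixel_size_um[1]))
  print(table(x$truth$shape_class))
  invisible(x)
}

#' Write / read a gallery as TIFF images plus a truth table
#'
#' Images are stored as 16-bit grayscale TIFFs named `<object_id>.tif`, the
#' ground truth as `truth.csv`.
#'
#' @param gallery an `ifc_gallery`
#' @param dir output directory (created if missing)
#' @return `write_gallery` returns `dir` invisibly; `read_gallery` returns an
#'   `ifc_gallery`
#' @export
write_gallery <- function(gallery, dir) {
  stopifnot(inherits(gallery, "ifc_gallery"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create gallery directory: ", dir)
  for (id in names(gallery$images))
    tiff::writeTIFF(gallery$images[[id]]$pixels,
                    file.path(dir, paste0(id, ".tif")), bits.per.sample = 16)
  write.csv(gallery$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  gallery$dir <- dir
  invisible(dir)
}

#' @rdname write_gallery
#' @export
read_gallery <- function(dir) {
  truth_path <- file.path(dir, "truth.csv")
  if (!file.exists(truth_path)) stop("no truth.csv in ", dir)
  truth <- read.csv(truth_path, stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(truth)), function(i) {
    m <- tiff::readTIFF(file.path(dir, paste0(truth$object_id[i], ".tif")))
    obj_image(m, truth$pixel_size_um[i])
  })
  structure(list(images = setNames(images, truth$object_id),
                 truth = truth, dir = dir), class = "ifc_gallery")
}

#' Simulate a Brownian-motion trait on a phylogeny
#'
#' Evolves a continuous trait along the branches of `phy` under Brownian
#' motion with variance rate `sigma2` and root state 0, the null model
#' underlying Blomberg's K.
#'
#' @param phy an [ape::phylo] tree with branch lengths
#' @param sigma2 Brownian variance rate per unit branch length (>= 0)
#' @param seed optional integer seed
#' @return named numeric vector of tip states
#' @export
#' @examples
#' tr <- ape::rcoal(5)
#' simulate_bm_trait(tr, sigma2 = 1, seed = 1)
simulate_bm_trait <- function(phy, sigma2, seed = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length) || any(phy$edge.length <= 0))
    stop("tree must have positive branch lengths")
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::reorder.phylo(phy, "cladewise")  # parents precede children
  ntip <- length(phy$tip.label)
  state <- numeric(ntip + phy$Nnode)
  inc <- if (sigma2 == 0) numeric(nrow(phy$edge)) else
    rnorm(nrow(phy$edge), 0, sqrt(sigma2 * phy$edge.length))
  for (e in seq_len(nrow(phy$edge)))
    state[phy$edge[e, 2]] <- state[phy$edge[e, 1]] + inc[e]
  setNames(state[seq_len(ntip)], phy$tip.label)
}
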