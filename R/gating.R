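#' @title Quality gating cascade and hierarchical size summaries
#'
#' @description The gating cascade isolates high-quality (HQ) single pollen:
#'   debris removal on brightfield intensities, doublet removal on
#'   circularity, cropped-object removal on the border-touch flag and
#'   automated outlier flagging (median/MAD modified z-scores), followed by
#'   polar/equatorial view sorting on elongatedness where a species needs
#'   it. Labels always partition the input: every object receives exactly
#'   one terminal label. Size summaries are reported both pooled over pollen
#'   and over per-individual means (equal weight per individual), since
#'   uneven pollen counts per plant would otherwise bias species means.
#'
#' @name gating
NULL

# 1-D Otsu threshold via EBImage on a vector
.otsu_vec <- function(v) {
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  z <- (v - r[1]) / diff(r)
  th <- EBImage::otsu(EBImage::Image(matrix(z, nrow = 1)), range = c(0, 1))
  th * diff(r) + r[1]
}

# deepest density valley between the lowest and highest mode; NA when the
# distribution is effectively unimodal (no mode pair separated by a valley
# dipping below half the smaller mode)
# min_sep is the smallest mode separation (feature units) regarded as real
# structure rather than pixel quantization of the feature
.kde_valley <- function(x, min_sep = 0) {
  if (length(unique(x)) < 3) return(NA_real_)
  d <- density(x, n = 512)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  modes <- which(is_max & y >= 0.05 * max(y))  # suppress noise wiggles
  if (length(modes) < 2) return(NA_real_)
  lo <- min(modes); hi <- max(modes)
  if (d$x[hi] - d$x[lo] < min_sep) return(NA_real_)
  valley <- lo + which.min(y[lo:hi]) - 1
  if (y[valley] > 0.5 * min(y[lo], y[hi])) return(NA_real_)
  d$x[valley]
}

#' Debris gate on brightfield intensities
#'
#' Debris has low summed brightfield absorbance on both cameras. Thresholds
#' are set per channel by Otsu's criterion on `log10(1 + intensity)`;
#' objects below threshold on both channels are labelled debris. With a
#' single camera, the same 1-D threshold on the available channel is used.
#' Thresholds can be overridden (intensity units) to replay a manual gate.
#'
#' @param features feature table from [extract_gallery()]
#' @param thresholds optional named list/vector with elements `ch01` and/or
#'   `ch09` overriding the automatic thresholds (intensity units)
#' @return character vector of labels, `"debris"` or `"ok"`, with the
#'   thresholds used attached as attribute `"thresholds"`
#' @export
gate_debris <- function(features, thresholds = NULL) {
  chans <- intersect(c("intensity_ch01", "intensity_ch09"), names(features))
  chans <- chans[colSums(!is.na(features[, chans, drop = FALSE])) > 0]
  if (length(chans) == 0) stop("no intensity channel present")
  used <- list()
  below <- matrix(FALSE, nrow(features), length(chans))
  for (k in seq_along(chans)) {
    ch <- chans[k]
    v <- features[[ch]]
    key <- sub("intensity_", "", ch)
    th <- if (!is.null(thresholds) && !is.null(thresholds[[key]]))
      thresholds[[key]]
    else {
      lv <- log10(1 + pmax(v[!is.na(v)], 0))
      10^.otsu_vec(lv) - 1
    }
    used[[key]] <- th
    below[, k] <- !is.na(v) & v < th
  }
  lab <- ifelse(rowSums(below) == length(chans) & !is.na(features[[chans[1]]]),
                "debris", "ok")
  ndeb <- sum(lab == "debris")
  if (ndeb == 0 || ndeb == nrow(features))
    warning("degenerate debris split: ", ndeb, " of ", nrow(features),
            " objects labelled debris")
  structure(lab, thresholds = used)
}

#' Singlet gate on circularity
#'
#' Single grains are near-circular; doublets and clumps are not. The
#' threshold is the deepest kernel-density valley of the circularity
#' distribution between its lowest and highest modes; objects below it are
#' labelled `"multiple"`. If the density is unimodal all objects pass, with
#' a warning.
#'
#' @param features feature table
#' @param threshold optional manual circularity threshold override
#' @param min_sep smallest circularity mode separation treated as real
#'   bimodality
#' @return character vector `"multiple"`/`"ok"` with attribute `"threshold"`
#' @export
gate_singlets <- function(features, threshold = NULL, min_sep = 2) {
  circ <- features$circularity
  if (is.null(circ)) stop("circularity column required")
  th <- threshold
  if (is.null(th)) {
    th <- .kde_valley(circ[!is.na(circ)], min_sep = min_sep)
    if (is.na(th)) {
      warning("unimodal circularity distribution: no multiples gated")
      return(structure(rep("ok", nrow(features)), threshold = NA_real_))
    }
  }
  lab <- ifelse(!is.na(circ) & circ < th, "multiple", "ok")
  structure(lab, threshold = th)
}

#' Quality flags: cropped objects and automated outliers
#'
#' Cropped objects are those whose object mask touches the frame. Remaining
#' objects are screened with modified z-scores (`0.6745 * (x - median) /
#' MAD`) on log area and on elongatedness; objects beyond `z_cutoff` on
#' either are flagged `"outlier"` (e.g. oversized masks from attached
#' debris). With fewer than 8 records the outlier stage is skipped.
#'
#' @param features feature table
#' @param z_cutoff modified z-score cutoff (default 3.5)
#' @return character vector with labels `"cropped"`, `"outlier"` or `"ok"`
#' @export
flag_quality <- function(features, z_cutoff = 3.5) {
  lab <- rep("ok", nrow(features))
  lab[!is.na(features$border_touch) & features$border_touch] <- "cropped"
  idx <- which(lab == "ok" & !is.na(features$area_um2))
  if (length(idx) < 8) {
    if (length(idx) > 0)
      warning("fewer than 8 records: outlier stage skipped")
    return(lab)
  }
  mz <- function(x) {
    m <- median(x); s <- mad(x, constant = 1)
    if (s == 0) return(rep(0, length(x)))
    0.6745 * (x - m) / s
  }
  z1 <- mz(log(features$area_um2[idx]))
  z2 <- mz(features$elongatedness[idx])
  lab[idx[abs(z1) > z_cutoff | abs(z2) > z_cutoff]] <- "outlier"
  lab
}

#' Full gating cascade
#'
#' Applies, in order: debris gate, cropped flag (border touch is a hard
#' instrument flag and would otherwise distort the circularity density),
#' singlet gate, outlier flag; survivors are labelled `"hq_single"`. Objects
#' that failed feature extraction are labelled `"debris"` at the extraction
#' stage (nothing measurable above the contrast floor). The labels partition
#' the input exactly.
#'
#' @param features feature table from [extract_gallery()]
#' @param debris_thresholds,singlet_threshold,z_cutoff gate overrides, see
#'   [gate_debris()], [gate_singlets()], [flag_quality()]
#' @return data frame `(object_id, label, stage)` with one row per input
#'   object; thresholds used are attached as attribute `"gates"`
#' @export
apply_gates <- function(features, debris_thresholds = NULL,
                        singlet_threshold = NULL, z_cutoff = 3.5) {
  n <- nrow(features)
  label <- rep(NA_character_, n)
  stage <- rep(NA_character_, n)

  failed <- !is.na(features$status) & features$status != "ok"
  label[failed] <- "debris"; stage[failed] <- "extraction"

  live <- which(is.na(label))
  deb <- suppressWarnings(gate_debris(features[live, , drop = FALSE],
                                      thresholds = debris_thresholds))
  label[live[deb == "debris"]] <- "debris"
  stage[live[deb == "debris"]] <- "debris_gate"

  live <- which(is.na(label))
  cropped <- live[!is.na(features$border_touch[live]) &
                    features$border_touch[live]]
  label[cropped] <- "cropped"; stage[cropped] <- "cropped_flag"

  live <- which(is.na(label))
  sg <- suppressWarnings(gate_singlets(features[live, , drop = FALSE],
                                       threshold = singlet_threshold))
  label[live[sg == "multiple"]] <- "multiple"
  stage[live[sg == "multiple"]] <- "singlet_gate"

  live <- which(is.na(label))
  fq <- suppressWarnings(flag_quality(features[live, , drop = FALSE],
                                      z_cutoff = z_cutoff))
  label[live[fq == "outlier"]] <- "outlier"
  stage[live[fq == "outlier"]] <- "quality_gate"

  label[is.na(label)] <- "hq_single"
  stage[is.na(stage)] <- "quality_gate"
  structure(
    data.frame(object_id = features$object_id, label = label, stage = stage,
               stringsAsFactors = FALSE),
    gates = list(debris = attr(deb, "thresholds"),
                 singlet = attr(sg, "threshold"), z_cutoff = z_cutoff))
}

#' Sort oblate pollen into polar and equatorial views
#'
#' Threshold at the kernel-density valley of the elongatedness histogram:
#' above the valley the elongated (equatorial) profile is visible, below it
#' the near-circular polar outline. Spherical species give a unimodal
#' histogram and are labelled all-polar with a warning.
#'
#' @param features feature table (HQ singles of one species)
#' @param threshold optional manual elongatedness threshold override
#' @param min_sep smallest elongatedness mode separation treated as real
#'   bimodality (pixel quantization of near-spherical grains produces
#'   spurious narrow modes)
#' @return character vector `"polar"`/`"equatorial"` with attribute
#'   `"threshold"`
#' @export
sort_views <- function(features, threshold = NULL, min_sep = 0.15) {
  el <- features$elongatedness
  th <- threshold
  if (is.null(th)) {
    th <- .kde_valley(el[!is.na(el)], min_sep = min_sep)
    if (is.na(th)) {
      warning("unimodal elongatedness distribution: all labelled polar")
      return(structure(rep("polar", nrow(features)), threshold = NA_real_))
    }
  }
  structure(ifelse(!is.na(el) & el > th, "equatorial", "polar"),
            threshold = th)
}

#' Two-level species size summaries
#'
#' Per-individual means of the size feature are computed first; species
#' mean and SD are then reported both pooled over all pollen
#' (`level = "pooled_pollen"`) and over the per-individual means with equal
#' weight per individual (`level = "individual_means"`). The second level is
#' the one used for method comparison, since uneven pollen counts per plant
#' would otherwise bias the species mean.
#'
#' @param features feature table of HQ single pollen with `species_label`
#'   and `individual_label` columns
#' @param value name of the size column to summarize (default `"length_um"`)
#' @return data frame with columns `species_label`, `level`,
#'   `n_individuals`, `n_pollen`, `mean_um`, `sd_um` (SD is `NA` at the
#'   individual-means level for single-individual species)
#' @export
summarize_sizes <- function(features, value = "length_um") {
  stopifnot(all(c("species_label", "individual_label", value) %in%
                  names(features)))
  x <- features[!is.na(features[[value]]), , drop = FALSE]
  out <- lapply(split(x, x$species_label), function(sp) {
    ind_means <- tapply(sp[[value]], sp$individual_label, mean)
    rbind(
      data.frame(species_label = sp$species_label[1], level = "pooled_pollen",
                 n_individuals = length(ind_means), n_pollen = nrow(sp),
                 mean_um = mean(sp[[value]]),
                 sd_um = if (nrow(sp) > 1) sd(sp[[value]]) else NA_real_),
      data.frame(species_label = sp$species_label[1],
                 level = "individual_means",
                 n_individuals = length(ind_means), n_pollen = nrow(sp),
                 mean_um = mean(ind_means),
                 sd_um = if (length(ind_means) > 1) sd(ind_means) else NA_real_))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Modal size of a sample
#'
#' Histogram mode with bin width equal to the pixel size (the resolution of
#' the size features); on ties the lowest bin wins. Used for bead-based
#' calibration, where the certified value is the modal diameter.
#'
#' @param x numeric vector of sizes (um)
#' @param pixel_size_um bin width (um)
#' @return centre of the highest histogram bin (um)
#' @export
modal_size <- function(x, pixel_size_um = 0.5) {
  x <- x[!is.na(x)]
  if (length(x) < 30)
    warning("modal size estimated from fewer than 30 objects")
  bw <- pixel_size_um
  breaks <- seq(floor(min(x) / bw) * bw, ceiling(max(x) / bw) * bw + bw, by = bw)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  i <- which.max(counts)          # which.max returns the first (lowest) tie
  (breaks[i] + breaks[i + 1]) / 2
}
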