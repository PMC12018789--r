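#' @title Run configuration, pipeline driver and table export
#'
#' @description A run configuration collects the acquisition and analysis
#'   constants (pixel size, adaptive-erode threshold, particle limit, gate
#'   overrides, outlier cutoff, seeds) and round-trips through YAML, so a
#'   run can be replayed exactly. [run_pipeline()] chains extraction, gating
#'   and summarization over a gallery and writes every intermediate plus a
#'   machine-readable provenance record.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param pixel_size_um micrometres per pixel (0.5 at x40, 1.0 at x20)
#' @param ae_threshold adaptive-erode threshold, in `[50, 100]`
#' @param particle_limit acquisition cap on gallery size
#' @param outlier_z modified z-score cutoff of the outlier gate
#' @param loose_dilation_px dilation radius of the loose default-style mask
#' @param gate_overrides list with optional elements `debris_thresholds`,
#'   `singlet_threshold`, `view_threshold`
#' @param seed integer seed governing simulation
#' @param rename_map optional named character vector of tip renames
#' @param out_dir optional output directory for pipeline products
#' @return list of class `ifc_config`
#' @export
run_config <- function(pixel_size_um = 0.5, ae_threshold = 95,
                       particle_limit = 5000, outlier_z = 3.5,
                       loose_dilation_px = 4, gate_overrides = list(),
                       seed = 1, rename_map = NULL, out_dir = NULL) {
  if (!pixel_size_um > 0) stop("pixel_size_um must be positive")
  if (ae_threshold < 50 || ae_threshold > 100)
    stop("ae_threshold must be in [50, 100]")
  if (particle_limit < 1) stop("particle_limit must be >= 1")
  if (outlier_z <= 0) stop("outlier_z must be positive")
  structure(list(pixel_size_um = pixel_size_um, ae_threshold = ae_threshold,
                 particle_limit = particle_limit, outlier_z = outlier_z,
                 loose_dilation_px = loose_dilation_px,
                 gate_overrides = gate_overrides, seed = seed,
                 rename_map = rename_map, out_dir = out_dir),
            class = "ifc_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config an [run_config()] object
#' @param path YAML file path
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   `ifc_config` (validated through [run_config()])
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ifc_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), known)])
}

#' Export a feature table
#'
#' Writes the feature table as comma- or tab-delimited text with a header;
#' decimal points are locale-independent and all lengths are micrometres
#' (areas in square micrometres), as documented in a leading comment line.
#'
#' @param records nonempty feature data frame
#' @param path output file
#' @param dialect `"csv"` or `"tsv"` (tab-delimited, the instrument's
#'   txt-export convention)
#' @return `path`, invisibly
#' @export
export_feature_table <- function(records, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (is.null(records) || nrow(records) == 0)
    stop("no records to export")
  sep <- if (dialect == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ifcpollen feature table; lengths in um, areas in um^2", con)
  utils::write.table(records, con, sep = sep, row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' @rdname export_feature_table
#' @export
read_feature_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run the full extraction-gating-summary pipeline over a gallery
#'
#' Stages: feature extraction on the adaptive-erode mask, gating cascade,
#' per-species two-level size summaries. When `config$out_dir` is set, every
#' intermediate (features, gate labels, summaries) is written as CSV
#' together with a JSON provenance record (package version, seed,
#' thresholds, per-stage object counts).
#'
#' @param config an [run_config()]
#' @param gallery an `ifc_gallery` or gallery directory
#' @return list with `features`, `gates`, `summaries`, `counts` (named
#'   per-label object counts) and `provenance`
#' @export
run_pipeline <- function(config, gallery) {
  stopifnot(inherits(config, "ifc_config"))
  if (is.character(gallery)) gallery <- read_gallery(gallery)
  ov <- config$gate_overrides
  features <- extract_gallery(gallery, ae_threshold = config$ae_threshold)
  gates <- apply_gates(features,
                       debris_thresholds = ov$debris_thresholds,
                       singlet_threshold = ov$singlet_threshold,
                       z_cutoff = config$outlier_z)
  hq <- features[features$object_id %in%
                   gates$object_id[gates$label == "hq_single"], , drop = FALSE]
  summaries <- if (nrow(hq) && all(c("species_label", "individual_label")
                                   %in% names(hq)))
    summarize_sizes(hq) else NULL
  counts <- table(gates$label)
  provenance <- list(
    package = "ifcpollen",
    version = as.character(utils::packageVersion("ifcpollen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    pixel_size_um = config$pixel_size_um,
    ae_threshold = config$ae_threshold,
    outlier_z = config$outlier_z,
    gates = attr(gates, "gates"),
    counts = as.list(counts),
    n_input = nrow(features))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    export_feature_table(features, file.path(config$out_dir, "features.csv"))
    write.csv(gates, file.path(config$out_dir, "gates.csv"), row.names = FALSE)
    if (!is.null(summaries))
      write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(features = features, gates = gates, summaries = summaries,
       counts = counts, provenance = provenance)
}
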