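#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end analysis: the seed, the significance
#' cutoff, the test method, the radial exclusion threshold, histogram
#' binning, and the synthetic-organ settings used when no measured raw table
#' is supplied. A configuration can also be read from a YAML file whose keys
#' mirror the arguments (profiles given as a list of per-gene entries).
#'
#' @param seed Integer seed for all randomness in the run.
#' @param alpha Significance cutoff in (0, 1); default 0.01.
#' @param method `"asymptotic"` or `"permutation"` KS p-values.
#' @param min_lamella Radial exclusion threshold (micrometers).
#' @param n_bins Histogram bins (display only).
#' @param n_organs Organs per gene for simulation.
#' @param profiles Profile table; default [default_gene_profiles()].
#' @param raw_path Optional path to a measured raw cell table; when given,
#'   simulation is skipped.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.01,
                            method = c("asymptotic", "permutation"),
                            min_lamella = 50, n_bins = 20L, n_organs = 5L,
                            profiles = default_gene_profiles(),
                            raw_path = NULL) {
  method <- match.arg(method)
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 ||
      seed != round(seed))
    stop("`seed` must be a non-negative integer", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  validate_profiles(profiles)
  structure(list(seed = as.integer(seed), alpha = alpha, method = method,
                 min_lamella = min_lamella, n_bins = as.integer(n_bins),
                 n_organs = as.integer(n_organs), profiles = profiles,
                 raw_path = raw_path),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- if (!is.null(y$profiles)) {
    do.call(rbind, lapply(y$profiles, function(p) do.call(gene_profile, p)))
  } else default_gene_profiles()
  pipeline_config(
    seed = y$seed %||% 1L,
    alpha = y$alpha %||% 0.01,
    method = y$method %||% "asymptotic",
    min_lamella = y$min_lamella %||% 50,
    n_bins = y$n_bins %||% 20L,
    n_organs = y$n_organs %||% 5L,
    profiles = profiles,
    raw_path = y$raw_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(quiet, stage, ...) {
  if (!quiet) message("[", stage, "] ", ...)
}

#' Run the full expression-zone pipeline
#'
#' Sequences the stages end to end: obtain a raw cell table (simulate with
#' the configured profiles, or read `raw_path`), normalize coordinates,
#' compute per-gene descriptors, build the three pairwise KS comparison
#' matrices over the sparse receptor genes, derive per-coordinate groups and
#' the combined zone partition, and run the receptor-vs-marker contrasts.
#' All tabular artifacts are written under `out_dir` together with a JSON
#' run manifest (seed, settings, package version); identical configuration
#' and seed reproduce identical tables.
#'
#' @param config A `"pipeline_config"`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `raw`, `cells`, `descriptors`, `matrices`,
#'   `zones`, `markers`, and the paths written.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$raw_path)) {
    pipeline_log(quiet, "simulate", "generating ",
                 nrow(config$profiles), " gene profiles x ",
                 config$n_organs, " organs (seed ", config$seed, ")")
    raw <- simulate_cells(config$profiles, n_organs = config$n_organs,
                          seed = config$seed)
  } else {
    pipeline_log(quiet, "simulate", "reading raw table ", config$raw_path)
    raw <- read_raw_cells(config$raw_path)
  }
  if (nrow(raw) == 0L)
    stop("normalize: raw cell table is empty", call. = FALSE)
  write_raw_cells(raw, file.path(out_dir, "raw_cells.tsv"))

  pipeline_log(quiet, "normalize", nrow(raw), " records")
  cells <- normalize_cells(raw, min_lamella = config$min_lamella)
  write_normalized(cells, file.path(out_dir, "normalized_cells.tsv"))

  pipeline_log(quiet, "stats", "descriptors per gene and coordinate")
  descriptors <- summarize_distributions(cells)
  write_descriptors(descriptors, file.path(out_dir, "descriptors.tsv"))

  genes <- intersect(sparse_genes(), unique(cells$gene))
  if (length(genes) < 2L) genes <- sort(unique(cells$gene))
  pipeline_log(quiet, "compare", "pairwise KS over ",
               length(genes), " genes, alpha = ", config$alpha)
  matrices <- lapply(names(coordinate_names), function(co) {
    cm <- pairwise_matrix(coordinate_samples(cells, co, genes),
                          coordinate = co, alpha = config$alpha,
                          method = config$method, seed = config$seed)
    write_comparison_matrix(cm, file.path(out_dir, paste0("ks_", co)))
    cm
  })
  names(matrices) <- names(coordinate_names)

  pipeline_log(quiet, "zones", "combined partition")
  zones <- zone_partition(matrices)
  write_zone_report(zones, file.path(out_dir, "zones.json"))

  markers <- marker_contrasts(cells, alpha = config$alpha,
                              method = config$method)
  write_tsv6(markers, file.path(out_dir, "marker_contrasts.tsv"))

  manifest <- list(
    seed = config$seed, alpha = config$alpha, method = config$method,
    min_lamella = config$min_lamella, n_organs = config$n_organs,
    genes = genes, n_cells = nrow(cells), n_zones = zones$n_zones,
    package_version = as.character(utils::packageVersion("olfzones")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(raw = raw, cells = cells, descriptors = descriptors,
                 matrices = matrices, zones = zones, markers = markers,
                 out_dir = out_dir))
}
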