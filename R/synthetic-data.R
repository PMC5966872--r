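#' Per-gene spatial expression profiles
#'
#' A profile specifies, for one gene, the three coordinate laws used by the
#' synthetic organ generator — laminar height within the epithelial layer,
#' relative radius within the lamella, and height within the organ (z) — each
#' as a logit-normal law given by its median and interquartile width, plus the
#' mean number of labeled cells per section.
#'
#' @param gene Gene name.
#' @param laminar_median,laminar_width Median and interquartile width of the
#'   relative laminar height law (0 basal, 1 apical).
#' @param radial_median,radial_width Median and width of the relative radius
#'   law (0 innermost, 1 outermost).
#' @param z_median,z_width Median and width of the relative organ-height law
#'   (0 top section, 1 bottommost).
#' @param cells_per_section Mean labeled cells per section; sparse receptor
#'   genes in the reference calibration use 2.0, broadly expressed genes 20.
#' @return A one-row data frame; rows from several calls can be combined with
#'   `rbind()` into a profile table.
#' @seealso [default_gene_profiles()] for the packaged calibration.
#' @export
gene_profile <- function(gene, laminar_median, laminar_width,
                         radial_median, radial_width,
                         z_median, z_width, cells_per_section) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  vals <- c(laminar_median, laminar_width, radial_median, radial_width,
            z_median, z_width)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals >= 1))
    stop("profile medians and widths must lie strictly inside (0, 1)",
         call. = FALSE)
  if (!is.finite(cells_per_section) || cells_per_section < 0)
    stop("`cells_per_section` must be a non-negative rate", call. = FALSE)
  data.frame(gene = gene,
             laminar_median = laminar_median, laminar_width = laminar_width,
             radial_median = radial_median, radial_width = radial_width,
             z_median = z_median, z_width = z_width,
             cells_per_section = cells_per_section,
             stringsAsFactors = FALSE)
}

#' Packaged profile calibration for the reference gene set
#'
#' Returns profiles for six sparsely expressed OlfC receptor genes (g1, n1,
#' q1, u1, j1, t1), the broadly expressed putative co-receptor c1, and the
#' two neuron-type marker genes omp (ciliated) and trpc2 (microvillous).
#'
#' The calibration encodes the zone structure reported for the adult
#' zebrafish olfactory rosette:
#' * laminar medians span exactly 0.603 (j1, t1; broad) to 0.714 (g1;
#'   narrow), with n1, q1, u1 intermediate at 0.660 — three laminar groups;
#' * radial medians differ by at most 0.13 of lamellar length with
#'   interquartile widths of 0.23; j1 vs t1 and u1 vs q1 are radially
#'   separable, and c1 sits outermost, separable from trpc2;
#' * z medians sit at 0.50 except u1 at 0.30 (closer to the organ opening),
#'   which separates u1 from every other sparse gene;
#' * omp is markedly more basal (laminar median 0.45) than every OlfC gene,
#'   while trpc2 shares the intermediate laminar law of n1/q1/u1.
#'
#' Genes sharing a zone (n1, q1) have identical laws in all three
#' coordinates, so their population KS distance is exactly zero; every pair
#' reported as separable has population KS distance at least 0.15 in its
#' separating coordinate (verifiable with [logitnorm_ks_distance()]).
#'
#' @return A profile table with one row per gene (see [gene_profile()]).
#' @examples
#' prof <- default_gene_profiles()
#' range(prof$laminar_median[prof$sparse])
#' @export
default_gene_profiles <- function() {
  p <- rbind(
    gene_profile("g1",    0.714, 0.12, 0.50, 0.23, 0.50, 0.30, 2),
    gene_profile("n1",    0.660, 0.14, 0.50, 0.23, 0.50, 0.30, 2),
    gene_profile("q1",    0.660, 0.14, 0.50, 0.23, 0.50, 0.30, 2),
    gene_profile("u1",    0.660, 0.14, 0.43, 0.23, 0.30, 0.30, 2),
    gene_profile("j1",    0.603, 0.20, 0.44, 0.23, 0.50, 0.30, 2),
    gene_profile("t1",    0.603, 0.20, 0.55, 0.23, 0.50, 0.30, 2),
    gene_profile("c1",    0.660, 0.14, 0.56, 0.23, 0.50, 0.30, 20),
    gene_profile("omp",   0.450, 0.20, 0.48, 0.23, 0.50, 0.30, 20),
    gene_profile("trpc2", 0.660, 0.14, 0.48, 0.23, 0.50, 0.30, 20)
  )
  p$sparse <- p$gene %in% sparse_genes()
  p
}

#' @rdname default_gene_profiles
#' @export
sparse_genes <- function() c("g1", "n1", "q1", "u1", "j1", "t1")

#' @rdname default_gene_profiles
#' @export
marker_genes <- function() c("omp", "trpc2")

validate_profiles <- function(profiles) {
  needed <- c("gene", "laminar_median", "laminar_width", "radial_median",
              "radial_width", "z_median", "z_width", "cells_per_section")
  missing <- setdiff(needed, names(profiles))
  if (length(missing))
    stop("profile table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(profiles$gene))
    stop("duplicate gene names in profile table", call. = FALSE)
  frac <- as.matrix(profiles[c("laminar_median", "laminar_width",
                               "radial_median", "radial_width",
                               "z_median", "z_width")])
  if (any(!is.finite(frac)) || any(frac <= 0) || any(frac >= 1))
    stop("profile medians and widths must lie strictly inside (0, 1)",
         call. = FALSE)
  if (any(profiles$cells_per_section < 0))
    stop("`cells_per_section` must be non-negative", call. = FALSE)
  invisible(profiles)
}

# Geometry of one simulated cup-shaped organ: per-section layer thickness and
# lamella length. The lamella ramps up linearly from 0 over the first
# `n_growth` sections (the sensory surface does not reach the median raphe in
# the topmost sections), then fluctuates uniformly; only relative coordinates
# matter downstream, so absolute scales are nominal.
sample_organ_geometry <- function(organ_id,
                                  section_range = c(40L, 60L),
                                  thickness_range = c(30, 60),
                                  lamella_range = c(200, 400),
                                  n_growth = 5L) {
  if (section_range[1] < 1L) stop("organs need at least one section",
                                  call. = FALSE)
  n <- sample(seq(section_range[1], section_range[2]), 1L)
  thickness <- stats::runif(n, thickness_range[1], thickness_range[2])
  lamella <- stats::runif(n, lamella_range[1], lamella_range[2])
  ramp_k <- min(n_growth, n - 1L)                 # sections 0..ramp_k-1 ramp up
  if (ramp_k > 0L) {
    base <- lamella[ramp_k + 1L]                  # first full-length section
    lamella[seq_len(ramp_k)] <- base * (seq_len(ramp_k) - 1L) / ramp_k
  }
  list(organ_id = organ_id, n_sections = n,
       layer_thickness = thickness, lamella_length = lamella)
}

#' Simulate labeled-cell measurements over serial sections of synthetic organs
#'
#' Generates raw per-cell measurement records emulating in situ hybridization
#' series over cup-shaped olfactory organs cut into 40–60 horizontal sections.
#' For each organ, gene, and section, the number of labeled cells is Poisson
#' with rate `cells_per_section` modulated by the gene's organ-height density
#' discretized over sections; each cell then receives independent laminar and
#' radial relative coordinates from the gene's logit-normal laws, which are
#' de-normalized with the section's layer thickness and lamella length.
#' Organs are drawn independently per gene, mirroring a study design in which
#' each probe is hybridized on sections from different animals.
#'
#' @param profiles A profile table (see [gene_profile()],
#'   [default_gene_profiles()]).
#' @param n_organs Organs per gene (study range 3–5; default 5).
#' @param seed Integer seed; identical `seed` and arguments reproduce the
#'   table exactly.
#' @param section_range Inclusive range for the number of sections per organ.
#' @param thickness_range,lamella_range Uniform ranges (micrometers) for the
#'   per-section layer thickness and full lamella length.
#' @param n_growth Number of topmost sections over which the lamella ramps up
#'   linearly from length zero.
#' @return A data frame of raw cell records with columns `organ_id`, `gene`,
#'   `section_index` (0-based), `total_sections`, `side`,
#'   `soma_height_um`, `layer_thickness_um`, `radial_distance_um`,
#'   `lamella_length_um`.
#' @examples
#' raw <- simulate_cells(default_gene_profiles(), n_organs = 2, seed = 1)
#' table(raw$gene)
#' @export
simulate_cells <- function(profiles, n_organs = 5L, seed = NULL,
                           section_range = c(40L, 60L),
                           thickness_range = c(30, 60),
                           lamella_range = c(200, 400),
                           n_growth = 5L) {
  validate_profiles(profiles)
  if (n_organs < 1L) stop("`n_organs` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  pieces <- vector("list", nrow(profiles) * n_organs)
  k <- 0L
  for (g in seq_len(nrow(profiles))) {
    prof <- profiles[g, ]
    par_h <- logitnorm_params(prof$laminar_median, prof$laminar_width)
    par_r <- logitnorm_params(prof$radial_median, prof$radial_width)
    par_z <- logitnorm_params(prof$z_median, prof$z_width)
    for (o in seq_len(n_organs)) {
      geom <- sample_organ_geometry(
        organ_id = sprintf("%s_o%d", prof$gene, o),
        section_range = section_range, thickness_range = thickness_range,
        lamella_range = lamella_range, n_growth = n_growth)
      n <- geom$n_sections
      # discretized z-density: probability mass of each section's z slab,
      # scaled so the average per-section rate equals cells_per_section
      edges <- seq(0, 1, length.out = n + 1L)
      mass <- diff(plogitnorm(pmin(pmax(edges, 1e-12), 1 - 1e-12),
                              par_z$mu, par_z$sigma))
      mass <- mass / sum(mass)
      counts <- stats::rpois(n, prof$cells_per_section * n * mass)
      total <- sum(counts)
      k <- k + 1L
      if (total == 0L) next
      sec <- rep.int(seq_len(n) - 1L, counts)           # 0-based index
      h_rel <- rlogitnorm(total, par_h$mu, par_h$sigma)
      r_rel <- rlogitnorm(total, par_r$mu, par_r$sigma)
      pieces[[k]] <- data.frame(
        organ_id = geom$organ_id,
        gene = prof$gene,
        section_index = sec,
        total_sections = n,
        side = sample(c("left", "right"), total, replace = TRUE),
        soma_height_um = h_rel * geom$layer_thickness[sec + 1L],
        layer_thickness_um = geom$layer_thickness[sec + 1L],
        radial_distance_um = r_rel * geom$lamella_length[sec + 1L],
        lamella_length_um = geom$lamella_length[sec + 1L],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out)) out <- empty_raw_table()
  rownames(out) <- NULL
  out
}

empty_raw_table <- function() {
  data.frame(organ_id = character(), gene = character(),
             section_index = integer(), total_sections = integer(),
             side = character(), soma_height_um = numeric(),
             layer_thickness_um = numeric(), radial_distance_um = numeric(),
             lamella_length_um = numeric(), stringsAsFactors = FALSE)
}

raw_table_columns <- c("organ_id", "gene", "section_index", "total_sections",
                       "side", "soma_height_um", "layer_thickness_um",
                       "radial_distance_um", "lamella_length_um")

#' Read and write raw cell tables
#'
#' Tab-separated text with a one-line header; columns as produced by
#' [simulate_cells()]. Numeric columns are serialized at 6 significant
#' digits.
#'
#' @param x Raw cell table.
#' @param path File path.
#' @return `read_raw_cells()` returns the table; `write_raw_cells()` returns
#'   `path` invisibly.
#' @export
write_raw_cells <- function(x, path) {
  write_tsv6(x[raw_table_columns], path)
}

#' @rdname write_raw_cells
#' @export
read_raw_cells <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(raw_table_columns, names(x))
  if (length(missing))
    stop("raw cell table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x[raw_table_columns]
}

# shared TSV writer: 6 significant digits for doubles, no quoting
write_tsv6 <- function(x, path) {
  y <- x
  for (j in seq_along(y))
    if (is.double(y[[j]])) y[[j]] <- signif(y[[j]], 6)
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
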