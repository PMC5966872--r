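#' Normalized spatial coordinates of labeled cells
#'
#' The pipeline locates each labeled cell by three dimensionless coordinates:
#'
#' * **laminar height** `h_rel` — distance from the basal border of the
#'   sensory layer to the soma center, divided by the local layer thickness
#'   (0 basal, 1 apical);
#' * **relative radius** `r_rel` — distance from the lamellar apex (nearest
#'   the median raphe) to the soma center, divided by the lamella length
#'   (0 innermost, 1 outermost); sections whose lamella is shorter than
#'   `min_length` are excluded from the radial analysis because the sensory
#'   surface has not yet extended toward the median raphe there;
#' * **organ height** `z_rel` — 0-based horizontal section index divided by
#'   `total_sections - 1`, so 0 is the top section (organ opening) and 1 the
#'   bottommost.
#'
#' @param soma_height Distance (micrometers) from the basal border to the
#'   soma center.
#' @param layer_thickness Local thickness of the sensory layer (micrometers).
#' @return `laminar_height()` returns `soma_height / layer_thickness`.
#' @name coordinates
NULL

#' @rdname coordinates
#' @export
laminar_height <- function(soma_height, layer_thickness) {
  if (any(!is.finite(layer_thickness)) || any(layer_thickness <= 0))
    stop("`layer_thickness` must be positive", call. = FALSE)
  bad <- !is.finite(soma_height) | soma_height < 0 |
    soma_height > layer_thickness
  if (any(bad))
    stop("`soma_height` outside [0, layer_thickness] for record(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  soma_height / layer_thickness
}

#' @rdname coordinates
#' @param radial_distance Distance (micrometers) from the lamellar apex to the
#'   soma center.
#' @param lamella_length Full lamella length (micrometers) in the cell's
#'   section.
#' @param min_length Exclusion threshold (micrometers): sections with a
#'   lamella shorter than this yield `NA` (excluded from radial analysis).
#' @export
radial_position <- function(radial_distance, lamella_length, min_length = 50) {
  if (any(!is.finite(radial_distance)) || any(radial_distance < 0))
    stop("`radial_distance` must be non-negative", call. = FALSE)
  excluded <- lamella_length < min_length
  bad <- !excluded & radial_distance > lamella_length
  if (any(bad))
    stop("`radial_distance` exceeds `lamella_length` for record(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  out <- radial_distance / lamella_length
  out[excluded] <- NA_real_
  out
}

#' @rdname coordinates
#' @param section_index 0-based horizontal section index, counted from the
#'   top of the organ.
#' @param total_sections Total number of sections containing sensory
#'   epithelium.
#' @export
organ_height <- function(section_index, total_sections) {
  if (any(total_sections < 1L))
    stop("`total_sections` must be at least 1", call. = FALSE)
  bad <- section_index < 0L | section_index >= total_sections
  if (any(bad))
    stop("`section_index` out of [0, total_sections) for record(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  ifelse(total_sections > 1L,
         section_index / (total_sections - 1L), 0)
}

#' Normalize a raw cell table
#'
#' Applies the three coordinate normalizations to every record, pooling left
#' and right sides (no side difference is expected), and flags the radial
#' coordinate as excluded (`NA`) in short-lamella sections. Counts are
#' conserved: each raw record yields exactly one normalized record, and an
#' excluded radial value does not remove the cell from the laminar and
#' organ-height analyses.
#'
#' @param raw Raw cell table (see [simulate_cells()], [read_raw_cells()]).
#' @param min_lamella Radial exclusion threshold in micrometers.
#' @param lenient If `TRUE`, malformed rows are dropped with a warning that
#'   names their row numbers; the default is fail-fast.
#' @return A data frame with columns `organ_id`, `gene`, `section_index`,
#'   `h_rel`, `r_rel` (`NA` when excluded), `z_rel`.
#' @examples
#' raw <- simulate_cells(default_gene_profiles()[1:2, ], n_organs = 2, seed = 1)
#' cells <- normalize_cells(raw)
#' nrow(cells) == nrow(raw)
#' @export
normalize_cells <- function(raw, min_lamella = 50, lenient = FALSE) {
  missing <- setdiff(raw_table_columns, names(raw))
  if (length(missing))
    stop("raw table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L)
    return(data.frame(organ_id = character(), gene = character(),
                      section_index = integer(), h_rel = numeric(),
                      r_rel = numeric(), z_rel = numeric(),
                      stringsAsFactors = FALSE))
  excl <- raw$lamella_length_um < min_lamella
  bad <- !is.finite(raw$layer_thickness_um) | raw$layer_thickness_um <= 0 |
    !is.finite(raw$soma_height_um) | raw$soma_height_um < 0 |
    raw$soma_height_um > raw$layer_thickness_um |
    !is.finite(raw$radial_distance_um) | raw$radial_distance_um < 0 |
    (!excl & raw$radial_distance_um > raw$lamella_length_um) |
    raw$total_sections < 1L | raw$section_index < 0L |
    raw$section_index >= raw$total_sections
  if (any(bad)) {
    if (!lenient)
      stop("malformed raw record(s) at row(s) ",
           paste(utils::head(which(bad), 10), collapse = ", "),
           call. = FALSE)
    warning("dropping ", sum(bad), " malformed raw record(s) at row(s) ",
            paste(utils::head(which(bad), 10), collapse = ", "),
            call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
    excl <- excl[!bad]
  }
  data.frame(
    organ_id = raw$organ_id,
    gene = raw$gene,
    section_index = raw$section_index,
    h_rel = raw$soma_height_um / raw$layer_thickness_um,
    r_rel = ifelse(excl, NA_real_,
                   raw$radial_distance_um / raw$lamella_length_um),
    z_rel = ifelse(raw$total_sections > 1L,
                   raw$section_index / (raw$total_sections - 1L), 0),
    stringsAsFactors = FALSE)
}

normalized_columns <- c("organ_id", "gene", "section_index",
                        "h_rel", "r_rel", "z_rel")

#' Read and write normalized cell tables
#'
#' Tab-separated with header; the excluded radial coordinate is written as an
#' empty cell and read back as `NA`.
#'
#' @param x Normalized cell table from [normalize_cells()].
#' @param path File path.
#' @export
write_normalized <- function(x, path) {
  write_tsv6(x[normalized_columns], path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(normalized_columns, names(x))
  if (length(missing))
    stop("normalized table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x[normalized_columns]
}
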