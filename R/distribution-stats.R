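#' Empirical cumulative distribution function as an explicit step function
#'
#' Represents a sample by the points of its ECDF: data values are sorted and
#' each distinct value x carries the cumulative fraction F(x) = (# values
#' <= x) / n, so ties accumulate into a single step of height k/n. The step
#' representation keeps every observation (nothing is binned away) and is the
#' form on which distribution distances are computed.
#'
#' @param values Non-empty numeric sample.
#' @return An object of class `"step_ecdf"`: a list with sorted distinct `x`,
#'   cumulative fractions `F` (final value 1), and the sample size `n`.
#' @examples
#' e <- step_ecdf(c(0.2, 0.4, 0.4, 0.8))
#' eval_ecdf(e, 0.4)   # 0.75
#' @export
step_ecdf <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("cannot form an ECDF from an empty sample", call. = FALSE)
  n <- length(values)
  tab <- table(values)
  x <- as.numeric(names(tab))
  structure(list(x = x, F = cumsum(as.numeric(tab)) / n, n = n),
            class = "step_ecdf")
}

#' @rdname step_ecdf
#' @param e A `"step_ecdf"` object.
#' @param q Points at which to evaluate the (right-continuous) ECDF.
#' @export
eval_ecdf <- function(e, q) {
  stopifnot(inherits(e, "step_ecdf"))
  idx <- findInterval(q, e$x)
  c(0, e$F)[idx + 1L]
}

#' @export
print.step_ecdf <- function(x, ...) {
  cat("ECDF of", x$n, "observations on [", format(min(x$x)), ",",
      format(max(x$x)), "] with", length(x$x), "steps\n")
  invisible(x)
}

#' Quartile descriptors of a coordinate sample
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7). The half-width — the study's measure of how
#' broad an expression zone is — is the interquartile range Q3 - Q1.
#'
#' @param values Non-empty numeric sample (NAs dropped).
#' @return `coord_quartiles()` returns a named vector `(q1, median, q3)`.
#' @examples
#' coord_quartiles(c(0, 1))         # 0.25 0.50 0.75
#' half_width(0.40, 0.64)           # 0.24
#' @export
coord_quartiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' @rdname coord_quartiles
#' @param q1,q3 First and third quartile.
#' @export
half_width <- function(q1, q3) {
  if (any(q3 < q1)) stop("q3 must not be below q1", call. = FALSE)
  q3 - q1
}

#' Maximal vertical distance between two ECDFs
#'
#' The supremum over x of |F_a(x) - F_b(x)|, i.e. the two-sample
#' Kolmogorov-Smirnov statistic D. The supremum of a pair of step functions
#' is attained at a step point, so it is evaluated exactly over the union of
#' the two step-point sets; ties within and between samples are handled by
#' the step representation without jittering.
#'
#' @param a,b Numeric samples or `"step_ecdf"` objects.
#' @return D, a number in \[0, 1\].
#' @examples
#' ks_distance(c(0, 1), 0.5)   # 0.5
#' @export
ks_distance <- function(a, b) {
  if (!inherits(a, "step_ecdf")) a <- step_ecdf(a)
  if (!inherits(b, "step_ecdf")) b <- step_ecdf(b)
  xs <- sort(unique(c(a$x, b$x)))
  max(abs(eval_ecdf(a, xs) - eval_ecdf(b, xs)))
}

# fast path for raw samples (no step_ecdf allocation); used by the
# permutation loop. Assumes no NAs.
ks_distance_sorted <- function(x, y) {
  n_x <- length(x); n_y <- length(y)
  w <- c(x, y)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= n_x, 1 / n_x, -1 / n_y))
  ws <- w[ord]
  keep <- c(diff(ws) != 0, TRUE)   # evaluate only at distinct values
  max(abs(steps[keep]))
}

#' Range of pairwise distribution distances
#'
#' Minimum and maximum maximal-vertical-distance (KS D) over all unordered
#' gene pairs, reported in percent of cells — the study's summary of how
#' different a set of coordinate distributions is.
#'
#' @param samples Named list of numeric samples, one per gene (>= 2 genes).
#' @return Named vector `(min, max)` in percent, rounded half away from zero
#'   to one decimal.
#' @export
distance_range <- function(samples) {
  if (length(samples) < 2L)
    stop("need at least two genes to compare", call. = FALSE)
  ecdfs <- lapply(samples, step_ecdf)
  pairs <- utils::combn(length(samples), 2)
  d <- apply(pairs, 2, function(ij) ks_distance(ecdfs[[ij[1]]],
                                                ecdfs[[ij[2]]]))
  c(min = percent1(min(d)), max = percent1(max(d)))
}

# percent, rounded half away from zero to one decimal
percent1 <- function(x) sign(x) * floor(abs(x) * 1000 + 0.5) / 10

#' Equal-width histogram on the unit interval
#'
#' Display-only binning companion to the ECDF representation; all statistics
#' are computed on the unbinned sample.
#'
#' @param values Sample of fractions in \[0, 1\] (NAs dropped).
#' @param n_bins Number of equal-width bins (default 20).
#' @return Data frame with bin `lower`, `upper`, and `count`; counts sum to
#'   the sample size.
#' @export
coord_histogram <- function(values, n_bins = 20L) {
  if (n_bins < 1L) stop("`n_bins` must be at least 1", call. = FALSE)
  values <- values[!is.na(values)]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  data.frame(lower = breaks[-(n_bins + 1L)], upper = breaks[-1L],
             count = tabulate(idx, nbins = n_bins))
}

coordinate_names <- c(laminar = "h_rel", radial = "r_rel", z = "z_rel")

#' Extract per-gene coordinate samples from a normalized table
#'
#' @param cells Normalized cell table from [normalize_cells()].
#' @param coordinate One of `"laminar"`, `"radial"`, `"z"`.
#' @param genes Genes to keep (default: all present).
#' @param by_organ If `TRUE`, returns a nested list gene -> organ -> sample.
#' @return Named list of numeric samples (radial exclusions dropped).
#' @export
coordinate_samples <- function(cells, coordinate = c("laminar", "radial", "z"),
                               genes = NULL, by_organ = FALSE) {
  coordinate <- match.arg(coordinate)
  col <- coordinate_names[[coordinate]]
  if (is.null(genes)) genes <- sort(unique(cells$gene))
  out <- lapply(genes, function(g) {
    sub <- cells[cells$gene == g, ]
    if (by_organ) {
      lapply(split(sub[[col]], sub$organ_id), function(v) v[!is.na(v)])
    } else {
      v <- sub[[col]]
      v[!is.na(v)]
    }
  })
  names(out) <- genes
  out
}

#' Per-gene, per-coordinate distribution descriptors
#'
#' Computes, for every gene and each of the three coordinates, the pooled
#' sample size, quartiles, and half-width, pooling cells over organs
#' (per-organ curves are retained by [coordinate_samples()] for display).
#' Genes with no cells in a coordinate are reported with a warning and
#' omitted from that coordinate's rows.
#'
#' @param cells Normalized cell table.
#' @param genes Genes to summarize (default: all present).
#' @return Data frame with columns `gene`, `coordinate`, `n`, `q1`, `median`,
#'   `q3`, `half_width`.
#' @examples
#' raw <- simulate_cells(default_gene_profiles()[1:3, ], n_organs = 2, seed = 1)
#' summarize_distributions(normalize_cells(raw))
#' @export
summarize_distributions <- function(cells, genes = NULL) {
  if (nrow(cells) == 0L) stop("empty normalized table", call. = FALSE)
  if (is.null(genes)) genes <- sort(unique(cells$gene))
  rows <- list()
  for (coord in names(coordinate_names)) {
    samples <- coordinate_samples(cells, coord, genes)
    empty <- vapply(samples, length, integer(1)) == 0L
    if (any(empty)) {
      warning("no ", coord, " observations for gene(s): ",
              paste(names(samples)[empty], collapse = ", "), call. = FALSE)
      samples <- samples[!empty]
    }
    for (g in names(samples)) {
      q <- coord_quartiles(samples[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, coordinate = coord, n = length(samples[[g]]),
        q1 = q[["q1"]], median = q[["median"]], q3 = q[["q3"]],
        half_width = half_width(q[["q1"]], q[["q3"]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quartile-box ellipse specifications for coordinate pairs
#'
#' Summarizes each gene's joint position in two coordinates as an ellipse
#' centered on the medians and extending from the first to the third quartile
#' along each axis, the study's compact comparison graphic.
#'
#' @param descriptors Output of [summarize_distributions()].
#' @param x_coord,y_coord Coordinate names for the two axes.
#' @return Data frame with per-gene center (`x_center`, `y_center`) and
#'   quartile extents (`x_q1`, `x_q3`, `y_q1`, `y_q3`); the extent per axis
#'   equals that axis's half-width.
#' @export
ellipse_specs <- function(descriptors, x_coord = "radial",
                          y_coord = "laminar") {
  dx <- descriptors[descriptors$coordinate == x_coord, ]
  dy <- descriptors[descriptors$coordinate == y_coord, ]
  genes <- intersect(dx$gene, dy$gene)
  dx <- dx[match(genes, dx$gene), ]
  dy <- dy[match(genes, dy$gene), ]
  data.frame(gene = genes,
             x_center = dx$median, y_center = dy$median,
             x_q1 = dx$q1, x_q3 = dx$q3, y_q1 = dy$q1, y_q3 = dy$q3,
             stringsAsFactors = FALSE)
}

#' Laminar median spread as percent of epithelial height
#'
#' Difference between the most apical and the most basal laminar medians
#' among the given genes, in percent of total epithelial layer height.
#'
#' @param descriptors Output of [summarize_distributions()].
#' @param genes Genes over which to take the spread (default: all rows of the
#'   laminar coordinate).
#' @return Percent, one decimal.
#' @export
median_spread <- function(descriptors, genes = NULL) {
  d <- descriptors[descriptors$coordinate == "laminar", ]
  if (!is.null(genes)) d <- d[d$gene %in% genes, ]
  if (nrow(d) < 2L) stop("need at least two laminar medians", call. = FALSE)
  percent1(max(d$median) - min(d$median))
}

#' Write a descriptor table as tab-separated text
#'
#' One row per gene and coordinate: `gene`, `coordinate`, `n`, `q1`,
#' `median`, `q3`, `half_width`.
#'
#' @param descriptors Descriptor table from [summarize_distributions()].
#' @param path File path.
#' @export
write_descriptors <- function(descriptors, path) {
  write_tsv6(descriptors, path)
}
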