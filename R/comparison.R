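#' Two-sample Kolmogorov-Smirnov test on unbinned samples
#'
#' Computes the maximal vertical distance D between the two ECDFs exactly at
#' their step points, then a p-value either from the asymptotic Kolmogorov
#' limit distribution with effective size `n_a * n_b / (n_a + n_b)` (default)
#' or from a seeded permutation null (label reshuffling), which serves as the
#' small-sample and verification oracle. No assumption is made about the
#' shape of the underlying distributions; coordinate distributions in this
#' domain are typically skewed and non-Gaussian, which is why the test is the
#' study's comparison instrument.
#'
#' @param a,b Non-empty numeric samples (NAs dropped).
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm Number of permutations for the permutation method.
#' @param seed Optional seed for the permutation draw.
#' @return List with elements `D`, `p`, `n_a`, `n_b`, `method`.
#' @examples
#' set.seed(1)
#' ks_test2(runif(50), runif(50))$p
#' @export
ks_test2 <- function(a, b, method = c("asymptotic", "permutation"),
                     n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n_a <- length(a); n_b <- length(b)
  D <- ks_distance_sorted(a, b)
  if (method == "asymptotic") {
    n_eff <- n_a * n_b / (n_a + n_b)
    p <- kolmogorov_sf(sqrt(n_eff) * D)
  } else {
    if (!is.null(seed)) set.seed(seed)
    pool <- c(a, b)
    n <- n_a + n_b
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, n_a)
      if (ks_distance_sorted(pool[idx], pool[-idx]) >= D - 1e-12)
        hits <- hits + 1L
    }
    p <- (hits + 1L) / (n_perm + 1L)
  }
  list(D = D, p = min(1, p), n_a = n_a, n_b = n_b, method = method)
}

# Survival function of the Kolmogorov distribution, Q(t) = P(K > t).
# Two complementary series: the alternating sum for moderate-to-large t and
# the theta-function dual for small t, where the alternating sum converges
# slowly.
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  if (t < 1) {
    k <- 1:20
    s <- sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * t^2)))
    return(max(0, min(1, 1 - sqrt(2 * pi) / t * s)))
  }
  k <- 1:101
  max(0, min(1, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Pairwise KS comparison matrix for one coordinate
#'
#' Tests every unordered pair of genes on their pooled (across organs)
#' unbinned samples. Raw p-values are compared against the cutoff
#' `alpha = 0.01`; because the test is very sensitive for large samples
#' (n > 100), the cutoff is deliberately strict and no multiple-testing
#' adjustment is applied by default (Bonferroni available via `p_adjust`).
#'
#' @param samples Named list of per-gene samples (>= 2 genes). Genes with an
#'   empty sample are excluded with a warning.
#' @param coordinate Label stored with the matrix.
#' @param alpha Significance cutoff on (possibly adjusted) p-values.
#' @param method Passed to [ks_test2()].
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @param seed Seed forwarded to permutation tests.
#' @return A `"comparison_matrix"`: list with `coordinate`, `genes`,
#'   symmetric matrices `D` and `p` (diagonal 0 and 1), `alpha`, and the
#'   logical `significant` matrix `p < alpha`.
#' @export
pairwise_matrix <- function(samples, coordinate = "laminar", alpha = 0.01,
                            method = c("asymptotic", "permutation"),
                            p_adjust = c("none", "bonferroni"), seed = NULL) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  samples <- lapply(samples, function(v) v[!is.na(v)])
  empty <- vapply(samples, length, integer(1)) == 0L
  if (any(empty)) {
    warning("excluding gene(s) with empty sample: ",
            paste(names(samples)[empty], collapse = ", "), call. = FALSE)
    samples <- samples[!empty]
  }
  k <- length(samples)
  if (k < 2L) stop("need at least two genes with observations",
                   call. = FALSE)
  genes <- names(samples)
  D <- matrix(0, k, k, dimnames = list(genes, genes))
  p <- matrix(1, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      res <- ks_test2(samples[[i]], samples[[j]], method = method,
                      seed = seed)
      D[i, j] <- D[j, i] <- res$D
      p[i, j] <- p[j, i] <- res$p
    }
  }
  if (p_adjust == "bonferroni") {
    m <- k * (k - 1L) / 2L
    p <- pmin(p * m, 1)
    diag(p) <- 1
  }
  sig <- p < alpha
  diag(sig) <- FALSE
  structure(list(coordinate = coordinate, genes = genes, D = D, p = p,
                 alpha = alpha, significant = sig),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat("Pairwise KS comparison (", x$coordinate, "), ",
      length(x$genes), " genes, alpha = ", x$alpha, "\n", sep = "")
  cat("significant pairs:",
      sum(x$significant[upper.tri(x$significant)]), "of",
      choose(length(x$genes), 2), "\n")
  invisible(x)
}

# indistinguishability graph: edge iff p >= alpha
indist_graph <- function(cm) {
  adj <- !cm$significant
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Per-coordinate gene groups as maximal cliques
#'
#' Genes are grouped by mutual indistinguishability: the indistinguishability
#' graph has an edge between two genes iff their distributions do not differ
#' at the cutoff, and groups are its maximal cliques. Cliques may overlap —
#' a gene with an intermediate distribution can be similar to two groups
#' that differ from each other.
#'
#' @param cm A `"comparison_matrix"`.
#' @return List of character vectors (sorted member names), ordered
#'   lexicographically; every gene appears in at least one group.
#' @export
coordinate_groups <- function(cm) {
  stopifnot(inherits(cm, "comparison_matrix"))
  cl <- igraph::max_cliques(indist_graph(cm))
  groups <- lapply(cl, function(v) sort(names(v)))
  groups[order(vapply(groups, paste, character(1), collapse = "\r"))]
}

#' Combined expression-zone partition over all three coordinates
#'
#' Two genes share a zone only if they are indistinguishable in every
#' coordinate; the combined indistinguishability graph (edge iff p >= alpha
#' in all three matrices) is formed, and zones are its connected components.
#' The zone count is the number of components.
#'
#' @param matrices List of three `"comparison_matrix"` objects (laminar,
#'   radial, z) over the same gene set.
#' @return A `"zone_partition"`: list with per-coordinate `groups` (maximal
#'   cliques), `zones` (list of components, each a sorted character vector,
#'   ordered lexicographically), and `n_zones`.
#' @examples
#' raw <- simulate_cells(default_gene_profiles(), seed = 1)
#' cells <- normalize_cells(raw)
#' mats <- lapply(c("laminar", "radial", "z"), function(co)
#'   pairwise_matrix(coordinate_samples(cells, co, sparse_genes()), co))
#' zone_partition(mats)
#' @export
zone_partition <- function(matrices) {
  stopifnot(length(matrices) == 3L,
            all(vapply(matrices, inherits, logical(1), "comparison_matrix")))
  gene_sets <- lapply(matrices, function(m) sort(m$genes))
  if (!all(vapply(gene_sets, identical, logical(1), gene_sets[[1]])))
    stop("all three matrices must cover the same gene set", call. = FALSE)
  genes <- gene_sets[[1]]
  adj <- Reduce(`&`, lapply(matrices, function(m)
    !m$significant[genes, genes, drop = FALSE]))
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  zones <- split(genes, comp$membership)
  zones <- lapply(zones, sort)
  zones <- zones[order(vapply(zones, paste, character(1), collapse = "\r"))]
  names(zones) <- NULL
  groups <- lapply(matrices, coordinate_groups)
  names(groups) <- vapply(matrices, `[[`, character(1), "coordinate")
  structure(list(groups = groups, zones = zones,
                 n_zones = length(zones), genes = genes),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(x$n_zones, "expression zones for", length(x$genes), "genes:\n")
  for (z in x$zones) cat("  {", paste(z, collapse = ", "), "}\n")
  for (co in names(x$groups)) {
    cat(co, "groups:",
        paste(vapply(x$groups[[co]], function(g)
          paste0("{", paste(g, collapse = ","), "}"), character(1)),
          collapse = " "), "\n")
  }
  invisible(x)
}

#' Receptor-vs-marker distribution contrasts
#'
#' Tests each sparse receptor gene against the ciliated-neuron marker omp
#' and the microvillous marker trpc2 on laminar height, and the co-receptor
#' c1 against trpc2 on the radial coordinate. Missing marker genes are
#' skipped with a warning.
#'
#' @param cells Normalized cell table containing receptor and marker genes.
#' @param receptors Sparse receptor genes (default [sparse_genes()]).
#' @param alpha Significance cutoff.
#' @param method Passed to [ks_test2()].
#' @return Data frame with columns `gene_a`, `gene_b`, `coordinate`, `D`,
#'   `p`, `significant`.
#' @export
marker_contrasts <- function(cells, receptors = sparse_genes(),
                             alpha = 0.01,
                             method = c("asymptotic", "permutation")) {
  method <- match.arg(method)
  present <- unique(cells$gene)
  receptors <- intersect(receptors, present)
  plan <- list()
  for (m in c("omp", "trpc2")) {
    if (!m %in% present) {
      warning("marker gene ", m, " absent; skipping its contrasts",
              call. = FALSE)
      next
    }
    for (g in receptors)
      plan[[length(plan) + 1L]] <- c(g, m, "laminar")
  }
  if (all(c("c1", "trpc2") %in% present)) {
    plan[[length(plan) + 1L]] <- c("c1", "trpc2", "radial")
  } else if ("trpc2" %in% present) {
    warning("co-receptor c1 absent; skipping radial contrast",
            call. = FALSE)
  }
  rows <- lapply(plan, function(pl) {
    smp <- coordinate_samples(cells, pl[3], genes = pl[1:2])
    res <- ks_test2(smp[[pl[1]]], smp[[pl[2]]], method = method)
    data.frame(gene_a = pl[1], gene_b = pl[2], coordinate = pl[3],
               D = res$D, p = res$p, significant = res$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_a = character(), gene_b = character(),
                      coordinate = character(), D = numeric(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  out
}

#' Write comparison matrices and zone reports
#'
#' `write_comparison_matrix()` writes the D and p matrices of one coordinate
#' as two gene-by-gene tab-separated files (suffixes `_D.tsv`, `_p.tsv`).
#' `write_zone_report()` serializes a zone partition as JSON: per-coordinate
#' cliques, combined zones, and the zone count.
#'
#' @param cm A `"comparison_matrix"`.
#' @param prefix Path prefix for the two matrix files.
#' @export
write_comparison_matrix <- function(cm, prefix) {
  for (what in c("D", "p")) {
    m <- signif(cm[[what]], 6)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, paste0(prefix, "_", what, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_comparison_matrix
#' @param zp A `"zone_partition"`.
#' @param path Output JSON path.
#' @export
write_zone_report <- function(zp, path) {
  stopifnot(inherits(zp, "zone_partition"))
  jsonlite::write_json(
    list(n_zones = zp$n_zones,
         zones = zp$zones,
         coordinate_groups = zp$groups,
         genes = zp$genes),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
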