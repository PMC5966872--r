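#' Read an amino-acid alignment from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that checks all rows
#' have equal length (an alignment block) and returns the alignment as a
#' named character vector of gapped sequences, the representation used by
#' the curation filters.
#'
#' @param path FASTA file of aligned amino-acid sequences (gap `-`).
#' @return Named character vector, all elements of equal nchar.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  aln <- as.character(aa)
  check_alignment(aln)
  aln
}

check_alignment <- function(aln) {
  if (length(aln) == 0L) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  if (is.null(names(aln)) || any(!nzchar(names(aln))))
    stop("alignment rows must be named", call. = FALSE)
  invisible(aln)
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Remove alignment columns dominated by gaps
#'
#' Columns whose gap fraction is strictly greater than the threshold are
#' removed (a column that is exactly 90% gaps is retained under the default);
#' row order is preserved. The operation is idempotent.
#'
#' @param aln Named character vector of equal-length gapped sequences (see
#'   [read_alignment()]).
#' @param gap_fraction_threshold Columns with gap fraction strictly above
#'   this are dropped; default 0.90.
#' @return The stripped alignment in the same representation.
#' @export
strip_gap_columns <- function(aln, gap_fraction_threshold = 0.90) {
  check_alignment(aln)
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= gap_fraction_threshold
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(aln)
  out
}

#' Percent amino-acid identity between two aligned rows
#'
#' Identity is computed over mutually ungapped positions only: matches
#' divided by the number of positions where neither row is a gap, times 100.
#' Symmetric, in \[0, 100\].
#'
#' @param seq_a,seq_b Gapped sequences of equal length.
#' @return Percent identity.
#' @examples
#' pairwise_identity("AA--", "AAAA")   # 100: two comparable positions
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must be aligned to equal length", call. = FALSE)
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  comparable <- a != "-" & b != "-"
  if (!any(comparable))
    stop("no mutually ungapped positions to compare", call. = FALSE)
  100 * sum(a[comparable] == b[comparable]) / sum(comparable)
}

#' Collapse allelic variants by single-linkage identity clustering
#'
#' Sequences whose amino-acid identity is strictly greater than the
#' threshold are considered allelic variants of one gene. Clustering is
#' single-linkage (the transitive closure of the pairwise relation), and
#' each cluster is represented by its longest ungapped sequence, ties broken
#' lexicographically by name.
#'
#' @param aln Alignment (named character vector).
#' @param identity_threshold Percent identity above which two sequences are
#'   alleles; default 98.
#' @return List with `clusters` (list of sorted member-name vectors, one per
#'   gene) and `representatives` (character vector, one per cluster).
#' @export
collapse_alleles <- function(aln, identity_threshold = 98.0) {
  check_alignment(aln)
  k <- length(aln)
  adj <- matrix(FALSE, k, k, dimnames = list(names(aln), names(aln)))
  if (k > 1L) {
    for (i in seq_len(k - 1L))
      for (j in seq(i + 1L, k))
        adj[i, j] <- adj[j, i] <-
          pairwise_identity(aln[[i]], aln[[j]]) > identity_threshold
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- lapply(split(names(aln), comp$membership), sort)
  names(clusters) <- NULL
  reps <- vapply(clusters, function(members) {
    len <- nchar(gsub("-", "", aln[members], fixed = TRUE))
    members[order(-len, members)][1]
  }, character(1))
  ord <- order(reps)
  list(clusters = clusters[ord], representatives = reps[ord])
}

#' Distributed-difference acceptance rule for a candidate pair
#'
#' A candidate sequence is accepted as distinct from another only when the
#' overall difference is at least `min_diff_pct` percent *and* the variable
#' positions are distributed along the sequence rather than clustered
#' (guarding against locally divergent chimeras or mispredicted termini).
#' "Distributed" is formalized as the span of the mismatching positions
#' (last minus first, inclusive) covering at least `span_fraction` of the
#' alignment length.
#'
#' @param seq_a,seq_b Aligned sequences of equal length.
#' @param min_diff_pct Minimum percent difference (100 - identity).
#' @param span_fraction Minimum fraction of the alignment length the
#'   mismatch span must cover.
#' @return List with `accepted`, `reason` (`"ok"`, `"too_similar"` or
#'   `"clustered_differences"`), `diff_pct`, and `span_obs` (observed span
#'   fraction).
#' @export
distributed_difference <- function(seq_a, seq_b, min_diff_pct = 2.0,
                                   span_fraction = 0.5) {
  diff_pct <- 100 - pairwise_identity(seq_a, seq_b)
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  var_pos <- which(a != "-" & b != "-" & a != b)
  span_obs <- if (length(var_pos))
    (max(var_pos) - min(var_pos) + 1) / length(a) else 0
  if (diff_pct < min_diff_pct)
    list(accepted = FALSE, reason = "too_similar",
         diff_pct = diff_pct, span_obs = span_obs)
  else if (span_obs < span_fraction)
    list(accepted = FALSE, reason = "clustered_differences",
         diff_pct = diff_pct, span_obs = span_obs)
  else
    list(accepted = TRUE, reason = "ok",
         diff_pct = diff_pct, span_obs = span_obs)
}

#' Read a tabular locus file
#'
#' Tab-separated with header `name`, `chrom`, `start`, `end`, `strand`;
#' coordinates 0-based half-open.
#'
#' @param path File path.
#' @return Data frame of loci.
#' @export
read_loci <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "chrom", "start", "end", "strand")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop("locus table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x[needed]
}

#' Flag candidates that do not map to a unique, non-overlapping position
#'
#' Candidates whose genomic intervals overlap any other candidate on the
#' same chromosome/scaffold and strand are flagged as conflicts. Intervals
#' are 0-based half-open, so abutting intervals (`[100,200)` and `[200,300)`)
#' do not overlap. Overlap detection uses [GenomicRanges::findOverlaps()].
#'
#' @param loci Data frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @return List with `accepted` (names free of conflict) and `conflicts`
#'   (names involved in at least one overlap).
#' @export
overlap_filter <- function(loci) {
  if (any(!is.finite(loci$start)) || any(!is.finite(loci$end)) ||
      any(loci$start >= loci$end) || any(loci$start < 0))
    stop("malformed interval(s): need 0 <= start < end", call. = FALSE)
  if (anyDuplicated(loci$name))
    stop("duplicate locus names", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  conflict_idx <- unique(c(S4Vectors::queryHits(hits),
                           S4Vectors::subjectHits(hits)))
  conflicts <- sort(loci$name[conflict_idx])
  list(accepted = sort(setdiff(loci$name, conflicts)),
       conflicts = conflicts)
}

#' Read a Newick tree with numeric branch-support labels
#'
#' @param path Newick file; internal node labels hold support values
#'   (e.g. bootstrap or aLRT percentages).
#' @return An [ape] `phylo` object.
#' @export
read_support_tree <- function(path) ape::read.tree(path)

#' Filter candidates by phylogenetic placement and branch support
#'
#' The family clade is the smallest clade containing all anchor taxa
#' (established family members). A candidate is accepted when it descends
#' from that clade and every internal node on its path up to and including
#' the clade root has support strictly greater than `min_support`;
#' candidates inside the clade attached via a node at or below the
#' threshold are reported as unresolved, and candidates outside the clade
#' are rejected. Nodes without a numeric support label are not held against
#' a candidate.
#'
#' @param tree `phylo` tree with support values in `node.label`.
#' @param anchors Tip labels defining the family clade; all must be present.
#' @param candidates Tip labels to classify (default: all non-anchor tips).
#' @param min_support Support threshold (strictly-greater rule); default 80.
#' @return List with `accepted`, `unresolved`, `rejected` (sorted character
#'   vectors) and `clade_support` (support of the family clade root).
#' @export
support_filter <- function(tree, anchors, candidates = NULL,
                           min_support = 80.0) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(anchors, tree$tip.label)
  if (length(missing))
    stop("anchor taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(anchors) < 2L)
    stop("need at least two anchor taxa to define the clade", call. = FALSE)
  if (is.null(candidates)) candidates <- setdiff(tree$tip.label, anchors)
  ntip <- length(tree$tip.label)
  mrca <- ape::getMRCA(tree, anchors)
  clade_tips <- ape::extract.clade(tree, mrca)$tip.label
  support <- suppressWarnings(as.numeric(tree$node.label))
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]

  # minimum labeled support on the path from the tip's parent up to and
  # including the family clade root
  path_support <- function(tip_idx) {
    node <- parent_of[tip_idx]
    s <- Inf
    repeat {
      lab <- support[node - ntip]
      if (!is.na(lab)) s <- min(s, lab)
      if (node == mrca) break
      node <- parent_of[node]
    }
    s
  }

  status <- vapply(candidates, function(cand) {
    idx <- match(cand, tree$tip.label)
    if (is.na(idx) || !cand %in% clade_tips) return("rejected")
    if (path_support(idx) > min_support) "accepted" else "unresolved"
  }, character(1))
  clade_support <- support[mrca - ntip]
  list(accepted = sort(candidates[status == "accepted"]),
       unresolved = sort(candidates[status == "unresolved"]),
       rejected = sort(candidates[status == "rejected"]),
       clade_support = clade_support)
}

#' Full acceptance filter chain for candidate family members
#'
#' Applies, in order: gap-column stripping (>90% gaps removed), allele
#' collapsing (>98% identity, single linkage, longest-ungapped
#' representative), the distributed-difference distinctness rule against
#' every other representative, the unique non-overlapping genomic position
#' filter, and the phylogenetic support filter (>80%). A candidate is
#' accepted when it is a cluster representative and passes all three
#' remaining filters.
#'
#' @param aln Alignment of all candidate sequences (named character vector).
#' @param loci Locus table (see [read_loci()]) covering every candidate.
#' @param tree Support-labeled `phylo` tree containing candidates and
#'   anchors.
#' @param anchors Tip labels of established family members.
#' @param gap_fraction_threshold,identity_threshold,min_diff_pct,span_fraction,min_support
#'   Filter thresholds; see the individual filter functions.
#' @return List with `report` (one row per candidate: filter outcomes and
#'   an overall `accepted` flag with `reason`) and `accepted` (sorted names).
#' @export
curate_family <- function(aln, loci, tree, anchors,
                          gap_fraction_threshold = 0.90,
                          identity_threshold = 98.0,
                          min_diff_pct = 2.0, span_fraction = 0.5,
                          min_support = 80.0) {
  aln <- strip_gap_columns(aln, gap_fraction_threshold)
  candidates <- names(aln)
  missing <- setdiff(candidates, loci$name)
  if (length(missing))
    stop("loci missing for candidate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  alleles <- collapse_alleles(aln, identity_threshold)
  reps <- alleles$representatives
  rep_of <- character(0)
  for (i in seq_along(alleles$clusters))
    rep_of[alleles$clusters[[i]]] <- reps[i]

  distinct_fail <- vapply(reps, function(r) {
    others <- setdiff(reps, r)
    any(!vapply(others, function(o)
      distributed_difference(aln[[r]], aln[[o]], min_diff_pct,
                             span_fraction)$accepted, logical(1)))
  }, logical(1))

  ov <- overlap_filter(loci[loci$name %in% candidates, ])
  sup <- support_filter(tree, anchors, candidates, min_support)

  status <- data.frame(
    candidate = candidates,
    representative = rep_of[candidates],
    is_representative = candidates %in% reps,
    distinct_pass = !distinct_fail[rep_of[candidates]],
    overlap_pass = !candidates %in% ov$conflicts,
    support_status = ifelse(candidates %in% sup$accepted, "accepted",
                     ifelse(candidates %in% sup$unresolved, "unresolved",
                            "rejected")),
    stringsAsFactors = FALSE)
  status$accepted <- status$is_representative & status$distinct_pass &
    status$overlap_pass & status$support_status == "accepted"
  status$reason <- ifelse(status$accepted, "ok",
    ifelse(!status$is_representative,
           paste0("allelic_variant_of_", status$representative),
    ifelse(!status$distinct_pass, "insufficient_distributed_difference",
    ifelse(!status$overlap_pass, "overlapping_locus",
           paste0("support_", status$support_status)))))
  rownames(status) <- NULL
  list(report = status, accepted = sort(status$candidate[status$accepted]))
}

#' Synthetic candidate family with planted curation outcomes
#'
#' Generates a fully synthetic 20-candidate amino-acid family for validating
#' the curation chain: two planted allelic pairs (>98% identity), one
#' planted genomic overlap conflict, and one interloper attached inside the
#' family clade via a low-support (50) node. All other candidates are
#' mutually unrelated random sequences on non-overlapping loci inside a
#' 99-support clade anchored by two named family members.
#'
#' @param seed Seed for the sequence draw.
#' @param seq_length Alignment length (amino acids).
#' @return List with `alignment`, `loci`, `tree`, `anchors`, and `truth`
#'   (the planted allele pairs, overlap conflicts, interloper, and the
#'   candidate set a correct chain must accept).
#' @export
synthetic_family <- function(seed = 1L, seq_length = 300L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_seq <- function() paste(sample(aa, seq_length, replace = TRUE),
                               collapse = "")
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(seq_length, k)
    for (p in pos) v[p] <- sample(setdiff(aa, v[p]), 1)
    paste(v, collapse = "")
  }
  regular <- paste0("cand", sprintf("%02d", 1:15))
  seqs <- stats::setNames(vapply(seq_along(regular), function(i) rand_seq(),
                                 character(1)), regular)
  # planted allele pairs: 2 substitutions over 300 sites => 99.3% identity
  seqs["alleleA1"] <- rand_seq()
  seqs["alleleA2"] <- mutate(seqs[["alleleA1"]], 2L)
  seqs["alleleB1"] <- rand_seq()
  seqs["alleleB2"] <- mutate(seqs[["alleleB1"]], 2L)
  seqs["interloper"] <- rand_seq()
  anchors <- c("anchor1", "anchor2")
  seqs_all <- c(seqs, stats::setNames(c(rand_seq(), rand_seq()), anchors))

  candidates <- names(seqs)
  loci <- data.frame(
    name = names(seqs_all),
    chrom = "chr7",
    start = seq(0L, by = 10000L, length.out = length(seqs_all)),
    strand = "+", stringsAsFactors = FALSE)
  loci$end <- loci$start + 3000L
  # planted conflict: cand01 and cand02 overlap on the same strand
  loci$start[loci$name == "cand02"] <- loci$start[loci$name == "cand01"] + 1500L
  loci$end[loci$name == "cand02"] <- loci$start[loci$name == "cand02"] + 3000L
  loci <- loci[c("name", "chrom", "start", "end", "strand")]

  inner <- setdiff(candidates, "interloper")
  newick <- paste0(
    "((outgroup1:1,outgroup2:1)100:1,(",
    paste(paste0(inner, ":1"), collapse = ","),
    ",(interloper:1,anchor1:1)50:1,anchor2:1)99:1);")
  tree <- ape::read.tree(text = newick)

  allele_pairs <- list(c("alleleA1", "alleleA2"), c("alleleB1", "alleleB2"))
  accepted <- sort(c(setdiff(regular, c("cand01", "cand02")),
                     "alleleA1", "alleleB1"))
  list(alignment = seqs, loci = loci, tree = tree, anchors = anchors,
       truth = list(allele_pairs = allele_pairs,
                    overlap_conflicts = c("cand01", "cand02"),
                    interloper = "interloper",
                    accepted = accepted))
}
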