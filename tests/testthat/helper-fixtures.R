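# Shared fixtures built in code at test time.

# Sparse-genes-only profile table, in the canonical gene order.
sparse_profiles <- function() {
  p <- default_gene_profiles()
  p[match(sparse_genes(), p$gene), ]
}

# Small fixture for fast structural tests: three genes, two organs.
small_fixture <- function(seed = 42) {
  simulate_cells(default_gene_profiles()[1:3, ], n_organs = 2, seed = seed)
}

# Full default fixture at a fixed seed, cached per test run.
full_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_cells(default_gene_profiles(), seed = seed)
    cache[[key]]
  }
})

# Exhaustive maximal-clique enumeration over a logical adjacency matrix,
# independent oracle for coordinate_groups().
brute_force_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  subsets <- unlist(lapply(seq_len(n), function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  is_clique <- function(s) all(adj[s, s][upper.tri(diag(length(s)))])
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(setdiff(seq_len(n), s), function(v)
      is_clique(c(s, v)), logical(1)))
  }, cliques)
  out <- lapply(maximal, function(s) sort(nodes[s]))
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# Build a comparison_matrix directly from a p-value matrix (for graph tests).
fake_matrix <- function(p, coordinate = "laminar", alpha = 0.01) {
  sig <- p < alpha
  diag(sig) <- FALSE
  structure(list(coordinate = coordinate, genes = rownames(p),
                 D = 0 * p, p = p, alpha = alpha, significant = sig),
            class = "comparison_matrix")
}
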