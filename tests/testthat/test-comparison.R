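test_that("KS test degenerate and separated cases behave as expected", {
  x <- c(0.2, 0.4, 0.6)
  res <- ks_test2(x, x)
  expect_equal(res$D, 0)
  expect_equal(res$p, 1)
  a <- seq(0.1, 0.2, length.out = 50)
  b <- seq(0.8, 0.9, length.out = 50)
  res2 <- ks_test2(a, b)
  expect_equal(res2$D, 1)
  expect_lt(res2$p, 1e-6)
  expect_error(ks_test2(numeric(0), x), "non-empty")
})

test_that("asymptotic p agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(80 + i)
    b <- rnorm(120, mean = 0.2)
    ours <- ks_test2(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-4)
  }
})

test_that("asymptotic and permutation p-values agree on same-law samples", {
  p <- logitnorm_params(0.66, 0.14)
  set.seed(2026)
  a <- rlogitnorm(500, p$mu, p$sigma)
  b <- rlogitnorm(500, p$mu, p$sigma)
  asym <- ks_test2(a, b, method = "asymptotic")
  perm <- ks_test2(a, b, method = "permutation", n_perm = 10000, seed = 3)
  expect_lt(abs(asym$p - perm$p), 0.02)
})

test_that("rejection power reaches 0.95 at population distance 0.15", {
  # u1 vs q1 radial laws: population D just over 0.15
  pa <- logitnorm_params(0.43, 0.23)
  pb <- logitnorm_params(0.50, 0.23)
  expect_gte(logitnorm_ks_distance(pa, pb), 0.15)
  set.seed(606)
  rej <- replicate(200, {
    ks_test2(rlogitnorm(600, pa$mu, pa$sigma),
             rlogitnorm(600, pb$mu, pb$sigma))$p < 0.01
  })
  expect_gte(mean(rej), 0.95)
})

test_that("pairwise matrices are symmetric, complete and threshold-aware", {
  cells <- normalize_cells(full_fixture(1))
  samples <- coordinate_samples(cells, "laminar", sparse_genes())
  cm <- pairwise_matrix(samples, "laminar")
  k <- length(sparse_genes())
  expect_equal(dim(cm$D), c(k, k))
  expect_equal(cm$D, t(cm$D))
  expect_equal(cm$p, t(cm$p))
  expect_equal(unname(diag(cm$D)), rep(0, k))
  expect_equal(unname(diag(cm$p)), rep(1, k))
  expect_true(all(cm$p >= 0 & cm$p <= 1))
  # the narrow apical gene separates from every other sparse gene
  expect_true(all(cm$significant["g1", setdiff(sparse_genes(), "g1")]))
  # two genes -> a single off-diagonal pair
  cm2 <- pairwise_matrix(samples[1:2], "laminar")
  expect_equal(sum(upper.tri(cm2$p)), 1)
  expect_warning(pairwise_matrix(c(samples, list(zz = numeric(0))),
                                 "laminar"), "empty")
  expect_error(pairwise_matrix(samples[1], "laminar"), "at least two")
  # Bonferroni never decreases p
  cmb <- pairwise_matrix(samples, "laminar", p_adjust = "bonferroni")
  expect_true(all(cmb$p >= cm$p - 1e-12))
})

test_that("maximal cliques match exhaustive enumeration", {
  genes <- letters[1:3]
  p <- matrix(0, 3, 3, dimnames = list(genes, genes))
  p["a", "b"] <- p["b", "a"] <- 0.5
  p["b", "c"] <- p["c", "b"] <- 0.5
  diag(p) <- 1
  groups <- coordinate_groups(fake_matrix(p))
  expect_equal(groups, list(c("a", "b"), c("b", "c")))

  set.seed(31)
  for (i in 1:15) {
    n <- sample(3:8, 1)
    nm <- paste0("g", seq_len(n))
    pm <- matrix(0, n, n, dimnames = list(nm, nm))
    up <- upper.tri(pm)
    pm[up] <- ifelse(runif(sum(up)) < 0.5, 0.5, 0.001)
    pm <- pmax(pm, t(pm)); diag(pm) <- 1
    cm <- fake_matrix(pm)
    expect_equal(coordinate_groups(cm),
                 brute_force_cliques(!cm$significant))
  }
})

test_that("all-significant and no-significant matrices give the trivial groupings", {
  nm <- c("a", "b", "c", "d")
  all_sig <- matrix(0.001, 4, 4, dimnames = list(nm, nm)); diag(all_sig) <- 1
  expect_equal(coordinate_groups(fake_matrix(all_sig)),
               list("a", "b", "c", "d"))
  none_sig <- matrix(0.5, 4, 4, dimnames = list(nm, nm)); diag(none_sig) <- 1
  expect_equal(coordinate_groups(fake_matrix(none_sig)), list(nm))
})

test_that("zone partition combines coordinates into connected components", {
  nm <- c("a", "b", "c")
  mk <- function(sig_pairs, coord) {
    p <- matrix(0.5, 3, 3, dimnames = list(nm, nm)); diag(p) <- 1
    for (pr in sig_pairs) p[pr[1], pr[2]] <- p[pr[2], pr[1]] <- 0.001
    fake_matrix(p, coord)
  }
  # no pair distinguished anywhere -> one zone
  zp1 <- zone_partition(list(mk(list(), "laminar"), mk(list(), "radial"),
                             mk(list(), "z")))
  expect_equal(zp1$n_zones, 1)
  # every pair distinguished somewhere -> all singleton zones
  zp3 <- zone_partition(list(mk(list(c("a", "b")), "laminar"),
                             mk(list(c("b", "c")), "radial"),
                             mk(list(c("a", "c")), "z")))
  expect_equal(zp3$n_zones, 3)
  # chaining: a~b everywhere, b!~c in one coordinate -> zones {a,b},{c}
  zp2 <- zone_partition(list(mk(list(c("b", "c"), c("a", "c")), "laminar"),
                             mk(list(), "radial"), mk(list(), "z")))
  expect_equal(zp2$zones, list(c("a", "b"), "c"))
  expect_error(zone_partition(list(mk(list(), "laminar"),
                                   mk(list(), "radial"))), "length")
  bad <- mk(list(), "z"); bad$genes <- c("a", "b", "x")
  rownames(bad$p) <- colnames(bad$p) <- bad$genes
  rownames(bad$significant) <- colnames(bad$significant) <- bad$genes
  expect_error(zone_partition(list(mk(list(), "laminar"),
                                   mk(list(), "radial"), bad)),
               "same gene set")
})

test_that("zone partition is invariant to gene order and organ labels", {
  cells <- normalize_cells(full_fixture(1))
  build <- function(cells, gene_order) {
    mats <- lapply(c("laminar", "radial", "z"), function(co)
      pairwise_matrix(coordinate_samples(cells, co, gene_order), co))
    zone_partition(mats)
  }
  zp <- build(cells, sparse_genes())
  zp_rev <- build(cells, rev(sparse_genes()))
  expect_equal(zp$zones, zp_rev$zones)
  relabeled <- cells
  relabeled$organ_id <- paste0("X", relabeled$organ_id)
  expect_equal(build(relabeled, sparse_genes())$zones, zp$zones)
})

test_that("marker contrasts separate receptors from omp but not the matched marker", {
  cells <- normalize_cells(full_fixture(1))
  mc <- marker_contrasts(cells)
  omp <- mc[mc$gene_b == "omp", ]
  expect_equal(nrow(omp), 6)
  expect_true(all(omp$significant))
  # trpc2 shares the generating law of the intermediate genes
  intermediate <- mc[mc$gene_b == "trpc2" &
                       mc$gene_a %in% c("n1", "q1", "u1"), ]
  expect_false(all(intermediate$significant))
  # the broad co-receptor differs from trpc2 radially
  c1 <- mc[mc$gene_a == "c1", ]
  expect_equal(c1$coordinate, "radial")
  expect_true(c1$significant)
  # missing marker is skipped with a warning
  expect_warning(marker_contrasts(cells[cells$gene != "omp", ]), "omp")
})
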