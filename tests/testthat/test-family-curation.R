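mk_aln <- function(...) {
  v <- c(...)
  stats::setNames(v, paste0("s", seq_along(v)))
}

test_that("gap-column stripping applies the strictly-greater rule", {
  # 10 rows; column 1 all gaps (100%), column 2 exactly 9 gaps (90%)
  rows <- c(paste0("--", "A"), rep(paste0("--", "C"), 8), paste0("-A", "C"))
  aln <- mk_aln(rows)
  out <- strip_gap_columns(aln)
  expect_equal(unname(nchar(out)), rep(2, 10))   # 100% column removed
  expect_equal(substr(out[[10]], 1, 1), "A")     # 90% column retained
  # gap-free alignment unchanged; idempotence
  clean <- mk_aln("ACD", "AED")
  expect_equal(strip_gap_columns(clean), clean)
  expect_equal(strip_gap_columns(out), out)
  expect_error(strip_gap_columns(character(0)), "empty")
})

test_that("pairwise identity ignores gapped positions", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  expect_equal(pairwise_identity("AA--", "AAAA"), 100)
  expect_equal(pairwise_identity("AA-T", "AAA-"), 100)  # only 2 comparable
  expect_equal(pairwise_identity("AC", "CA"), 0)
  # symmetry and range
  expect_equal(pairwise_identity("ACDE", "ACDF"),
               pairwise_identity("ACDF", "ACDE"))
  expect_error(pairwise_identity("--A", "A--"), "no mutually ungapped")
  expect_error(pairwise_identity("AA", "AAA"), "equal length")
})

test_that("allele collapsing is single-linkage with a deterministic representative", {
  # identical pair -> one cluster
  twin <- c(x = "ACDEFGHIKL", y = "ACDEFGHIKL")
  res <- collapse_alleles(twin)
  expect_equal(length(res$clusters), 1)
  expect_equal(res$representatives, "x")         # tie broken by name
  # chain closure: a~b and b~c above threshold, a~c below
  chain <- c(a = paste(rep("A", 100), collapse = ""),
             b = paste(c(rep("A", 99), "C"), collapse = ""),
             c = paste(c(rep("A", 98), "C", "C"), collapse = ""))
  expect_equal(pairwise_identity(chain[["a"]], chain[["c"]]), 98)
  res2 <- collapse_alleles(chain)
  expect_equal(res2$clusters, list(c("a", "b", "c")))
  # all pairwise identities at or below threshold -> singletons
  res3 <- collapse_alleles(c(a = "AAAA", b = "CCCC", c = "DDDD"))
  expect_equal(length(res3$clusters), 3)
  # clusters partition the input and contain their representative
  fam <- synthetic_family(seed = 3)
  res4 <- collapse_alleles(fam$alignment)
  expect_setequal(unlist(res4$clusters), names(fam$alignment))
  expect_equal(anyDuplicated(unlist(res4$clusters)), 0)
  expect_true(all(mapply(function(cl, r) r %in% cl,
                         res4$clusters, res4$representatives)))
  # longest ungapped sequence wins representation
  gappy <- c(long = paste(rep("A", 100), collapse = ""),
             short = paste(c(rep("A", 99), "-"), collapse = ""))
  expect_equal(collapse_alleles(gappy)$representatives, "long")
})

test_that("distributed-difference rule rejects clustered variability", {
  base <- paste(rep("A", 200), collapse = "")
  expect_false(distributed_difference(base, base)$accepted)
  expect_equal(distributed_difference(base, base)$reason, "too_similar")
  # 3% difference packed into the first 5% of positions -> clustered
  front <- strsplit(base, "")[[1]]; front[1:6] <- "C"
  res <- distributed_difference(base, paste(front, collapse = ""))
  expect_false(res$accepted)
  expect_equal(res$reason, "clustered_differences")
  # the same 3% at both termini spans the alignment -> accepted
  ends <- strsplit(base, "")[[1]]; ends[c(1:3, 198:200)] <- "C"
  res2 <- distributed_difference(base, paste(ends, collapse = ""))
  expect_true(res2$accepted)
  expect_equal(res2$diff_pct, 3)
})

test_that("overlap filter uses the half-open convention per chromosome and strand", {
  loci <- data.frame(
    name = c("a", "b"), chrom = c("chr1", "chr2"),
    start = c(100, 100), end = c(200, 200), strand = "+",
    stringsAsFactors = FALSE)
  expect_equal(overlap_filter(loci)$accepted, c("a", "b"))
  same <- data.frame(name = c("a", "b"), chrom = "chr1",
                     start = c(100, 150), end = c(200, 250), strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(overlap_filter(same)$conflicts, c("a", "b"))
  abut <- data.frame(name = c("a", "b"), chrom = "chr1",
                     start = c(100, 200), end = c(200, 300), strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(overlap_filter(abut)$conflicts, character(0))
  opposite <- data.frame(name = c("a", "b"), chrom = "chr1",
                         start = c(100, 150), end = c(200, 250),
                         strand = c("+", "-"), stringsAsFactors = FALSE)
  expect_equal(overlap_filter(opposite)$conflicts, character(0))
  bad <- data.frame(name = "a", chrom = "chr1", start = 200, end = 100,
                    strand = "+", stringsAsFactors = FALSE)
  expect_error(overlap_filter(bad), "malformed")
})

test_that("support filter applies the strictly-greater rule at the clade root", {
  tr <- ape::read.tree(
    text = "((out1:1,out2:1)100:1,(cand1:1,anchor1:1,anchor2:1)99:1);")
  res <- support_filter(tr, c("anchor1", "anchor2"))
  expect_equal(res$accepted, "cand1")
  expect_equal(res$clade_support, 99)
  expect_equal(res$rejected, c("out1", "out2"))
  # support exactly at the threshold -> unresolved
  tr80 <- ape::read.tree(
    text = "((out1:1,out2:1)100:1,(cand1:1,anchor1:1,anchor2:1)80:1);")
  expect_equal(support_filter(tr80, c("anchor1", "anchor2"))$unresolved,
               "cand1")
  expect_error(support_filter(tr, c("anchor1", "nope")), "absent")
})

test_that("full curation chain recovers the planted truth exactly", {
  fam <- synthetic_family(seed = 1)
  res <- curate_family(fam$alignment, fam$loci, fam$tree, fam$anchors)
  expect_equal(res$accepted, fam$truth$accepted)
  rep <- res$report
  # allele pairs collapse onto their first-named member
  for (pair in fam$truth$allele_pairs) {
    expect_equal(rep$reason[rep$candidate == pair[2]],
                 paste0("allelic_variant_of_", pair[1]))
    expect_true(rep$accepted[rep$candidate == pair[1]])
  }
  # overlap conflict flags both partners
  for (g in fam$truth$overlap_conflicts)
    expect_equal(rep$reason[rep$candidate == g], "overlapping_locus")
  # the low-support interloper is unresolved, not accepted
  expect_equal(rep$support_status[rep$candidate == fam$truth$interloper],
               "unresolved")
  expect_false(rep$accepted[rep$candidate == fam$truth$interloper])
})

test_that("alignment and locus readers round-trip the text formats", {
  fam <- synthetic_family(seed = 2)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(fam$alignment), "\n", fam$alignment), fa)
  aln <- read_alignment(fa)
  expect_equal(aln, fam$alignment)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(fam$loci, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_loci(tsv), fam$loci)
  nw <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(fam$tree, nw)
  tr <- read_support_tree(nw)
  expect_setequal(tr$tip.label, fam$tree$tip.label)
})
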