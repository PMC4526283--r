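aa_cols_from <- function(s, L = nchar(s), offset = 0L) {
  v <- rep(NA_character_, L)
  ch <- strsplit(s, "")[[1L]]
  v[offset + seq_along(ch)] <- ch
  v
}

test_that("contig filters apply both cutoffs after duplicate collapse", {
  long_aa <- strrep("K", 110L)
  ok <- make_test_contig("a", aa_cols_from(long_aa), nt = strrep("AAG", 110L),
                         bits = 60)
  short <- make_test_contig("b", aa_cols_from(strrep("K", 99L)),
                            nt = substr(strrep("AAG", 100L), 1L, 299L),
                            bits = 60)
  weak <- make_test_contig("c", aa_cols_from(strrep("K", 150L)),
                           nt = strrep("AAG", 150L), bits = 49.9)
  dup <- make_test_contig("zz_dup", aa_cols_from(long_aa),
                          nt = strrep("AAG", 110L), bits = 60)
  kept <- filter_contigs(list(weak, ok, short, dup))
  expect_equal(vapply(kept, `[[`, character(1L), "id"), "a")
  expect_equal(filter_contigs(list()), list())
  expect_equal(filter_contigs(kept), kept)            # idempotent
})

test_that("identity is computed over overlapping model columns", {
  a <- make_test_contig("a", aa_cols_from(strrep("A", 100L)))
  expect_equal(pairwise_aa_identity(a, a), 1)
  b_seq <- paste0(strrep("A", 50L), "C", strrep("A", 49L))
  b <- make_test_contig("b", aa_cols_from(b_seq))
  expect_equal(pairwise_aa_identity(a, b), 0.99)
  c <- make_test_contig("c", aa_cols_from(strrep("A", 40L), L = 100L,
                                          offset = 60L), L = 100L)
  d <- make_test_contig("d", aa_cols_from(strrep("A", 40L), L = 100L),
                        L = 100L)
  expect_equal(pairwise_aa_identity(c, d), 0)          # disjoint spans
})

test_that("complete-linkage clustering picks the longest representative", {
  s1 <- strrep("A", 100L)
  s3 <- paste0(strrep("A", 90L), strrep("C", 10L))     # 90% identical
  x1 <- make_test_contig("x1", aa_cols_from(s1), nt = strrep("GCT", 100L))
  x2 <- make_test_contig("x2", aa_cols_from(s1),
                         nt = paste0(strrep("GCT", 100L), ""))
  x3 <- make_test_contig("x3", aa_cols_from(s3), nt = strrep("GCT", 100L))
  cl <- cluster_contigs(list(x1, x2, x3), threshold = 0.99)
  sizes <- sort(vapply(cl, function(c) length(c$members), integer(1L)))
  expect_equal(sizes, c(1L, 2L))
  # threshold 1: only exact duplicates group
  cl2 <- cluster_contigs(list(x1, x2, x3), threshold = 1)
  expect_equal(length(cl2), 2L)
  # singleton input is its own representative
  cl3 <- cluster_contigs(list(x1))
  expect_equal(cl3[[1L]]$representative$id, "x1")
  # input order invariance
  cl_rev <- cluster_contigs(list(x3, x2, x1), threshold = 0.99)
  rep_ids <- function(cl) sort(vapply(cl, function(c) c$representative$id,
                                      character(1L)))
  expect_equal(rep_ids(cl_rev), rep_ids(cl))
})

test_that("split-count coverage conserves totals and shares evenly", {
  # two contigs sharing their first 10-mer exactly
  shared <- "ACGTACGTAC"
  c1 <- make_test_contig("c1", aa_cols_from("KKKKK"),
                         nt = paste0(shared, "AAAAAAAAAA"))
  c2 <- make_test_contig("c2", aa_cols_from("KKKKK"),
                         nt = paste0(shared, "CCCCCCCCCC"))
  cov <- kmer_coverage(list(c1, c2), c(shared), k = 10L)
  expect_equal(cov$total_split, cov$total_matched)
  expect_equal(cov$total_matched, 1L)
  # the single occurrence split 0.5/0.5 over 11 positions each
  expect_equal(cov$coverage$mean_coverage, rep(0.5 / 11, 2L))
  # exact c-fold non-overlapping tiling of a lone contig: closed form
  set.seed(123)
  gene <- paste(sample(c("A", "C", "G", "T"), 100L, replace = TRUE),
                collapse = "")
  ct <- make_test_contig("t", aa_cols_from(strrep("K", 33L)), nt = gene)
  tile <- vapply(seq(1L, 76L, by = 25L), function(p) {
    substr(gene, p, p + 24L)
  }, character(1L))
  reads <- rep(tile, 3L)
  cov2 <- kmer_coverage(list(ct), reads, k = 10L)
  expect_equal(cov2$total_split, cov2$total_matched)
  # 3 tiles x 4 reads x 16 kmer positions over 91 contig positions
  expect_equal(cov2$coverage$mean_coverage[1L], 3 * 4 * 16 / 91,
               tolerance = 1e-12)
  # no hits at all
  cov3 <- kmer_coverage(list(ct), c("GGGGGGGGGGGG"), k = 10L)
  expect_equal(cov3$coverage$mean_coverage, 0)
  expect_equal(unname(cov3$read_hits["g"]), 0L)
})

test_that("relative abundance is the read-hit ratio with rplB at unity", {
  expect_equal(relative_abundance(100L, 1000L), 0.1)
  expect_equal(relative_abundance(1000L, 1000L), 1)
  expect_equal(relative_abundance(0L, 1000L), 0)
  expect_warning(ab <- relative_abundance(10L, 0L), "zero")
  expect_true(is.na(ab))
})

test_that("OTU abundances sum member coverages and conserve totals", {
  s1 <- strrep("A", 100L)
  x1 <- make_test_contig("x1", aa_cols_from(s1), nt = strrep("GCA", 100L))
  x2 <- make_test_contig("x2", aa_cols_from(s1), nt = strrep("GCA", 100L))
  clusters <- list(s1 = cluster_contigs(list(x1, x2), threshold = 0.95))
  coverage <- list(s1 = data.frame(id = c("x1", "x2"), gene = "g",
                                   mean_coverage = c(2, 3)))
  m <- coverage_weighted_otu_table(clusters, coverage)
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(unname(m[1L, 1L]), 5)
  expect_equal(sum(m["s1", ]), sum(coverage$s1$mean_coverage))
})
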