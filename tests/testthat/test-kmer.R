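test_that("reverse complement is the Watson-Crick involution", {
  expect_equal(reverse_complement("AAACCC"), "GGGTTT")
  expect_equal(reverse_complement("ACGT"), "ACGT")    # palindrome
  set.seed(7)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
               collapse = "")
    expect_equal(reverse_complement(reverse_complement(x)), x)
  }
})

test_that("kmer decomposition skips windows containing ambiguity codes", {
  expect_equal(read_kmers("ACGTA", 4L), c("ACGT", "CGTA"))
  expect_equal(read_kmers("ACNTA", 3L), character(0))
  expect_equal(read_kmers("ACG", 4L), character(0))
  expect_equal(read_kmers("acgta", 4L), c("ACGT", "CGTA"))  # case folded
})

test_that("counts are strand-symmetric and exact on the hash backend", {
  ctr <- build_counter(c("AAAA", "AAAA"), k = 4L)
  expect_equal(kmer_count(ctr, "AAAA"), 2L)
  expect_equal(kmer_count(ctr, "TTTT"), 2L)
  expect_equal(kmer_count(ctr, "ACGT"), 0L)
  expect_false(passes_min_count(ctr, "GGGG", 1L))
  # every read kmer passes min_count 1
  set.seed(11)
  reads <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  }, character(1L))
  ctr2 <- build_counter(reads, 6L)
  all_kmers <- unlist(lapply(reads, read_kmers, k = 6L))
  expect_true(all(passes_min_count(ctr2, all_kmers, 1L)))
})

test_that("minimum-abundance filtering obeys the cutoff", {
  ctr <- build_counter(c("ACGTACG", "ACGTAAA"), k = 4L)
  expect_equal(kmer_count(ctr, "ACGT"), 2L)
  expect_false(passes_min_count(ctr, "GTAC", 2L))   # count 1, min 2
  expect_true(passes_min_count(ctr, "ACGT", 2L))
})

test_that("counting Bloom filter never undercounts and meets its rate", {
  set.seed(42)
  reads <- vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  }, character(1L))
  exact <- build_counter(reads, 9L)
  bloom <- build_counter(reads, 9L, backend = "bloom",
                         bloom_counters = 2^16, bloom_hashes = 4L)
  kms <- unique(unlist(lapply(reads, read_kmers, k = 9L)))
  ce <- kmer_count(exact, kms)
  cb <- kmer_count(bloom, kms)
  expect_true(all(cb >= pmin(ce, 15L)))             # no false negatives
  # false positives: absent kmers reported present
  set.seed(43)
  absent <- character(0)
  while (length(absent) < 2000L) {
    km <- paste(sample(c("A", "C", "G", "T"), 9L, replace = TRUE),
                collapse = "")
    if (kmer_count(exact, km) == 0L) absent <- c(absent, km)
  }
  fp <- mean(kmer_count(bloom, absent) > 0L)
  expect_lte(fp, 2 * bloom$expected_fp + 0.01)
  expect_error(build_counter(reads, 9L, backend = "bloom",
                             bloom_counters = 2^8, bloom_hashes = 4L),
               "false-positive")
})

test_that("codon neighbours require all three intermediate steps", {
  ctr <- build_counter("ACGTGACTT", k = 6L)
  nb <- codon_neighbors(ctr, "ACGTGA", "right")
  expect_equal(nb$kmer, "TGACTT")
  expect_equal(nb$codon, "CTT")
  empty <- build_counter("ACGTACGT", k = 6L)
  expect_length(codon_neighbors(empty, "AAAAAA", "right")$kmer, 0L)
  # against the brute-force single-step walker on random read sets
  set.seed(5)
  for (rep in 1:10) {
    reads <- vapply(1:4, function(i) {
      paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE), collapse = "")
    }, character(1L))
    ctr2 <- build_counter(reads, 6L)
    start <- substr(reads[1L], 1L, 6L)
    for (dir in c("right", "left")) {
      got <- codon_neighbors(ctr2, start, dir)
      want <- oracle_codon_steps(ctr2, start, dir)
      expect_setequal(got$kmer, vapply(want, `[[`, character(1L), "kmer"))
      expect_setequal(paste(got$kmer, got$codon),
                      vapply(want, function(w) paste(w$kmer, w$codon),
                             character(1L)))
    }
  }
})

test_that("left and right walks mirror under reverse complement", {
  set.seed(9)
  reads <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  }, character(1L))
  ctr <- build_counter(reads, 6L)      # canonical storage: same counter
  start <- substr(reads[1L], 4L, 9L)
  right <- codon_neighbors(ctr, start, "right")
  left_rc <- codon_neighbors(ctr, reverse_complement(start), "left")
  expect_setequal(reverse_complement(right$kmer), left_rc$kmer)
})
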