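# A linear single-gene world: one protein, one back-translated gene,
# reads tiling it perfectly.
linear_world <- function(len = 20L, seed = 17L, k = 6L) {
  prot <- random_protein(len, seed = seed)
  nt <- back_translate(prot, seed = seed + 1L)
  reads <- vapply(seq(1L, nchar(nt) - 17L, by = 3L), function(p) {
    substr(nt, p, p + 17L)
  }, character(1L))
  list(prot = prot, nt = nt, counter = build_counter(c(nt, reads), k),
       model = build_profile_hmm(msa_from(c(ref = prot)), name = "g"),
       k = k)
}

test_that("successors follow the combined-graph edge rules", {
  w <- linear_world()
  start <- substr(w$nt, 1L, 6L)
  succ <- cag_successors(w$model, w$counter, start, 2L, "M", "right")
  m_idx <- which(succ$state == "M")
  expect_length(m_idx, 1L)                       # unique-kmer linear path
  expect_equal(succ$kmer[m_idx], substr(w$nt, 4L, 9L))
  expect_equal(succ$aa[m_idx], substr(w$prot, 3L, 3L))
  # delete successor exists regardless of counter contents
  empty <- build_counter("GGGGGGGG", 6L)
  succ2 <- cag_successors(w$model, empty, start, 2L, "M", "right")
  expect_equal(succ2$state, "D")
  expect_equal(succ2$kmer, start)                # kmer carried through
  # successor count bound: <= 64 codons x (M,I) + 1 delete
  expect_lte(length(succ$state), 129L)
})

test_that("A* recovers a planted gene with the exact raw score", {
  w <- linear_world()
  res <- astar_search(w$model, w$counter, substr(w$nt, 1L, 6L), 2L, "right",
                      prune = -1L)
  expect_true(res$found)
  nt_out <- paste0(substr(w$nt, 1L, 6L),
                   paste(res$path$codon[!is.na(res$path$codon)],
                         collapse = ""))
  expect_equal(nt_out, w$nt)
  # independent forward-walk score of the true path, match states only
  aa <- strsplit(w$prot, "")[[1L]]
  expected_raw <- 0
  for (j in 3:w$model$L) {
    expected_raw <- expected_raw + log(w$model$trans[j, "MM"]) +
      log(w$model$match_emission[j, aa[j]] / w$model$background[[aa[j]]])
  }
  expect_equal(res$raw, unname(expected_raw), tolerance = 1e-9)
})

test_that("exhaustion returns the best intermediate vertex, flagged partial", {
  w <- linear_world()
  lonely <- build_counter(substr(w$nt, 1L, 6L), 6L)  # start kmer only
  res <- astar_search(w$model, w$counter, substr(w$nt, 1L, 6L), w$model$L,
                      "right")
  expect_true(res$found)                         # start at goal: trivial
  res2 <- astar_search(w$model, lonely, substr(w$nt, 1L, 6L), 2L, "right",
                       prune = 5L)
  expect_true(res2$partial)
  expect_equal(nrow(res2$path), 1L)              # start vertex alone
})

test_that("modified and raw scores differ by the column constant", {
  # the correction subtracts c_j once per column entered through M or D,
  # so a complete path from column c to L satisfies
  # raw - modified = sum_{j=c+1}^{L} c_j
  w <- linear_world()
  for (start_col in c(2L, 5L)) {
    p <- 3L * (start_col - 2L) + 1L
    res <- astar_search(w$model, w$counter, substr(w$nt, p, p + 5L),
                        start_col, "right", prune = -1L)
    expect_true(res$found)
    const <- sum(w$model$cmax[(start_col + 1L):w$model$L])
    expect_equal(res$raw - res$g, const, tolerance = 1e-9)
  }
})

test_that("assembly from any interior seed reconstructs the same contig", {
  fx_in <- get_search_inputs("clean")
  gene <- "rplB"
  m <- fx_in$models[[gene]]
  starts <- fx_in$starts[fx_in$starts$gene == gene, ]
  truth <- fixture_truth(fx_in$fx)
  picks <- starts[c(1L, nrow(starts) %/% 2L, nrow(starts)), ]
  nts <- vapply(seq_len(nrow(picks)), function(i) {
    assemble_gene(as.list(picks[i, ]), m$forward, m$reverse,
                  fx_in$counter)$nt
  }, character(1L))
  expect_true(all(nts %in% truth))
  # a seed at the model start leaves the left search trivially empty
  first <- as.list(starts[starts$model_column_first == 1L, ][1L, ])
  ct <- assemble_gene(first, m$forward, m$reverse, fx_in$counter)
  expect_equal(ct$span[1L], 1L)
  expect_equal(substr(ct$nt, 1L, 45L), first$nt_kmer)
})

test_that("best-path caching does not change the contig set", {
  fx_in <- get_search_inputs("clean")
  gene <- "nirK"
  m <- fx_in$models[[gene]]
  starts <- fx_in$starts[fx_in$starts$gene == gene, ][1:20, ]
  with_cache <- assemble_gene_all(starts, m$forward, m$reverse,
                                  fx_in$counter)
  no_cache <- lapply(seq_len(nrow(starts)), function(i) {
    assemble_gene(as.list(starts[i, ]), m$forward, m$reverse, fx_in$counter)
  })
  nts1 <- sort(vapply(with_cache, `[[`, character(1L), "nt"))
  nts2 <- sort(unique(vapply(no_cache, `[[`, character(1L), "nt")))
  expect_equal(nts1, nts2)
})

test_that("rescoring matches the closed-form consensus score", {
  m <- build_profile_hmm(msa_from(c("MKVLAWDE", "MKVLAWDE", "MKVIAWDE")))
  consensus <- paste(AA_ALPHABET[apply(m$elo, 1L, which.max)],
                     collapse = "")
  expected <- sum(log2(m$trans[seq_len(m$L), "MM"]) + m$cmax / log(2))
  expect_equal(rescore_contig(consensus, m), unname(expected),
               tolerance = 1e-9)
  expect_error(rescore_contig("MK*VL", m), "stop")
  # invariance: a function of the sequence only
  expect_equal(rescore_contig(consensus, m), rescore_contig(consensus, m))
})
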