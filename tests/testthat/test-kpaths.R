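path_keys <- function(path) {
  paste(paste0(path$kmer, "|", path$col, "|", path$state), collapse = " ")
}

test_that("K = 1 reduces to the plain A* best path", {
  inst <- toy_instance(101L)
  one <- k_shortest_paths(inst$model, inst$counter, inst$start_kmer,
                          inst$start_col, "right", K = 1L, prune = -1L)
  best <- astar_search(inst$model, inst$counter, inst$start_kmer,
                       inst$start_col, "right", prune = -1L)
  expect_length(one, 1L)
  expect_equal(one[[1L]]$g, best$g)
  expect_equal(path_keys(one[[1L]]$path), path_keys(best$path))
})

test_that("a diamond graph yields both variants and nothing more", {
  prot <- "MKVLAWDE"
  vb <- "MKVICWDE"                        # differs at codons 4-5
  ntA <- back_translate(prot, seed = 31L)
  ntB <- paste0(substr(ntA, 1L, 9L),
                back_translate(substr(vb, 4L, 5L), seed = 32L),
                substr(ntA, 16L, 24L))
  model <- build_profile_hmm(msa_from(c(a = prot, b = vb)))
  counter <- build_counter(c(ntA, ntB), 6L)
  for (K in c(2L, 3L, 6L)) {
    rp <- k_shortest_paths(model, counter, substr(ntA, 1L, 6L), 2L,
                           "right", K = K, prune = -1L)
    nts <- vapply(rp, function(r) {
      paste0(substr(ntA, 1L, 6L),
             paste(r$path$codon[!is.na(r$path$codon)], collapse = ""))
    }, character(1L))
    expect_setequal(nts, c(ntA, ntB))     # K >= 2: both, never a third
    expect_equal(vapply(rp, `[[`, integer(1L), "rank"), seq_along(rp))
    gs <- vapply(rp, `[[`, numeric(1L), "g")
    expect_true(all(diff(gs) <= 1e-12))   # non-increasing with rank
  }
})

test_that("ranked paths equal brute-force enumeration under both filters", {
  for (s in c(7L, 19L, 23L, 57L, 91L)) {
    inst <- toy_instance(s)
    paths <- oracle_enumerate(inst$model, inst$counter, inst$start_kmer,
                              inst$start_col)
    expect_true(attr(paths, "complete"))
    if (length(paths) == 0L) next
    want <- oracle_ranked(paths, K = 4L)
    got <- k_shortest_paths(inst$model, inst$counter, inst$start_kmer,
                            inst$start_col, "right", K = 4L, prune = -1L,
                            max_spur_attempts = 5000L)
    expect_equal(length(got), length(want), info = paste("seed", s))
    for (i in seq_along(want)) {
      expect_equal(got[[i]]$g, want[[i]]$g, tolerance = 1e-9,
                   info = paste("seed", s, "rank", i))
      expect_equal(got[[i]]$raw, want[[i]]$raw, tolerance = 1e-9,
                   info = paste("seed", s, "rank", i))
      # path identity up to exact score ties: tied alignments of equal
      # score may be discovered (and greedily filtered) in either order,
      # so the returned path must be one of the enumeration's paths at
      # exactly the claimed score
      tied <- vapply(paths, function(p) {
        abs(p$g - want[[i]]$g) < 1e-12 && abs(p$raw - want[[i]]$raw) < 1e-12
      }, logical(1L))
      tied_keys <- vapply(paths[tied], function(p) {
        paste(p$vkeys, collapse = " ")
      }, character(1L))
      expect_true(path_keys(got[[i]]$path) %in% tied_keys,
                  info = paste("seed", s, "rank", i))
    }
  }
})

test_that("no returned path duplicates a lower rank's nucleotide sequence", {
  inst <- toy_instance(77L)
  rp <- k_shortest_paths(inst$model, inst$counter, inst$start_kmer,
                         inst$start_col, "right", K = 6L, prune = -1L,
                         max_spur_attempts = 3000L)
  nts <- vapply(rp, function(r) {
    paste0(inst$start_kmer,
           paste(r$path$codon[!is.na(r$path$codon)], collapse = ""))
  }, character(1L))
  expect_equal(anyDuplicated(nts), 0L)
})
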