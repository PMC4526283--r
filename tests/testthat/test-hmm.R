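test_that("model construction follows the stated counting rules", {
  m1 <- build_profile_hmm(msa_from("MKVLA"))
  expect_equal(m1$L, 5L)                      # every column a match column
  # column with residues {A, A}: (2 + 1/20) / (2 + 1)
  m2 <- build_profile_hmm(msa_from(c("AC", "AC")))
  expect_equal(unname(m2$match_emission[1L, "A"]), (2 + 0.05) / 3,
               tolerance = 1e-12)
  # with no observed delete events the prior mean dominates (interior col)
  expect_equal(unname(m2$trans[2L, "DM"]), 0.95)
  expect_equal(unname(m2$trans[2L, "DD"]), 0.05)
  # normalisation invariants
  m3 <- build_profile_hmm(msa_from(c("MKVA", "MK-A", "MRVA")))
  expect_equal(rowSums(m3$match_emission), rep(1, m3$L), tolerance = 1e-9)
  expect_equal(unname(rowSums(m3$trans[, c("MM", "MI", "MD")])),
               rep(1, m3$L + 1L), tolerance = 1e-9)
  expect_equal(unname(rowSums(m3$trans[, c("IM", "II")])),
               rep(1, m3$L + 1L), tolerance = 1e-9)
  expect_equal(sum(m3$background), 1, tolerance = 1e-9)
  expect_error(build_profile_hmm(msa_from(c("--", "--"))), "match columns")
})

test_that("emissions converge to observed frequencies as pseudocount -> 0", {
  aln <- msa_from(rep("MKV", 50L))
  m <- build_profile_hmm(aln, emission_pseudocount = 1e-9)
  expect_equal(unname(m$match_emission[1L, "M"]), 1, tolerance = 1e-6)
  expect_equal(unname(m$match_emission[2L, "K"]), 1, tolerance = 1e-6)
})

test_that("the reversed model is the column-reversed forward model", {
  seqs <- c("MKVLA", "MRVLA", "MKVIA")
  fwd <- build_profile_hmm(msa_from(seqs))
  rev <- build_reverse_model(msa_from(seqs))
  expect_equal(rev$L, fwd$L)
  expect_equal(rev$direction, "reversed")
  for (j in seq_len(fwd$L)) {
    expect_equal(rev$match_emission[j, ], fwd$match_emission[fwd$L - j + 1L, ])
  }
  # reverse of the reverse equals the forward model
  rev2 <- build_reverse_model(msa_from(vapply(seqs, function(s) {
    paste(rev(strsplit(s, "")[[1L]]), collapse = "")
  }, character(1L))))
  expect_equal(rev2$match_emission, fwd$match_emission, tolerance = 1e-12)
  expect_equal(rev2$trans, fwd$trans, tolerance = 1e-12)
})

test_that("HMMER3 write/parse round trip preserves parameters", {
  m <- build_profile_hmm(msa_from(c("MKVLACDE", "MRVLACDE", "MKVIACDW")),
                         name = "rt")
  tf <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(m, tf)
  m2 <- parse_hmmer3(tf)
  expect_equal(m2$L, m$L)
  expect_equal(m2$match_emission, m$match_emission, tolerance = 1e-4)
  expect_equal(m2$trans, m$trans, tolerance = 1e-4)
  expect_equal(unname(m2$background), unname(m$background[AA_ALPHABET]),
               tolerance = 1e-4)
})

test_that("a model written by the reference builder parses cleanly", {
  m <- parse_hmmer3(test_path("synthetic-model.hmm"))
  expect_equal(m$L, 25L)
  expect_true(all(abs(rowSums(m$match_emission) - 1) < 1e-3))
  expect_true(all(abs(rowSums(m$trans[, c("MM", "MI", "MD")]) - 1) < 1e-3))
  # "*" tokens become probability zero (terminal node d->d, m->d)
  expect_equal(unname(m$trans[m$L + 1L, "DD"]), 0)
})

test_that("non-amino-acid models are rejected", {
  tf <- withr::local_tempfile(fileext = ".hmm")
  writeLines(c("HMMER3/f [x]", "NAME  dna", "LENG  4", "ALPH  DNA",
               "HMM A C G T", "//"), tf)
  expect_error(parse_hmmer3(tf), "alphabet")
})

test_that("emission log-odds are null-normalised", {
  m <- build_profile_hmm(msa_from(c("MKV", "MKV")))
  # argmax amino acid attains the per-column maximum used for correction
  for (j in 1:3) {
    amax <- AA_ALPHABET[which.max(m$elo[j, ])]
    expect_equal(emission_logodds(m, j, amax), unname(m$cmax[j]))
  }
  # an emission equal to background has log-odds 0 (construct directly)
  m$match_emission[1L, ] <- m$background[AA_ALPHABET]
  m$elo[1L, ] <- log(m$match_emission[1L, ] / m$background[AA_ALPHABET])
  expect_equal(emission_logodds(m, 1L, "A"), 0)
  expect_equal(emission_logodds(m, 1L, "*"), -Inf)
})

test_that("edge weights implement the monotonicity correction", {
  m <- build_profile_hmm(msa_from(c("MKVLA", "MRVLA")))
  j <- 3L
  amax <- AA_ALPHABET[which.max(m$elo[j, ])]
  # modified M->M weight with the argmax amino acid reduces to log t
  wm <- edge_weight(m, list(state = "M", col = j - 1L),
                    list(state = "M", col = j), amax, "modified")
  expect_equal(wm, unname(log(m$trans[j, "MM"])), tolerance = 1e-12)
  # edges into insert states are uncorrected
  wi_raw <- edge_weight(m, list(state = "M", col = j),
                        list(state = "I", col = j), "A", "raw")
  wi_mod <- edge_weight(m, list(state = "M", col = j),
                        list(state = "I", col = j), "A", "modified")
  expect_equal(wi_mod, wi_raw)
  # raw delete weight carries no emission term
  wd <- edge_weight(m, list(state = "M", col = j - 1L),
                    list(state = "D", col = j), variant = "raw")
  expect_equal(wd, unname(log(m$trans[j, "MD"])))
  expect_error(edge_weight(m, list(state = "I", col = j),
                           list(state = "D", col = j + 1L), "A"),
               "illegal")
})

test_that("the completion heuristic is the best all-match suffix", {
  m <- build_profile_hmm(msa_from(c("MK", "MK", "MR")))
  h <- heuristic_table(m)
  expect_equal(unname(h["M", m$L + 1L]), 0)          # goal
  expect_equal(unname(h["M", 2L]), unname(log(m$trans[2L, "MM"])),
               tolerance = 1e-12)                    # L=2 toy: h(M1)
  # non-positive everywhere for probability-valued transitions
  m2 <- build_profile_hmm(msa_from(c("MKVLACD", "MRVIACD")))
  expect_true(all(heuristic_table(m2) <= 1e-12))
})

test_that("bit conversion is nats over ln 2", {
  expect_equal(bit_score(0), 0)
  expect_equal(bit_score(log(2)), 1)
  expect_equal(bit_score(3.1) + bit_score(1.2), bit_score(4.3))
})
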