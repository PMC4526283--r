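# Shared fixtures, built once per test run (generation and full pipeline
# runs are the expensive part of the suite).

.fx_cache <- new.env(parent = emptyenv())

fixture_seed <- c(clean = 1L, two_haplotype = 2L, shared_kmer = 3L,
                  low_coverage = 4L)

get_fixture <- function(name) {
  if (is.null(.fx_cache[[name]])) {
    dir <- file.path(tempdir(), paste0("hmmasm_fx_", name))
    unlink(dir, recursive = TRUE)
    .fx_cache[[name]] <- make_fixture(name, dir, seed = fixture_seed[[name]])
  }
  .fx_cache[[name]]
}

fixture_truth <- function(fx) {
  recs <- read_fasta(file.path(fx$dir, "truth_nt.fasta"))
  setNames(toupper(vapply(recs, function(r) r$seq, character(1L))),
           vapply(recs, function(r) r$id, character(1L)))
}

# default-parameter pipeline run on the clean fixture, memoised
get_clean_pipeline <- function() {
  if (is.null(.fx_cache$clean_pipeline)) {
    fx <- get_fixture("clean")
    out <- file.path(tempdir(), "hmmasm_clean_out")
    unlink(out, recursive = TRUE)
    .fx_cache$clean_pipeline <- run_pipeline(fx$dir, out, k = 45L)
  }
  .fx_cache$clean_pipeline
}

# counter + models + starting kmers for one fixture, memoised
get_search_inputs <- function(name, k = 45L) {
  key <- paste0("inputs_", name, "_", k)
  if (is.null(.fx_cache[[key]])) {
    fx <- get_fixture(name)
    reads <- read_fastq(file.path(fx$dir, "reads.fastq"))
    counter <- build_counter(reads, k)
    genes <- names(fx$genes)
    models <- lapply(genes, function(g) {
      aln <- read_alignment(file.path(fx$dir, g, "seed.aln"))
      list(forward = build_profile_hmm(aln, name = g),
           reverse = build_reverse_model(aln, name = g),
           refs = read_alignment(file.path(fx$dir, g, "refs.aln")))
    })
    names(models) <- genes
    map <- build_reference_kmer_map(lapply(models, `[[`, "refs"), k %/% 3L)
    starts <- find_starting_kmers(reads, map, k)
    starts <- starts[passes_min_count(counter, starts$nt_kmer), ,
                     drop = FALSE]
    .fx_cache[[key]] <- list(fx = fx, reads = reads, counter = counter,
                             models = models, starts = starts)
  }
  .fx_cache[[key]]
}

# build a minimal contig object directly (for post-processing tests)
make_test_contig <- function(id, aa_cols, gene = "g", nt = NULL,
                             bits = 100, L = length(aa_cols)) {
  present <- which(!is.na(aa_cols))
  aa <- paste(aa_cols[present], collapse = "")
  if (is.null(nt)) nt <- strrep("ACG", nchar(aa))
  structure(list(gene = gene, id = id, nt = nt, aa = aa, bits = bits,
                 span = range(present), partial = FALSE,
                 seed = list(kmer = substr(nt, 1, 45), first = present[1L],
                             last = present[1L]),
                 aa_cols = aa_cols, score_mod = 0, score_raw = 0,
                 n_opened = 0L, rank = 1L),
            class = "contig")
}

msa_from <- function(seqs) {
  nms <- names(seqs)
  if (is.null(nms)) nms <- paste0("s", seq_along(seqs))
  recs <- lapply(seq_along(seqs), function(i) {
    seq_record(nms[i], seqs[[i]])
  })
  structure(list(records = recs, n_columns = nchar(seqs[[1L]])),
            class = "msa")
}
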