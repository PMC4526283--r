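# Synthetic-community fixture generator: gene families, planted genomes,
# and shotgun reads with known ground truth, so every assembly stage is
# testable without external datasets.

#' Evolve a protein family from an ancestor
#'
#' Independent per-site substitution at rate `sub_rate` with uniform
#' replacement over the other 19 amino acids; no indels by default, so
#' the family is trivially aligned.  Reproducible by seed.
#'
#' @param ancestor Ancestor protein string.
#' @param n Number of descendant sequences.
#' @param sub_rate Per-site substitution probability in [0, 1].
#' @param seed RNG seed.
#' @return Character vector of `n` proteins, names `v1..vn`.
#' @export
evolve_family <- function(ancestor, n, sub_rate, seed = 1L) {
  stopifnot(n >= 1L, sub_rate >= 0, sub_rate <= 1)
  set.seed(seed)
  anc <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
  out <- vapply(seq_len(n), function(i) {
    s <- anc
    hit <- runif(length(s)) < sub_rate
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(a) {
        sample(setdiff(AA_ALPHABET, a), 1L)
      }, character(1L))
    }
    paste(s, collapse = "")
  }, character(1L))
  setNames(out, paste0("v", seq_len(n)))
}

#' Random protein of a given length
#'
#' Residues drawn from the background composition; the first residue is
#' M so back-translations begin with ATG.
#'
#' @param length Protein length in residues.
#' @param seed RNG seed.
#' @return Protein string.
#' @export
random_protein <- function(length, seed = 1L) {
  set.seed(seed)
  bg <- aa_background()
  paste(c("M", sample(AA_ALPHABET, length - 1L, replace = TRUE, prob = bg)),
        collapse = "")
}

# synonymous codon sets, built once from the genetic code
.codons_by_aa <- local({
  aa <- .codon_table
  split(names(aa), aa)
})

#' Back-translate a protein to a nucleotide gene
#'
#' Uniform random choice among synonymous codons, deterministic by seed;
#' `translate_nt(result) == protein`.
#'
#' @param protein Protein string (no stops).
#' @param seed RNG seed for codon choice.
#' @return Nucleotide string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein, seed = 1L) {
  set.seed(seed)
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- vapply(res, function(a) {
    opts <- .codons_by_aa[[a]]
    if (is.null(opts)) stop("cannot back-translate residue '", a, "'")
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L))
  paste(codons, collapse = "")
}

.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate shotgun reads from genomes
#'
#' Uniform start positions, both strands equiprobable, independent
#' substitution errors at `error_rate`, constant quality (error bases
#' optionally downgraded).  Genomes are sampled proportionally to
#' `weights` (per-base, so longer genomes receive proportionally more
#' reads).  A manifest records each read's origin.
#'
#' @param genomes Named character vector of genome sequences.
#' @param coverage Target mean fold coverage.
#' @param read_length Read length (reads never run off the genome end).
#' @param error_rate Per-base substitution error probability.
#' @param weights Optional per-genome relative abundance weights.
#' @param seed RNG seed.
#' @param base_quality Constant Phred score assigned to all bases.
#' @return List: `reads` (list of [seq_record]), `manifest` (data.frame
#'   read_id/genome/start/strand/n_errors).
#' @export
generate_reads <- function(genomes, coverage = 30, read_length = 100L,
                           error_rate = 0, weights = NULL, seed = 1L,
                           base_quality = 35L) {
  stopifnot(coverage > 0)
  set.seed(seed)
  glen <- nchar(genomes)
  if (any(glen < read_length)) stop("genome shorter than read length")
  if (is.null(weights)) weights <- rep(1, length(genomes))
  weights <- weights / sum(weights)
  total_bases <- sum(glen) * coverage
  n_reads <- max(1L, round(total_bases / read_length))
  pick_p <- weights * glen / sum(weights * glen)
  origin <- sample(seq_along(genomes), n_reads, replace = TRUE, prob = pick_p)
  reads <- vector("list", n_reads)
  manifest <- data.frame(read_id = character(n_reads),
                         genome = character(n_reads),
                         start = integer(n_reads),
                         strand = character(n_reads),
                         n_errors = integer(n_reads),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_reads)) {
    gi <- origin[i]
    start <- sample.int(glen[gi] - read_length + 1L, 1L)
    s <- substr(genomes[gi], start, start + read_length - 1L)
    strand <- if (runif(1) < 0.5) "+" else "-"
    nerr <- 0L
    if (error_rate > 0) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      hit <- runif(read_length) < error_rate
      nerr <- sum(hit)
      if (nerr > 0L) {
        ch[hit] <- vapply(ch[hit], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1L))
        s <- paste(ch, collapse = "")
      }
    }
    if (strand == "-") s <- reverse_complement(s)
    rid <- sprintf("read%06d", i)
    reads[[i]] <- seq_record(rid, s, qual = rep(base_quality, read_length))
    manifest$read_id[i] <- rid
    manifest$genome[i] <- names(genomes)[gi]
    manifest$start[i] <- start
    manifest$strand[i] <- strand
    manifest$n_errors[i] <- nerr
  }
  list(reads = reads, manifest = manifest)
}

.write_aln <- function(seqs, path) {
  write_fasta(setNames(as.character(seqs), names(seqs)), path)
}

#' Build a named test fixture with known ground truth
#'
#' Writes a fixture directory in the layout the pipeline consumes:
#' `reads.fastq`, per-gene `<gene>/seed.aln` and `<gene>/refs.aln`,
#' `truth_nt.fasta` / `truth_aa.fasta`, and `manifest.tsv`.  All content
#' is synthetic, generated from the seed.  Fixtures:
#'
#' * `"clean"` — two gene families (`rplB`, `nirK`), two planted variants
#'   each, 30x coverage, error-free reads: full-length recovery expected.
#' * `"two_haplotype"` — one gene, two haplotypes identical outside a
#'   divergent interior block (identical codons elsewhere): the K-paths
#'   microheterogeneity case.
#' * `"shared_kmer"` — two diverged variants sharing one exact interior
#'   33 nt run: cross-variant joins are possible for k below the shared
#'   length and impossible for k above it (the chimera/kmer-length case).
#' * `"low_coverage"` — 0.5x coverage with zero-coverage gaps: the
#'   search-exhaustion / partial-contig case.
#'
#' @param name Fixture name (above).
#' @param dir Output directory (created).
#' @param seed Base RNG seed.
#' @return Invisibly, a list describing the fixture (genes, truth
#'   sequences, read count, paths).
#' @export
make_fixture <- function(name = c("clean", "two_haplotype", "shared_kmer",
                                  "low_coverage"),
                         dir, seed = 1L) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  protein_length <- 110L
  read_length <- 100L

  build_family <- function(anc, n, rate, seed) {
    fam <- evolve_family(anc, n, rate, seed = seed)
    fam
  }

  genes <- list()
  truth_nt <- character(0)
  coverage <- 30
  error_rate <- 0

  if (name == "clean") {
    for (gi in seq_along(c("rplB", "nirK"))) {
      gene <- c("rplB", "nirK")[gi]
      anc <- random_protein(protein_length, seed = seed + 10L * gi)
      fam <- build_family(anc, 8L, 0.10, seed = seed + 10L * gi + 1L)
      planted <- fam[c(1L, 2L)]
      nt <- vapply(seq_along(planted), function(i) {
        back_translate(planted[i], seed = seed + 100L * gi + i)
      }, character(1L))
      names(nt) <- paste0(gene, "_", names(planted))
      genes[[gene]] <- list(seed_aln = fam, refs_aln = fam, planted = planted)
      truth_nt <- c(truth_nt, nt)
    }
  } else if (name == "two_haplotype") {
    gene <- "nirK"
    hap1 <- random_protein(protein_length, seed = seed + 5L)
    block <- 55:75                       # divergent interior block (aa)
    set.seed(seed + 7L)
    h2 <- strsplit(hap1, "", fixed = TRUE)[[1L]]
    h2[block] <- vapply(h2[block], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1L)
    }, character(1L))
    hap2 <- paste(h2, collapse = "")
    nt1 <- back_translate(hap1, seed = seed + 8L)
    # identical codons outside the block: substitute codons only inside
    set.seed(seed + 9L)
    codons <- substring(nt1, 3L * (seq_len(protein_length) - 1L) + 1L,
                        3L * seq_len(protein_length))
    for (p in block) {
      opts <- .codons_by_aa[[h2[p]]]
      codons[p] <- if (length(opts) == 1L) opts else sample(opts, 1L)
    }
    nt2 <- paste(codons, collapse = "")
    # seed family supports both haplotypes symmetrically
    fam <- c(evolve_family(hap1, 4L, 0.08, seed = seed + 10L),
             evolve_family(hap2, 4L, 0.08, seed = seed + 11L))
    names(fam) <- paste0("r", seq_along(fam))
    refs <- c(fam, hap1 = hap1, hap2 = hap2)
    genes[[gene]] <- list(seed_aln = refs, refs_aln = refs,
                          planted = c(hap1 = hap1, hap2 = hap2))
    truth_nt <- c(nirK_hap1 = nt1, nirK_hap2 = nt2)
  } else if (name == "shared_kmer") {
    gene <- "nirK"
    vA <- random_protein(protein_length, seed = seed + 21L)
    shared_aa <- 50:60                   # 11 codons = 33 nt shared run
    set.seed(seed + 23L)
    vB_chars <- strsplit(vA, "", fixed = TRUE)[[1L]]
    diverge <- setdiff(seq_len(protein_length), shared_aa)
    hit <- diverge[runif(length(diverge)) < 0.5]
    vB_chars[hit] <- vapply(vB_chars[hit], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1L)
    }, character(1L))
    vB <- paste(vB_chars, collapse = "")
    ntA <- back_translate(vA, seed = seed + 24L)
    ntB <- back_translate(vB, seed = seed + 25L)
    # splice the exact shared nucleotide run from A into B
    lo <- 3L * (min(shared_aa) - 1L) + 1L
    hi <- 3L * max(shared_aa)
    ntB <- paste0(substr(ntB, 1L, lo - 1L), substr(ntA, lo, hi),
                  substr(ntB, hi + 1L, nchar(ntB)))
    # seed family supports both variants symmetrically
    fam <- c(evolve_family(vA, 4L, 0.08, seed = seed + 26L),
             evolve_family(vB, 4L, 0.08, seed = seed + 27L))
    names(fam) <- paste0("r", seq_along(fam))
    refs <- c(fam, vA = vA, vB = vB)
    genes[[gene]] <- list(seed_aln = refs, refs_aln = refs,
                          planted = c(vA = vA, vB = vB))
    truth_nt <- c(nirK_vA = ntA, nirK_vB = ntB)
  } else if (name == "low_coverage") {
    gene <- "rplB"
    anc <- random_protein(protein_length, seed = seed + 31L)
    fam <- build_family(anc, 8L, 0.10, seed = seed + 32L)
    planted <- fam[1L]
    nt <- back_translate(planted, seed = seed + 33L)
    genes[[gene]] <- list(seed_aln = fam, refs_aln = fam, planted = planted)
    truth_nt <- c(rplB_v1 = unname(nt))
    coverage <- 0.5
  }

  # genomes: each planted gene embedded in random background DNA
  set.seed(seed + 1000L)
  genomes <- vapply(seq_along(truth_nt), function(i) {
    paste0(.random_dna(300L), truth_nt[i], .random_dna(300L))
  }, character(1L))
  names(genomes) <- names(truth_nt)

  sim <- generate_reads(genomes, coverage = coverage,
                        read_length = read_length,
                        error_rate = error_rate, seed = seed + 2000L)
  write_fastq(sim$reads, file.path(dir, "reads.fastq"))
  write.table(sim$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (gene in names(genes)) {
    gdir <- file.path(dir, gene)
    dir.create(gdir, showWarnings = FALSE)
    .write_aln(genes[[gene]]$seed_aln, file.path(gdir, "seed.aln"))
    .write_aln(genes[[gene]]$refs_aln, file.path(gdir, "refs.aln"))
  }
  write_fasta(truth_nt, file.path(dir, "truth_nt.fasta"))
  truth_aa <- vapply(truth_nt, translate_nt, character(1L))
  write_fasta(truth_aa, file.path(dir, "truth_aa.fasta"))

  invisible(list(name = name, dir = dir, genes = genes,
                 truth_nt = truth_nt, genomes = genomes,
                 n_reads = length(sim$reads)))
}
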