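# Post-assembly processing: quality filters, duplicate collapsing,
# complete-linkage clustering at a fixed amino-acid identity with the
# longest member as representative, split-count k-mer coverage, and
# single-copy-gene-normalised relative abundance.

#' Filter contigs on length and HMM bit score
#'
#' Exact-duplicate nucleotide sequences are collapsed first (keeping the
#' lexicographically smallest id), then contigs shorter than `min_nt`
#' nucleotides or scoring below `min_bits` bits are discarded.  Defaults
#' follow the conventional cutoffs of 300 nt and 50 bits.  Idempotent.
#'
#' @param contigs List of `contig` objects (rescored).
#' @param min_nt Minimum nucleotide length.
#' @param min_bits Minimum HMM bit score.
#' @return Filtered list of contigs.
#' @export
filter_contigs <- function(contigs, min_nt = 300L, min_bits = 50) {
  if (length(contigs) == 0L) return(contigs)
  ids <- vapply(contigs, `[[`, character(1L), "id")
  contigs <- contigs[order(ids)]
  nts <- vapply(contigs, `[[`, character(1L), "nt")
  contigs <- contigs[!duplicated(nts)]
  keep <- vapply(contigs, function(ct) {
    nchar(ct$nt) >= min_nt && ct$bits >= min_bits
  }, logical(1L))
  contigs[keep]
}

#' Pairwise amino-acid identity in model-column space
#'
#' Every contig's residues are already placed in model coordinates by
#' construction (the search emits along an HMM path), so identity needs
#' no separate aligner: it is matches over compared positions in the
#' overlap of the two model-column projections.  A column where both
#' contigs are gapped (delete states) is not compared; a gap against a
#' residue counts as a mismatch.  Contigs with no overlapping columns
#' have identity 0 by convention.
#'
#' @param a,b `contig` objects from the same gene/model.
#' @return Fraction in [0, 1].
#' @export
pairwise_aa_identity <- function(a, b) {
  lo <- max(a$span[1L], b$span[1L])
  hi <- min(a$span[2L], b$span[2L])
  if (lo > hi) return(0)
  ra <- a$aa_cols[lo:hi]
  rb <- b$aa_cols[lo:hi]
  compared <- !(is.na(ra) & is.na(rb))
  if (!any(compared)) return(0)
  same <- !is.na(ra) & !is.na(rb) & ra == rb
  sum(same) / sum(compared)
}

#' Cluster contigs at an amino-acid identity threshold
#'
#' Complete-linkage agglomeration on distance 1 - identity, cut at
#' 1 - threshold, so all pairwise member identities meet the threshold.
#' The representative is the longest member; ties break on higher bit
#' score, then lexicographic id.  Input order does not affect the result
#' (contigs are sorted by id before clustering).
#'
#' @param contigs List of `contig` objects.
#' @param threshold Identity threshold in (0, 1]; 0.99 for representative
#'   selection, 0.95 for OTUs.
#' @return List of clusters, each `list(members, representative)`.
#' @export
cluster_contigs <- function(contigs, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- length(contigs)
  if (n == 0L) return(list())
  ids <- vapply(contigs, `[[`, character(1L), "id")
  contigs <- contigs[order(ids)]
  if (n == 1L) {
    return(list(list(members = contigs, representative = contigs[[1L]])))
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 1 - pairwise_aa_identity(contigs[[i]],
                                                     contigs[[j]])
    }
  }
  hc <- hclust(as.dist(d), method = "complete")
  grp <- cutree(hc, h = 1 - threshold + 1e-9)
  lapply(sort(unique(grp)), function(g) {
    members <- contigs[grp == g]
    lens <- vapply(members, function(ct) nchar(ct$nt), integer(1L))
    bits <- vapply(members, `[[`, numeric(1L), "bits")
    mids <- vapply(members, `[[`, character(1L), "id")
    ord <- order(-lens, -bits, mids)
    list(members = members, representative = members[[ord[1L]]])
  })
}

#' Split-count k-mer coverage of contigs
#'
#' All contig k-mers are indexed in canonical form; each read k-mer
#' occurrence contributes 1/m to each of the m contigs containing that
#' k-mer, avoiding overcounting of shared regions.  A contig's coverage
#' is the mean count over its |nt| - k + 1 k-mer positions.  Also counts,
#' per gene, the reads covering at least one contig k-mer (the input to
#' relative abundance).
#'
#' @param contigs List of `contig` objects.
#' @param reads List of [seq_record] or character vector.
#' @param k K-mer length used at assembly.
#' @return List: `coverage` (data.frame contig/gene/mean coverage),
#'   `read_hits` (named vector of per-gene read counts), `total_split`
#'   and `total_matched` (conservation bookkeeping, equal by
#'   construction).
#' @export
kmer_coverage <- function(contigs, reads, k) {
  stopifnot(length(contigs) > 0L)
  ids <- vapply(contigs, `[[`, character(1L), "id")
  genes <- vapply(contigs, `[[`, character(1L), "gene")
  index <- new.env(parent = emptyenv(), size = 4096L)
  n_positions <- integer(length(contigs))
  for (i in seq_along(contigs)) {
    kms <- canonical_kmer(read_kmers(contigs[[i]]$nt, k))
    n_positions[i] <- length(kms)
    for (km in unique(kms)) {
      index[[km]] <- c(index[[km]], i)
    }
  }
  if (is.character(reads)) seqs <- reads else seqs <- record_seqs(reads)
  split_counts <- numeric(length(contigs))
  gene_read_hit <- setNames(integer(length(unique(genes))), unique(genes))
  total_matched <- 0L
  for (s in seqs) {
    kms <- canonical_kmer(read_kmers(s, k))
    hit_contigs <- integer(0)
    for (km in kms) {
      owners <- index[[km]]
      if (is.null(owners)) next
      total_matched <- total_matched + 1L
      share <- 1 / length(unique(owners))
      for (ci in unique(owners)) {
        split_counts[ci] <- split_counts[ci] + share
      }
      hit_contigs <- c(hit_contigs, owners)
    }
    if (length(hit_contigs) > 0L) {
      for (g in unique(genes[unique(hit_contigs)])) {
        gene_read_hit[g] <- gene_read_hit[g] + 1L
      }
    }
  }
  # per-position mean: each position of a duplicated kmer shares its split
  # count equally within the contig
  coverage <- numeric(length(contigs))
  for (i in seq_along(contigs)) {
    coverage[i] <- if (n_positions[i] > 0L) split_counts[i] / n_positions[i]
                   else 0
  }
  list(coverage = data.frame(id = ids, gene = genes,
                             mean_coverage = coverage,
                             n_kmer_positions = n_positions,
                             stringsAsFactors = FALSE),
       read_hits = gene_read_hit,
       total_split = sum(split_counts),
       total_matched = total_matched)
}

#' Relative gene abundance normalised by a single-copy gene
#'
#' The ratio of reads covering at least one k-mer of the gene's contigs
#' to reads covering at least one k-mer of the normaliser's contigs
#' (conventionally rplB, the single-copy ribosomal protein L2).  The
#' normaliser against itself is 1 by construction.
#'
#' @param gene_hits Read-hit count for the gene of interest.
#' @param rplb_hits Read-hit count for the normalising single-copy gene.
#' @return The abundance ratio; `NA` with a warning when the normaliser
#'   has zero hits.
#' @export
relative_abundance <- function(gene_hits, rplb_hits) {
  if (is.na(rplb_hits) || rplb_hits == 0) {
    warning("normalising gene has zero read hits; abundance undefined")
    return(NA_real_)
  }
  unname(gene_hits / rplb_hits)
}

#' Coverage-weighted OTU table
#'
#' OTUs are clusters at a fixed identity (conventionally 95% aa for
#' ordination input); each OTU's abundance in a sample is the sum of the
#' mean k-mer coverages of its member contigs, so column sums conserve
#' each sample's total weighted coverage.
#'
#' @param sample_clusters Named list (per sample) of cluster lists from
#'   [cluster_contigs].
#' @param sample_coverage Named list (per sample) of coverage data.frames
#'   from [kmer_coverage].
#' @return Matrix samples x OTUs; OTUs are labelled by representative id.
#' @export
coverage_weighted_otu_table <- function(sample_clusters, sample_coverage) {
  samples <- names(sample_clusters)
  otu_ids <- unique(unlist(lapply(sample_clusters, function(cl) {
    vapply(cl, function(x) x$representative$id, character(1L))
  })))
  m <- matrix(0, nrow = length(samples), ncol = length(otu_ids),
              dimnames = list(samples, otu_ids))
  for (s in samples) {
    cov <- sample_coverage[[s]]
    covmap <- setNames(cov$mean_coverage, cov$id)
    for (cl in sample_clusters[[s]]) {
      rid <- cl$representative$id
      ab <- sum(vapply(cl$members, function(ct) {
        v <- covmap[ct$id]
        if (is.na(v)) 0 else v
      }, numeric(1L)))
      m[s, rid] <- m[s, rid] + ab
    }
  }
  m
}
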