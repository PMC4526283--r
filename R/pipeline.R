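# Pipeline driver: wires graph building, start finding, per-gene search
# and post-processing into reproducible runs.  The `hmmasm` command-line
# script is a thin wrapper over these functions.

#' Assemble one gene from all its starting k-mers
#'
#' Runs [assemble_gene] from every starting k-mer (deduplicated), sharing
#' per-direction best-path caches across seeds, and collapses duplicate
#' nucleotide contigs.  With `kpaths > 1`, ranked alternatives from the
#' modified Yen's search are combined with the best path of the opposite
#' direction.
#'
#' @param starts Data.frame of starting k-mers for one gene
#'   (from [find_starting_kmers]).
#' @param forward_model,reverse_model The gene's models.
#' @param counter A `kmer_counter`.
#' @param min_count,prune,kpaths Search parameters.
#' @return List of `contig` objects, sorted by id.
#' @export
assemble_gene_all <- function(starts, forward_model, reverse_model, counter,
                              min_count = 1L, prune = 20L, kpaths = 1L) {
  caches <- list(right = new.env(parent = emptyenv()),
                 left = new.env(parent = emptyenv()))
  contigs <- list()
  for (i in seq_len(nrow(starts))) {
    st <- as.list(starts[i, ])
    ct <- if (kpaths > 1L) {
      assemble_gene_kpaths(st, forward_model, reverse_model, counter,
                           K = kpaths, min_count = min_count, prune = prune)
    } else {
      list(assemble_gene(st, forward_model, reverse_model, counter,
                         min_count = min_count, prune = prune,
                         caches = caches, rescore = FALSE))
    }
    contigs <- c(contigs, ct)
  }
  if (length(contigs) == 0L) return(contigs)
  ids <- vapply(contigs, `[[`, character(1L), "id")
  contigs <- contigs[order(ids)]
  nts <- vapply(contigs, `[[`, character(1L), "nt")
  contigs <- contigs[!duplicated(nts)]
  # bit scores are a function of the sequence alone: rescore once per
  # unique contig rather than once per seed
  lapply(contigs, function(ct) {
    if (is.na(ct$bits)) ct$bits <- rescore_contig(ct$aa, forward_model)
    ct
  })
}

#' Ranked contigs from one starting k-mer
#'
#' Enumerates the K best rightward paths and the K best leftward paths
#' with [k_shortest_paths]; each alternative in one direction is spliced
#' with the best path of the other, and duplicates are collapsed.  Ranks
#' follow the combined modified score.
#'
#' @inheritParams assemble_gene
#' @param K Number of ranked paths per direction.
#' @return List of `contig` objects with `rank` set.
#' @export
assemble_gene_kpaths <- function(starting, forward_model, reverse_model,
                                 counter, K = 2L, min_count = 1L,
                                 prune = 20L) {
  L <- forward_model$L
  kmer <- toupper(starting$nt_kmer)
  rights <- k_shortest_paths(forward_model, counter, kmer,
                             starting$model_column_last, "right", K = K,
                             min_count = min_count, prune = prune)
  left_col <- L - starting$model_column_first + 1L
  lefts <- k_shortest_paths(reverse_model, counter, kmer, left_col, "left",
                            K = K, min_count = min_count, prune = prune)
  combos <- list()
  for (r in seq_along(rights)) {
    combos[[length(combos) + 1L]] <- list(left = lefts[[1L]],
                                          right = rights[[r]])
  }
  if (length(lefts) > 1L) {
    for (l in 2:length(lefts)) {
      combos[[length(combos) + 1L]] <- list(left = lefts[[l]],
                                            right = rights[[1L]])
    }
  }
  contigs <- lapply(combos, function(cb) {
    .splice_contig(starting, forward_model, cb$left, cb$right,
                   score_mod = cb$left$g + cb$right$g)
  })
  scores <- vapply(contigs, `[[`, numeric(1L), "score_mod")
  contigs <- contigs[order(-scores)]
  nts <- vapply(contigs, `[[`, character(1L), "nt")
  contigs <- contigs[!duplicated(nts)]
  for (i in seq_along(contigs)) contigs[[i]]$rank <- i
  contigs
}

.read_reads <- function(dir) {
  fq <- file.path(dir, "reads.fastq")
  fa <- file.path(dir, "reads.fasta")
  if (file.exists(fq)) read_fastq(fq)
  else if (file.exists(fa)) read_fasta(fa)
  else stop("no reads.fastq or reads.fasta under ", dir)
}

.gene_dirs <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  subs[vapply(subs, function(d) file.exists(file.path(d, "seed.aln")),
              logical(1L))]
}

.load_gene_models <- function(gdir) {
  gene <- basename(gdir)
  seed <- read_alignment(file.path(gdir, "seed.aln"))
  hmm_file <- file.path(gdir, "gene.hmm")
  fwd <- if (file.exists(hmm_file)) parse_hmmer3(hmm_file)
         else build_profile_hmm(seed, name = gene)
  rev <- build_reverse_model(seed, name = gene)
  refs <- read_alignment(file.path(gdir, "refs.aln"))
  list(gene = gene, forward = fwd, reverse = rev, refs = refs)
}

#' Run the full assembly pipeline on one sample
#'
#' Input layout: `<input_dir>/reads.fastq` (or `.fasta`) plus one
#' directory per target gene containing `seed.aln` (HMM seed alignment),
#' `refs.aln` (start-finding references) and optionally `gene.hmm` (a
#' prebuilt HMMER3 model).  Stages: k-mer counter (graph) construction,
#' single-pass starting-kmer identification for all genes, per-gene
#' bidirectional A* assembly, then filtering, clustering, coverage and
#' rplB-normalised abundance.  Identical configurations produce
#' byte-identical outputs regardless of `threads`.
#'
#' @param input_dir Sample directory (fixture layout above).
#' @param out_dir Output directory.
#' @param k Nucleotide k-mer length (multiple of 3).
#' @param min_count Minimum k-mer abundance for graph membership.
#' @param prune Pruning patience; negative disables.
#' @param kpaths Paths per starting k-mer (1 = single best).
#' @param min_nt,min_bits Contig filters.
#' @param cluster_id Clustering identity for representative selection.
#' @param backend Counter backend, `"exact"` or `"bloom"`.
#' @param quality_floor Phred floor for read tail trimming (NULL skips
#'   trimming; FASTA input is never trimmed).
#' @param threads Worker processes for per-gene search.
#' @param normalizer Gene used for relative abundance (default "rplB").
#' @return Invisibly, a list: per-gene contigs, representatives, reports.
#' @export
run_pipeline <- function(input_dir, out_dir, k = 45L, min_count = 1L,
                         prune = 20L, kpaths = 1L, min_nt = 300L,
                         min_bits = 50, cluster_id = 0.99,
                         backend = "exact", quality_floor = 2L,
                         threads = 1L, normalizer = "rplB") {
  stopifnot(k %% 3L == 0L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  logline <- function(...) {
    writeLines(paste0(...), logcon)
  }
  logline("stage=config k=", k, " min_count=", min_count, " prune=", prune,
          " kpaths=", kpaths, " backend=", backend)

  reads <- .read_reads(input_dir)
  n_raw <- length(reads)
  if (!is.null(quality_floor) && !is.null(reads[[1L]]$qual)) {
    reads <- lapply(reads, quality_trim, floor = quality_floor)
  }
  lens <- vapply(reads, function(r) nchar(r$seq), integer(1L))
  n_short <- sum(lens < k)
  reads <- reads[lens >= k]       # reads shorter than k contribute no kmers
  logline("stage=reads n_raw=", n_raw, " n_discarded_short=", n_short)

  counter <- build_counter(reads, k, backend = backend)
  logline("stage=build distinct_backend=", backend,
          " total_kmer_occurrences=", counter$n_total)

  gdirs <- .gene_dirs(input_dir)
  if (length(gdirs) == 0L) stop("no gene directories (with seed.aln) under ",
                                input_dir)
  models <- lapply(gdirs, .load_gene_models)
  names(models) <- vapply(models, `[[`, character(1L), "gene")
  models <- models[order(names(models))]

  pk <- k %/% 3L
  refs <- lapply(models, `[[`, "refs")
  Ls <- vapply(models, function(m) m$forward$L, integer(1L))
  map <- build_reference_kmer_map(refs, pk, L = Ls)
  starts <- find_starting_kmers(reads, map, k)
  # starts must exist in the graph at the configured abundance
  starts <- starts[passes_min_count(counter, starts$nt_kmer, min_count), ,
                   drop = FALSE]
  logline("stage=find n_starting_kmers=", nrow(starts),
          " single_pass_over_reads=1")

  search_one <- function(gene) {
    m <- models[[gene]]
    gs <- starts[starts$gene == gene, , drop = FALSE]
    contigs <- assemble_gene_all(gs, m$forward, m$reverse, counter,
                                 min_count = min_count, prune = prune,
                                 kpaths = kpaths)
    contigs
  }
  genes <- names(models)
  contig_sets <- if (threads > 1L) {
    res <- parallel::mclapply(genes, search_one, mc.cores = threads)
    res
  } else {
    lapply(genes, search_one)
  }
  names(contig_sets) <- genes
  for (gene in genes) {
    n_open <- sum(vapply(contig_sets[[gene]], `[[`, numeric(1L), "n_opened"),
                  na.rm = TRUE)
    logline("stage=search gene=", gene,
            " n_contigs_raw=", length(contig_sets[[gene]]),
            " opened_vertices=", n_open)
  }

  results <- list()
  rep_sets <- list()
  for (gene in genes) {
    kept <- filter_contigs(contig_sets[[gene]], min_nt = min_nt,
                           min_bits = min_bits)
    clusters <- cluster_contigs(kept, threshold = cluster_id)
    reps <- lapply(clusters, `[[`, "representative")
    rep_sets[[gene]] <- reps
    logline("stage=post gene=", gene, " n_filtered=", length(kept),
            " n_clusters=", length(clusters))
    results[[gene]] <- list(contigs = contig_sets[[gene]], filtered = kept,
                            clusters = clusters, representatives = reps)
  }

  # coverage and abundance over representatives of all genes at once
  all_reps <- unlist(rep_sets, recursive = FALSE)
  cov <- NULL
  abundance <- NULL
  if (length(all_reps) > 0L) {
    cov <- kmer_coverage(all_reps, reads, k)
    hits <- cov$read_hits
    norm_hits <- if (normalizer %in% names(hits)) hits[[normalizer]] else NA
    abundance <- data.frame(
      gene = genes,
      read_hits = vapply(genes, function(g) {
        if (g %in% names(hits)) hits[[g]] else 0L
      }, integer(1L)),
      stringsAsFactors = FALSE)
    abundance$relative_abundance <- if (!is.na(norm_hits) && norm_hits > 0) {
      abundance$read_hits / norm_hits
    } else NA_real_
  }

  .write_outputs(out_dir, results, cov, abundance, logline)
  invisible(list(genes = results, coverage = cov, abundance = abundance,
                 starts = starts, out_dir = out_dir))
}

.write_outputs <- function(out_dir, results, cov, abundance, logline) {
  for (gene in names(results)) {
    res <- results[[gene]]
    reps <- res$representatives
    if (length(reps) > 0L) {
      nt <- setNames(vapply(reps, `[[`, character(1L), "nt"),
                     vapply(reps, `[[`, character(1L), "id"))
      aa <- setNames(vapply(reps, `[[`, character(1L), "aa"), names(nt))
      write_fasta(nt, file.path(out_dir, paste0(gene, "_nt.fasta")))
      write_fasta(aa, file.path(out_dir, paste0(gene, "_prot.fasta")))
    }
    rep_ids <- vapply(reps, `[[`, character(1L), "id")
    report <- data.frame(
      id = vapply(res$filtered, `[[`, character(1L), "id"),
      length_nt = vapply(res$filtered, function(x) nchar(x$nt), integer(1L)),
      bits = round(vapply(res$filtered, `[[`, numeric(1L), "bits"), 4L),
      span_first = vapply(res$filtered, function(x) x$span[1L], integer(1L)),
      span_last = vapply(res$filtered, function(x) x$span[2L], integer(1L)),
      partial = vapply(res$filtered, `[[`, logical(1L), "partial"),
      seed = vapply(res$filtered, function(x) x$seed$kmer, character(1L)),
      representative = vapply(res$filtered, function(x) x$id %in% rep_ids,
                              logical(1L)),
      stringsAsFactors = FALSE)
    write.table(report, file.path(out_dir, paste0(gene, "_contigs.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    clus <- res$clusters
    if (length(clus) > 0L) {
      cluster_df <- data.frame(
        cluster = rep(seq_along(clus),
                      vapply(clus, function(cl) length(cl$members),
                             integer(1L))),
        id = unlist(lapply(clus, function(cl) {
          vapply(cl$members, `[[`, character(1L), "id")
        })),
        representative = unlist(lapply(clus, function(cl) {
          vapply(cl$members, function(m) {
            m$id == cl$representative$id
          }, logical(1L))
        })),
        stringsAsFactors = FALSE)
      write.table(cluster_df,
                  file.path(out_dir, paste0(gene, "_clusters.tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(cov)) {
    covdf <- cov$coverage
    covdf$mean_coverage <- round(covdf$mean_coverage, 6L)
    write.table(covdf, file.path(out_dir, "coverage.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  if (!is.null(abundance)) {
    ab <- abundance
    ab$relative_abundance <- round(ab$relative_abundance, 6L)
    write.table(ab, file.path(out_dir, "abundance.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

#' Emit UCHIME inputs and ingest a chimera report
#'
#' Chimera detection itself is delegated to an external tool: this writes
#' the representative nucleotide contigs (query) alongside the reference
#' nucleotide set in the layout such tools consume, and
#' [apply_chimera_report] drops contigs a UCHIME-style tab report flags
#' (`Y` in the final column).
#'
#' @param contigs List of `contig` objects.
#' @param ref_nt Named character vector of reference nucleotide sequences.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_chimera_inputs <- function(contigs, ref_nt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- file.path(dir, "query_nt.fasta")
  r <- file.path(dir, "reference_nt.fasta")
  nt <- setNames(vapply(contigs, `[[`, character(1L), "nt"),
                 vapply(contigs, `[[`, character(1L), "id"))
  write_fasta(nt, q)
  write_fasta(ref_nt, r)
  invisible(c(query = q, reference = r))
}

#' @rdname write_chimera_inputs
#' @param report_path Tab-separated UCHIME output (query id in column 2,
#'   Y/N flag in the final column).
#' @export
apply_chimera_report <- function(contigs, report_path) {
  lines <- readLines(report_path, warn = FALSE)
  flagged <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 2L && toupper(f[length(f)]) == "Y") {
      flagged <- c(flagged, sub("^(\\S+?)(/ab=.*)?$", "\\1", f[2L]))
    }
  }
  ids <- vapply(contigs, `[[`, character(1L), "id")
  contigs[!ids %in% flagged]
}
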