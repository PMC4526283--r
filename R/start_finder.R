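# Starting-kmer identification: peptide k-mers of aligned references are
# hashed; reads are translated in all six frames and scanned for exact
# peptide matches, each of which anchors a search at a known model column.

#' Build the reference peptide-kmer map
#'
#' For every reference sequence and every window of `peptide_k`
#' consecutive non-gap residues occupying consecutive match columns, the
#' peptide is mapped to its gene and the match column of its first
#' residue.  Windows interrupted by insert-column residues (or spanning a
#' gap) are skipped.  Multiple genes share a single map so that starts for
#' all genes are found in one pass over the reads.
#'
#' @param refs Named list: one `msa` of aligned references per gene.
#'   References must be aligned in the column space of the gene's model.
#' @param peptide_k Peptide k-mer length (nucleotide k / 3).
#' @param match_cols Optional named list of match-column indices per gene
#'   (defaults to the gap-fraction rule used by [build_profile_hmm]).
#' @param L Optional named vector of model lengths for consistency checks.
#' @param symfrac Gap-fraction threshold for the default match-column rule.
#' @return A `ref_kmer_map` object.
#' @export
build_reference_kmer_map <- function(refs, peptide_k, match_cols = NULL,
                                     L = NULL, symfrac = 0.5) {
  stopifnot(peptide_k >= 1L)
  env <- new.env(parent = emptyenv(), size = 4096L)
  genes <- names(refs)
  if (is.null(genes)) stop("refs must be a named list (one msa per gene)")
  for (gene in genes) {
    aln <- refs[[gene]]
    seqs <- toupper(record_seqs(aln$records))
    nc <- aln$n_columns
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(seqs), ncol = nc, byrow = TRUE)
    mc <- if (!is.null(match_cols[[gene]])) match_cols[[gene]]
          else which(colMeans(.is_gap(chars)) < symfrac)
    if (!is.null(L) && !is.na(L[gene]) && length(mc) != L[gene]) {
      stop("reference alignment for gene '", gene, "' implies ", length(mc),
           " match columns but the model has L = ", L[gene])
    }
    is_mc <- logical(nc); is_mc[mc] <- TRUE
    mc_index <- cumsum(is_mc)
    for (s in seq_len(nrow(chars))) {
      row <- chars[s, ]
      resid <- which(!.is_gap(row))
      if (length(resid) < peptide_k) next
      in_match <- is_mc[resid]
      mcols <- mc_index[resid]               # match index (valid where in_match)
      n <- length(resid)
      for (i in seq_len(n - peptide_k + 1L)) {
        win <- i:(i + peptide_k - 1L)
        if (!all(in_match[win])) next        # residue in an insert column
        cols <- mcols[win]
        if (any(diff(cols) != 1L)) next      # non-consecutive match columns
        pep <- paste(row[resid[win]], collapse = "")
        if (grepl("[^A-Z]", pep) || grepl("[BJOUXZ*]", pep)) next
        hit <- list(gene = gene, col = cols[1L])
        cur <- env[[pep]]
        if (is.null(cur)) {
          env[[pep]] <- list(hit)
        } else if (!any(vapply(cur, function(h) {
          h$gene == gene && h$col == cols[1L]
        }, logical(1L)))) {
          env[[pep]] <- c(cur, list(hit))
        }
      }
    }
  }
  structure(list(peptide_k = peptide_k, env = env,
                 n_peptides = length(ls(env))), class = "ref_kmer_map")
}

#' @export
print.ref_kmer_map <- function(x, ...) {
  cat(sprintf("<ref_kmer_map: %d peptide %d-mers>\n", x$n_peptides,
              x$peptide_k))
  invisible(x)
}

#' Find starting k-mers in reads
#'
#' Each read is translated in all six frames; every window whose
#' translation exactly matches a reference peptide k-mer yields a starting
#' k-mer.  The nucleotide k-mer is reported on the coding strand, so a
#' read and its reverse complement yield identical starts.  Results are
#' deduplicated on (k-mer, gene, first model column) and returned in a
#' deterministic order.  Frames containing a stop codon inside the window
#' produce no hit.
#'
#' @param reads List of [seq_record] or character vector of sequences.
#' @param map A `ref_kmer_map`.
#' @param nucleotide_k Nucleotide k-mer length (3 x peptide_k).
#' @return A data.frame with columns `nt_kmer`, `gene`,
#'   `model_column_first`, `model_column_last`, `frame`, `read_id`.
#' @export
find_starting_kmers <- function(reads, map, nucleotide_k) {
  pk <- map$peptide_k
  stopifnot(nucleotide_k == 3L * pk)
  if (is.character(reads)) {
    ids <- names(reads) %||% as.character(seq_along(reads))
    seqs <- unname(reads)
  } else {
    ids <- record_ids(reads); seqs <- record_seqs(reads)
  }
  env <- map$env
  out <- list(); nout <- 0L
  for (ri in seq_along(seqs)) {
    s <- toupper(seqs[ri])
    rc <- reverse_complement(s)
    n <- nchar(s)
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      src <- if (fr > 0L) s else rc
      off <- abs(fr)
      len <- ((n - off + 1L) %/% 3L) * 3L
      if (len < nucleotide_k) next
      frame_nt <- substr(src, off, off + len - 1L)
      pep <- translate_nt(frame_nt)
      np <- nchar(pep)
      if (np < pk) next
      windows <- substring(pep, 1:(np - pk + 1L), pk:np)
      for (wi in seq_along(windows)) {
        w <- windows[wi]
        hits <- env[[w]]
        if (is.null(hits)) next
        nt <- substr(frame_nt, 3L * (wi - 1L) + 1L,
                     3L * (wi - 1L) + nucleotide_k)
        for (h in hits) {
          nout <- nout + 1L
          out[[nout]] <- list(nt_kmer = nt, gene = h$gene,
                              model_column_first = as.integer(h$col),
                              model_column_last = as.integer(h$col + pk - 1L),
                              frame = fr, read_id = ids[ri])
        }
      }
    }
  }
  if (nout == 0L) {
    return(data.frame(nt_kmer = character(0), gene = character(0),
                      model_column_first = integer(0),
                      model_column_last = integer(0),
                      frame = integer(0), read_id = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    nt_kmer = vapply(out, `[[`, character(1L), "nt_kmer"),
    gene = vapply(out, `[[`, character(1L), "gene"),
    model_column_first = vapply(out, `[[`, integer(1L), "model_column_first"),
    model_column_last = vapply(out, `[[`, integer(1L), "model_column_last"),
    frame = vapply(out, `[[`, integer(1L), "frame"),
    read_id = vapply(out, `[[`, character(1L), "read_id"),
    stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("nt_kmer", "gene", "model_column_first")])
  df <- df[!dup, , drop = FALSE]
  df <- df[order(df$gene, df$model_column_first, df$nt_kmer), , drop = FALSE]
  rownames(df) <- NULL
  df
}
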