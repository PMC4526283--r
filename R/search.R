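# The core assembler: lazy construction of the combined assembly graph
# (k-mer x HMM-state product) and A* best-path search over it, with the
# path-pruning rule, best-path caching, and bidirectional contig assembly.

.vkey <- function(kmer, col, state) paste0(kmer, "|", col, "|", state)

#' Successor vertices in the combined assembly graph
#'
#' A vertex pairs a de Bruijn k-mer with an HMM state (match/insert/delete
#' at a model column).  Match and insert successors require a codon step
#' in the k-mer graph (three single-nucleotide steps, each present at the
#' abundance cutoff) and emit the translated codon; delete successors keep
#' the k-mer and advance the column.  Stop-codon emissions are excluded:
#' paths never read through stops.
#'
#' @param model A `profile_hmm` (the reversed model for leftward search).
#' @param counter A `kmer_counter`.
#' @param kmer,col,state The vertex: k-mer string, model column, state
#'   ("M", "I" or "D").
#' @param direction `"right"` (append codons) or `"left"` (prepend).
#' @param min_count Minimum k-mer abundance for graph membership.
#' @return A list of parallel vectors `kmer`, `col`, `state`, `codon`,
#'   `aa`, `w_mod`, `w_raw` (possibly empty).
#' @export
cag_successors <- function(model, counter, kmer, col, state,
                           direction = "right", min_count = 1L) {
  L <- model$L
  lt <- model$log_trans
  r <- col + 1L
  out_kmer <- character(0); out_col <- integer(0); out_state <- character(0)
  out_codon <- character(0); out_aa <- character(0)
  out_mod <- numeric(0); out_raw <- numeric(0)

  if (col < L) {
    cn <- codon_neighbors(counter, kmer, direction, min_count)
    if (length(cn$kmer) > 0L) {
      aa <- translate_codons(cn$codon)
      ok <- aa %in% AA_ALPHABET
      if (any(ok)) {
        aak <- aa[ok]; kk <- cn$kmer[ok]; cc <- cn$codon[ok]
        # match successors at column col+1
        wr <- lt[r, paste0(state, "M")] + model$elo[col + 1L, aak]
        out_kmer <- c(out_kmer, kk)
        out_col <- c(out_col, rep(col + 1L, length(kk)))
        out_state <- c(out_state, rep("M", length(kk)))
        out_codon <- c(out_codon, cc); out_aa <- c(out_aa, aak)
        out_raw <- c(out_raw, wr)
        out_mod <- c(out_mod, wr - model$cmax[col + 1L])
        # insert successors at column col (no D->I transition)
        if (state != "D") {
          wi <- rep(lt[r, paste0(state, "I")], length(kk))
          out_kmer <- c(out_kmer, kk)
          out_col <- c(out_col, rep(col, length(kk)))
          out_state <- c(out_state, rep("I", length(kk)))
          out_codon <- c(out_codon, cc); out_aa <- c(out_aa, aak)
          out_raw <- c(out_raw, wi)
          out_mod <- c(out_mod, wi)
        }
      }
    }
    # delete successor at column col+1 (no I->D transition); kmer carried
    if (state != "I") {
      wd <- lt[r, paste0(state, "D")]
      out_kmer <- c(out_kmer, kmer)
      out_col <- c(out_col, col + 1L)
      out_state <- c(out_state, "D")
      out_codon <- c(out_codon, NA_character_)
      out_aa <- c(out_aa, NA_character_)
      out_raw <- c(out_raw, wd)
      out_mod <- c(out_mod, wd - model$cmax[col + 1L])
    }
  }
  list(kmer = out_kmer, col = out_col, state = out_state,
       codon = out_codon, aa = out_aa, w_mod = out_mod, w_raw = out_raw)
}

.ns_new <- function(cap = 512L) {
  ns <- new.env(parent = emptyenv())
  ns$kmer <- character(cap); ns$col <- integer(cap); ns$state <- character(cap)
  ns$codon <- character(cap); ns$aa <- character(cap)
  ns$parent <- integer(cap); ns$g <- numeric(cap); ns$raw <- numeric(cap)
  ns$steps <- integer(cap); ns$bestraw <- numeric(cap); ns$bestnode <- integer(cap)
  ns$vkey <- character(cap)
  ns$n <- 0L
  ns
}

.ns_add <- function(ns, kmer, col, state, codon, aa, parent, g, raw,
                    steps, bestraw, bestnode, vkey) {
  n <- ns$n + 1L
  if (n > length(ns$kmer)) {
    grow <- length(ns$kmer)
    ns$kmer <- c(ns$kmer, character(grow)); ns$col <- c(ns$col, integer(grow))
    ns$state <- c(ns$state, character(grow)); ns$codon <- c(ns$codon, character(grow))
    ns$aa <- c(ns$aa, character(grow)); ns$parent <- c(ns$parent, integer(grow))
    ns$g <- c(ns$g, numeric(grow)); ns$raw <- c(ns$raw, numeric(grow))
    ns$steps <- c(ns$steps, integer(grow)); ns$bestraw <- c(ns$bestraw, numeric(grow))
    ns$bestnode <- c(ns$bestnode, integer(grow)); ns$vkey <- c(ns$vkey, character(grow))
  }
  ns$kmer[n] <- kmer; ns$col[n] <- col; ns$state[n] <- state
  ns$codon[n] <- codon; ns$aa[n] <- aa; ns$parent[n] <- parent
  ns$g[n] <- g; ns$raw[n] <- raw; ns$steps[n] <- steps
  ns$bestraw[n] <- bestraw; ns$bestnode[n] <- bestnode; ns$vkey[n] <- vkey
  ns$n <- n
  n
}

.reconstruct <- function(ns, id) {
  idx <- integer(0)
  while (id != 0L) { idx <- c(id, idx); id <- ns$parent[id] }
  data.frame(kmer = ns$kmer[idx], col = ns$col[idx], state = ns$state[idx],
             codon = ns$codon[idx], aa = ns$aa[idx],
             stringsAsFactors = FALSE)
}

#' A* best-path search through the combined assembly graph
#'
#' Starts at a (k-mer, match-column) vertex and searches toward the model
#' end under the modified (monotone) weights, guided by the admissible
#' all-match completion heuristic.  Goal vertices are the terminal-column
#' match and delete states.  A popped vertex whose raw HMM score has not
#' improved within `prune` openings along its path is discarded.  When a
#' best-path cache is supplied, a vertex lying on a previously returned
#' best path opens only the next cached vertex.  If the open set is
#' exhausted before the goal, the path to the highest-raw-score vertex
#' seen is returned and flagged partial.  Ties in the open set break on
#' (f, then raw score, then insertion order), so results are deterministic.
#'
#' @inheritParams cag_successors
#' @param start_kmer Starting k-mer (must pass `min_count`).
#' @param start_col Its model column (of the k-mer's last residue for
#'   rightward search; mirrored column for leftward).
#' @param prune Pruning patience in openings; negative disables.
#' @param cache Optional environment holding cached best-path suffixes
#'   (shared across searches of one gene/direction).
#' @param banned_edges Optional environment/set of edge keys to exclude
#'   (used by the K-shortest-path spur searches).
#' @param banned_vertices Optional environment/set of vertex keys to
#'   exclude.
#' @return A list: `found`, `partial`, `path` (data.frame of vertices from
#'   the start, with emitted codons), `g` (modified score), `raw` (nats),
#'   `n_opened`.
#' @export
astar_search <- function(model, counter, start_kmer, start_col,
                         direction = c("right", "left"), min_count = 1L,
                         prune = 20L, cache = NULL,
                         banned_edges = NULL, banned_vertices = NULL,
                         start_state = "M") {
  direction <- match.arg(direction)
  L <- model$L
  start_kmer <- toupper(start_kmer)
  if (!passes_min_count(counter, start_kmer, min_count)) {
    stop("starting kmer not in the graph at min_count=", min_count, ": ",
         start_kmer)
  }
  stopifnot(start_col >= 1L, start_col <= L, start_state %in% c("M", "I", "D"))

  ns <- .ns_new()
  skey <- .vkey(start_kmer, start_col, start_state)
  sid <- .ns_add(ns, start_kmer, start_col, start_state, NA_character_,
                 NA_character_, 0L, 0, 0, 0L, 0, 0L, skey)
  ns$bestnode[sid] <- sid

  if (start_col == L && start_state %in% c("M", "D")) {
    return(list(found = TRUE, partial = FALSE, path = .reconstruct(ns, sid),
                g = 0, raw = 0, n_opened = 0L))
  }

  # fast path: a start vertex already on a cached best path is followed
  # straight to the goal without touching the open set
  if (!is.null(cache) && is.null(banned_edges) && is.null(banned_vertices) &&
      !is.null(cache[[skey]])) {
    res <- .follow_cache(model, cache, start_kmer, start_col, start_state)
    if (!is.null(res)) return(res)
  }

  open <- heap_new()
  closed <- new.env(parent = emptyenv(), size = 1024L)
  pushseq <- 1L
  heap_push(open, sid, model$heuristic[start_state, start_col + 1L], 0,
            pushseq)
  best_raw_global <- 0
  best_node_global <- sid
  n_opened <- 0L
  lt <- model$log_trans

  while (!heap_empty(open)) {
    id <- heap_pop(open)
    nkey <- ns$vkey[id]
    cg <- closed[[nkey]]
    if (!is.null(cg) && cg >= ns$g[id]) next      # stale or dominated entry
    col <- ns$col[id]; st <- ns$state[id]
    if (col == L && (st == "M" || st == "D")) {
      return(list(found = TRUE, partial = FALSE, path = .reconstruct(ns, id),
                  g = ns$g[id], raw = ns$raw[id], n_opened = n_opened))
    }
    if (prune >= 0L && ns$steps[id] > prune) next # pruned, not expanded
    closed[[nkey]] <- ns$g[id]
    n_opened <- n_opened + 1L
    if (ns$raw[id] > best_raw_global) {
      best_raw_global <- ns$raw[id]
      best_node_global <- id
    }

    kmer <- ns$kmer[id]
    cached <- if (!is.null(cache)) cache[[nkey]] else NULL
    if (!is.null(cached)) {
      # follow the cached best path: open only its next vertex
      tn <- paste0(st, cached$state)
      wr <- lt[col + 1L, tn]
      if (cached$state == "M") wr <- wr + model$elo[cached$col, cached$aa]
      wm <- if (cached$state %in% c("M", "D")) wr - model$cmax[cached$col]
            else wr
      succ <- list(kmer = cached$kmer, col = cached$col, state = cached$state,
                   codon = cached$codon, aa = cached$aa,
                   w_mod = wm, w_raw = wr)
    } else {
      succ <- cag_successors(model, counter, kmer, col, st, direction,
                             min_count)
    }
    nsucc <- length(succ$kmer)
    if (nsucc == 0L) next
    for (s in seq_len(nsucc)) {
      ckey <- .vkey(succ$kmer[s], succ$col[s], succ$state[s])
      if (!is.null(banned_vertices) && !is.null(banned_vertices[[ckey]])) next
      if (!is.null(banned_edges) &&
          !is.null(banned_edges[[paste0(nkey, ">", ckey)]])) next
      g2 <- ns$g[id] + succ$w_mod[s]
      if (!is.finite(g2)) next
      prev <- closed[[ckey]]
      if (!is.null(prev) && prev >= g2) next
      raw2 <- ns$raw[id] + succ$w_raw[s]
      if (raw2 > ns$bestraw[id]) {
        steps2 <- 0L; bestraw2 <- raw2; bestnode2 <- 0L   # fixed after add
      } else {
        steps2 <- ns$steps[id] + 1L
        bestraw2 <- ns$bestraw[id]; bestnode2 <- ns$bestnode[id]
      }
      f2 <- g2 + model$heuristic[succ$state[s], succ$col[s] + 1L]
      if (!is.finite(f2)) next
      cid <- .ns_add(ns, succ$kmer[s], succ$col[s], succ$state[s],
                     succ$codon[s], succ$aa[s], id, g2, raw2,
                     steps2, bestraw2, bestnode2, ckey)
      if (steps2 == 0L) ns$bestnode[cid] <- cid
      pushseq <- pushseq + 1L
      heap_push(open, cid, f2, raw2, pushseq)
    }
  }
  # exhausted: return the path to the best intermediate vertex w_m
  list(found = FALSE, partial = TRUE,
       path = .reconstruct(ns, best_node_global),
       g = ns$g[best_node_global], raw = ns$raw[best_node_global],
       n_opened = n_opened)
}

# Walk a cached best-path suffix from a start vertex to the goal,
# accumulating modified and raw weights.  Returns NULL if the chain is
# broken (then the normal search runs).
.follow_cache <- function(model, cache, kmer, col, state) {
  L <- model$L
  lt <- model$log_trans
  kmers <- kmer; cols <- col; states <- state
  codons <- NA_character_; aas <- NA_character_
  g <- 0; raw <- 0
  repeat {
    key <- .vkey(kmer, col, state)
    nxt <- cache[[key]]
    if (is.null(nxt)) {
      if (col == L && state %in% c("M", "D")) break
      return(NULL)
    }
    tn <- paste0(state, nxt$state)
    wr <- lt[col + 1L, tn]
    if (nxt$state == "M") wr <- wr + model$elo[nxt$col, nxt$aa]
    wm <- if (nxt$state %in% c("M", "D")) wr - model$cmax[nxt$col] else wr
    g <- g + wm; raw <- raw + wr
    kmers <- c(kmers, nxt$kmer); cols <- c(cols, nxt$col)
    states <- c(states, nxt$state); codons <- c(codons, nxt$codon)
    aas <- c(aas, nxt$aa)
    kmer <- nxt$kmer; col <- nxt$col; state <- nxt$state
  }
  list(found = TRUE, partial = FALSE,
       path = data.frame(kmer = kmers, col = cols, state = states,
                         codon = codons, aa = aas, stringsAsFactors = FALSE),
       g = g, raw = raw, n_opened = length(kmers) - 1L)
}

# Record the suffix of a completed best path in the cache.
.cache_update <- function(cache, result) {
  if (is.null(cache) || !result$found) return(invisible(NULL))
  p <- result$path
  n <- nrow(p)
  if (n < 2L) return(invisible(NULL))
  for (i in seq_len(n - 1L)) {
    key <- .vkey(p$kmer[i], p$col[i], p$state[i])
    if (is.null(cache[[key]])) {
      cache[[key]] <- list(kmer = p$kmer[i + 1L], col = p$col[i + 1L],
                           state = p$state[i + 1L], codon = p$codon[i + 1L],
                           aa = p$aa[i + 1L])
    }
  }
  invisible(NULL)
}

.path_codons <- function(path) {
  cds <- path$codon[!is.na(path$codon)]
  cds
}

#' Assemble one contig from a starting k-mer
#'
#' Runs the rightward A* search under the forward model from the seed's
#' last match column, the leftward search under the column-reversed model
#' from the mirrored first column (forward column j maps to reversed
#' column L - j + 1), and splices reversed-left emissions, the seed k-mer,
#' and right emissions into one nucleotide contig.  The HMM bit score is
#' recomputed from the unmodified weights by a deterministic rescoring
#' pass over the translated contig ([rescore_contig]).
#'
#' @param starting A starting-kmer record from [find_starting_kmers].
#' @param forward_model,reverse_model The gene's forward and
#'   column-reversed `profile_hmm`s.
#' @param counter A `kmer_counter`.
#' @param min_count Minimum k-mer abundance.
#' @param prune Pruning patience (negative disables).
#' @param caches Optional `list(right = env, left = env)` of best-path
#'   caches, updated in place.
#' @return A `contig` object (list: `gene`, `id`, `nt`, `aa`, `bits`,
#'   `span`, `partial`, `seed`, `aa_cols`, `score_mod`, `score_raw`,
#'   `n_opened`), or `NULL` when both directions fail to extend and the
#'   seed alone is shorter than a codon step.
#' @export
assemble_gene <- function(starting, forward_model, reverse_model, counter,
                          min_count = 1L, prune = 20L, caches = NULL,
                          rescore = TRUE) {
  L <- forward_model$L
  stopifnot(reverse_model$L == L)
  kmer <- toupper(starting$nt_kmer)
  pk <- nchar(kmer) %/% 3L

  right <- astar_search(forward_model, counter, kmer,
                        starting$model_column_last, "right",
                        min_count = min_count, prune = prune,
                        cache = caches$right)
  left_col <- L - starting$model_column_first + 1L
  left <- astar_search(reverse_model, counter, kmer, left_col, "left",
                       min_count = min_count, prune = prune,
                       cache = caches$left)
  .cache_update(caches$right, right)
  .cache_update(caches$left, left)

  .splice_contig(starting, forward_model, left, right,
                 score_mod = left$g + right$g, rescore = rescore)
}

# Combine a left and a right search result into a contig.
.splice_contig <- function(starting, forward_model, left, right, score_mod,
                           rank = 1L, rescore = TRUE) {
  L <- forward_model$L
  kmer <- toupper(starting$nt_kmer)
  pk <- nchar(kmer) %/% 3L
  left_codons <- rev(.path_codons(left$path))    # prepended; restore order
  right_codons <- .path_codons(right$path)
  nt <- paste0(paste(left_codons, collapse = ""), kmer,
               paste(right_codons, collapse = ""))
  aa <- translate_nt(nt)

  # model-column projection of the amino acids (match states only)
  aa_cols <- rep(NA_character_, L)
  seed_aa <- strsplit(translate_nt(kmer), "", fixed = TRUE)[[1L]]
  seed_cols <- starting$model_column_first:starting$model_column_last
  aa_cols[seed_cols] <- seed_aa
  rp <- right$path
  rm <- which(rp$state == "M" & !is.na(rp$aa))
  aa_cols[rp$col[rm]] <- rp$aa[rm]
  lp <- left$path
  lm <- which(lp$state == "M" & !is.na(lp$aa))
  aa_cols[L - lp$col[lm] + 1L] <- lp$aa[lm]

  right_cols <- rp$col[rp$state %in% c("M", "D")]
  left_cols <- L - lp$col[lp$state %in% c("M", "D")] + 1L
  span <- range(c(seed_cols, right_cols, left_cols))

  bits <- if (rescore) rescore_contig(aa, forward_model) else NA_real_
  structure(list(
    gene = starting$gene,
    id = paste0(starting$gene, "_", kmer, "_", starting$model_column_first),
    nt = nt, aa = aa, bits = bits,
    span = span, partial = left$partial || right$partial,
    seed = list(kmer = kmer, first = starting$model_column_first,
                last = starting$model_column_last),
    aa_cols = aa_cols, score_mod = score_mod,
    score_raw = left$raw + right$raw,
    n_opened = left$n_opened + right$n_opened,
    rank = rank), class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig %s: %d nt, %.1f bits, columns %d-%d%s>\n",
              x$id, nchar(x$nt), x$bits, x$span[1], x$span[2],
              if (x$partial) ", partial" else ""))
  invisible(x)
}

#' HMM bit score of a contig from the unmodified weights
#'
#' Deterministic rescoring pass: a Viterbi alignment of the translated
#' contig to the forward model under the raw (unmodified) weights, with
#' model-local entry (the first residue may sit at any column j, charged
#' the M_{j-1} -> M_j transition) and free exit.  Being a function of the
#' sequence alone, the score is invariant to which seed produced the
#' contig.
#'
#' @param x A `contig` or an amino-acid string (no internal stops).
#' @param model The forward `profile_hmm`.
#' @return Bit score (log2-odds versus the background null model).
#' @export
rescore_contig <- function(x, model) {
  aa <- if (inherits(x, "contig")) x$aa else x
  res <- strsplit(aa, "", fixed = TRUE)[[1L]]
  if (any(res == "*")) stop("contig contains an internal stop codon")
  n <- length(res)
  if (n == 0L) return(0)
  L <- model$L
  lt <- model$log_trans
  elo <- model$elo
  eres <- vapply(res, function(a) {
    if (a %in% AA_ALPHABET) elo[, a] else rep(-Inf, L)
  }, numeric(L))                               # L x n

  entry <- lt[seq_len(L), "MM"]                # t(M_{j-1} -> M_j)
  VM <- entry + eres[, 1L]
  VI <- rep(-Inf, L)
  VD <- rep(-Inf, L)
  # deletes reachable before consuming further residues
  for (j in seq_len(L - 1L)) {
    VD[j + 1L] <- max(VD[j + 1L], VM[j] + lt[j + 1L, "MD"],
                      VD[j] + lt[j + 1L, "DD"])
  }
  if (n >= 2L) {
    for (i in 2:n) {
      VI2 <- pmax(VM + lt[2:(L + 1L), "MI"], VI + lt[2:(L + 1L), "II"])
      VM2 <- rep(-Inf, L)
      prevM <- c(-Inf, VM[-L]); prevI <- c(-Inf, VI[-L]); prevD <- c(-Inf, VD[-L])
      tMM <- lt[seq_len(L), "MM"]; tIM <- lt[seq_len(L), "IM"]
      tDM <- lt[seq_len(L), "DM"]
      VM2 <- pmax(prevM + tMM, prevI + tIM, prevD + tDM) + eres[, i]
      VD2 <- rep(-Inf, L)
      for (j in seq_len(L - 1L)) {
        VD2[j + 1L] <- max(VM2[j] + lt[j + 1L, "MD"],
                           VD2[j] + lt[j + 1L, "DD"])
      }
      VM <- VM2; VI <- VI2; VD <- VD2
    }
  }
  bit_score(max(VM))
}
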