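# Modified Yen's K-shortest-path enumeration over the combined assembly
# graph, for exploring microheterogeneity from a single starting vertex.
#
# Deviations from textbook Yen: (i) Lawler's speedup — spur only at or
# after the point where a path branched from its parent; (ii) a candidate
# is ranked only if it contains at least one edge absent from all
# lower-rank paths (avoiding a combinatorial explosion of minor
# variants); (iii) a completed candidate whose nucleotide k-mer set adds
# nothing to the union over ranked paths is discarded without consuming a
# rank, so every returned path carries new sequence information.
# Rejected candidates still seed further spur searches, so enumeration
# order matches brute force.

.path_vkeys <- function(path) .vkey(path$kmer, path$col, path$state)

.path_edges <- function(path) {
  vk <- .path_vkeys(path)
  n <- length(vk)
  if (n < 2L) return(character(0))
  paste0(vk[-n], ">", vk[-1L])
}

# cumulative modified / raw scores along a path, recomputed from the model
.path_scores <- function(model, path) {
  n <- nrow(path)
  g <- numeric(n); raw <- numeric(n)
  lt <- model$log_trans
  for (i in seq_len(n - 1L)) {
    tn <- paste0(path$state[i], path$state[i + 1L])
    wr <- lt[path$col[i] + 1L, tn]
    if (path$state[i + 1L] == "M") {
      wr <- wr + model$elo[path$col[i + 1L], path$aa[i + 1L]]
    }
    wm <- if (path$state[i + 1L] %in% c("M", "D")) {
      wr - model$cmax[path$col[i + 1L]]
    } else wr
    g[i + 1L] <- g[i] + wm
    raw[i + 1L] <- raw[i] + wr
  }
  list(g = g, raw = raw)
}

#' K best paths from one starting vertex
#'
#' Rank 1 is the plain A* best path.  Subsequent ranks come from Yen-style
#' spur searches off already-enumerated paths (best-path caching is
#' disabled during spurs so alternatives are not biased), subject to the
#' new-edge and new-kmer constraints described above.  Fewer than `K`
#' paths is a normal return when candidates are exhausted.
#'
#' @inheritParams astar_search
#' @param K Number of ranked paths requested.
#' @param max_spur_attempts Guard on the total number of spur searches
#'   (default `100 * K`).
#' @return List of ranked results; each is an [astar_search] result plus
#'   `rank`.
#' @export
k_shortest_paths <- function(model, counter, start_kmer, start_col,
                             direction = c("right", "left"), K = 1L,
                             min_count = 1L, prune = 20L,
                             max_spur_attempts = 100L * K) {
  direction <- match.arg(direction)
  stopifnot(K >= 1L)
  best <- astar_search(model, counter, start_kmer, start_col, direction,
                       min_count = min_count, prune = prune)
  best$rank <- 1L
  if (!best$found || K == 1L) return(list(best))

  accepted <- list(best)
  accepted_edges <- new.env(parent = emptyenv())
  for (e in .path_edges(best$path)) accepted_edges[[e]] <- TRUE
  accepted_kmers <- new.env(parent = emptyenv())
  for (km in unique(best$path$kmer)) accepted_kmers[[km]] <- TRUE

  processed <- list(list(path = best$path, branch = 1L,
                         scores = .path_scores(model, best$path)))
  seen_keys <- new.env(parent = emptyenv())
  seen_keys[[paste(.path_vkeys(best$path), collapse = " ")]] <- TRUE

  candidates <- list()     # each: path, g, raw, branch, key
  attempts <- 0L

  gen_spurs <- function(entry) {
    p <- entry$path
    vk <- .path_vkeys(p)
    n <- nrow(p)
    if (n < 2L || entry$branch > n - 1L) return(invisible(NULL))
    for (j in seq.int(entry$branch, n - 1L)) {
      if (attempts >= max_spur_attempts) return(invisible(NULL))
      banned_edges <- new.env(parent = emptyenv())
      for (q in processed) {
        qv <- .path_vkeys(q$path)
        if (length(qv) > j && identical(qv[seq_len(j)], vk[seq_len(j)])) {
          banned_edges[[paste0(qv[j], ">", qv[j + 1L])]] <- TRUE
        }
      }
      banned_vertices <- NULL
      if (j > 1L) {
        banned_vertices <- new.env(parent = emptyenv())
        for (v in vk[seq_len(j - 1L)]) banned_vertices[[v]] <- TRUE
      }
      attempts <<- attempts + 1L
      spur <- astar_search(model, counter, p$kmer[j], p$col[j], direction,
                           min_count = min_count, prune = prune,
                           banned_edges = banned_edges,
                           banned_vertices = banned_vertices,
                           start_state = p$state[j])
      if (!spur$found) next
      cand_path <- rbind(p[seq_len(j), , drop = FALSE],
                         spur$path[-1L, , drop = FALSE])
      rownames(cand_path) <- NULL
      key <- paste(.path_vkeys(cand_path), collapse = " ")
      if (!is.null(seen_keys[[key]])) next
      seen_keys[[key]] <- TRUE
      candidates[[length(candidates) + 1L]] <<- list(
        path = cand_path,
        g = entry$scores$g[j] + spur$g,
        raw = entry$scores$raw[j] + spur$raw,
        branch = j, key = key)
    }
    invisible(NULL)
  }

  gen_spurs(processed[[1L]])

  while (length(accepted) < K && length(candidates) > 0L &&
         attempts < max_spur_attempts) {
    gs <- vapply(candidates, `[[`, numeric(1L), "g")
    raws <- vapply(candidates, `[[`, numeric(1L), "raw")
    keys <- vapply(candidates, `[[`, character(1L), "key")
    ord <- order(-gs, -raws, keys)
    ci <- ord[1L]
    cand <- candidates[[ci]]
    candidates <- candidates[-ci]

    entry <- list(path = cand$path, branch = cand$branch,
                  scores = .path_scores(model, cand$path))
    processed[[length(processed) + 1L]] <- entry

    edges <- .path_edges(cand$path)
    has_new_edge <- any(vapply(edges, function(e) {
      is.null(accepted_edges[[e]])
    }, logical(1L)))
    kms <- unique(cand$path$kmer)
    has_new_kmer <- any(vapply(kms, function(km) {
      is.null(accepted_kmers[[km]])
    }, logical(1L)))

    if (has_new_edge && has_new_kmer) {
      res <- list(found = TRUE, partial = FALSE, path = cand$path,
                  g = cand$g, raw = cand$raw, n_opened = NA_integer_,
                  rank = length(accepted) + 1L)
      accepted[[length(accepted) + 1L]] <- res
      for (e in edges) accepted_edges[[e]] <- TRUE
      for (km in kms) accepted_kmers[[km]] <- TRUE
    }
    gen_spurs(entry)
  }
  accepted
}
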