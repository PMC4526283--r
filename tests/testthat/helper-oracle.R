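# Independent oracles for the search modules.  These deliberately avoid
# the package's successor/weight/search code paths: weights come straight
# from the model's probability tables, codon steps are re-derived from
# three explicit single-nucleotide membership queries, and path
# enumeration is a depth-first walk over simple paths.

oracle_aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# genetic code for the oracle, from Biostrings directly
oracle_codon_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

# single-nucleotide step: does shifting the window by `base` stay in the
# graph?  (right: drop first char, append; left: drop last, prepend)
oracle_step1 <- function(counter, kmer, base, direction) {
  k <- nchar(kmer)
  cand <- if (direction == "right") paste0(substr(kmer, 2L, k), base)
          else paste0(base, substr(kmer, 1L, k - 1L))
  if (kmer_count(counter, cand) >= 1L) cand else NULL
}

# brute-force codon step over all 64 codons via three single steps
# (memoised per call tree; memoisation does not change the logic)
oracle_codon_steps <- function(counter, kmer, direction, memo = NULL) {
  if (!is.null(memo)) {
    key <- paste0(kmer, "@", direction)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
  }
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (b1 in bases) {
    s1 <- oracle_step1(counter, kmer, b1, direction)
    if (is.null(s1)) next
    for (b2 in bases) {
      s2 <- oracle_step1(counter, s1, b2, direction)
      if (is.null(s2)) next
      for (b3 in bases) {
        s3 <- oracle_step1(counter, s2, b3, direction)
        if (is.null(s3)) next
        codon <- if (direction == "right") paste0(b1, b2, b3)
                 else paste0(b3, b2, b1)
        out[[length(out) + 1L]] <- list(kmer = s3, codon = codon)
      }
    }
  }
  if (!is.null(memo)) memo[[key]] <- out
  out
}

# raw and modified weight of one transition, from first principles
oracle_weights <- function(model, from_state, col_from, to_state, aa) {
  tn <- paste0(from_state, to_state)
  t <- model$trans[col_from + 1L, tn]
  col_to <- if (to_state == "I") col_from else col_from + 1L
  raw <- log(unname(t))
  if (to_state == "M") {
    raw <- raw + log(unname(model$match_emission[col_to, aa]) /
                     unname(model$background[[aa]]))
  }
  cmaxj <- log(max(unname(model$match_emission[col_to, oracle_aa]) /
                   unname(model$background[oracle_aa])))
  mod <- if (to_state %in% c("M", "D")) raw - cmaxj else raw
  c(raw = unname(raw), mod = unname(mod))
}

# enumerate every simple start->goal path by DFS; returns list of
# list(g, raw, vkeys, kmers, edges).  Also records, for every vertex
# visited on any partial path, the best (modified) completion-to-goal
# score, for the heuristic admissibility audit.
oracle_enumerate <- function(model, counter, start_kmer, start_col,
                             direction = "right", start_state = "M",
                             max_paths = 20000L) {
  L <- model$L
  memo <- new.env(parent = emptyenv())
  paths <- list()
  vkey <- function(km, cl, st) paste0(km, "|", cl, "|", st)
  n_emitted <- 0L

  dfs <- function(km, cl, st, g, raw, vks, kms, visited) {
    if (length(paths) >= max_paths) return(invisible(NULL))
    if (cl == L && st %in% c("M", "D")) {
      paths[[length(paths) + 1L]] <<- list(g = g, raw = raw, vkeys = vks,
                                           kmers = kms)
      return(invisible(NULL))
    }
    if (cl >= L) return(invisible(NULL))
    # match / insert successors
    for (step in oracle_codon_steps(counter, km, direction, memo)) {
      aa <- oracle_codon_aa[[step$codon]]
      if (!aa %in% oracle_aa) next
      w <- oracle_weights(model, st, cl, "M", aa)
      key <- vkey(step$kmer, cl + 1L, "M")
      if (is.finite(w[["mod"]]) && !key %in% visited) {
        dfs(step$kmer, cl + 1L, "M", g + w[["mod"]], raw + w[["raw"]],
            c(vks, key), c(kms, step$kmer), c(visited, key))
      }
      if (st != "D") {
        wi <- oracle_weights(model, st, cl, "I", aa)
        keyi <- vkey(step$kmer, cl, "I")
        if (is.finite(wi[["mod"]]) && !keyi %in% visited) {
          dfs(step$kmer, cl, "I", g + wi[["mod"]], raw + wi[["raw"]],
              c(vks, keyi), c(kms, step$kmer), c(visited, keyi))
        }
      }
    }
    if (st != "I") {
      wd <- oracle_weights(model, st, cl, "D", NA)
      keyd <- vkey(km, cl + 1L, "D")
      if (is.finite(wd[["mod"]]) && !keyd %in% visited) {
        dfs(km, cl + 1L, "D", g + wd[["mod"]], raw + wd[["raw"]],
            c(vks, keyd), c(kms, km), c(visited, keyd))
      }
    }
    invisible(NULL)
  }

  k0 <- vkey(start_kmer, start_col, start_state)
  dfs(toupper(start_kmer), start_col, start_state, 0, 0, k0,
      toupper(start_kmer), k0)
  attr(paths, "complete") <- length(paths) < max_paths
  paths
}

# exact optimum via the branch-and-bound completion search (complete even
# when full enumeration would explode)
oracle_optimum <- function(model, counter, start_kmer, start_col,
                           direction = "right") {
  best <- oracle_best_completion(model, counter, toupper(start_kmer),
                                 start_col, "M", direction)
  if (is.finite(best)) best else NULL
}

oracle_best_score <- function(paths) {
  if (length(paths) == 0L) return(NULL)
  max(vapply(paths, `[[`, numeric(1L), "g"))
}

# greedy new-edge / new-kmer filter over score-ordered complete paths:
# the reference result for the modified Yen's enumeration
oracle_ranked <- function(paths, K) {
  if (length(paths) == 0L) return(list())
  gs <- vapply(paths, `[[`, numeric(1L), "g")
  raws <- vapply(paths, `[[`, numeric(1L), "raw")
  keys <- vapply(paths, function(p) paste(p$vkeys, collapse = " "),
                 character(1L))
  ord <- order(-gs, -raws, keys)
  accepted <- list()
  seen_edges <- character(0)
  seen_kmers <- character(0)
  for (i in ord) {
    if (length(accepted) >= K) break
    p <- paths[[i]]
    vk <- p$vkeys
    edges <- if (length(vk) > 1L) paste0(vk[-length(vk)], ">", vk[-1L])
             else character(0)
    if (length(accepted) > 0L) {
      if (!any(!edges %in% seen_edges)) next
      if (!any(!unique(p$kmers) %in% seen_kmers)) next
    }
    accepted[[length(accepted) + 1L]] <- p
    seen_edges <- union(seen_edges, edges)
    seen_kmers <- union(seen_kmers, unique(p$kmers))
  }
  accepted
}

# all vertices reachable from the start, by breadth-first expansion over
# the oracle's own successor rules
oracle_reachable <- function(model, counter, start_kmer, start_col,
                             direction = "right", cap = 2000L) {
  L <- model$L
  seen <- new.env(parent = emptyenv())
  memo <- new.env(parent = emptyenv())
  queue <- list(list(km = toupper(start_kmer), cl = start_col, st = "M"))
  seen[[paste0(start_kmer, "|", start_col, "|M")]] <- TRUE
  out <- list(queue[[1L]])
  while (length(queue) > 0L && length(out) < cap) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (v$cl >= L) next
    succ <- list()
    for (step in oracle_codon_steps(counter, v$km, direction, memo)) {
      aa <- oracle_codon_aa[[step$codon]]
      if (!aa %in% oracle_aa) next
      succ[[length(succ) + 1L]] <- list(km = step$kmer, cl = v$cl + 1L,
                                        st = "M")
      if (v$st != "D") {
        succ[[length(succ) + 1L]] <- list(km = step$kmer, cl = v$cl,
                                          st = "I")
      }
    }
    if (v$st != "I") {
      succ[[length(succ) + 1L]] <- list(km = v$km, cl = v$cl + 1L, st = "D")
    }
    for (s in succ) {
      key <- paste0(s$km, "|", s$cl, "|", s$st)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        queue[[length(queue) + 1L]] <- s
        out[[length(out) + 1L]] <- s
      }
    }
  }
  out
}

# best modified-weight completion from a vertex to the goal, by exhaustive
# simple-path DFS with branch-and-bound (every edge weight is negative, so
# a partial path at or below the incumbent cannot recover)
oracle_best_completion <- function(model, counter, km, cl, st,
                                   direction = "right", memo = NULL) {
  L <- model$L
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  best <- -Inf
  dfs <- function(km, cl, st, g, visited) {
    if (cl == L && st %in% c("M", "D")) {
      if (g > best) best <<- g
      return(invisible(NULL))
    }
    if (cl >= L || g <= best) return(invisible(NULL))
    for (step in oracle_codon_steps(counter, km, direction, memo)) {
      aa <- oracle_codon_aa[[step$codon]]
      if (!aa %in% oracle_aa) next
      w <- oracle_weights(model, st, cl, "M", aa)
      key <- paste0(step$kmer, "|", cl + 1L, "|M")
      if (is.finite(w[["mod"]]) && !key %in% visited) {
        dfs(step$kmer, cl + 1L, "M", g + w[["mod"]], c(visited, key))
      }
      if (st != "D") {
        wi <- oracle_weights(model, st, cl, "I", aa)
        keyi <- paste0(step$kmer, "|", cl, "|I")
        if (is.finite(wi[["mod"]]) && !keyi %in% visited) {
          dfs(step$kmer, cl, "I", g + wi[["mod"]], c(visited, keyi))
        }
      }
    }
    if (st != "I") {
      wd <- oracle_weights(model, st, cl, "D", NA)
      keyd <- paste0(km, "|", cl + 1L, "|D")
      if (is.finite(wd[["mod"]]) && !keyd %in% visited) {
        dfs(km, cl + 1L, "D", g + wd[["mod"]], c(visited, keyd))
      }
    }
    invisible(NULL)
  }
  dfs(km, cl, st, 0, paste0(km, "|", cl, "|", st))
  best
}

# random toy instance: a small model plus a sparse kmer graph seeded with
# one coding path and random distractor reads
toy_instance <- function(seed, L_range = 4:8, k = 6L) {
  set.seed(seed)
  L <- sample(L_range, 1L)
  aln_seqs <- vapply(1:3, function(i) {
    paste(sample(oracle_aa, L, replace = TRUE), collapse = "")
  }, character(1L))
  model <- build_profile_hmm(msa_from(aln_seqs), name = "toy")
  # a coding read guaranteeing one complete path, sometimes truncated
  coding_aa <- aln_seqs[1L]
  coding_nt <- back_translate(coding_aa, seed = seed + 1L)
  if (runif(1) < 0.25) {
    coding_nt <- substr(coding_nt, 1L, nchar(coding_nt) - 3L * sample(1:2, 1L))
  }
  n_extra <- sample(0:2, 1L)
  extras <- character(0)
  if (n_extra > 0L) {
    extras <- vapply(seq_len(n_extra), function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(12:24, 1L), replace = TRUE),
            collapse = "")
    }, character(1L))
  }
  # occasionally add a mutated copy of the coding read for branching
  if (runif(1) < 0.5) {
    pos <- sample(seq_len(nchar(coding_nt)), 1L)
    mut <- paste0(substr(coding_nt, 1L, pos - 1L),
                  sample(c("A", "C", "G", "T"), 1L),
                  substr(coding_nt, pos + 1L, nchar(coding_nt)))
    extras <- c(extras, mut)
  }
  counter <- build_counter(c(coding_nt, extras), k)
  list(model = model, counter = counter, start_kmer = substr(coding_nt, 1L, k),
       start_col = k %/% 3L, L = L)
}
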