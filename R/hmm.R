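# Profile hidden Markov models: construction from a seed alignment,
# HMMER3 ASCII round-trip, null-normalised emission log-odds, raw and
# monotonicity-corrected ("modified") edge weights, and the admissible
# completion heuristic used by A*.
#
# Transition layout: `trans` is an (L+1) x 7 matrix; row r = j + 1 holds
# the transitions out of column j's states (j = 0 is the begin node, whose
# M is the begin state B).  Columns: MM MI MD IM II DM DD, i.e.
# M_j->M_{j+1}, M_j->I_j, M_j->D_{j+1}, I_j->M_{j+1}, I_j->I_j,
# D_j->M_{j+1}, D_j->D_{j+1}.  Row L+1's M->M / I->M / D->M lead to the
# end state.

TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

.str_rev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                              collapse = ""), character(1L), USE.NAMES = FALSE)
}

.is_gap <- function(ch) ch == "-" | ch == "."

#' Build a profile HMM from a protein seed alignment
#'
#' Alignment columns whose gap fraction is below `symfrac` become match
#' columns.  No sequence weighting is applied (every sequence counts 1),
#' the appropriate regime when the model targets close homologs rather
#' than remote ones.  Match emissions use a uniform Laplace pseudocount
#' (`emission_pseudocount` per residue); insert emissions equal the
#' background, so insert log-odds are zero.  Transition probabilities are
#' posterior means `(count + w * prior_mean) / (total + w)` with prior
#' strength `w = prior_strength`; the delete->match and insert->match
#' prior means are 0.95 and delete->delete / insert->insert are 0.05,
#' discouraging the long nonproductive insert/delete excursions that
#' generic priors permit.  Remaining transition priors are uniform over
#' the legal options.
#'
#' @param aln An `msa` from [read_alignment] (amino-acid, >= 1 sequence).
#' @param name Model name.
#' @param symfrac Gap-fraction threshold below which a column is a match
#'   column.
#' @param emission_pseudocount Pseudocount added per amino acid.
#' @param prior_strength Total pseudo-observation weight behind the
#'   transition prior means.
#' @param background Named background frequency vector over [AA_ALPHABET];
#'   defaults to a Swiss-Prot-style composition ([aa_background]).
#' @return A `profile_hmm` object.
#' @export
build_profile_hmm <- function(aln, name = "model", symfrac = 0.5,
                              emission_pseudocount = 1 / 20,
                              prior_strength = 1,
                              background = aa_background()) {
  seqs <- toupper(record_seqs(aln$records))
  nseq <- length(seqs)
  nc <- aln$n_columns
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = nseq, ncol = nc, byrow = TRUE)
  gapfrac <- colMeans(.is_gap(chars))
  match_cols <- which(gapfrac < symfrac)
  L <- length(match_cols)
  if (L == 0L) stop("alignment has no match columns (all columns gappier ",
                    "than symfrac = ", symfrac, ")")

  emis <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA_ALPHABET))
  tcount <- matrix(0, nrow = L + 1L, ncol = 7L,
                   dimnames = list(NULL, TRANS_NAMES))
  is_match_col <- logical(nc)
  is_match_col[match_cols] <- TRUE
  col_to_j <- cumsum(is_match_col)   # match index reached at/on each column

  for (s in seq_len(nseq)) {
    row <- chars[s, ]
    st <- "M"; j <- 0L              # begin state
    for (cc in seq_len(nc)) {
      ch <- row[cc]
      if (is_match_col[cc]) {
        jn <- col_to_j[cc]
        if (!.is_gap(ch)) {
          if (ch %in% AA_ALPHABET) emis[jn, ch] <- emis[jn, ch] + 1
          tn <- paste0(st, "M")
          if (tn %in% TRANS_NAMES) tcount[j + 1L, tn] <- tcount[j + 1L, tn] + 1
          st <- "M"
        } else {
          tn <- paste0(st, "D")
          # plan-7 models have no I->D transition; such events are dropped
          if (tn %in% TRANS_NAMES) tcount[j + 1L, tn] <- tcount[j + 1L, tn] + 1
          st <- "D"
        }
        j <- jn
      } else if (!.is_gap(ch)) {
        tn <- paste0(st, "I")
        if (tn %in% TRANS_NAMES) tcount[j + 1L, tn] <- tcount[j + 1L, tn] + 1
        st <- "I"
      }
    }
    tn <- paste0(st, "M")          # exit to the end state
    tcount[j + 1L, tn] <- tcount[j + 1L, tn] + 1
  }

  pc <- emission_pseudocount
  match_emission <- (emis + pc) / (rowSums(emis) + 20 * pc)
  insert_emission <- matrix(rep(background, each = L), nrow = L,
                            dimnames = list(NULL, AA_ALPHABET))

  w <- prior_strength
  trans <- matrix(0, nrow = L + 1L, ncol = 7L,
                  dimnames = list(NULL, TRANS_NAMES))
  for (r in seq_len(L + 1L)) {
    j <- r - 1L
    m_opts <- if (j == L) c(MM = 0.5, MI = 0.5)
              else c(MM = 1 / 3, MI = 1 / 3, MD = 1 / 3)
    mtot <- sum(tcount[r, names(m_opts)])
    trans[r, names(m_opts)] <- (tcount[r, names(m_opts)] + w * m_opts) /
      (mtot + w)
    i_opts <- c(IM = 0.95, II = 0.05)
    itot <- sum(tcount[r, names(i_opts)])
    trans[r, names(i_opts)] <- (tcount[r, names(i_opts)] + w * i_opts) /
      (itot + w)
    if (j == 0L || j == L) {
      trans[r, "DM"] <- 1; trans[r, "DD"] <- 0   # no D0; D_L exits to end
    } else {
      d_opts <- c(DM = 0.95, DD = 0.05)
      dtot <- sum(tcount[r, names(d_opts)])
      trans[r, names(d_opts)] <- (tcount[r, names(d_opts)] + w * d_opts) /
        (dtot + w)
    }
  }

  .hmm_finalize(list(
    name = name, L = L, direction = "forward",
    match_emission = match_emission, insert_emission = insert_emission,
    trans = trans, background = background, match_cols = match_cols))
}

#' Build the column-reversed companion model
#'
#' Equals [build_profile_hmm] applied to the alignment with every
#' sequence's residue order reversed.  Search left of a starting vertex
#' runs against this model: its column r corresponds to forward column
#' L - r + 1.
#'
#' @inheritParams build_profile_hmm
#' @return A `profile_hmm` with `direction = "reversed"`.
#' @export
build_reverse_model <- function(aln, name = "model", ...) {
  rev_records <- lapply(aln$records, function(r) {
    seq_record(r$id, .str_rev(r$seq), desc = r$desc)
  })
  rev_aln <- structure(list(records = rev_records, n_columns = aln$n_columns),
                       class = "msa")
  m <- build_profile_hmm(rev_aln, name = name, ...)
  m$direction <- "reversed"
  m
}

# Precompute the log-space tables every search touches: transition logs,
# null-normalised match emission log-odds `elo`, the per-column maximum
# log-odds `cmax` subtracted for monotonicity, and the heuristic table.
.hmm_finalize <- function(model) {
  model$log_trans <- log(model$trans)
  bg <- model$background[AA_ALPHABET]
  model$elo <- log(sweep(model$match_emission[, AA_ALPHABET, drop = FALSE],
                         2, bg, "/"))
  model$cmax <- apply(model$elo, 1L, max)
  model$heuristic <- .heuristic_table(model)
  class(model) <- "profile_hmm"
  model
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm %s: L=%d (%s)>\n", x$name, x$L, x$direction))
  invisible(x)
}

#' Emission log-odds of a match column
#'
#' `log(match_emission[j, aa] / background[aa])` in nats.  Insert states
#' emit at background frequency, so their log-odds are zero by
#' construction and are not tabulated.
#'
#' @param model A `profile_hmm`.
#' @param j Match column, 1..L.
#' @param aa Amino-acid one-letter code; a stop (`"*"`) or unknown residue
#'   returns `-Inf`.
#' @return Log-odds in nats.
#' @export
emission_logodds <- function(model, j, aa) {
  stopifnot(j >= 1L, j <= model$L)
  if (!aa %in% AA_ALPHABET) return(-Inf)
  unname(model$elo[j, aa])
}

#' Weight of one edge of the combined assembly graph
#'
#' Raw weight: `log t(from -> to)` plus the emission log-odds when the
#' target is a match state (insert emissions are null-normalised to 0,
#' delete states emit nothing).  Modified weight: the per-column maximum
#' match log-odds `c_j` is additionally subtracted from every edge
#' entering column j's match or delete state (the five transition types
#' M->M, I->M, M->D, D->M, D->D), making all edge weights non-positive so
#' both the path score and the heuristic are monotone.
#'
#' @param model A `profile_hmm`.
#' @param from,to Lists `list(state=, col=)` with state one of "M","I","D";
#'   the begin state is `list(state="M", col=0)`.
#' @param aa Emitted amino acid (required when `to` is a match or insert
#'   state).
#' @param variant `"modified"` (default, used during search) or `"raw"`.
#' @return Weight in nats.
#' @export
edge_weight <- function(model, from, to, aa = NULL,
                        variant = c("modified", "raw")) {
  variant <- match.arg(variant)
  tn <- paste0(from$state, to$state)
  legal <- switch(tn,
    MM = to$col == from$col + 1L,
    MI = to$col == from$col,
    MD = to$col == from$col + 1L,
    IM = to$col == from$col + 1L,
    II = to$col == from$col,
    DM = to$col == from$col + 1L,
    DD = to$col == from$col + 1L,
    FALSE)
  if (!isTRUE(legal)) {
    stop("illegal HMM transition ", from$state, from$col, " -> ",
         to$state, to$col)
  }
  wt <- model$log_trans[from$col + 1L, tn]
  if (to$state == "M") {
    if (is.null(aa)) stop("match target requires an emitted amino acid")
    wt <- wt + emission_logodds(model, to$col, aa)
  }
  if (variant == "modified" && to$state %in% c("M", "D")) {
    wt <- wt - model$cmax[to$col]
  }
  unname(wt)
}

# h(state, j): best possible modified-weight completion from column j to
# the model end, assuming the most likely transition into the next match
# state and all-match thereafter.  Under modified weights the emission
# term of the argmax amino acid cancels c_j exactly, so each step
# contributes only its transition log.  Matrix rows M/I/D, column r = j+1.
.heuristic_table <- function(model) {
  L <- model$L
  lt <- log(model$trans)
  suffix <- numeric(L + 1L)                 # suffix[j+1] = sum_{i>=j} log tMM
  if (L >= 2L) {
    for (j in (L - 1L):1L) suffix[j] <- lt[j + 1L, "MM"] + suffix[j + 1L]
  }
  h <- matrix(0, nrow = 3L, ncol = L + 1L, dimnames = list(c("M", "I", "D")))
  for (j in 0:(L - 1L)) {
    r <- j + 1L
    h["M", r] <- lt[r, "MM"] + suffix[j + 1L]
    h["I", r] <- lt[r, "IM"] + suffix[j + 1L]
    h["D", r] <- lt[r, "DM"] + suffix[j + 1L]
  }
  h[, L + 1L] <- 0                          # goal states
  h
}

#' Heuristic completion table
#'
#' @param model A `profile_hmm`.
#' @return 3 x (L+1) matrix, rows `M`,`I`,`D`; entry `[s, j+1]` is h for
#'   state s at column j.  Zero at the terminal (goal) column.
#' @export
heuristic_table <- function(model) model$heuristic

#' Convert a natural-log score to bits
#'
#' @param nats Score in nats.
#' @return Score in bits (`nats / ln 2`).
#' @export
bit_score <- function(nats) nats / log(2)

# --- HMMER3 ASCII model files -------------------------------------------

.fmt_p <- function(p) {
  ifelse(p <= 0, "*", sprintf("%.5f", -log(p)))
}

#' Write a model in HMMER3 ASCII format
#'
#' Writes the subset of fields the parser consumes (HMM3/f dialect:
#' NAME, LENG, ALPH, COMPO, per-node match/insert/transition lines).
#'
#' @param model A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmmer3 <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  L <- model$L
  writeLines(c("HMMER3/f [hmmasm]",
               paste0("NAME  ", model$name),
               paste0("LENG  ", L),
               "ALPH  amino"), con)
  writeLines(paste0("HMM    ", paste(sprintf("%8s", AA_ALPHABET),
                                     collapse = " ")), con)
  writeLines(paste0("       ", paste(sprintf("%8s",
    c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
    collapse = " ")), con)
  bg <- model$background[AA_ALPHABET]
  writeLines(paste0("  COMPO ", paste(sprintf("%8s", .fmt_p(bg)),
                                      collapse = " ")), con)
  ins0 <- bg                               # node-0 insert emits background
  writeLines(paste0("        ", paste(sprintf("%8s", .fmt_p(ins0)),
                                      collapse = " ")), con)
  writeLines(paste0("        ", paste(sprintf("%8s",
    .fmt_p(model$trans[1L, TRANS_NAMES])), collapse = " ")), con)
  for (j in seq_len(L)) {
    writeLines(paste0(sprintf("%7d ", j),
      paste(sprintf("%8s", .fmt_p(model$match_emission[j, AA_ALPHABET])),
            collapse = " ")), con)
    writeLines(paste0("        ",
      paste(sprintf("%8s", .fmt_p(model$insert_emission[j, AA_ALPHABET])),
            collapse = " ")), con)
    writeLines(paste0("        ",
      paste(sprintf("%8s", .fmt_p(model$trans[j + 1L, TRANS_NAMES])),
            collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Parse a HMMER3 ASCII model file
#'
#' Reads the HMMER3/b and /f amino-acid dialects (the fields used for
#' search: LENG, ALPH, COMPO, match/insert emissions, transitions).
#' Stored values are negative natural logs; `*` denotes probability zero.
#' The COMPO line, when present, supplies the background composition;
#' otherwise the built-in table is used.
#'
#' @param path Path to a `.hmm` file.
#' @return A `profile_hmm`.
#' @export
parse_hmmer3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^HMMER3", lines[1L])) {
    stop("not a HMMER3 ASCII model: ", path)
  }
  name <- "model"; L <- NA_integer_
  i <- 2L
  aa_order <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^NAME\\s", ln)) name <- trimws(sub("^NAME\\s+", "", ln))
    if (grepl("^LENG\\s", ln)) L <- as.integer(trimws(sub("^LENG\\s+", "", ln)))
    if (grepl("^ALPH\\s", ln)) {
      alph <- tolower(trimws(sub("^ALPH\\s+", "", ln)))
      if (alph != "amino") {
        stop("unsupported alphabet '", alph, "' in ", path,
             " (only amino-acid models are searched)")
      }
    }
    if (grepl("^HMM\\s", ln)) {
      aa_order <- strsplit(trimws(sub("^HMM\\s+", "", ln)), "\\s+")[[1L]]
      i <- i + 2L                          # skip the transition header line
      break
    }
    i <- i + 1L
  }
  if (is.null(aa_order) || is.na(L)) {
    stop("HMMER3 format error in ", path, ": missing HMM/LENG header")
  }
  if (!setequal(aa_order, AA_ALPHABET)) {
    stop("HMMER3 format error in ", path, ": unexpected symbol alphabet")
  }
  .num <- function(tok) ifelse(tok == "*", Inf, suppressWarnings(as.numeric(tok)))
  toks <- function(ln) strsplit(trimws(ln), "\\s+")[[1L]]

  background <- aa_background()
  if (i <= length(lines) && grepl("^\\s*COMPO\\s", lines[i])) {
    v <- .num(toks(lines[i])[-1L])[seq_len(20L)]
    background <- setNames(exp(-v), aa_order)[AA_ALPHABET]
    background <- background / sum(background)
    i <- i + 1L
  }
  i <- i + 2L                               # node-0 insert + transition lines
  match_emission <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  insert_emission <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  trans <- matrix(0, L + 1L, 7L, dimnames = list(NULL, TRANS_NAMES))
  # node-0 transitions live two lines back from the current position
  t0 <- .num(toks(lines[i - 1L]))[seq_len(7L)]
  trans[1L, ] <- exp(-t0)
  for (j in seq_len(L)) {
    if (i + 2L > length(lines)) stop("HMMER3 format error in ", path,
                                     ": truncated at node ", j)
    m <- toks(lines[i])
    if (suppressWarnings(as.integer(m[1L])) != j) {
      stop("HMMER3 format error in ", path, ": expected node ", j,
           ", got '", m[1L], "'")
    }
    match_emission[j, aa_order] <- exp(-.num(m[2L:21L]))
    insert_emission[j, aa_order] <- exp(-.num(toks(lines[i + 1L])[seq_len(20L)]))
    trans[j + 1L, ] <- exp(-.num(toks(lines[i + 2L])[seq_len(7L)]))
    i <- i + 3L
  }
  if (i > length(lines) || trimws(lines[i]) != "//") {
    stop("HMMER3 format error in ", path, ": missing // terminator")
  }
  .hmm_finalize(list(
    name = name, L = L, direction = "forward",
    match_emission = match_emission, insert_emission = insert_emission,
    trans = trans, background = background, match_cols = NULL))
}
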