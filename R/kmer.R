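# K-mer counting: the implicit de Bruijn graph.
#
# The graph is never materialised; vertex membership and abundance are
# queried against a counter built from all read k-mers.  Two backends:
# an exact hash (default, environment-based) and a counting Bloom filter
# with 4-bit saturating counters.  Storage is canonical (lexicographic
# min of k-mer and reverse complement) so both strands are queryable.

canonical_kmer <- function(kmers) {
  rc <- reverse_complement(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Enumerate the k-mers of a sequence
#'
#' Yields every window of length `k` consisting only of A/C/G/T
#' (case-folded).  Windows containing N or any other code are skipped;
#' sequences shorter than `k` yield nothing.
#'
#' @param seq Nucleotide string (or a [seq_record]).
#' @param k K-mer length.
#' @return Character vector of k-mers, in sequence order.
#' @export
read_kmers <- function(seq, k) {
  if (inherits(seq, "seq_record")) seq <- seq$seq
  stopifnot(k >= 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  kmers[grepl("^[ACGT]+$", kmers)]
}

# --- counting Bloom filter ----------------------------------------------

# Deterministic string hashing: polynomial rolling hash of the 2-bit base
# codes modulo a prime < 2^26 (products stay exact in doubles), one
# multiplier per hash function derived from the published seed.
.bloom_prime <- 67108859
.bloom_multipliers <- function(n_hash, seed = 1299709) {
  m <- numeric(n_hash)
  x <- seed
  for (i in seq_len(n_hash)) {
    x <- (x * 48271) %% 2147483647
    m[i] <- 256 + (x %% 65536)
  }
  m
}

.bloom_indices <- function(kmer, mult, m) {
  codes <- utf8ToInt(kmer)
  idx <- numeric(length(mult))
  for (i in seq_along(mult)) {
    h <- 0
    mi <- mult[i]
    for (c in codes) h <- (h * mi + c) %% .bloom_prime
    idx[i] <- (h %% m) + 1
  }
  idx
}

# --- counter construction -----------------------------------------------

#' Build a k-mer abundance counter from reads
#'
#' Every k-mer of every read is counted in canonical form (the
#' lexicographically smaller of the k-mer and its reverse complement), so
#' counts are strand-symmetric.  All k-mers are kept regardless of
#' abundance; minimum-abundance filtering happens at query time
#' ([passes_min_count]).
#'
#' @param reads List of [seq_record] objects or a character vector of
#'   sequences.
#' @param k K-mer length; must be a multiple of 3 for protein-HMM search.
#' @param backend `"exact"` (hash, default) or `"bloom"` (counting Bloom
#'   filter, 4-bit saturating counters).
#' @param bloom_counters Number of Bloom counters (backend `"bloom"`).
#' @param bloom_hashes Number of hash functions (backend `"bloom"`).
#' @param max_fp_rate Configuration ceiling on the expected Bloom
#'   false-positive rate; sizing that implies a higher rate is an error.
#' @return A `kmer_counter` object.
#' @export
build_counter <- function(reads, k, backend = c("exact", "bloom"),
                          bloom_counters = 2^20, bloom_hashes = 4L,
                          max_fp_rate = 0.05) {
  backend <- match.arg(backend)
  if (is.character(reads)) seqs <- reads else seqs <- record_seqs(reads)
  all_kmers <- unlist(lapply(seqs, read_kmers, k = k), use.names = FALSE)
  canon <- canonical_kmer(all_kmers)

  if (backend == "exact") {
    tab <- table(canon)
    env <- new.env(hash = TRUE, size = max(29L, length(tab)))
    nm <- names(tab)
    cnt <- as.integer(tab)
    for (i in seq_along(nm)) assign(nm[i], cnt[i], envir = env)
    counter <- list(k = k, backend = "exact", env = env,
                    n_distinct = length(tab), n_total = length(canon))
  } else {
    n_distinct_est <- length(unique(canon))
    fp <- (1 - exp(-bloom_hashes * n_distinct_est / bloom_counters))^bloom_hashes
    if (fp > max_fp_rate) {
      stop("bloom sizing implies expected false-positive rate ",
           signif(fp, 3), " > ceiling ", max_fp_rate,
           "; increase bloom_counters")
    }
    counters <- integer(bloom_counters)
    mult <- .bloom_multipliers(bloom_hashes)
    for (km in canon) {
      idx <- .bloom_indices(km, mult, bloom_counters)
      counters[idx] <- pmin(counters[idx] + 1L, 15L)
    }
    counter <- list(k = k, backend = "bloom", counters = counters,
                    n_counters = bloom_counters, n_hash = bloom_hashes,
                    mult = mult, expected_fp = fp, n_total = length(canon))
  }
  structure(counter, class = "kmer_counter")
}

#' @export
print.kmer_counter <- function(x, ...) {
  cat(sprintf("<kmer_counter k=%d backend=%s, %s k-mer occurrences>\n",
              x$k, x$backend, format(x$n_total, big.mark = ",")))
  invisible(x)
}

#' Query k-mer counts
#'
#' @param counter A `kmer_counter`.
#' @param kmers Character vector of k-mers (either strand).
#' @return Integer vector of counts (0 for absent k-mers on the exact
#'   backend; the Bloom backend never undercounts but may overcount).
#' @export
kmer_count <- function(counter, kmers) {
  canon <- canonical_kmer(toupper(kmers))
  if (counter$backend == "exact") {
    env <- counter$env
    vapply(canon, function(km) {
      v <- env[[km]]
      if (is.null(v)) 0L else v
    }, integer(1L), USE.NAMES = FALSE)
  } else {
    vapply(canon, function(km) {
      idx <- .bloom_indices(km, counter$mult, counter$n_counters)
      min(counter$counters[idx])
    }, integer(1L), USE.NAMES = FALSE)
  }
}

#' Minimum-abundance filter
#'
#' TRUE iff the k-mer's count is at least `min_count`; `min_count = 1`
#' reduces to graph membership.
#'
#' @inheritParams kmer_count
#' @param min_count Minimum abundance cutoff (>= 1).
#' @return Logical vector.
#' @export
passes_min_count <- function(counter, kmers, min_count = 1L) {
  stopifnot(min_count >= 1L)
  kmer_count(counter, kmers) >= min_count
}

# --- codon-step neighbour enumeration -----------------------------------

#' Codon-step neighbours of a k-mer
#'
#' Walking the nucleotide de Bruijn graph in protein space means taking
#' three single-nucleotide steps at a time: a codon step exists only if
#' each of the three intermediate shifted k-mers passes the abundance
#' cutoff.  `direction = "right"` drops the 3-prefix and appends a codon;
#' `"left"` drops the 3-suffix and prepends one.  The returned codon is
#' always in left-to-right reading orientation.
#'
#' @inheritParams passes_min_count
#' @param kmer A single k-mer (length a multiple of 3).
#' @param direction `"right"` or `"left"`.
#' @return A list with character vectors `kmer` and `codon` (parallel;
#'   possibly empty).
#' @export
codon_neighbors <- function(counter, kmer, direction = c("right", "left"),
                            min_count = 1L) {
  direction <- match.arg(direction)
  k <- counter$k
  stopifnot(nchar(kmer) == k, k %% 3L == 0L)
  kmer <- toupper(kmer)

  if (direction == "right") {
    core1 <- substr(kmer, 2L, k)            # append 1st base
    cand1 <- paste0(core1, DNA_BASES)
    ok1 <- DNA_BASES[passes_min_count(counter, cand1, min_count)]
    if (length(ok1) == 0L) return(list(kmer = character(0), codon = character(0)))
    core2 <- substr(kmer, 3L, k)
    pre2 <- as.vector(outer(ok1, DNA_BASES, paste0))
    cand2 <- paste0(core2, pre2)
    ok2 <- pre2[passes_min_count(counter, cand2, min_count)]
    if (length(ok2) == 0L) return(list(kmer = character(0), codon = character(0)))
    core3 <- substr(kmer, 4L, k)
    pre3 <- as.vector(outer(ok2, DNA_BASES, paste0))
    cand3 <- paste0(core3, pre3)
    ok <- passes_min_count(counter, cand3, min_count)
    list(kmer = cand3[ok], codon = pre3[ok])
  } else {
    core1 <- substr(kmer, 1L, k - 1L)       # prepend 3rd codon base first
    cand1 <- paste0(DNA_BASES, core1)
    ok1 <- DNA_BASES[passes_min_count(counter, cand1, min_count)]
    if (length(ok1) == 0L) return(list(kmer = character(0), codon = character(0)))
    core2 <- substr(kmer, 1L, k - 2L)
    suf2 <- as.vector(outer(ok1, DNA_BASES, function(z, y) paste0(y, z)))
    cand2 <- paste0(suf2, core2)
    ok2 <- suf2[passes_min_count(counter, cand2, min_count)]
    if (length(ok2) == 0L) return(list(kmer = character(0), codon = character(0)))
    core3 <- substr(kmer, 1L, k - 3L)
    suf3 <- as.vector(outer(ok2, DNA_BASES, function(z, x) paste0(x, z)))
    cand3 <- paste0(suf3, core3)
    ok <- passes_min_count(counter, cand3, min_count)
    list(kmer = cand3[ok], codon = suf3[ok])
  }
}
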