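# Binary max-heap keyed lexicographically by (f, raw, -insertion order).
# The third key makes pop order — and therefore every search — fully
# deterministic even when scores tie.

heap_new <- function(capacity = 256L) {
  h <- new.env(parent = emptyenv())
  h$id <- integer(capacity)
  h$f <- numeric(capacity)
  h$raw <- numeric(capacity)
  h$seq <- integer(capacity)
  h$n <- 0L
  h
}

.heap_before <- function(h, a, b) {
  # TRUE if slot a has priority over slot b
  if (h$f[a] != h$f[b]) return(h$f[a] > h$f[b])
  if (h$raw[a] != h$raw[b]) return(h$raw[a] > h$raw[b])
  h$seq[a] < h$seq[b]
}

.heap_swap <- function(h, a, b) {
  tmp <- h$id[a]; h$id[a] <- h$id[b]; h$id[b] <- tmp
  tmpd <- h$f[a]; h$f[a] <- h$f[b]; h$f[b] <- tmpd
  tmpd <- h$raw[a]; h$raw[a] <- h$raw[b]; h$raw[b] <- tmpd
  tmp <- h$seq[a]; h$seq[a] <- h$seq[b]; h$seq[b] <- tmp
}

heap_push <- function(h, id, f, raw, seq) {
  n <- h$n + 1L
  if (n > length(h$id)) {
    grow <- length(h$id) * 2L
    h$id <- c(h$id, integer(grow)); h$f <- c(h$f, numeric(grow))
    h$raw <- c(h$raw, numeric(grow)); h$seq <- c(h$seq, integer(grow))
  }
  h$id[n] <- id; h$f[n] <- f; h$raw[n] <- raw; h$seq[n] <- seq
  h$n <- n
  while (n > 1L) {
    p <- n %/% 2L
    if (.heap_before(h, n, p)) { .heap_swap(h, n, p); n <- p } else break
  }
  invisible(h)
}

heap_pop <- function(h) {
  if (h$n == 0L) return(NULL)
  top <- h$id[1L]
  n <- h$n
  .heap_swap(h, 1L, n)
  h$n <- n - 1L
  n <- h$n
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    best <- i
    if (l <= n && .heap_before(h, l, best)) best <- l
    if (r <= n && .heap_before(h, r, best)) best <- r
    if (best == i) break
    .heap_swap(h, i, best)
    i <- best
  }
  top
}

heap_empty <- function(h) h$n == 0L
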