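# Alphabets, genetic code and translation helpers.

#' Amino-acid alphabet in profile-HMM column order
#'
#' The 20 standard amino acids in the alphabetical one-letter order used by
#' HMMER3 model files (`A C D E F G H I K L M N P Q R S T V W Y`).
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

# Background amino-acid frequencies (Swiss-Prot-style composition),
# normalised to sum exactly to 1.  Used as the null model for emission
# log-odds; a uniform 1/20 background is available via `background =`.
.aa_background_raw <- c(
  A = 0.0787, C = 0.0151, D = 0.0535, E = 0.0668, F = 0.0397,
  G = 0.0696, H = 0.0229, I = 0.0590, K = 0.0581, L = 0.0963,
  M = 0.0237, N = 0.0409, P = 0.0480, Q = 0.0393, R = 0.0552,
  S = 0.0714, T = 0.0541, V = 0.0673, W = 0.0110, Y = 0.0292)

#' Default background amino-acid frequencies
#'
#' Swiss-Prot-style composition over [AA_ALPHABET], normalised to sum to 1.
#' This is the null model against which match emissions are normalised.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  .aa_background_raw / sum(.aa_background_raw)
}

# codon -> amino acid lookup (standard code; identical to bacterial table 11
# for all coding triplets).  Stops map to "*".
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Translate a nucleotide sequence in frame 1
#'
#' @param nt Character scalar of A/C/G/T (case-insensitive).  Length must be
#'   a multiple of 3.
#' @return Character scalar of amino acids; stop codons become `"*"`.
#' @export
translate_nt <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3: ", n)
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"   # codons containing N or other ambiguity codes
  paste(aa, collapse = "")
}

translate_codons <- function(codons) {
  aa <- .codon_table[toupper(codons)]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick reverse complement; an involution.  IUPAC ambiguity codes
#' are complemented where defined (N stays N).
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
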