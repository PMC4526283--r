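# Sequence record containers and FASTA/FASTQ/alignment input-output.

#' Construct a sequence record
#'
#' @param id Record identifier (first whitespace-delimited token of a
#'   FASTA/FASTQ header).
#' @param seq Residue string (nucleotide or amino acid); non-empty.
#' @param desc Remainder of the header line ("" if none).
#' @param qual Optional integer vector of per-residue Phred scores; must
#'   have one entry per residue.
#' @return A list with class `seq_record`.
#' @export
seq_record <- function(id, seq, desc = "", qual = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  if (!is.null(qual) && length(qual) != nchar(seq)) {
    stop("quality length ", length(qual), " != sequence length ", nchar(seq),
         " for record '", id, "'")
  }
  structure(list(id = id, desc = desc, seq = seq, qual = qual),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s: %d residues%s>\n", x$id, nchar(x$seq),
              if (is.null(x$qual)) "" else ", with quality"))
  invisible(x)
}

record_seqs <- function(records) {
  vapply(records, function(r) r$seq, character(1L))
}

record_ids <- function(records) {
  vapply(records, function(r) r$id, character(1L))
}

.split_header <- function(h) {
  h <- sub("^[>@]", "", h)
  id <- sub("\\s.*$", "", h)
  desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
  list(id = id, desc = desc)
}

#' Read a FASTA file
#'
#' Parsing is delegated to Biostrings; records come back in file order with
#' case preserved.  Malformed input (a record with an empty sequence, or
#' sequence data before any header) raises a format error naming the first
#' offending line.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return List of [seq_record] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) .fasta_diagnose(path, conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error in ", path, ": no records")
  w <- which(Biostrings::width(set) == 0L)
  if (length(w) > 0L) .fasta_diagnose(path, "empty sequence")
  seqs <- as.character(set)
  headers <- names(set)
  lapply(seq_along(seqs), function(i) {
    h <- .split_header(headers[i])
    seq_record(h$id, seqs[[i]], desc = h$desc)
  })
}

# Locate the first malformed FASTA record so the error can name a line.
.fasta_diagnose <- function(path, why) {
  lines <- readLines(path, warn = FALSE)
  last_header <- NA_integer_
  has_residues <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (!is.na(last_header) && !has_residues) {
        stop("FASTA format error in ", path, " at line ", last_header,
             ": header with empty sequence")
      }
      last_header <- i
      has_residues <- FALSE
    } else if (nzchar(trimws(ln))) {
      if (is.na(last_header)) {
        stop("FASTA format error in ", path, " at line ", i,
             ": sequence data before any header")
      }
      has_residues <- TRUE
    }
  }
  if (!is.na(last_header) && !has_residues) {
    stop("FASTA format error in ", path, " at line ", last_header,
         ": header with empty sequence")
  }
  stop("FASTA format error in ", path, ": ", why)
}

#' Read a FASTQ file
#'
#' Expects 4-line records.  Quality is decoded as Phred+33 by default; pass
#' `offset = 64` for legacy Phred+64 data.
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @param offset Quality encoding offset, 33 (default) or 64.
#' @return List of [seq_record] objects with integer `qual`.
#' @export
read_fastq <- function(path, offset = 33) {
  if (!file.exists(path)) stop("no such file: ", path)
  .fastq_validate(path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("FASTQ format error in ", path, ": ", conditionMessage(e))
    })
  seqs <- as.character(set)
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  headers <- names(set)
  lapply(seq_along(seqs), function(i) {
    q <- utf8ToInt(quals[i]) - offset
    if (length(q) != nchar(seqs[i])) {
      stop("FASTQ format error in ", path, ": sequence/quality length ",
           "mismatch for record '", headers[i], "'")
    }
    h <- .split_header(headers[i])
    seq_record(h$id, seqs[[i]], desc = h$desc, qual = q)
  })
}

# Structural check of the 4-line record layout, so truncation and
# sequence/quality length mismatches fail with a clear message rather
# than decoding garbage.
.fastq_validate <- function(path) {
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ format error in ", path, ": truncated record (",
         length(lines), " lines is not a multiple of 4)")
  }
  for (i in seq(1L, length(lines), by = 4L)) {
    if (!startsWith(lines[i], "@") || !startsWith(lines[i + 2L], "+")) {
      stop("FASTQ format error in ", path, " at line ", i,
           ": expected @header / + separator")
    }
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) {
      stop("FASTQ format error in ", path, ": sequence/quality length ",
           "mismatch for record at line ", i)
    }
  }
  invisible(TRUE)
}

#' Trim the low-quality tail of a read
#'
#' Removes the maximal trailing run of bases whose quality is at or below
#' `floor`.  The default floor of Phred 2 corresponds to the quality
#' character "B" under Phred+64 and "#" under Phred+33, the conventional
#' Illumina read-segment-quality marker.  Interior low-quality bases are
#' kept; a fully low-quality read trims to an empty record.
#'
#' @param record A [seq_record] with quality.
#' @param floor Phred score at or below which trailing bases are removed.
#' @return The trimmed [seq_record] (possibly with an empty sequence).
#' @export
quality_trim <- function(record, floor = 2) {
  if (is.null(record$qual)) stop("record '", record$id, "' has no quality")
  q <- record$qual
  n <- length(q)
  keep <- n
  while (keep > 0L && q[keep] <= floor) keep <- keep - 1L
  if (keep == n) return(record)
  structure(list(id = record$id, desc = record$desc,
                 seq = substr(record$seq, 1L, keep),
                 qual = q[seq_len(keep)]),
            class = "seq_record")
}

#' Read a multiple alignment
#'
#' Supports aligned FASTA and Stockholm.  The dialect is chosen from the
#' file content by default (`# STOCKHOLM` magic).  Gap characters are `-`
#' and `.`; residue case is preserved.
#'
#' @param path Path to the alignment.
#' @param dialect `"auto"`, `"fasta"`, or `"stockholm"`.
#' @return A list with class `msa`: `records` (list of [seq_record]) and
#'   `n_columns`.
#' @export
read_alignment <- function(path, dialect = c("auto", "fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    dialect <- if (length(first) && grepl("^#\\s*STOCKHOLM", first))
      "stockholm" else "fasta"
  }
  records <- if (dialect == "stockholm") .read_stockholm(path)
             else read_fasta(path)
  widths <- nchar(record_seqs(records))
  if (length(unique(widths)) > 1L) {
    bad <- record_ids(records)[widths != widths[1L]]
    stop("ragged alignment in ", path, ": record(s) ",
         paste(bad, collapse = ", "), " differ in aligned length")
  }
  structure(list(records = records, n_columns = widths[1L]), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa: %d sequences x %d columns>\n",
              length(x$records), x$n_columns))
  invisible(x)
}

# Minimal Stockholm reader: sequence lines only; '#' annotation and '//'
# terminator ignored; multi-block files are concatenated per id.
.read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln)) || startsWith(ln, "#") || startsWith(ln, "//"))
      next
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L) {
      stop("Stockholm format error in ", path, ": cannot parse line: ", ln)
    }
    id <- parts[1L]
    if (is.null(seqs[[id]])) order <- c(order, id)
    seqs[[id]] <- paste0(seqs[[id]] %||% "", parts[2L])
  }
  if (length(order) == 0L) stop("Stockholm format error in ", path,
                                ": no sequences")
  lapply(order, function(id) seq_record(id, seqs[[id]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write records to FASTA
#'
#' @param records List of [seq_record] (or a named character vector).
#' @param path Output path.
#' @param wrap Line width for sequence wrapping; 0 writes one line per
#'   sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (is.character(records)) {
    records <- lapply(seq_along(records), function(i) {
      seq_record(names(records)[i] %||% as.character(i), records[[i]])
    })
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
    writeLines(paste0(">", header), con)
    n <- nchar(r$seq)
    if (wrap > 0L && n > wrap) {
      starts <- seq.int(1L, n, by = wrap)
      writeLines(substring(r$seq, starts, pmin(starts + wrap - 1L, n)), con)
    } else {
      writeLines(r$seq, con)
    }
  }
  invisible(path)
}

#' Write records to FASTQ (Phred+33)
#'
#' @param records List of [seq_record]; every record must carry quality.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    if (is.null(r$qual)) stop("record '", r$id, "' has no quality")
    header <- if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
    writeLines(c(paste0("@", header), r$seq, "+",
                 intToUtf8(r$qual + 33L)), con)
  }
  invisible(path)
}
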