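# Sequence I/O and coordinate conventions.
#
# Internal coordinates are 0-based half-open everywhere; positions inside an
# siRNA that are quoted to the user (e.g., "10th nt") are 1-based. Conversion
# happens only at I/O boundaries.

#' Create a transcript object
#'
#' A transcript is a sense-orientation nucleotide sequence with an identifier
#' and, optionally, an open reading frame annotation. Any `U` in the input is
#' stored as `T`; lowercase is uppercased.
#'
#' @param id transcript identifier (no whitespace)
#' @param seq nucleotide string; IUPAC codes allowed, unambiguous A/C/G/T
#'   expected for design
#' @param orf optional `interval()` delimiting the ORF (0-based half-open)
#' @return object of class `transcript` with elements `id`, `seq`, `orf`
#' @export
transcript <- function(id, seq, orf = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("u", "t", seq)
  seq <- toupper(chartr("U", "T", seq))
  if (!nzchar(seq)) stop("transcript '", id, "': empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% IUPAC_CHARS)
  if (length(bad) > 0L) {
    stop("transcript '", id, "': non-IUPAC character '", chars[bad[1]],
         "' at position ", bad[1])
  }
  if (!is.null(orf)) orf <- validate_interval(orf, nchar(seq))
  structure(list(id = id, seq = seq, orf = orf), class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %s  (%d nt%s)\n", x$id, nchar(x$seq),
              if (is.null(x$orf)) "" else
                sprintf(", ORF %d-%d", x$orf$start, x$orf$end)))
  invisible(x)
}

#' 0-based half-open interval
#'
#' @param start 0-based inclusive offset
#' @param end 0-based exclusive offset
#' @return object of class `interval`
#' @export
interval <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end <= start) stop("invalid interval [", start, ", ", end, ")")
  structure(list(start = start, end = end), class = "interval")
}

validate_interval <- function(x, seq_len) {
  stopifnot(inherits(x, "interval"))
  if (x$end > seq_len) {
    stop("interval [", x$start, ", ", x$end, ") outside sequence of length ",
         seq_len)
  }
  x
}

interval_length <- function(x) x$end - x$start

#' Read transcripts from a FASTA file
#'
#' Record ids are truncated at the first whitespace; sequences are uppercased
#' and U is converted to T. Duplicate ids and non-IUPAC characters are errors.
#'
#' @param path FASTA file
#' @return list of `transcript` objects
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate id '", dup[1], "' in ", path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- transcript(ids[i], as.character(set[[i]]))
  }
  names(out) <- ids
  out
}

#' Write transcripts to a FASTA file
#'
#' Output is wrapped at 60 columns so that `write_fasta(read_fasta(f))`
#' reproduces sequence content exactly.
#'
#' @param transcripts list of `transcript` objects
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(transcripts, path) {
  stopifnot(length(transcripts) > 0L)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in transcripts) {
    stopifnot(inherits(t, "transcript"))
    writeLines(paste0(">", t$id), con)
    n <- nchar(t$seq)
    starts <- seq(1L, n, by = 60L)
    writeLines(substring(t$seq, starts, pmin(starts + 59L, n)), con)
  }
  invisible(path)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Locate the longest open reading frame
#'
#' Scans the three forward frames for ATG-initiated ORFs ending at the first
#' in-frame stop codon (stop included). Transcripts are assumed to be in
#' sense orientation, so reverse frames are not searched. Ties in length are
#' broken by leftmost start.
#'
#' @param t `transcript`
#' @param min_len minimum ORF length in nt (stop included); default 90
#'   suppresses spurious micro-ORFs on random sequence
#' @return `interval` or `NULL` when no qualifying ORF exists
#' @export
find_longest_orf <- function(t, min_len = 90L) {
  stopifnot(inherits(t, "transcript"))
  n <- nchar(t$seq)
  if (n < 3L) stop("sequence shorter than one codon")
  best <- NULL
  best_len <- 0L
  for (frame in 0:2) {
    starts <- seq(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(t$seq, starts, starts + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    open_from <- NA_integer_  # codon index of current ORF start
    for (ci in seq_along(codons)) {
      if (is.na(open_from) && is_atg[ci]) open_from <- ci
      if (!is.na(open_from) && is_stop[ci]) {
        len <- (ci - open_from + 1L) * 3L
        s0 <- starts[open_from] - 1L  # to 0-based
        better <- len >= min_len &&
          (len > best_len || (len == best_len && s0 < best$start))
        if (better) {
          best <- interval(s0, s0 + len)
          best_len <- len
        }
        open_from <- NA_integer_
      }
    }
  }
  best
}

#' Annotate a transcript with its longest ORF
#'
#' @inheritParams find_longest_orf
#' @return the transcript with `$orf` set (or left `NULL`)
#' @export
annotate_orf <- function(t, min_len = 90L) {
  t$orf <- find_longest_orf(t, min_len = min_len)
  t
}
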