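# Mismatch-tolerant off-target search and safety scoring.
#
# Matching is Hamming-only (no indels), mirroring the zero/low-mismatch
# semantics of short-read aligners run in -v mode. The matcher uses
# pigeonhole seed partitioning: a k-mer matched with at most m mismatches
# must contain at least one of m+1 disjoint exact seeds, which are located
# with an exact substring search and then verified by Hamming count.

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# disjoint seed intervals covering 1..k, m+1 pieces as equal as possible
pigeonhole_seeds <- function(k, m) {
  bounds <- floor(seq(0L, k, length.out = m + 2L))
  data.frame(start = bounds[-length(bounds)] + 1L, end = bounds[-1L])
}

#' Find all near matches of an siRNA target site in a transcriptome
#'
#' Reports every occurrence of the k-mer, or of its reverse complement, in
#' any transcript at Hamming distance at most `m` — matches are looked up
#' regardless of directionality, since either strand of the dsRNA-derived
#' siRNA duplex can silence a transcript. Strand is "sense" when the k-mer
#' itself matches and "antisense" when its reverse complement does.
#'
#' @param site target-site k-mer (DNA, unambiguous)
#' @param transcriptome list of `transcript` objects
#' @param m allowed mismatches, 0, 1 or 2
#' @return data.frame with columns `transcript_id`, `position` (0-based
#'   match start), `strand`, `mismatches`
#' @export
mismatch_hits <- function(site, transcriptome, m = 1L) {
  stopifnot(m %in% 0:2)
  if (grepl("[^ACGT]", site)) stop("ambiguous base in siRNA site")
  k <- nchar(site)
  seqs <- vapply(transcriptome, `[[`, "", "seq")
  ids <- vapply(transcriptome, `[[`, "", "id")
  subject <- Biostrings::DNAStringSet(seqs)
  seeds <- pigeonhole_seeds(k, m)
  queries <- c(sense = site, antisense = revcomp_dna(site))
  out <- list()
  for (strand in names(queries)) {
    q <- queries[[strand]]
    # candidate start positions per transcript from exact seed matches
    cand <- vector("list", length(seqs))
    for (s in seq_len(nrow(seeds))) {
      seed <- substr(q, seeds$start[s], seeds$end[s])
      mt <- Biostrings::vmatchPattern(seed, subject)
      for (ti in seq_along(seqs)) {
        starts <- Biostrings::startIndex(mt)[[ti]]
        if (length(starts) > 0L) {
          cand[[ti]] <- c(cand[[ti]], starts - seeds$start[s] + 1L)
        }
      }
    }
    for (ti in seq_along(seqs)) {
      pos <- unique(cand[[ti]])
      pos <- pos[pos >= 1L & pos + k - 1L <= nchar(seqs[ti])]
      if (length(pos) == 0L) next
      words <- substring(seqs[ti], pos, pos + k - 1L)
      mm <- vapply(words, hamming, 0L, b = q, USE.NAMES = FALSE)
      keep <- mm <= m
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = ids[ti], position = pos[keep] - 1L,
          strand = strand, mismatches = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(), position = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Count off-target transcripts per candidate siRNA for one species
#'
#' The counting unit is transcripts hit (deduplicated), not occurrences;
#' occurrence-level detail remains available via [mismatch_hits()].
#' Essential-gene ids absent from the transcriptome are ignored with a
#' warning.
#'
#' @param sites character vector of target-site k-mers (one per candidate)
#' @param transcriptome list of `transcript` objects
#' @param essential character vector of transcript ids considered essential
#' @param m allowed mismatches (0-2)
#' @return data.frame with one row per candidate: `total_transcripts_hit`,
#'   `essential_transcripts_hit`
#' @export
offtarget_counts <- function(sites, transcriptome, essential = character(),
                             m = 1L) {
  ids <- vapply(transcriptome, `[[`, "", "id")
  unknown <- setdiff(essential, ids)
  if (length(unknown) > 0L) {
    warning("essential ids absent from transcriptome: ",
            paste(head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) " ...")
  }
  total <- integer(length(sites))
  ess <- integer(length(sites))
  for (i in seq_along(sites)) {
    hits <- mismatch_hits(sites[i], transcriptome, m = m)
    hit_ids <- unique(hits$transcript_id)
    total[i] <- length(hit_ids)
    ess[i] <- sum(hit_ids %in% essential)
  }
  data.frame(total_transcripts_hit = total, essential_transcripts_hit = ess)
}

#' Percent-normalized safety scores
#'
#' Each candidate's weighted off-target count is
#' `essential_weight * essential + 1 * (total - essential)`, summed over
#' species with equal species weights. The candidate with the fewest
#' weighted off-targets scores 100 and the one with the most scores 0; when
#' all candidates tie, all score 100.
#'
#' @param counts data.frame from [offtarget_counts()], or a list of such
#'   data.frames (one per species)
#' @param essential_weight weight of an essential-gene transcript hit
#'   relative to an ordinary hit; default 20
#' @return numeric vector of percent scores in \[0, 100\]
#' @export
safety_scores <- function(counts, essential_weight = 20) {
  if (essential_weight < 0) stop("essential_weight must be non-negative")
  if (is.data.frame(counts)) counts <- list(counts)
  w <- 0
  for (cts in counts) {
    stopifnot(all(cts$essential_transcripts_hit <= cts$total_transcripts_hit))
    w <- w + essential_weight * cts$essential_transcripts_hit +
      (cts$total_transcripts_hit - cts$essential_transcripts_hit)
  }
  if (length(w) == 0L) stop("at least one candidate required")
  if (max(w) == min(w)) return(rep(100, length(w)))
  100 * (max(w) - w) / (max(w) - min(w))
}

#' Read an essential-gene id list
#'
#' Plain text, one transcript id per line; blank lines and lines starting
#' with `#` are skipped.
#'
#' @param path file path
#' @return character vector of ids
#' @export
read_essential_ids <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
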