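# Strand-specific mapping of RISC-bound small-RNA reads onto a dsRNA
# template and the downstream profile statistics.
#
# Mapping is exact (zero mismatches): a read maps in sense orientation when
# it is a verbatim substring of the template and in antisense orientation
# when its reverse complement is. All occurrences count, mirroring an
# all-valid-alignments aligner run with zero mismatches.

all_occurrences <- function(needle, haystack) {
  n <- nchar(needle); L <- nchar(haystack)
  if (n > L) return(integer())
  starts <- 1:(L - n + 1L)
  starts[substring(haystack, starts, starts + n - 1L) == needle]
}

#' Map small-RNA reads onto a dsRNA template
#'
#' @param reads character vector of read sequences (DNA alphabet; U is
#'   converted to T), e.g. from [read_fastq()]
#' @param template `transcript` holding the dsRNA template (sense strand)
#' @param profile_length read length used for the positional profile;
#'   default 21, the dominant siRNA length
#' @return object of class `strand_profile`: `template_id`,
#'   `template_length`, `sense`/`antisense` (per-position counts of
#'   21-nt alignment starts, 0-based positions), `total_sense`/
#'   `total_antisense` (21-nt alignment totals), `length_histogram`
#'   (mapped reads by length 16-30), `n_mapped`, `n_unmapped`
#' @export
map_reads <- function(reads, template, profile_length = 21L) {
  stopifnot(inherits(template, "transcript"))
  tmpl <- template$seq
  if (!nzchar(tmpl)) stop("empty template")
  reads <- toupper(chartr("Uu", "TT", reads))
  L <- nchar(tmpl)
  np <- L - profile_length + 1L
  sense <- integer(np); antisense <- integer(np)
  hist <- setNames(integer(15L), 16:30)
  n_mapped <- 0L; n_unmapped <- 0L
  tally <- table(reads)
  for (r in names(tally)) {
    mult <- as.integer(tally[[r]])
    fwd <- all_occurrences(r, tmpl)
    rev_ <- all_occurrences(revcomp_dna(r), tmpl)
    if (length(fwd) + length(rev_) == 0L) {
      n_unmapped <- n_unmapped + mult
      next
    }
    n_mapped <- n_mapped + mult
    len <- nchar(r)
    if (len >= 16L && len <= 30L) {
      hist[as.character(len)] <- hist[as.character(len)] + mult
    }
    if (len == profile_length) {
      for (p in fwd) sense[p] <- sense[p] + mult
      for (p in rev_) antisense[p] <- antisense[p] + mult
    }
  }
  structure(list(template_id = template$id, template_length = L,
                 profile_length = profile_length,
                 sense = sense, antisense = antisense,
                 total_sense = sum(sense), total_antisense = sum(antisense),
                 length_histogram = hist,
                 n_mapped = n_mapped, n_unmapped = n_unmapped),
            class = "strand_profile")
}

#' @export
print.strand_profile <- function(x, ...) {
  cat(sprintf("<strand_profile> %s (%d nt): %d sense / %d antisense %d-nt alignments\n",
              x$template_id, x$template_length, x$total_sense,
              x$total_antisense, x$profile_length))
  invisible(x)
}

#' Percentage of antisense-strand siRNA alignments
#'
#' Only the antisense (guide) strand can direct cleavage of the target
#' mRNA, so a higher antisense fraction indicates more productive RISC
#' loading.
#'
#' @param p `strand_profile`
#' @return percent, `100 * antisense / (antisense + sense)` over the
#'   profile-length alignments
#' @export
antisense_fraction <- function(p) {
  stopifnot(inherits(p, "strand_profile"))
  tot <- p$total_sense + p$total_antisense
  if (tot == 0L) stop("no mapped ", p$profile_length, "-nt reads")
  100 * p$total_antisense / tot
}

#' Extract most- and least-abundant antisense siRNA sequences
#'
#' Ranks antisense site positions (pooled across profiles) by their mapped
#' count and returns the antisense sequences of the top and bottom
#' `fraction`. Ties at the percentile boundary are broken by template/
#' position order for determinism.
#'
#' @param profiles a `strand_profile` or list of them
#' @param templates matching `transcript` or list of them
#' @param fraction tail fraction; default 0.15
#' @return list with character vectors `top` and `bottom` (antisense
#'   sequences, RNA alphabet, 5'->3')
#' @export
abundance_extremes <- function(profiles, templates, fraction = 0.15) {
  if (inherits(profiles, "strand_profile")) profiles <- list(profiles)
  if (inherits(templates, "transcript")) templates <- list(templates)
  stopifnot(length(profiles) == length(templates), fraction > 0,
            fraction < 0.5)
  seqs <- character(); counts <- integer()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]; t <- templates[[i]]
    k <- p$profile_length
    pos <- seq_along(p$antisense)  # 1-based site starts
    site <- substring(t$seq, pos, pos + k - 1L)
    anti <- vapply(site, function(s) dna_to_rna(revcomp_dna(s)), "",
                   USE.NAMES = FALSE)
    seqs <- c(seqs, anti)
    counts <- c(counts, p$antisense)
  }
  n_tail <- max(1L, floor(fraction * length(seqs)))
  # ties broken by template/position order in both directions
  asc <- order(counts, seq_along(counts))
  desc <- order(-counts, seq_along(counts))
  list(bottom = seqs[asc[seq_len(n_tail)]],
       top = seqs[desc[seq_len(n_tail)]])
}

chisq_2x2 <- function(a, b, c, d) {
  # Pearson chi-square without continuity correction on
  # rows (top, bottom) x cols (base, not base)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  n * (a * d - b * c)^2 / denom
}

#' Positional nucleotide composition test between abundance classes
#'
#' For every position and base, compares the base frequency between the two
#' sequence sets with a 2x2 Pearson chi-square test (no continuity
#' correction). P values are Bonferroni-adjusted for the full family of
#' positions x 4 bases (84 tests for 21-nt sequences).
#'
#' @param top character vector of equal-length sequences (RNA or DNA)
#' @param bottom character vector, same sequence length
#' @return data.frame with `position` (1-based), `base`, counts and
#'   proportions per set, `chisq`, `p`, `p_adj`
#' @export
position_composition_test <- function(top, bottom) {
  stopifnot(length(top) > 0L, length(bottom) > 0L)
  top <- chartr("T", "U", toupper(top))
  bottom <- chartr("T", "U", toupper(bottom))
  len <- unique(nchar(c(top, bottom)))
  if (length(len) != 1L) stop("sequences of unequal length")
  bases <- c("A", "C", "G", "U")
  top_m <- do.call(rbind, strsplit(top, "", fixed = TRUE))
  bot_m <- do.call(rbind, strsplit(bottom, "", fixed = TRUE))
  fam <- len * length(bases)
  out <- expand.grid(position = seq_len(len), base = bases,
                     stringsAsFactors = FALSE)
  out <- out[order(out$position, out$base), ]
  rownames(out) <- NULL
  res <- apply(out, 1, function(row) {
    pos <- as.integer(row[["position"]]); b <- row[["base"]]
    a <- sum(top_m[, pos] == b)
    c_ <- sum(bot_m[, pos] == b)
    stat <- chisq_2x2(a, length(top) - a, c_, length(bottom) - c_)
    c(a, c_, stat)
  })
  out$count_top <- res[1, ]
  out$count_bottom <- res[2, ]
  out$prop_top <- out$count_top / length(top)
  out$prop_bottom <- out$count_bottom / length(bottom)
  out$chisq <- res[3, ]
  out$p <- pchisq(out$chisq, df = 1, lower.tail = FALSE)
  out$p_adj <- pmin(1, out$p * fam)
  out
}

#' Read sequences from a FASTQ file
#'
#' @param path FASTQ file (plain or gzip)
#' @return character vector of read sequences
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fastq")
  as.character(set)
}

#' Write reads as FASTQ
#'
#' Constant quality (`I`, Q40) is assigned; the generators operate upstream
#' of quality filtering.
#'
#' @param reads character vector of read sequences (optionally named)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n",
                    vapply(nchar(reads), function(n)
                      strrep("I", n), "")), con)
  invisible(path)
}
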