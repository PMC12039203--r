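# Per-siRNA feature computation.
#
# A candidate siRNA is identified by the 0-based start of its 21-nt target
# site on the transcript (sense orientation). The antisense (guide) strand is
# the reverse complement of the site, written 5'->3' in the RNA alphabet.
# Positions quoted as "10th nt" etc. are 1-based along the antisense strand,
# 5'->3'.

revcomp_rna <- function(x) {
  chars <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  paste(c(A = "U", C = "G", G = "C", U = "A")[chars], collapse = "")
}

#' Enumerate candidate siRNAs along a transcript
#'
#' Every k-mer window of the transcript is a prospective siRNA target site.
#' Windows containing an ambiguous base are excluded and counted in the
#' `n_excluded` attribute. The duplex model is a blunt k-bp duplex (sense
#' strand = reverse complement of the antisense); the 2-nt 3' overhangs of
#' natural siRNAs lie outside the scored tetramers and are not represented.
#'
#' @param t `transcript`
#' @param k siRNA length in nt; default 21
#' @return data.frame with columns `index` (0-based site start), `site`
#'   (sense, DNA), `antisense` (RNA, 5'->3'), `region` ("ORF" when the whole
#'   site lies inside the annotated ORF, else "UTR"); attribute `n_excluded`
#' @export
enumerate_sirnas <- function(t, k = 21L) {
  stopifnot(inherits(t, "transcript"))
  k <- as.integer(k)
  n <- nchar(t$seq)
  if (n < k) stop("transcript shorter than siRNA length ", k)
  starts <- 0:(n - k)
  sites <- substring(t$seq, starts + 1L, starts + k)
  clean <- !grepl("[^ACGT]", sites)
  n_excluded <- sum(!clean)
  starts <- starts[clean]
  sites <- sites[clean]
  antisense <- vapply(sites, function(s) dna_to_rna(revcomp_dna(s)), "",
                      USE.NAMES = FALSE)
  region <- rep("UTR", length(starts))
  if (!is.null(t$orf)) {
    region[starts >= t$orf$start & (starts + k) <= t$orf$end] <- "ORF"
  }
  out <- data.frame(index = starts, site = sites, antisense = antisense,
                    region = region, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "k") <- k
  out
}

#' Thermodynamic end asymmetry of an siRNA duplex
#'
#' Difference between the pairing energy of the first four nucleotides of
#' the antisense strand (its 5' end) and that of the last four nucleotides
#' of the sense strand, both taken inside the paired region (overhangs are
#' excluded by construction of the blunt duplex model). Positive values mean
#' the antisense 5' end is the weaker-paired end, which favors its loading
#' into RISC as the guide strand.
#'
#' @param antisense antisense strand, RNA alphabet, 5'->3', length >= 8
#' @param table `stack_table`
#' @return kcal/mol; positive favors antisense guide selection
#' @export
thermo_asymmetry <- function(antisense, table = default_stack_table()) {
  k <- nchar(antisense)
  if (k < 8L) stop("antisense must be at least 8 nt")
  anti5 <- substr(antisense, 1L, 4L)
  # 5'-terminal tetramer of the sense strand = revcomp of the last four
  # antisense nucleotides
  sense5 <- revcomp_rna(substr(antisense, k - 3L, k))
  nn_duplex_energy(anti5, table) - nn_duplex_energy(sense5, table)
}

#' Composition features of the antisense strand
#'
#' @param antisense antisense strand (RNA or DNA alphabet), length >= 14
#' @return list with `gc_full` (percent GC over the whole strand), `gc_9_14`
#'   (percent GC over 1-based positions 9-14) and `a10` (TRUE when position
#'   10 is adenine)
#' @export
sequence_features <- function(antisense) {
  if (nchar(antisense) < 14L) stop("antisense must be at least 14 nt")
  chars <- strsplit(antisense, "", fixed = TRUE)[[1]]
  gc <- chars %in% c("G", "C")
  list(gc_full = 100 * mean(gc),
       gc_9_14 = 100 * mean(gc[9:14]),
       a10 = chars[10] == "A")
}

#' Binding energy of the antisense strand to its target
#'
#' Nearest-neighbor energy of the full-length antisense strand hybridized to
#' its perfect complement (the target mRNA site).
#'
#' @inheritParams thermo_asymmetry
#' @return kcal/mol
#' @export
antisense_binding_energy <- function(antisense,
                                     table = default_stack_table()) {
  nn_duplex_energy(antisense, table)
}

#' Compute the full per-siRNA feature table
#'
#' One row per candidate siRNA with all raw features. Each scalar equals the
#' value returned by the corresponding single-candidate operation.
#' Accessibility is the expensive column (a partition function per site);
#' it can be switched off when only the default efficacy features are
#' needed.
#'
#' @param t `transcript` (annotate with [annotate_orf()] first to obtain
#'   ORF/UTR labels)
#' @param k siRNA length; default 21
#' @param table `stack_table`
#' @param flank accessibility context width, see [site_accessibility()]
#' @param accessibility compute the accessibility column (default TRUE)
#' @return data.frame: candidate columns from [enumerate_sirnas()] plus
#'   `thermo_asymmetry`, `self_fold_mfe`, `accessibility`, `gc_full`,
#'   `gc_9_14`, `a10`, `binding_energy`
#' @export
compute_feature_table <- function(t, k = 21L, table = default_stack_table(),
                                  flank = 80L, accessibility = TRUE) {
  cand <- enumerate_sirnas(t, k = k)
  cand$thermo_asymmetry <- vapply(cand$antisense, thermo_asymmetry, 0,
                                  table = table, USE.NAMES = FALSE)
  cand$self_fold_mfe <- vapply(cand$antisense, fold_mfe, 0, table = table,
                               USE.NAMES = FALSE)
  if (accessibility) {
    cand$accessibility <- vapply(cand$index, function(i) {
      site_accessibility(t, interval(i, i + k), flank = flank, table = table)
    }, 0)
  } else {
    cand$accessibility <- NA_real_
  }
  comp <- lapply(cand$antisense, sequence_features)
  cand$gc_full <- vapply(comp, `[[`, 0, "gc_full")
  cand$gc_9_14 <- vapply(comp, `[[`, 0, "gc_9_14")
  cand$a10 <- vapply(comp, `[[`, TRUE, "a10")
  cand$binding_energy <- vapply(cand$antisense, antisense_binding_energy, 0,
                                table = table, USE.NAMES = FALSE)
  cand
}

#' Write a feature/score table as TSV
#'
#' Site coordinates are converted to 1-based inclusive `start`/`end` for
#' user-facing output.
#'
#' @param features data.frame from [compute_feature_table()] (optionally
#'   with score columns added)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_feature_table <- function(features, path) {
  out <- features
  out$start <- out$index + 1L
  out$end <- out$index + nchar(out$site[1])
  out$index <- NULL
  front <- c("start", "end")
  out <- out[, c(front, setdiff(names(out), front))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
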