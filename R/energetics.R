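# Thermodynamic backends: nearest-neighbor duplex energies, single-strand
# folding, and target-site accessibility.

# gas constant (kcal/mol/K) times 310.15 K
RT37 <- 0.0019872 * 310.15

.pkg_env <- new.env(parent = emptyenv())

#' Load a nearest-neighbor stack table
#'
#' The table maps each of the 16 dinucleotide stacks (written 5'->3' on the
#' top strand; the partner strand is the Watson-Crick complement) to its
#' helix-propagation free energy at 37 degrees C in kcal/mol. The default is
#' the Watson-Crick parameter set determined by optical melting experiments
#' (Xia et al. 1998). Initiation, duplex-symmetry and terminal-AU penalty
#' terms are deliberately excluded: the asymmetry feature is a difference of
#' two tetramer energies, so such shared constants cancel.
#'
#' @param path delimited text file with columns `stack` and `dg37`; default
#'   the table shipped with the package
#' @return named numeric vector of length 16 (class `stack_table`)
#' @export
load_stack_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_stacks_dg37.tsv",
                        package = "rnaidesign", mustWork = TRUE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("stack", "dg37") %in% names(tab))) {
    stop("stack table needs columns 'stack' and 'dg37'")
  }
  v <- setNames(as.numeric(tab$dg37), toupper(tab$stack))
  bases <- c("A", "C", "G", "U")
  # order must match the C++ backend's 4 * first + second indexing
  expected <- paste0(rep(bases, each = 4), rep(bases, times = 4))
  missing <- setdiff(expected, names(v))
  if (length(missing) > 0L) {
    stop("stack table missing entries: ", paste(missing, collapse = ", "))
  }
  if (any(v >= 0)) stop("all stack energies must be negative")
  structure(v[expected], class = "stack_table")
}

default_stack_table <- function() {
  if (is.null(.pkg_env$stack_table)) {
    .pkg_env$stack_table <- load_stack_table()
  }
  .pkg_env$stack_table
}

check_rna <- function(strand) {
  chars <- strsplit(strand, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop("non-ACGU character '", chars[bad[1]], "' at position ", bad[1])
  }
  chars
}

# encode ACGU -> 0..3 for the C++ backend
encode_rna <- function(chars) {
  match(chars, c("A", "C", "G", "U")) - 1L
}

#' Nearest-neighbor free energy of a perfect RNA duplex
#'
#' The strand is hybridized to its full Watson-Crick complement; the energy
#' is the sum of the `nchar(strand) - 1` stack terms. By duplex rotation
#' symmetry the result is unchanged under reverse complementation.
#'
#' @param strand RNA string (A/C/G/U), length >= 2
#' @param table `stack_table`; default the shipped parameter set
#' @return free energy in kcal/mol (negative)
#' @export
nn_duplex_energy <- function(strand, table = default_stack_table()) {
  stopifnot(is.character(strand), length(strand) == 1L)
  if (nchar(strand) < 2L) stop("duplex needs at least 2 nt")
  chars <- check_rna(strand)
  n <- length(chars)
  stacks <- paste0(chars[-n], chars[-1])
  sum(unname(table[stacks]))
}

#' Minimum free energy of single-strand secondary structure
#'
#' Computes the MFE under a reduced model: Watson-Crick pairs only, minimum
#' hairpin loop of 3 nt, structure energy equal to the sum of
#' nearest-neighbor stacking terms over directly stacked pairs (loops free).
#' The open structure has energy 0, so the result is never positive. The
#' same model drives the accessibility partition function, and is exactly
#' enumerable for verification.
#'
#' @param strand RNA string
#' @param table `stack_table`
#' @return MFE in kcal/mol (<= 0)
#' @export
fold_mfe <- function(strand, table = default_stack_table()) {
  stopifnot(is.character(strand), length(strand) == 1L, nchar(strand) >= 1L)
  chars <- check_rna(strand)
  c_fold_mfe(encode_rna(chars), unname(table))
}

#' Target-site accessibility
#'
#' Mean per-base unpaired probability of the target site under the
#' equilibrium partition function of the reduced folding model, computed on
#' the local subsequence `site` plus `flank` nt on either side (clipped at
#' the transcript ends). Values near 1 mean the site sits in unstructured
#' mRNA context.
#'
#' @param t `transcript`
#' @param site `interval` on the transcript (0-based half-open), typically
#'   one siRNA target site
#' @param flank context width in nt on each side; default 80 keeps the
#'   computation local and desk-scale
#' @param table `stack_table`
#' @return fraction in \[0, 1\]
#' @export
site_accessibility <- function(t, site, flank = 80L,
                               table = default_stack_table()) {
  stopifnot(inherits(t, "transcript"))
  site <- validate_interval(site, nchar(t$seq))
  lo <- max(0L, site$start - flank)
  hi <- min(nchar(t$seq), site$end + flank)
  sub <- substr(t$seq, lo + 1L, hi)
  chars <- strsplit(dna_to_rna(sub), "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "U"))) {
    stop("ambiguous base in accessibility window")
  }
  pos0 <- (site$start - lo):(site$end - lo - 1L)  # 0-based within window
  probs <- c_unpaired_probs(encode_rna(chars), unname(table), pos0, RT37)
  mean(probs)
}
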