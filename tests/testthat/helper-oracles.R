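# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: folding by exhaustive structure enumeration,
# off-target search by position-wise Hamming counting, window selection by
# direct exhaustive search.

oracle_rt37 <- 0.0019872 * 310.15

oracle_stacks <- function() {
  path <- system.file("extdata", "nn_stacks_dg37.tsv", package = "rnaidesign")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$dg37, tab$stack)
}

# independent table lookup: sum of dinucleotide stack energies
oracle_duplex_energy <- function(strand) {
  st <- oracle_stacks()
  chars <- strsplit(strand, "")[[1]]
  tot <- 0
  for (i in seq_len(length(chars) - 1)) {
    tot <- tot + st[[paste0(chars[i], chars[i + 1])]]
  }
  tot
}

oracle_pairable <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC")
}

# enumerate all nested structures (lists of 2-col pair matrices), min
# hairpin loop 3; feasible for n <= ~14
oracle_enumerate <- function(chars, i = 1L, j = length(chars)) {
  if (j - i + 1L < 5L) return(list(matrix(integer(), ncol = 2)))
  out <- list()
  # i unpaired
  for (s in oracle_enumerate(chars, i + 1L, j)) {
    out[[length(out) + 1L]] <- s
  }
  # i paired with k
  for (k in (i + 4L):j) {
    if (!oracle_pairable(chars[i], chars[k])) next
    inner <- oracle_enumerate(chars, i + 1L, k - 1L)
    outer <- oracle_enumerate(chars, k + 1L, j)
    for (s1 in inner) for (s2 in outer) {
      out[[length(out) + 1L]] <- rbind(matrix(c(i, k), ncol = 2), s1, s2)
    }
  }
  out
}

# structure energy under the reduced model: stacks over directly nested
# adjacent pairs
oracle_structure_energy <- function(pairs, chars) {
  if (nrow(pairs) < 2L) return(0)
  st <- oracle_stacks()
  key <- paste(pairs[, 1], pairs[, 2])
  tot <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (paste(i + 1L, j - 1L) %in% key) {
      tot <- tot + st[[paste0(chars[i], chars[i + 1L])]]
    }
  }
  tot
}

oracle_fold_mfe <- function(strand) {
  chars <- strsplit(strand, "")[[1]]
  structs <- oracle_enumerate(chars)
  min(0, vapply(structs, oracle_structure_energy, 0, chars = chars))
}

# Boltzmann unpaired probability per position by enumeration
oracle_unpaired_probs <- function(strand) {
  chars <- strsplit(strand, "")[[1]]
  n <- length(chars)
  structs <- oracle_enumerate(chars)
  w <- vapply(structs, function(s)
    exp(-oracle_structure_energy(s, chars) / oracle_rt37), 0)
  unp <- sapply(seq_len(n), function(p) {
    free <- vapply(structs, function(s) !(p %in% s), TRUE)
    sum(w[free]) / sum(w)
  })
  unp
}

# brute-force Hamming search over every position and both strands
oracle_mismatch_hits <- function(site, transcriptome, m) {
  k <- nchar(site)
  queries <- c(sense = site, antisense = rnaidesign::revcomp_dna(site))
  rows <- list()
  for (t in transcriptome) {
    L <- nchar(t$seq)
    tr <- strsplit(t$seq, "")[[1]]
    for (strand in names(queries)) {
      q <- strsplit(queries[[strand]], "")[[1]]
      mm <- integer(L - k + 1L)
      for (off in seq_len(k)) {
        mm <- mm + (tr[off:(L - k + off)] != q[off])
      }
      hit <- which(mm <= m)
      if (length(hit) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = t$id, position = hit - 1L, strand = strand,
          mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript_id = character(), position = integer(),
                      strand = character(), mismatches = integer()))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$transcript_id, res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

# exhaustive sliding-window search
oracle_select_window <- function(scores, L, k, W, objective = "max") {
  spw <- W - k + 1L
  starts <- 0:(L - W)
  means <- vapply(starts, function(s) mean(scores[(s + 1L):(s + spw)]), 0)
  best <- if (objective == "max") which.max(means) else which.min(means)
  list(start = starts[best], mean = means[best])
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""), "")
}

random_rna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len[i], replace = TRUE),
          collapse = ""), "")
}
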