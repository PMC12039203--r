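# Scoring, window selection and construct building.

# theoretical bounds of the 4-bp duplex energy over all tetramers
tetramer_energy_range <- function(table = default_stack_table()) {
  bases <- c("A", "C", "G", "U")
  tets <- do.call(paste0, expand.grid(bases, bases, bases, bases,
                                      stringsAsFactors = FALSE))
  e <- vapply(tets, nn_duplex_energy, 0, table = table, USE.NAMES = FALSE)
  range(e)
}

minmax_norm <- function(x, lo = min(x), hi = max(x)) {
  if (hi == lo) return(rep(100, length(x)))
  pmin(100, pmax(0, 100 * (x - lo) / (hi - lo)))
}

#' Default efficacy weights
#'
#' Equal weights over the four features significantly associated with
#' insecticidal efficacy (end asymmetry, antisense self-folding energy,
#' GC percent over antisense positions 9-14, adenine at position 10). The
#' remaining features are computed and reported but carry zero weight by
#' default.
#'
#' @return named numeric vector over all supported features
#' @export
default_efficacy_weights <- function() {
  c(thermo_asymmetry = 1, self_fold = 1, gc_9_14 = 1, a10 = 1,
    gc_full = 0, accessibility = 0, binding_energy = 0, region = 0)
}

#' Per-siRNA efficacy scores
#'
#' Each quantitative feature is min-max normalized to \[0, 100\] so that
#' higher means predicted better: asymmetry increases the score (bounds are
#' the theoretical extremes over all tetramers derived from the stack
#' table), self-folding MFE closer to 0 increases it (empirical bounds over
#' the candidate set), GC features are natively percentages, adenine at
#' position 10 maps to 100/0, accessibility uses empirical bounds, binding
#' energy scores stronger (more negative) hybridization higher, and
#' region ORF maps to 100. The efficacy score is the weighted mean of the
#' normalized features.
#'
#' @param features data.frame from [compute_feature_table()]
#' @param weights named non-negative weights; default
#'   [default_efficacy_weights()]
#' @param table `stack_table` used for the theoretical asymmetry bounds
#' @return numeric vector of percent scores in \[0, 100\]
#' @export
efficacy_scores <- function(features, weights = default_efficacy_weights(),
                            table = default_stack_table()) {
  full <- default_efficacy_weights() * 0
  full[names(weights)] <- weights
  if (any(full < 0)) stop("weights must be non-negative")
  if (sum(full) == 0) stop("at least one weight must be positive")
  er <- tetramer_energy_range(table)
  asym_max <- er[2] - er[1]
  norm <- list(
    thermo_asymmetry = minmax_norm(features$thermo_asymmetry,
                                   -asym_max, asym_max),
    self_fold = minmax_norm(features$self_fold_mfe),
    gc_9_14 = features$gc_9_14,
    a10 = 100 * as.numeric(features$a10),
    gc_full = features$gc_full,
    accessibility = if (all(is.na(features$accessibility))) NULL else
      minmax_norm(features$accessibility),
    binding_energy = minmax_norm(-features$binding_energy),
    region = 100 * as.numeric(features$region == "ORF")
  )
  score <- rep(0, nrow(features))
  for (f in names(full)) {
    if (full[f] == 0) next
    if (is.null(norm[[f]])) stop("feature '", f, "' not available")
    score <- score + full[f] * norm[[f]]
  }
  unname(score / sum(full))
}

#' Combine efficacy and safety scores by priority
#'
#' The priority slider sets the relative weight of efficacy versus safety:
#' at 50 the two are averaged; at 80 efficacy counts four times as much as
#' safety; at 100 only efficacy matters.
#'
#' @param efficacy percent vector
#' @param safety percent vector, same length
#' @param priority efficacy priority in \[0, 100\]; default 50
#' @return percent vector `(priority * E + (100 - priority) * S) / 100`
#' @export
combined_scores <- function(efficacy, safety, priority = 50) {
  if (length(efficacy) != length(safety)) {
    stop("efficacy and safety must have the same length")
  }
  stopifnot(priority >= 0, priority <= 100)
  (priority * efficacy + (100 - priority) * safety) / 100
}

#' Select the best-scoring dsRNA window
#'
#' Slides a window of `W` nt one nucleotide at a time over the allowed
#' region (the whole transcript, or the annotated ORF when
#' `restrict_to_orf`), computes for each placement the mean score of the
#' `W - k + 1` siRNA sites lying fully inside, and returns the optimal
#' placement (leftmost on ties). When the allowed region is shorter than
#' `W`, the whole region is returned with `truncated = TRUE` and a warning.
#'
#' @param scores per-candidate percent scores, `scores[i]` belonging to the
#'   site starting at 0-based position `i - 1` (i.e., candidates in
#'   transcript order with none excluded)
#' @param transcript_length length of the transcript in nt
#' @param k siRNA length; default 21
#' @param W window width in nt; default 300
#' @param restrict_to_orf restrict placements to the ORF
#' @param orf `interval` (required when `restrict_to_orf`)
#' @param objective `"max"` (default) or `"min"` (used for worst-region
#'   controls)
#' @return list with `window` (`interval`), `mean_score`, `site_scores`
#'   (scores of the sites inside the window), `restricted_to_orf`,
#'   `truncated`
#' @export
select_window <- function(scores, transcript_length, k = 21L, W = 300L,
                          restrict_to_orf = FALSE, orf = NULL,
                          objective = c("max", "min")) {
  objective <- match.arg(objective)
  n_sites <- transcript_length - k + 1L
  if (length(scores) != n_sites) {
    stop("expected ", n_sites, " scores for a ", transcript_length,
         "-nt transcript (got ", length(scores), ")")
  }
  if (restrict_to_orf) {
    if (is.null(orf)) stop("restrict_to_orf requires an ORF interval")
    lo <- orf$start; hi <- orf$end
  } else {
    lo <- 0L; hi <- transcript_length
  }
  truncated <- FALSE
  if (hi - lo < W) {
    warning("allowed region (", hi - lo, " nt) shorter than window ", W,
            " nt; returning the whole region")
    W <- hi - lo
    truncated <- TRUE
  }
  if (W < k) stop("no candidate sites in allowed region")
  spw <- W - k + 1L  # sites per window
  window_starts <- lo:(hi - W)  # 0-based
  # mean of scores[s+1 .. s+spw] for each window start s via cumulative sums
  cs <- cumsum(c(0, scores))
  means <- (cs[window_starts + spw + 1L] - cs[window_starts + 1L]) / spw
  best <- if (objective == "max") which.max(means) else which.min(means)
  s <- window_starts[best]
  list(window = interval(s, s + W), mean_score = means[best],
       site_scores = scores[(s + 1L):(s + spw)],
       restricted_to_orf = restrict_to_orf, truncated = truncated)
}

#' Build an siRNA-insertion dsRNA construct
#'
#' Inserts a single target-site k-mer into the middle of a neutral backbone
#' (e.g., a GFP sequence with no off-targets in the assayed species), the
#' layout used to assay individual siRNAs within a constant dsRNA context.
#'
#' @param backbone `transcript` or plain DNA string
#' @param site target-site sequence to insert (unambiguous DNA)
#' @return list with `backbone`, `insert`, `insertion_offset` (0-based) and
#'   `template` (final sequence of length `nchar(backbone) + nchar(site)`)
#' @export
build_insertion_construct <- function(backbone, site) {
  if (inherits(backbone, "transcript")) backbone <- backbone$seq
  stopifnot(is.character(backbone), nchar(backbone) >= 2L)
  if (grepl("[^ACGT]", site)) stop("ambiguous base in insert")
  off <- nchar(backbone) %/% 2L
  template <- paste0(substr(backbone, 1L, off), site,
                     substr(backbone, off + 1L, nchar(backbone)))
  list(backbone = backbone, insert = site, insertion_offset = off,
       template = template)
}

#' One-call dsRNA design for a transcript
#'
#' Convenience wrapper tying the pipeline together: ORF annotation, feature
#' computation, efficacy scoring, optional off-target safety scoring, and
#' window selection. The window mean uses combined scores when off-target
#' databases are supplied and efficacy alone otherwise.
#'
#' @param t `transcript`
#' @param k siRNA length; default 21
#' @param W window width; default 300
#' @param restrict_to_orf restrict the window to the ORF
#' @param offtarget_dbs list of transcriptomes (each a list of `transcript`)
#' @param essential_sets list of essential-id character vectors, parallel to
#'   `offtarget_dbs`
#' @param m allowed mismatches for the off-target search
#' @param priority efficacy-vs-safety priority in \[0, 100\]
#' @param weights efficacy feature weights
#' @param accessibility compute the accessibility feature column
#' @param table `stack_table`
#' @return list with `features` (per-siRNA table including score columns),
#'   `window` (result of [select_window()]) and `sequence` (the selected
#'   region)
#' @export
design_dsrna <- function(t, k = 21L, W = 300L, restrict_to_orf = FALSE,
                         offtarget_dbs = NULL, essential_sets = NULL,
                         m = 1L, priority = 50, weights =
                           default_efficacy_weights(),
                         accessibility = FALSE,
                         table = default_stack_table()) {
  t <- annotate_orf(t)
  feats <- compute_feature_table(t, k = k, table = table,
                                 accessibility = accessibility)
  if (attr(feats, "n_excluded") > 0L) {
    stop("transcript contains ambiguous bases; design requires a clean ",
         "sequence")
  }
  feats$efficacy <- efficacy_scores(feats, weights = weights, table = table)
  if (!is.null(offtarget_dbs)) {
    counts <- lapply(seq_along(offtarget_dbs), function(i) {
      ess <- if (is.null(essential_sets)) character() else essential_sets[[i]]
      offtarget_counts(feats$site, offtarget_dbs[[i]], essential = ess, m = m)
    })
    feats$safety <- safety_scores(counts)
    feats$combined <- combined_scores(feats$efficacy, feats$safety, priority)
    score <- feats$combined
  } else {
    score <- feats$efficacy
  }
  win <- select_window(score, nchar(t$seq), k = k, W = W,
                       restrict_to_orf = restrict_to_orf, orf = t$orf)
  list(features = feats, window = win,
       sequence = substr(t$seq, win$window$start + 1L, win$window$end))
}
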