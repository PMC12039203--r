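# Deterministic synthetic-data generators.
#
# Every generator is a pure function of its arguments: when `seed` is given,
# R's RNG state is saved, seeded, and restored, so the same call always
# yields byte-identical output and never perturbs the caller's RNG stream.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Generate a random transcriptome
#'
#' Bases are drawn i.i.d. at the requested GC content; ids are
#' `tx0001, tx0002, ...`.
#'
#' @param n number of transcripts
#' @param length transcript length in nt (scalar, or vector of length `n`)
#' @param gc GC fraction in (0, 1); default 0.5
#' @param seed integer seed (optional but recommended)
#' @return list of `transcript` objects
#' @export
gen_transcriptome <- function(n, length = 1000L, gc = 0.5, seed = NULL) {
  stopifnot(n >= 1L, all(length >= 50L))
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  lens <- rep_len(as.integer(length), n)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      transcript(sprintf("tx%04d", i),
                 paste(sample(names(probs), lens[i], replace = TRUE,
                              prob = probs), collapse = ""))
    })
  })
}

#' Plant a (possibly mutated) target site into a transcript
#'
#' Overwrites the transcript at `position` with `site` carrying exactly
#' `mismatches` substitutions at distinct random offsets; used to build
#' off-target search fixtures with known ground truth.
#'
#' @param t `transcript`
#' @param site sequence to plant (unambiguous DNA)
#' @param mismatches number of substitutions to introduce into the planted
#'   copy; default 0
#' @param position 0-based start of the planted site
#' @param seed integer seed for the mismatch placement
#' @return modified `transcript`
#' @export
plant_site <- function(t, site, mismatches = 0L, position, seed = NULL) {
  stopifnot(inherits(t, "transcript"))
  k <- nchar(site)
  if (position < 0L || position + k > nchar(t$seq)) {
    stop("position out of range")
  }
  if (grepl("[^ACGT]", site)) stop("ambiguous base in site")
  planted <- with_seed(seed, {
    chars <- strsplit(site, "", fixed = TRUE)[[1]]
    if (mismatches > 0L) {
      offs <- sample.int(k, mismatches)
      for (o in offs) {
        chars[o] <- sample(setdiff(c("A", "C", "G", "T"), chars[o]), 1L)
      }
    }
    paste(chars, collapse = "")
  })
  seq <- paste0(substr(t$seq, 1L, position), planted,
                substr(t$seq, position + k + 1L, nchar(t$seq)))
  transcript(t$id, seq, orf = t$orf)
}

#' Generate small-RNA reads from a dsRNA template
#'
#' Fixed-length reads are drawn from template start positions under an
#' optional positional weight vector (uniform by default, emulating the
#' non-uniform but template-wide processing of dsRNA into siRNAs when
#' weights are supplied); the strand of each read is antisense with the
#' given probability.
#'
#' @param template `transcript`
#' @param antisense_fraction percent of reads drawn antisense; default 50
#' @param positional_weights optional non-negative weight per start
#'   position (length `L - read_length + 1`)
#' @param n number of reads
#' @param read_length read length; default 21
#' @param seed integer seed
#' @return named character vector of read sequences (DNA alphabet)
#' @export
gen_reads <- function(template, antisense_fraction = 50,
                      positional_weights = NULL, n = 1000L,
                      read_length = 21L, seed = NULL) {
  stopifnot(inherits(template, "transcript"), n >= 1L)
  L <- nchar(template$seq)
  np <- L - read_length + 1L
  if (np < 1L) stop("template shorter than read length")
  if (is.null(positional_weights)) positional_weights <- rep(1, np)
  if (length(positional_weights) != np) {
    stop("positional_weights must have length ", np)
  }
  with_seed(seed, {
    starts <- sample.int(np, n, replace = TRUE, prob = positional_weights)
    anti <- runif(n) < antisense_fraction / 100
    fwd <- substring(template$seq, starts, starts + read_length - 1L)
    reads <- ifelse(anti, vapply(fwd, revcomp_dna, "", USE.NAMES = FALSE),
                    fwd)
    names(reads) <- sprintf("read%06d", seq_len(n))
    reads
  })
}

#' Generate bioassay survival data under a discrete daily-hazard model
#'
#' Subjects are checked daily; the control group dies with probability
#' `control_hazard` per day, and each treated group with daily probability
#' `1 - (1 - control_hazard)^HR`, which makes the survival curves exactly
#' proportional-hazards at ratio HR. Survivors are censored at `max_day`.
#'
#' @param n_per_group subjects per group; default 20, a typical injection
#'   bioassay cohort
#' @param hazard_ratios named numeric vector of treated-group hazard ratios
#'   (one group per element); names become group labels
#' @param control_hazard control daily death probability; default 0.06
#' @param max_day final observation day; default 14
#' @param seed integer seed
#' @return data.frame with columns `subject`, `group` ("control" plus the
#'   names of `hazard_ratios`), `time`, `event`
#' @export
gen_survival <- function(n_per_group = 20L,
                         hazard_ratios = c(treated = 2.5),
                         control_hazard = 0.06, max_day = 14L, seed = NULL) {
  stopifnot(all(hazard_ratios > 0), max_day >= 2L, n_per_group >= 1L)
  if (control_hazard <= 0 || control_hazard >= 1) {
    stop("control_hazard must be in (0, 1)")
  }
  if (is.null(names(hazard_ratios))) {
    names(hazard_ratios) <- paste0("treated", seq_along(hazard_ratios))
  }
  hazards <- c(control = control_hazard,
               1 - (1 - control_hazard)^hazard_ratios)
  with_seed(seed, {
    rows <- lapply(names(hazards), function(g) {
      h <- hazards[[g]]
      # geometric day of death; censored when beyond max_day
      day <- 1L + stats::rgeom(n_per_group, h)
      event <- as.integer(day <= max_day)
      day[event == 0L] <- max_day
      data.frame(subject = paste0(g, "_", seq_len(n_per_group)), group = g,
                 time = day, event = event, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write a survival table as delimited text
#'
#' Columns `subject`, `group`, `day`, `event`, tab separated — the format
#' read back by [read_survival_table()].
#'
#' @param records data.frame from [gen_survival()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_survival_table <- function(records, path) {
  out <- data.frame(subject = records$subject, group = records$group,
                    day = records$time, event = records$event)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
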