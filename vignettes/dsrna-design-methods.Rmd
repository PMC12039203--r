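---
title: "Methods: models and design choices behind rnaidesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices behind rnaidesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaidesign)
```

## The problem

Long double-stranded RNA (dsRNA) delivered to an insect is diced into ~21-nt
small interfering RNAs (siRNAs). Only the antisense (guide) strand of an
siRNA duplex, once loaded into RISC, silences the target mRNA — so two
dsRNA fragments of the same gene can differ several-fold in insecticidal
efficacy depending on which siRNAs they yield. `rnaidesign` scores every
prospective siRNA along a target transcript for predicted efficacy and
off-target safety, and selects the dsRNA region (300 bp by default) with
the best mean score. Companion modules quantify RISC-bound small-RNA
profiles from sequencing data and analyze the survival bioassays used to
validate designs.

## The efficacy model

For each k-mer target site (k = 21 by default) the package computes:

* **Thermodynamic end asymmetry** (kcal/mol): the pairing energy of the
  first four nucleotides of the antisense strand minus that of the last
  four nucleotides of the sense strand. Positive values mean the antisense
  5' end is the weaker-paired duplex end, which biases RISC toward loading
  the antisense strand as guide — the single best-supported design rule.
* **Antisense self-folding MFE** (kcal/mol, ≤ 0): guides that fold onto
  themselves load poorly; values near 0 are better.
* **GC percent over antisense positions 9–14**: higher values score
  higher. (In insects, stronger pairing around the catalytic center
  correlates with efficacy — note this is the *opposite* direction to the
  rule derived from human therapeutic siRNA data.)
* **Adenine at antisense position 10** (boolean).
* Reported but unweighted by default: whole-strand GC, target-site
  accessibility, antisense:target binding energy, and ORF/UTR region.
  These did not prove predictive for insect dsRNA design; they are still
  computed so users can re-weight them (`efficacy_scores(weights = ...)`).

Quantitative features are min–max normalized to [0, 100] with higher =
predicted better. Asymmetry uses *theoretical* bounds (the energy range
over all 256 tetramers derived from the stack table, ±7.15 kcal/mol for
the shipped parameters); GC features are natively percentages; self-fold
MFE and accessibility have no closed-form extremes and use the empirical
range over the transcript's candidate set, with an all-equal feature
normalizing to 100 for every candidate. The efficacy score is the
weighted mean of the normalized features; the default weights are *equal*
over the four predictive features. The underlying survival-model
coefficients are not re-derivable from printed sources, so we deliberately
do not pretend to a more precise weighting — the weights are a
configuration entry, not a constant.

## Thermodynamic backends

**Duplex energies.** Nearest-neighbor helix-propagation free energies at
37 °C come from the Watson–Crick parameter set determined by optical
melting experiments (Xia et al. 1998), shipped as a plain-text table
(`inst/extdata/nn_stacks_dg37.tsv`, columns `stack`, `dg37`) so an
alternative set can be loaded with `load_stack_table()`. Initiation,
duplex-symmetry and terminal-AU penalties are **excluded**: the asymmetry
feature is a difference of two tetramer energies taken inside the paired
region, so constant terms cancel, and the binding-energy feature is only
ever compared across equal-length candidates.

**Folding and accessibility.** No RNA-folding engine with R bindings is
assumed; the package implements a deliberately reduced model in compiled
code: Watson–Crick pairs only (no G·U wobble), minimum hairpin loop of
3 nt, and structure free energy equal to the sum of nearest-neighbor
stacking terms over directly stacked pairs, with loops free. The same
model drives both the MFE recursion (`fold_mfe()`) and the equilibrium
partition function behind `site_accessibility()`, and it is small enough
to verify *exhaustively*: the test suite enumerates every secondary
structure of short strands and reproduces both the MFE and the per-base
unpaired probabilities to 1e-9. Accessibility is computed on a local
window of the site ± 80 nt (flank configurable); a full-transcript
partition function is neither desk-scale nor better supported
biologically, since long-range pairing predictions are unreliable.
Temperature is fixed at 37 °C.

What the reduced model sacrifices: wobble pairs, loop-size entropies,
dangling ends, and coaxial stacking. Absolute MFE values are therefore
not comparable to full Turner-model engines; within the package the MFE
only enters after min–max normalization across candidates of the same
transcript, where the shared bias largely cancels. Accessibility behaves
correctly in the limits (poly-A context → 1, strong stems → ~0).

## Off-target search and safety score

Every candidate site k-mer and its reverse complement are searched against
each non-target transcriptome at Hamming distance ≤ m (m ∈ {0, 1, 2};
matches are reported regardless of orientation because either strand of
the diced duplex can act as a guide). The matcher splits the k-mer into
m + 1 disjoint seeds — at least one must occur exactly (pigeonhole) — and
verifies seed anchors by direct mismatch counting; the tests prove
equivalence with a position-by-position brute-force oracle at all m.
Indels are not considered, matching the zero/low-mismatch semantics of
short-read aligners used for this task.

The counting unit for scoring is *transcripts hit* (deduplicated), with
essential-gene transcripts weighted 20:1 against ordinary ones (an
essential hit counts 20, a non-essential hit 1; essential hits are not
double-counted in the ×1 term). Counts are summed across species with
equal weight — the simplest defensible pooling; a max-across-species rule
would be a one-line change. The weighted counts are percent-normalized:
fewest off-targets → 100, most → 0, all tied → all 100.

## Window selection and the priority slider

Efficacy (E) and safety (S) combine linearly:
`combined = (priority · E + (100 − priority) · S) / 100`, so priority 50
is the plain average and priority 80 weighs efficacy exactly 4× safety.
The window scan slides a 300-bp window one nucleotide at a time over the
allowed region (whole transcript, or the ORF when restricted), averaging
the combined scores of every siRNA site fully inside; combined scores are
used whenever off-target inputs are supplied, efficacy alone otherwise.
Ties break leftmost; a region shorter than the window is returned whole
with a `truncated` flag. ORFs are annotated as the longest forward-frame
ATG→stop reading frame of at least 90 nt (transcript input is assumed
sense-oriented; the cutoff suppresses spurious micro-ORFs on random
fixtures), with ties broken leftmost. A site must lie *entirely* inside
the ORF to be labeled ORF — a boundary-straddling window should not pass
as ORF-only.

The duplex is modeled blunt (sense = reverse complement of antisense over
all k positions). Natural siRNAs carry 2-nt 3' overhangs; both scored
terminal tetramers lie inside the paired region in either convention, so
the blunt model honors the "excluding overhangs" rule by construction.

## RISC-bound profile analysis

Reads map to a dsRNA template by exact substring matching — sense when
the read occurs verbatim, antisense when its reverse complement does —
with *all* occurrences counted, which is equivalent to a zero-mismatch
all-alignments aligner run. The positional profile is restricted to
21-nt reads (the dominant diced length); a 16–30-nt length histogram
covers the rest. The antisense fraction is the percentage of 21-nt
alignments in antisense orientation.

For motif comparisons, antisense sites are ranked by mapped count (pooled
across templates) and the top/bottom 15% extracted, with percentile-
boundary ties broken by template/position order for determinism. Each
(position, base) cell is tested with a 2×2 Pearson chi-square *without*
continuity correction — the convention that reproduces published values
when counts are reconstructed from rounded percentages — and Bonferroni
adjustment uses the full family of 21 positions × 4 bases = 84 tests.

## Survival statistics

`logrank_hazard_ratio()` is the observed/expected (Mantel–Haenszel style)
estimator: HR = (O_t/E_t)/(O_c/E_c) with χ² = Σ(O−E)²/E on 1 df, matching
the method standard bioassay software describes as "observed versus
expected deaths" — deliberately *not* the Cox-model HR. A one-tailed
option supports planned directional comparisons. Note the O/E estimator
is mildly conservative for larger true ratios; the parameter-recovery
test quantifies this under the package's own generator.

`cox_ph_fit()` delegates the partial likelihood to the `survival` package
with Efron tie handling (daily mortality checks make ties ubiquitous) and
reports Harrell's C with a normal-approximation 95% CI. Constant
covariates are dropped with a warning rather than erroring, since planted
fixture designs legitimately produce them. `hazard_regression()` is OLS
with treatment coding and a selectable reference level, reporting the
multiple R and a Shapiro–Wilk residual-normality p, mirroring the
regression used to attribute dsRNA efficacy to design scores. The paired
t test is the classical formula; identical pairs return the null result
(t = 0, p = 1) while a nonzero constant difference errors, as t is then
undefined.

## The synthetic world

The generators state the world the tests run in:

* `gen_transcriptome()`: i.i.d. bases at a requested GC (default 0.5).
  Real transcriptomes have codon structure, repeats and composition
  gradients; none of that is emulated, so green off-target tests certify
  the *matcher*, not genome-scale hit-rate realism.
* `plant_site()` writes a site with an exact number of substitutions,
  giving the off-target oracle known ground truth.
* `gen_reads()` draws fixed-length reads from template positions under an
  optional weight vector with a chosen antisense fraction. It emulates
  non-uniform processing along a template, not Dicer biology — actual
  processing biases are not well enough understood to simulate.
* `gen_survival()` uses a discrete daily-hazard (geometric) model:
  control daily death probability 0.06, treated groups at
  `1 − (1 − 0.06)^HR`, censoring at day 14 — a two-week assay against an
  essential-gene target with appreciable baseline mortality, chosen a
  priori so that a 200-subject recovery experiment yields enough events
  (~60% control event rate) for the log-rank estimator to be informative.
  Cohort size defaults to 20, a typical injection bioassay.

Every generator saves, seeds, and restores R's RNG, so identical
arguments give byte-identical output and callers' RNG streams are
untouched.

## Numerical conventions

* Internal coordinates 0-based half-open; user-facing positions (TSV,
  "10th nt") 1-based. Conversions happen only at I/O boundaries.
* All ties (ORF choice, window choice, abundance percentiles) break
  toward the leftmost/smallest index.
* Degenerate min–max normalization (all candidates equal) yields 100.
* Candidates whose site contains an ambiguous base are excluded and
  counted, never silently scored.
* The ninth historical efficacy feature is not identifiable from printed
  sources; the feature table carries the eight computable ones and the
  scoring interface accepts arbitrary weight maps, so an extra feature
  can be added without touching the pipeline.

## Limitations

* Efficacy weights are equal-by-default, not fitted; users with bioassay
  data for their species should refit and supply weights.
* The reduced folding model is for ranking within a transcript, not for
  absolute thermodynamics.
* Off-target search is Hamming-only and transcript-level; it does not
  model seed-region-weighted (miRNA-like) off-targeting.
* No primer design, no orthology inference for essential-gene lists, and
  no multi-fragment chimeric designs.
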