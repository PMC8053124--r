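---
title: "Methods: detecting and annotating composite RE-ARE elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and annotating composite RE-ARE elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the model

Transcription factors of the p53 family (p63) and the oxidative-stress
regulator NRF2 recognize distinct DNA consensus elements — the p53-family
response element (RE) and the antioxidant response element (ARE). If the two
elements co-occur within a short stretch of DNA, both factors can occupy the
same enhancer at once and co-regulate the nearby gene. `rearescan` asks the
genome-scale version of that question: are REs and AREs closer to each other
than chance placement would predict, and where do the close pairs sit with
respect to active chromatin and genes?

The analysis is deliberately simple and fully specified:

* **Matching model.** A site is an exact match of a degenerate IUPAC
  consensus — every base of a window must belong to the character class of
  its pattern position. There is no position-weight-matrix score or
  threshold; a consensus string either matches or it does not. This mirrors
  how the binding sequences are summarized from ChIP-seq data as IUPAC
  strings, and makes hit sets reproducible without tuning. The cost is
  all-or-nothing sensitivity: near-matches one mismatch away are invisible.
* **Pairing model.** Each RE is joined to the ARE minimizing the absolute
  *spacer* `n` — the inner gap in bases between the two motif intervals
  (`max(b_start − a_end, a_start − b_end)`; negative means overlap, 0 means
  abutting). Pairing is RE-driven and many-to-one: AREs outnumber REs
  severalfold genome-wide, so an ARE may serve several REs. A strict
  one-to-one mode exists for sensitivity analysis.
* **Null model.** The control genome keeps everything about the observed
  hit lists except their positions: the same *numbers* of RE and ARE motifs
  are re-placed uniformly at random, allocated to chromosomes by
  largest-remainder rounding of `total × L_i / ΣL`, then re-paired with the
  identical procedure. The null is positional only — no nucleotide sequence
  is realized — because only distances feed the downstream statistics.
* **Enrichment statistic.** Experimental and null spacer distributions are
  compared twice: by the fraction of pairs with spacer ≤ 2000 bp (a window
  capturing nucleosome-scale to enhancer-scale co-occurrence), and by a
  two-sample Kolmogorov–Smirnov test over the full distributions. The same
  machinery serves distances between pairs and transcription start sites.
* **Steric rule.** A pair supports simultaneous binding only when its
  spacer strictly exceeds 7 bp, the minimum gap that accommodates a p63
  tetramer and an NRF2–small-MAF dimer side by side regardless of which
  element is upstream. The package encodes only this threshold; no
  structural modeling is performed.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| steric threshold | 7 (strict `>`) | bp | minimum spacer for co-binding |
| enrichment window | 2000 (inclusive `≤`) | bp | short-spacer fraction |
| peak half-width | 300 | bp | center-window containment mode |
| gene association cutoff | 100 000 | bp | closest-TSS assignment |
| pairing window | unlimited | bp | max absolute spacer accepted |
| strands | both | — | scanning strandedness |

The RE and ARE consensus strings themselves are configuration inputs (a
two-column `name<TAB>pattern` table). The package ships documented
placeholders — `RRRCWWGYYYRRRCWWGYYY`, two canonical p53-family half-sites,
and the ARE core `TGACNNNGC` — with realistic information content;
study-specific strings must be supplied to reproduce any published
genome-wide totals.

## Design choices where the procedure was open

* **Strandedness.** Both strands are scanned by default: AREs and
  p53-family REs are functional in either orientation. A window matching on
  both strands (the placeholder RE is its own reverse complement) yields two
  hits; a `dedup` flag collapses same-interval double hits, and all counts
  state which convention produced them.
* **Spacer measured between full matches.** The gap is measured between the
  full IUPAC match intervals, not between "core" sub-sequences, since the
  core annotation is not part of the consensus input.
* **Tie-breaking.** An RE equidistant between two AREs takes the
  lower-coordinate ARE; gene association ties take the lower-coordinate TSS.
  Deterministic ties make reruns byte-identical.
* **Containment.** The default containment interval is the reported peak
  range from the BED file; a ±300 bp window around the peak center is a
  selectable mode, because peak sets defined by summit-centered enrichment
  are sometimes distributed as fixed windows. Both motifs of a pair must lie
  fully inside the interval; a pair straddling the boundary does not count.
  A pair under two overlapping peaks counts once per peak in peak-level
  statistics and once in pair-level statistics.
* **Gene distances from the peak center.** Closest-gene association
  measures |TSS − peak center|, the single-point convention of
  region-to-gene tools; a peak with *k* contained pairs lists its gene *k*
  times so that downstream ontology input weights multi-pair enhancers.
* **KS p-value.** `D` is computed exactly over the merged support (ties are
  handled by exact ECDF evaluation). The p-value is the asymptotic
  `Q(sqrt(ne) · D)` with `ne = n1·n2/(n1+n2)`, evaluated by the alternating
  series `Q(λ) = 2 Σ (−1)^{k−1} e^{−2k²λ²}` summed to convergence — the
  convention of standard statistical software, appropriate for the
  thousands-of-pairs samples this analysis produces. A finite-sample
  corrected λ and a seeded permutation p-value are available as options for
  small samples (below roughly 50 observations per side). Displayed
  p-values floor at `2.2e-16`; stored values keep full precision.
* **Full-distribution KS by default.** The KS test compares the complete
  spacer distributions; a mode restricted to values within the window
  exists, since window-restricted testing answers a subtly different
  question (shape within the window rather than mass into the window).

## The synthetic-data generator

`plant_world()` builds the complete input set — genome FASTA, peak BED, TSS
table — with machine-readable ground truth. It emulates:

* chromosomes of configurable length and GC content (i.i.d. bases);
* RE–ARE pairs planted at non-overlapping loci with spacers drawn from a
  fixed, uniform, or truncated-normal distribution, upstream/downstream
  order randomized 50/50;
* lone decoy REs and AREs scattered away from planted elements;
* peaks as planted-pair spans plus padding (peak calling itself is out of
  scope — only containment logic is under test), plus optional peaks over
  empty background;
* TSS at configured distances from pair spans.

With background exclusion on (the default), windows of the background that
happen to match either motif are re-drawn, and match windows created at
insert junctions are scrubbed afterwards, so the truth table is exact:
scanning recovers precisely the planted and decoy instances. A "dirty
background" mode keeps incidental matches for realism.

What the generator does **not** emulate: genome-scale base composition
structure (isochores, CpG islands, repeats), motif clustering in CpG-rich
promoters, chromatin-dependent peak width variation, and read-level noise.
Passing tests therefore demonstrate correctness of the computational chain
under known truth — recovery of planted signal, exact containment
bookkeeping, calibrated statistics — not biological sensitivity or
specificity on real chromatin.

## Numerical and degenerate-input conventions

* All coordinates are 0-based half-open (BED-native); 1-based TSS dialects
  convert at the read boundary (`one_based = TRUE`).
* `N` is a legal genome character but matches no pattern position, so
  assembly gaps cannot produce hits; soft-masked lower-case bases are
  upper-cased and treated as ordinary sequence.
* Empty RE or ARE hit lists yield empty pair tables, not errors; empty
  distance samples are usage errors for the statistics.
* Randomness flows from one master seed through deterministic
  per-chromosome, per-motif substreams, so placements are reproducible and
  independent of evaluation order. Non-overlapping null placement uses the
  exact gap-transform construction (uniform over feasible configurations)
  rather than rejection.
* Pair sequences exported past a chromosome end are clipped with a warning.

## Problem sizes used in the test suite

The suite validates the scanner against a brute-force per-position matcher
on fifty 10-kb random sequences; pairing against an all-pairs minimizer on
100 random instances; null-model spacing against the exponential
nearest-neighbour closed form at 10 000 motifs on a 1-Gb chromosome; KS
type-I error over 200 same-distribution replicates of 500 spacers; and
planted-signal recovery on twenty 5-Mb worlds with 500 pairs at spacer
~ N(100, 10) bp against matched uniform nulls. These sizes keep the full
suite to a few minutes while leaving each statistical check comfortably
powered.

## Known limitations

* Exact consensus matching cannot rank near-consensus sites; a PWM mode is
  intentionally out of scope.
* The uniform positional null ignores GC and chromatin structure; observed
  enrichment against it conflates sequence composition with genuine
  co-occurrence. A composition-matched null would be the natural extension.
* Published genome-wide totals depend on the exact consensus strings and
  assembly used; with placeholder motifs the pipeline's counts are
  internally consistent but not comparable to any published figure.
* The KS test treats pair spacers as i.i.d.; nearby REs sharing an ARE
  violate independence mildly at high motif density.
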