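# rearescan

Genome-wide co-occurrence analysis of composite **RE–ARE** regulatory
elements: sites where a p53-family (p63) response element (RE) and an NRF2
antioxidant response element (ARE) lie close enough together that both
transcription factors can bind the same enhancer simultaneously.

The package is aimed at regulatory genomicists studying transcription-factor
cross-talk (here, the p63–NRF2 axis of keratinocytes). It provides the full
computational chain:

1. **Motif scanning** — IUPAC degenerate consensus strings (e.g.
   `RRRCWWGYYYRRRCWWGYYY` for the p63 RE, `TGACNNNGC` for the ARE core) are
   matched exactly on both strands of a genome; assembly gaps (`N`) never
   match. The exact consensus strings are configuration inputs.
2. **Nearest-neighbour pairing** — every RE is joined to the ARE minimizing
   the absolute *spacer* `n`, the inner gap in bp between the two motif
   matches (negative when they overlap). A pair is sterically feasible for
   simultaneous p63/NRF2 binding when `n > 7` bp.
3. **Randomized-genome null** — the same numbers of RE and ARE motifs are
   re-placed uniformly at random, allocated to chromosomes proportionally to
   length (largest-remainder rounding), and re-paired identically.
4. **Enrichment statistics** — the experimental and null spacer (or
   TSS-distance) distributions are compared by the fraction of pairs within
   a 2000-bp window and a two-sample Kolmogorov–Smirnov test
   (`D = sup_x |F_exp(x) − F_null(x)|`, asymptotic p from the Kolmogorov
   distribution).
5. **Chromatin annotation** — a pair sits under a ChIP-seq peak iff both
   motifs are fully inside the peak interval (or a ±300-bp window around the
   peak center); per-state percentages, unique/common peak sets between two
   cell states, and closest-gene association within 100 kb (duplicated per
   contained pair) follow.
6. **Synthetic worlds** — a generator plants RE–ARE pairs at controlled
   spacers with decoys, peaks and TSS plus a machine-readable truth table,
   so the whole pipeline is testable without downloads.

## Worked example

```r
library(rearescan)

# a synthetic 500-kb genome with 50 planted RE-ARE pairs (spacer ~ N(100, 10)),
# decoy motifs, enhancer-like peaks over half the pairs, and 30 TSS
cfg <- synthetic_world_config(
  chrom_lengths = c(chr1 = 500000), n_planted_pairs = 50,
  spacer = list(kind = "normal", mean = 100, sd = 10),
  n_decoy_re = 10, n_decoy_are = 60,
  peak_coverage = 0.5, peak_padding = 150,
  n_background_peaks = 25, n_tss = 30, seed = 7
)
world <- plant_world(cfg)

motifs <- default_motifs()
scan <- scan_genome(motifs, world$genome, dedup = TRUE)
pairs <- pair_nearest(scan$hits[scan$hits$motif == "RE", ],
                      scan$hits[scan$hits$motif == "ARE", ])
head(pairs[, c("chrom", "re_start", "are_start", "spacer", "orientation")], 3)
#>   chrom re_start are_start spacer  orientation
#> 1  chr1     5724      5855    111  RE_upstream
#> 2  chr1    18678     18794     96  RE_upstream
#> 3  chr1    21846     20755   1082 ARE_upstream

spec <- null_genome_spec(chrom_lengths(world$genome),
                         n_re = sum(scan$hits$motif == "RE"),
                         n_are = sum(scan$hits$motif == "ARE"),
                         re_length = motifs$RE$length,
                         are_length = motifs$ARE$length, seed = 7)
compare_real_vs_null(pairs, simulate_null_pairs(spec)$pairs, window = 2000)
#> Experimental vs null distance comparison
#>   n (experimental / null): 60 / 60
#>   fraction within 2000 bp: 0.9167 (experimental) vs 0.5833 (null); difference 0.3333
#>   KS: D = 0.816667, p = < 2.2e-16

ann <- pairs_under_peaks(pairs, world$peaks)
percentage_with_pairs(ann)
#>      mark     state n_peaks n_with_pairs n_pairs_total percent_with_pairs
#> 1 H3K27ac synthetic      50           25            25                 50
```

The spacer distribution of recovered pairs is strongly shifted toward short
gaps relative to the randomized null (91.7% vs 58.3% within 2000 bp; KS
D = 0.82): the planted co-occurrence signal is detected. Half of the peaks
contain a pair, matching the generator's 50% coverage, and every
pair-containing peak is associated with its closest TSS within 100 kb.

To analyze real data, supply a genome FASTA, a motif table
(`name<TAB>IUPAC pattern` for `RE` and `ARE`), peak BED files and TSS
tables to `analysis_config()` / `run_full_analysis()`, or use the
subcommand wrapper `inst/cli/reare.R` (`scan`, `pair`, `nullsim`, `stats`,
`annotate`, `associate`, `export-seqs`, `simulate`, `run-all`).

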