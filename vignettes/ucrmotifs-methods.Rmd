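---
title: "Methods: motif discovery, scoring and co-regulation networks in upstream control regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif discovery, scoring and co-regulation networks in upstream control regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucrmotifs)
library(dplyr)
```

## The problem

When a microarray or RNA-seq experiment yields a set of co-upregulated
genes — say cuticular-protein (CP) and muscle genes induced together during
insect metamorphosis — the natural follow-up question is whether they share
cis-regulatory elements that could explain the co-regulation. `ucrmotifs`
implements that follow-up as a reusable, fully testable pipeline:

1. build an **upstream control region (UCR)** database from genome and
   annotation (3 kb cap, trimmed at flanking genes);
2. discover candidate motifs de novo in the upregulated group's UCRs;
3. score each candidate's **group specificity** against the UCR universe
   with three statistics (Church hypergeometric score, ROC-AUC, binomial
   enrichment) behind a two-stage filter;
4. match retained motifs to known transcription-factor binding sites in a
   TRANSFAC-format library at a PSSM-identity threshold;
5. assemble a bipartite **motif–gene network** over gene categories and ask
   which motifs are shared between categories (e.g. CP and muscle).

Because genome-scale inputs and licensed motif libraries cannot ship with a
package, every stage is exercised end to end on synthetic promoter data
with planted motifs and a known ground truth. The simulator is first-class,
tested code, and its defaults *are* the benchmark conditions reported by
`scripts/acceptance.R`.

## Upstream control regions

A gene's UCR is the intergenic sequence immediately 5' of its start, capped
at `requested_length` (default 3000 bases) and trimmed wherever another
annotated gene body bounds the region. Coordinates are 0-based half-open
throughout; the returned sequence reads 5'→3' toward the gene, so
minus-strand UCRs are reverse-complemented. Two deliberate interpretations,
both configurable and recorded here because annotation conventions differ:

* **Gene bodies stand in for ORFs.** Most non-model annotations lack
  UTR/TSS resolution, so the trimming boundary is the annotated gene
  interval, and the "promoter" is really *upstream intergenic sequence*.
* **Neighbours on either strand trim.** A flanking gene bounds the region
  regardless of its strand; an opposite-strand neighbour's sequence is no
  less genic.

Regions shorter than `min_length` (default 30 bases — narrower windows
cannot host a motif plus context) are excluded with a recorded reason. A
brute-force interval oracle in the test suite checks the rule, including
strand mirroring, on 1000 random annotations.

## PSSMs and the two similarity currencies

Motifs are position-specific scoring matrices (PSSMs): 4 × width
base-frequency columns. Two distinct comparisons recur and deliberately use
two distinct, documented metrics:

**Site similarity** (sequence window vs PSSM) is the mean over columns of
`f[base] / max(f)`, times 100. On a consensus-built PSSM this is exactly
the fraction of positions whose base the consensus allows, so thresholds
like "at least 70% similar to YCAAGGTCR" reproduce mismatch-count
semantics: a width-9 window passes 70% iff it has ≤ 2 disallowed
positions. The test suite confirms this equivalence by brute force over all
4⁹ windows. An `N` base contributes 0 at its column.

**PSSM identity** (PSSM vs PSSM) is the mean allele-sharing coefficient
`1 − ½·Σ|fa − fb|` over the overlapping columns, times 100, maximised over
all ungapped offsets and the reverse complement. It is bounded, symmetric,
and — unlike correlation — defined on zero-variance columns. The overlap
floor `max(4, 0.75 × shorter width)` blocks spurious short alignments.
Ties resolve to the smallest offset, forward orientation first.

## De novo discovery: ZOOPS Gibbs sampling

The internal finder is a zero-or-one-occurrence-per-sequence (ZOOPS) Gibbs
sampler. Per restart: one random site per sequence; then sweeps in which
each sequence's site is removed, the PSSM is rebuilt from the remaining
sites (pseudocount 0.25), and the site is resampled — any window on either
strand, or no site — with weight proportional to the likelihood ratio
against a background model fitted on the input. The per-sequence prior that
a site exists is 0.5 (neutral). The best alignment per restart is kept by
MAP score; restart winners are deduplicated at 95% PSSM identity.

The background is an **order-1 Markov model by default**. This matters:
realistic intergenic sequence is autocorrelated, and under an order-0
background the sampler's best "motifs" are homopolymer runs, which an
order-1 model prices correctly. Order 0 remains available for analytic
tests.

The MAP score of an alignment is

    MAP = Σ_sites log2 [ P(site | PSSM) / P(site | background) ]
          − n_sites · log2(T),

with `T` the total number of admissible window positions in the sequence
set. The penalty term charges each site for the positional uncertainty of
where it could have sat; a motif only scores positively when its per-site
log-likelihood ratio beats `log2 T`. With 20 × 400 bp sequences,
`log2 T ≈ 12.9`, which is why only well-conserved 8-mers (≈ 1.7+
bits/column as empirically estimated with pseudocounts) can clear the
`MAP > 5` filter — a feasibility analysis that fixed the simulator's
default planted motif (below).

Significance for internal motifs is a Monte-Carlo proxy: rerun discovery on
`n` dinucleotide-shuffled copies (Altschul–Erickson Eulerian-walk shuffle,
preserving dinucleotide counts exactly) and report
`(1 + #{shuffled best MAP ≥ observed}) / (n + 1)`. With the default 19
shuffles the floor is 0.05, and the stage-1 filter requires internal motifs
to sit at that floor. Imported motifs (MEME minimal format) carry a genuine
E-value and are filtered at the printed `E ≤ 1e-05` instead. The null
best-MAP distribution depends only on the sequence set and width, so the
pipeline computes it once and shares it across that run's motifs.

## Specificity scoring and the filter cascade

Presence of a motif in a sequence means ≥ 1 scan hit at the presence
threshold; counts are per sequence, never per occurrence, which keeps the
hypergeometric model exact. With `x` of `s` group sequences and `X` of `N`
universe sequences positive:

* **Church score** — hypergeometric upper tail `P(K ≥ x)`,
  `K ~ Hypergeom(N, X, s)`;
* **enrichment score** — binomial upper tail `P(B ≥ x)`,
  `B ~ Binomial(s, X/N)` (the enrichment model is not uniquely pinned down
  in the source literature; the binomial reading is implemented and
  flagged);
* **ROC-AUC** — normalised Mann–Whitney U on per-sequence best scan
  similarities, ties credited 0.5.

The cascade retains motifs passing stage 1 (`MAP > 5`, and the E-value or
proxy rule above) and stage 2 (`Church ≤ 1e-04`, `AUC ≥ 0.7`,
`enrichment ≤ 0.01`). The universe is all genes with a valid UCR. No
multiple-testing correction is applied across motifs — the cascade applies
fixed thresholds and reports raw values so users may correct downstream.

### Why the presence threshold defaults to 88, not 70

The 70% threshold is the right semantics for *reporting consensus sites*
(`ftzf1_site_analysis()` keeps it). It is the wrong operating point for
*presence calls on short motifs*: for an 8-column motif, ≥ 70% means ≤ 2
mismatches, and a 400 bp sequence contains such a window by chance with
probability ≈ 0.96 — presence saturates and Church/enrichment become
uninformative (this saturation is also the realistic explanation for
consensus scans coming back non-significant on 3 kb regions). The presence
default was therefore calibrated on synthetic benchmarks: 88 sits just
above the score of a 1-mismatch window on a sharply conserved 8-mer
(≈ 87.8) and well below genuine instance scores (≈ 95–100). Stricter calls
(e.g. 90) start to reward *overfitting* — a motif scored on the very group
that produced it counts its own training sites in `x` while chance support
in the universe vanishes — and measurably inflate the null false-pass rate.
The packaged null calibration (no planted motif, random group labels)
yields a stage-2 false-pass rate of 2.5% at 88 over its 200 datasets;
re-estimates on independently seeded null collections put the rate in the
3–6% band, so the control is real but not generous — stage 1 and the
Church gate carry most of the specificity.

## TF matching and the consensus analysis

Retained motifs are aligned to every record of a TRANSFAC-format library;
all pairs at ≥ 70% PSSM identity are reported, sorted by identity, so one
motif may legitimately resemble several factors. Licensed TRANSFAC matrices
cannot be redistributed: the package ships the format reader/writer and
builds synthetic libraries (planted motif + sharply conserved decoys) for
benchmarking. The FTZ-F1 analysis builds a PSSM from the consensus
`YCAAGGTCR`, scans group UCRs at 70% site similarity, and evaluates the
same three statistics for the consensus motif.

## The co-regulation network

`build_network()` draws one edge per (motif, gene) pair with at least one
hit in the gene's UCR at the scoring threshold, annotated with occurrence
count and best similarity; motif nodes carry their matched TFs and gene
nodes their category. `shared_motifs()` is exactly the predicate "adjacent
to ≥ 1 gene of each category"; the full network keeps all motifs so the
shared view is a restriction, not a loss. Export is GraphML (round-trips
through igraph) or an annotated TSV edge list. Whether network edges should
require filter-passing hits only is genuinely open; edges here use the same
scanning threshold as scoring, so the network is consistent with the
statistics printed beside it.

## The synthetic benchmark

`simulation_config()` defaults define the benchmark:

| parameter | default | why |
|---|---|---|
| genes | 200 (one contig) | universe of N = 200 UCRs |
| foreground | 10% (20 genes, half CP / half muscle) | group size s = 20 |
| intergenic spacing | uniform 420–520 bp | ~400 bp UCRs at the 400 bp cap |
| background | order-1 Markov, uniform composition | autocorrelated but stationary-exact |
| planted motif | 8-mer `TTGACCGA`, conservation 0.985 (1.86 bits/column) | the weakest class that can clear `MAP > 5` at these sizes (feasibility analysis above); instances are *sampled* from the PSSM, not consensus-copied |
| occupancy | 0.9 | 90% of foreground UCRs carry one instance |
| decoys | 5 library motifs, conservation 0.9–0.99 | non-trivial matching competition |

The order-1/order-2 backgrounds mix a "copy previous base" component with
i.i.d. draws from the configured composition, which adds short-range
autocorrelation while keeping the stationary distribution exactly equal to
the configured composition. What the simulator does **not** emulate — and
what passing benchmarks therefore cannot certify on real data — includes
isochore/GC heterogeneity, repeats and low-complexity tracts beyond order-1
autocorrelation, co-occurring motif modules, and annotation error.
Every operation takes an explicit seed, uses a private RNG stream, and
restores global random state; identical configurations are byte-identical
across runs.

Problem sizes for the packaged checks were chosen so the whole suite runs
comfortably on a single core: 10 seeded end-to-end pipeline runs (20-group
vs 200-universe), 200 null datasets (60 sequences, 15-sequence random
group) for the specificity calibration, 1000 random annotations for the
UCR oracle, and all 262,144 9-mers for the consensus-semantics check. The
sampler effort defaults in `run_motif_pipeline()` (6 restarts × 400 sweeps
with early stopping; 19 shuffled null sets at 2 × 150) were set where the
benchmark recovery became stable; `gibbs_discover()` itself defaults
higher (10 × 500) for standalone use.

## Numerical and degenerate-input choices

* PSSM columns must sum to 1 within 1e-9; all-zero count columns with zero
  pseudocount are errors, not NaNs.
* Sampler weights are exponentiated after subtracting the running maximum;
  windows containing `N` get −∞ motif log-likelihood and can never be
  selected.
* `pssm_identity()` ties break to the smallest offset, forward first;
  deduplication keeps the higher-MAP representative.
* Sequences shorter than the motif scan to an empty hit table, not an
  error; discovery on such sequences is an error (the width is infeasible).
* Percentages in the reporting module reproduce printed-table conventions:
  array shares to 1 decimal, gene-set shares to 2 decimals, and platform
  concordance *truncated* to 1 decimal (58/72 → 80.5), because that is how
  the published ratio it mirrors was printed; the mode is documented in
  `concordance()`.
* Protein masses use average residue masses plus one water (monoisotopic
  by flag); `GGY`/`GGYGG` are amino-acid literals (Y = tyrosine) and may
  overlap.

## Known limitations

* The finder is one ZOOPS sampler, not an ensemble of three external
  programs; motif-width selection is manual and gapped motifs are out of
  scope.
* The "70% similarity" and "70% identity" thresholds are necessarily
  re-specified here (site similarity and allele-sharing identity); other
  reasonable metrics would shift absolute percentages.
* Scoring a motif on the group that produced it carries selection bias;
  the Church gate and the calibrated presence threshold control but do not
  eliminate it. Held-out designs are the principled fix and are possible by
  splitting the group before discovery.
* UCRs are upstream intergenic proxies for promoters; without TSS/UTR
  annotation, true promoters may be missed or mislocated.
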