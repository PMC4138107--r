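---
title: "Motif-grammar classification of classical PTP domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-grammar classification of classical PTP domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptpscan)
```

## The problem

Classical (Class I soluble) protein tyrosine phosphatases (PTPs) share a
catalytic domain organized around ten conserved sequence motifs.  Four of
them build the active site: the KNRY loop (motif 1) that recruits the
phosphotyrosine, the WPD loop (motif 8) carrying the general-acid
aspartate, the P-loop (motif 9, the HCX5R signature) containing the
nucleophilic cysteine, and the Q loop (motif 10) that positions the
hydrolytic water.  The other six motifs stabilize the fold.  A domain with
all catalytic motifs intact is an active enzyme; domains with degenerate or
missing active-site motifs are pseudophosphatases, which typically work as
adaptors rather than catalysts.

`ptpscan` classifies PTP repertoires on this motif grammar: per-motif
competence calls, constellation-based domain detection in full-length
proteins, gene-level repertoire summaries, a percent-identity /
neighbor-joining stage for evolutionary context, and an
efficiency-corrected comparative-Ct stage for the expression experiments
that typically accompany such surveys (in the mosquito system these are
qPCR panels normalized to the rp49 housekeeping transcript, plus egg-count
assays).

## The motif grammar

The competence rules are degenerate residue patterns shipped as data
(`inst/extdata/ptp_motifs.tsv`), not hard-coded logic, because reasonable
people can disagree on the exact boundary between "conserved" and
"degenerate".  The packaged defaults are:

| motif | role | competent iff |
|---|---|---|
| 1 (KNRY) | substrate recruitment | `[KR].{0,2}R.?[YF]` — a basic residue, then R, then an aromatic |
| 8 (WPD)  | general acid | contiguous `WPD` |
| 9 (P-loop) | nucleophile | `HCSAG[IVLM]GR` — Cys in a C-x5-R frame with the PTP-specific SAG context |
| 10 (Q loop) | water positioning | a 9-residue window with Gln at positions 2 and 6 |

Three rules are worth spelling out.  First, the aromatic slot of motif 1
accepts phenylalanine as well as tyrosine: the *A. aegypti* reference
table calls `NKARNF` competent, so the grammar honors F at that position.
Second, ambiguity codes (B, Z, X) never satisfy an anchor position —
competence requires a confirmed catalytic residue.  Third, regions shorter
than a pattern's minimal span are `INACTIVE`, not an error, because
published tables print truncated degenerate motifs (e.g. `LWPKQSA`).

The packaged ten-protein reference table (`table1_motifs()`) is the
regression surface: the grammar reproduces every printed per-motif status
and every domain verdict, and the test suite enforces 100% agreement.

A domain is catalytically `ACTIVE` iff motifs 8, 9 and 10 are all
competent.  Motif 1 does not gate the verdict: the reference repertoire
contains an active enzyme whose KNRY loop is absent entirely, and motif 1
is a recruitment element, not a catalytic one.

## Domain scanning by motif constellation

Profile-HMM searches (Pfam `Y_phosphatase`) are the field's standard
domain detector; `ptpscan` replaces them with a deterministic,
configuration-driven constellation search so that every decision is
inspectable:

1. **Anchors.** Candidate P-loops are (a) every match of the relaxed
   `C-x5-R` frame and (b) anchors predicted from clusters of two or more
   core-motif hits via their registry offsets.  Route (b) rescues domains
   whose catalytic cysteine has been lost.
2. **Windows.** Each motif is searched in an offset window around the
   anchor (KNRY at −170 ± 50, WPD at −42 ± 18, Q loop at +50 ± 20, cores
   in between), offsets taken from the canonical PTP1B-like architecture.
   Among multiple matches the one closest to its expected position wins;
   ties go to the leftmost.
3. **Verdict.** A candidate locating at least 5 of the 10 motifs,
   including a located P-loop region, is a `WELL_FORMED` domain.  Core
   clusters that fail this test and contain no `C-x5-R` frame in their
   span are `DEGENERATE` ("absent") domains — the pseudophosphatase
   signature.
4. **Overlaps.** Candidates with more located motifs win; ties break to
   the leftmost start, so output is deterministic.

Boundaries are padded 30 residues upstream of the most upstream located
motif and 20 downstream of the Q loop, clipped to the sequence.  All
constants are configuration (`scan_params()`); boundaries of degenerate
domains are heuristic and not a validated surface.  Coordinates in all
reports are 1-based inclusive; `coords_to_base0()`/`coords_to_base1()`
convert to 0-based half-open and back, and the conversion is tested as an
exact round trip.

## Phylogenetics

Distances are `1 − identity/100` from pairwise global alignments
(Needleman–Wunsch, BLOSUM62, gap open 10 / extend 1, identity denominator
= full alignment length including gap columns).  This replaces the
progressive multiple alignment used in the original analyses — pairwise
distances are reproducible without an MSA stage and feed neighbor joining
directly; qualitative clusterings, not exact figure topologies, are the
validated surface.  A BLAST-style local mode is available because
published identity percentages do not always state their alignment
protocol.

Neighbor joining is the classical Saitou–Nei algorithm with two
determinism rules: ties on the Q-criterion break by lexicographic
taxon-pair order, and negative branch estimates are clamped to zero with
the deficit moved to the sister branch (Kuhner–Felsenstein), preserving
path lengths.  On additive matrices the algorithm is consistent — the
test suite checks exact recovery of random 4–8 taxon trees, branch
lengths included — and on the synthetic family generator it recovers the
true topology (Robinson–Foulds 0) in ≥95% of seeded replicates.

## Expression analysis

The comparative-Ct method and per-primer efficiency correction are
unified as the Pfaffl ratio

$$\mathrm{ratio} = \frac{E_t^{-\Delta Ct_t}}{E_r^{-\Delta Ct_r}},
\qquad \Delta Ct = \overline{Ct}_{\text{condition}} -
\overline{Ct}_{\text{calibrator}},$$

which reduces to the textbook $2^{-\Delta\Delta Ct}$ exactly when both
efficiencies equal 2; both modes are exposed (`ddct_mode`).  Replicates
aggregate by arithmetic mean of Ct (the geometric-mean equivalent on the
expression scale); no outlier handling is applied.  Standard errors
propagate from the replicate ΔCt spread by the delta method:
$\mathrm{Var}(\ln \mathrm{ratio}) = (\ln E_t)^2\mathrm{Var}(\Delta Ct_t) +
(\ln E_r)^2 \mathrm{Var}(\Delta Ct_r)$.  The calibrator is always an
explicit argument — baselines differ between designs and should never be
guessed.  Egg production normalizes to eggs per female per cage.

ANOVA and the pooled t test are computed from explicit sums of squares —
with the convention that identical constant groups give F = 0 (no
between-group signal) rather than 0/0 — and are cross-checked against
`stats::oneway.test` / `stats::t.test` and hand oracles at 1e-10.
Studentized-range post-hoc tests (Tukey) are out of scope; reports carry
the omnibus F and p only.

One analytic note on recovery precision: with triplicate wells, replicate
noise of sd $\sigma$ cycles gives
$\mathrm{sd}(\Delta\Delta Ct) = \sigma\sqrt{4/3}$, i.e. a multiplicative
ratio error of $2^{\sigma\sqrt{4/3}}$.  At $\sigma = 0.2$ that is ±17%
(one sigma), so individual fold estimates at realistic noise are not
expected inside ±15% with high probability; the estimator is, however,
median-unbiased, and the validated property is a median relative bias
below 5% across the fold × noise grid.

## The synthetic-data generator

The generator exists so that every stage is testable offline with known
truth.  Its defaults are the study conditions used throughout the tests:

* **Proteomes** — proteins carry 0–2 planted cassettes (probabilities
  0.15/0.65/0.20) separated by uniform-composition flanks of 60–150
  residues.  Well-formed cassettes embed the ten template motifs at their
  canonical offsets (245 residues around the anchor); lesioned cassettes
  mutate catalytic anchor residues (D of WPD, C of the P-loop, the first
  Q of the Q loop, the motif-1 aromatic); degenerate cassettes carry core
  motifs only and are cysteine-free, so they can never present a P-loop
  frame.  The `table1` preset plants the published motif strings verbatim
  (10 proteins, 8 loci, 13 domains) with cysteine-free flanks, so the
  planted frames are the only anchors and the fixture scan is exact.
* **Families** — 8 taxa, 300-residue root, branch lengths uniform on
  0.05–0.15 substitutions/site (typical within-family PTP divergence),
  point mutations only (no indels or codon models).
* **Ct tables** — fold changes on {0.5, 1, 2, 4}, replicate noise sd
  0.1–0.3 cycles, triplicates, efficiencies 2.0 by default (the
  underlying assays report ≥95% primer efficiency, i.e. ≥1.95).
* **Egg tables** — Poisson egg counts over cages of 10–15 females.

Uniform background composition keeps false motif-hit rates analytically
estimable (a `C-x5-R` frame appears in roughly half of random 300-mers,
which is why the constellation threshold, not the anchor alone, carries
the specificity).  What the generator does **not** emulate: real amino
acid composition biases, indels, splice-variant structure beyond shared
cassettes, correlated qPCR noise, or plate effects.  Passing tests
therefore demonstrate correctness of the algorithms under controlled
conditions, not detector performance on real proteomes — on real data the
windows and patterns are expected to need the same curation any
motif-based annotation needs.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script use: 1000 random
300-mers for the false-positive rate, 200 seeded proteomes for
recall/status agreement (thresholds 0.95), 100 seeded families for
topology recovery (threshold 0.95), 25 random additive matrices for NJ
consistency, 500 replicates per cell of the 4 × 3 fold/noise grid for
ΔΔCt bias, and 50 random pairs against a brute-force affine-gap DP oracle
(exact score equality).  These sizes put Monte-Carlo error well below
each threshold's margin while keeping a full run in the low minutes on
one core.

Tie-breaking and degeneracy rules are deterministic everywhere: motif
matches prefer the expected offset, candidate domains prefer more located
motifs then the leftmost start, NJ ties break lexicographically, and all
generators are pure functions of their seed.

## Known limitations

* The scanner's window search can read noise in an offset window as a
  degenerate motif (status `INACTIVE` where the truth is `ABSENT`); this
  caps per-motif status agreement near 96–97% on synthetic proteomes.
  Domain-level verdicts are unaffected in all tested conditions.
* A domain that loses its P-loop cysteine *and* all core motifs is
  invisible to both anchor routes; such doubly-degenerate domains are not
  recoverable by constellation search.
* Degenerate-domain boundaries are heuristic (cluster span plus padding).
* The identity comparison against external reference enzymes (e.g. human
  PTP1B) requires user-supplied sequences; the package ships no external
  proteins.
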