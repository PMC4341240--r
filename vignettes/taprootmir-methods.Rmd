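---
title: "Methods: staged small-RNA miRNA discovery and differential expression"
author: "taprootmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged small-RNA miRNA discovery and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taprootmir)
```

`taprootmir` re-implements, as tested and reusable functions, the analysis
chain used for profiling small RNAs across three developmental stages of a
plant storage root (pre-cortex splitting, cortex splitting, and expanding
taproot, sampled at 10/20/40 days after sowing): read cleaning, unique-tag
collapsing, hierarchical annotation, novel miRNA prediction from hairpin
folding, per-million normalization with exact-test differential-expression
(DE) screening, plant miRNA target scanning, and 2^-ddCt RT-qPCR
arithmetic. Everything runs against a synthetic reference bundle with
fully known planted truth, so each stage can be validated without
external databases or sequencing archives.

## Read cleaning and library accounting

A raw read is screened in a fixed order, first failure wins:

1. **Quality**: any `N`, more than 4 bases with Q < 10, or more than 6
   bases with Q < 13 — the read does not count as high-quality.
2. **3' adapter**: the adapter is located at the *leftmost* position
   where the remainder of the read matches the adapter prefix over the
   full available overlap (minimum 6 nt, at most 1 mismatch). No match:
   category `adapter3_null`.
3. **Null insert** (adapter at position 1), **5' adapter contaminant**
   (insert starts with an exact 8-nt 5'-adapter prefix), **poly(A)**
   (insert at least 80% A), then the length window: inserts shorter than
   18 nt or longer than 30 nt are removed (the over-long class is kept as
   a distinct category and reported alongside, since published accounting
   tables typically print only the short class).

We deliberately search for the adapter from position 1 rather than only
past the minimum insert length: the null-insert and shorter-than-18
categories *are* adapter matches at early positions, so a restricted
search could never populate them. Requiring the full available overlap
to match (rather than any 6-mer seed) makes false adapter hits inside
genuine inserts vanishingly rare, which is what keeps an artifact-free
simulated library 100% clean after screening.

Percentages are reported against the high-quality total at two decimal
places (round-half-even), and the partition invariant
`high_quality = clean + sum(removed)` is asserted in the tests on every
input. Surviving inserts are collapsed into unique tags with per-library
counts; tags are the unit of every downstream step.

## Annotation hierarchy

Tags are classified into exactly one of rRNA, tRNA, snRNA, snoRNA,
known miRNA, or unannotated. Non-coding RNA matching runs first (exact
substring of a catalog entry, either strand, with rRNA > tRNA > snRNA >
snoRNA priority), mirroring the elimination-first ordering used with
Rfam/GenBank catalogs; only then are the remaining tags compared to the
mature miRNA catalog.

Known-miRNA matching allows at most two mismatches. Because the
underlying rule says nothing about shifts or indels, we pin a policy:
the tag's 5' end is anchored at offsets −2..+2 against the mature, the
comparison window is the mature's length, positions falling outside the
tag count as mismatches, and no indels are allowed inside the window.
The minimum-mismatch anchoring wins, ties resolved by smaller |offset|
and then lexicographic mature name (with a warning when several matures
tie — the tag is still assigned to exactly one family, keeping the
category partition exact).

Reference mapping is exact-substring matching on both strands via a
hash index of all reference substrings at the observed tag lengths; the
published pipeline's seed-based aligner settings are not recoverable, and
for 18–30 nt tags exact matching is the defensible default.

## Hairpin folding and novel miRNA prediction

Candidate precursors are excised around each eligible tag locus
(unannotated, mapped, total count ≥ 5 — five reads being the lowest
abundance at which plant novel miRNAs are typically accepted): two
windows per locus, `[start − flank, end + small)` and
`[start − small, end + flank)` with defaults flank = 160 nt and
small = 15 nt, so precursors anywhere in the observed 47–354 nt length
range are reachable with the mature on either arm.

Folding is a dynamic program over all nested (pseudoknot-free)
structures with Watson–Crick and G:U pairs and a minimum hairpin loop of
3 nt, under a pinned loop-based nearest-neighbor model: stacking
energies graded by pair strength (G:C −3.2 kcal/mol for a G:C/G:C stack
down to −1.4 for G:U/G:U), a flat terminal-loop penalty (+5.0), bulge
(+3.0 + 1.0/nt) and internal-loop (+4.0 + 0.5/nt) penalties, a
multiloop term (+6.0 per closure, +1.0 per branch, unpaired bases free —
the one term the model sketch left open, pinned here), and an interior
loop cap of 30 nt per side. The table lives in `fold_energy_params()`
and is shared with the test suite's independent oracle, which
exhaustively enumerates every nested structure of short sequences and
scores them with a separate loop-decomposition implementation; the DP
matches it exactly on all tested inputs (enumeration is exact up to
~14 nt; beyond that the structure count grows exponentially, which is
why the oracle stops there). The model is a calibrated stand-in for a
thermodynamic folder: it reproduces kcal/mol-scale minimum free
energies (planted 60-nt hairpins fold to roughly −50 to −65 kcal/mol)
and is fully deterministic, which the tests require.

A candidate is accepted when all of the following hold on the window
fold: the mature pairs predominantly (≥ half its bases) with the
opposite arm across a single terminal loop; it does not pair with
itself or span the loop; at most 4 mature bases are unpaired in the
duplex; no asymmetric bulge exceeds 2 nt; and the precursor — trimmed
to the outermost mature pair and refolded — has MFE ≤ −18 kcal/mol
(the observed stability edge of accepted plant precursors). The miRNA*
search looks for a tag whose span equals the partner region of the
mature shifted 2 nt 3' (canonical Dicer overhang) with ≤ 1 nt slack; a
star more abundant than its mature is flagged, not rejected, since
near-equal mature/star abundance is occasionally observed in real
libraries.

Overlapping accepted precursors collapse to one candidate. Both arms of
a near-perfect hairpin pass the criteria symmetrically, so collapsing
purely by MFE can crown the star arm; we therefore prefer the more
abundant arm as the mature (star strands are degraded rapidly during
biogenesis, so abundance is the field's arm convention) and use MFE
only as the tie-break.

## Normalization, exact test, DE screen, clusters

Counts are normalized to reads per million *clean* reads
(`count / clean_total × 1e6`) — the clean total, not the mapped total,
is the denominator that reproduces published normalized values (e.g.
50,613 reads in an 18,853,348-read library → 2684.56). Fold changes are
`log2(treatment/control)` with the earlier stage as control, after
substituting 0.01 for a normalized value of exactly zero; a comparison
is skipped when **both** substituted values are below one (skipping on
either would forbid the published comparisons against 0.01).

The per-comparison p-value is the count-based exact test for
unreplicated libraries, with
`p(y|x) = (N2/N1)^y (x+y)!/(x!y!) (1+N2/N1)^-(x+y+1)` and a two-sided
p that doubles the smaller of the two tails at the observation, capped
at 1. It is computed in log space with the binomial coefficient in
`lbeta` form — the naive log-gamma difference loses ~6 digits at
counts near 1e5, and `k·log q` must come from a single log of the
rounded ratio for the same reason; with both in place the
implementation agrees with an independent negative-binomial oracle to
better than 1e-11 relative. Note the construction conditions on the
first library: swapping the two samples does *not* give an identical
p-value (the observed point enters the two directions off-by-one), so
the package fixes the convention control-first throughout. No
multiple-testing correction is applied, matching the original screen.

A miRNA is DE when at least one of the three stage comparisons has
|log2FC| ≥ 1.0 and p < 0.05 and was not skipped. Expression-pattern
clusters are the deterministic sign patterns of the two transitions
(stage1→stage2, stage2→stage3), each labeled down/flat/up at the same
|log2FC| ≥ 1 threshold — eight possible non-flat-flat patterns, empty
ones dropped. A distance-based clustering would need the unpublished
algorithm and seed; the sign rule is reproducible and matches how such
cluster tables are described (monotone decline, up-then-down, and so
on).

## Target scanning

The published analysis delegates target prediction to a web server with
default parameters, so the scoring scheme here is pinned by the
package: penalty 0 for Watson–Crick, 0.5 for G:U, 1 for mismatch (N
counts as mismatch), 2 per gap, all doubled at miRNA positions 2–13
(the 5'-anchored seed); cutoff 3.0; at most 1 gap; central mismatch at
positions 9–11 switches the predicted mode from cleavage to
translational repression. Every transcript window within ±1 nt of the
miRNA length is aligned by a small DP (checked against brute-force
alignment enumeration in the tests), overlapping windows deduplicate to
the best expectation, and lowering the cutoff can only remove hits.

## RT-qPCR arithmetic and reports

`ddct()` implements `2^-((Ct_t − Ct_ref) − (Ct_t,cal − Ct_ref,cal))`
with the classic efficiency-2 assumption (primer efficiencies were not
reported); it is invariant to adding a constant to all four Ct values.
`expression_tendency()` summarizes miRNA/target trajectories as
Spearman correlations flagged anti/co/none at |rho| ≥ 0.5 — a
deterministic stand-in for the qualitative anti-correlation narrative.
`build_reports()` writes the standard artifact set (cleaning summary,
length distribution, annotation summary, expression table, DE clusters,
novel candidates), every number recomputed from the upstream tables.

## The simulator and what passing tests mean

`make_reference()` + `simulate_libraries()` define the study conditions:

* three libraries of 16,820 / 18,853 / 17,083 clean reads — the
  published clean totals scaled down ~1000×, kept unequal so the
  normalization denominators are exercised;
* a planted miR156a-like decline proportional to
  505,759 : 50,613 : 16,238 reads (at twice the per-million fraction,
  so the smallest stage still carries ~30 reads);
* planted DE effects at |log2FC| = 3–5 with ≥ ~80 expected reads in the
  higher stage, eight flat (null) known miRNAs with 40–700 expected
  reads for the false-positive measurement, and one flat novel hairpin;
  these margins were chosen once, from the multinomial sampling noise at
  these library sizes, so recovery is seed-robust;
* three perfect-stem hairpins (60 nt by default: 25-bp stem, 10-nt
  loop) with star reads at one tenth of the mature;
* ncRNA contaminants (~8.5% of reads), ~70% unannotatable background
  drawn from unplanted reference positions, and Phred+33 reads of fixed
  36 nt with artifact classes injected at per-stage rates inspired by
  published accounting tables (0.1–0.9%).

Reads are sampled multinomially; artifact identity, *not* base
identity, is randomized (no sequencing-error substitution model beyond
quality-score and rare N injection, no PCR duplicates, no GC bias).
Passing the recovery suite therefore demonstrates that the pipeline's
logic is correct under clean planted truth — it does not demonstrate
robustness to sequencing error, isomiR variation, multi-locus families,
or cross-mapping between near-identical family members, all of which
real libraries contain. Hairpins are planted with perfect complementary
stems; the acceptance criteria are exercised on those, while imperfect
stems are covered by the negative-control tests (weak stems, matures
spanning the loop).

Problem sizes used by the test and acceptance runs — three ~17–19k-read
libraries, ~35k unique tags, a handful of folded windows of ~200 nt —
were chosen so a full run completes in about a minute on one core while
keeping every planted count far above the detection margins.

## Known limitations

* The folding model is pinned, not fitted to thermodynamic data;
  absolute MFEs are kcal/mol-scale but not literature-exact, and the
  −18 kcal/mol acceptance threshold belongs to this model.
* Exact-substring ncRNA matching cannot reproduce covariance-model
  (Rfam) hits; family assignment for heavily edited tags (> 2
  mismatches) is out of reach by construction.
* The exact test is unreplicated by design; with biological replicates
  a dispersion-based model (edgeR/DESeq2) would be the right tool.
* Target prediction has no accessibility/energy term and no degradome
  support; expectation scores are comparable only within this scheme.
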