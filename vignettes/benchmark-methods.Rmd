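---
title: "Benchmarking taxonomy classifiers with identity-constrained cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking taxonomy classifiers with identity-constrained cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxcvi)
```

## The problem

Taxonomy prediction assigns a rank-prefixed lineage (domain, phylum, ...,
genus, species) to a marker-gene sequence — typically a 16S rRNA or fungal
ITS OTU — by comparing it against an annotated reference database. Naive
cross-validation overstates accuracy because a random held-out sequence
usually has a near-identical twin left in the training data, while real
environmental queries sit anywhere between ~100% and ~75% identity to their
best reference hit. `taxcvi` implements an evaluation design that controls
this directly: test/training splits are engineered so that every test
sequence's best training hit lies at a prescribed identity *d*, and errors
are scored in a rank-aware way.

This vignette records the models, parameter choices and numerical decisions
behind the package, in the spirit of a methods appendix.

## Lowest common rank statistics

The lowest common rank (LCR) of two annotated sequences is the lowest rank
at which both carry the same taxon name; rank comparisons follow
domain > phylum > class > order > family > genus > species. For a reference
`R`, `lcrTable()` enumerates every unordered distinct pair, computes its
integer-rounded global identity `d` and its LCR, and estimates

    P(LCR = r | d) = m_{d,r} / M_d

where `M_d` counts pairs at identity `d` and `m_{d,r}` those whose LCR is
`r`. Three derived quantities:

* **Common-rank probability** `commonRankProb()`: the probability that a
  pair at identity `d` shares a name at rank `r`, i.e. the cumulative LCR
  probability over ranks at or below `r`. It is non-decreasing from species
  toward domain.
* **Most probable LCR** `mlr()`: the named rank maximizing
  `P(LCR = r | d)`.
* **Rank identity thresholds** `rankIdentityThresholds()`: `RIT(r)` is the
  minimum identity whose MLR is `r` — a clustering-free way to derive
  identity thresholds per rank. A rank that is never the MLR has no
  threshold.

Decisions worth recording:

* Pairs are **unordered and distinct**. A sampling-with-replacement reading
  would add self-pairs, injecting artificial lowest-rank mass at
  `d = 100`; the table is meant to describe *different* sequences.
* Pairs sharing no name at any rank are kept under a virtual **"none"**
  rank. It occupies probability mass in the denominator (rows always sum
  to 1) but is excluded from common-rank probabilities and can never be
  the MLR.
* MLR ties break toward the **lower** (more specific) rank; the argmax
  itself does not disambiguate ties.
* Rows resting on fewer than 10 pairs are flagged as statistically weak
  (a warning), mirroring the reporting floor used by the metrics.

## Known and novel OTU estimation

Given a query set's top-hit identity distribution (THID; `thid()` reports
the number of queries `N_d` whose best reference hit rounds to `d`), the
estimated number of OTUs whose rank-`r` taxon is present in the reference
is

    K_d(r) = P_CR(r | d) * N_d,    L_d(r) = (1 - P_CR(r | d)) * N_d,

summed over `d` for totals (`estimateKnownNovel()`). When a query identity
is absent from the probability table, `P_CR` is linearly interpolated
between the nearest occupied rows and clamped outside their range; such
rows are flagged and reported. Dense references rarely need this; sparse
toy references do.

## Cross-validation by identity (CVI)

`buildCviSplit()` partitions a reference into four disjoint sets: `S`
(test), `T` (designated top hits of `S`), `W` (sequences below `d` identity
to all of `S`) and `Z` (discards that would violate the constraint). The
training set is `A = T ∪ W`, and the contract — checked independently by
`verifyCviSplit()` — is that the raw top-hit identity of every `s ∈ S`
against `A` lies in `[d − δ, d + δ]`. Defaults follow the benchmark design:
`d ∈ {100, 99, 97, 95, 90}` with `δ = 0` at 100 (test and training are both
the whole reference — the constraint is trivially satisfied), `δ = 0.5` at
99/97/95 and `δ = 1` at 90.

The builder is greedy and makes no optimality claim: candidates are visited
in seeded-shuffled order; a candidate joins `S` when some eligible partner
lies in range (the in-range partner closest to `d` joins `T`, ties to the
earlier record) and no committed training member exceeds `d + δ` with it;
every sequence above `d + δ` identity to a test sequence is barred from the
training set. The remainder goes to `W` when below `d` against all of `S`,
else to `Z`. Only the verified contract matters; different seeds give
different (all valid) splits. The `W` rule uses strictly `< d`, not
`< d − δ`.

Leave-one-out evaluation (`l1oPairs()`, `l1oBenchmark()`) masks each query
by id at classification time rather than copying databases.

## Performance metrics

For each rank, with `N` test sequences annotated at that rank, `K` of them
*known* (name present in the training set at that rank) and `L = N − K`
*novel*:

* `TP` — known, predicted, equal; `MC` — known, predicted, different;
  `UC` — known, unpredicted; `OC` — novel, predicted (necessarily wrong).
* Rates (percent): `TPR = TP/K`, `UCR = UC/K`, `MCR = MC/K`, `OCR = OC/L`,
  `Acc = TP/(K + OC)` and `AccRDP = TP/N`.

A novel, unpredicted sequence is no event: true negatives are undefined in
this setting because an unpredicted rank is not a prediction of absence.
`Acc` divides correct predictions by the predictions whose correctness can
be determined; `AccRDP` is reported for comparability with older
leave-one-out studies and is bounded above by `K/N`. A metric is
unreported when its denominator is below 10 (the reporting floor is a
parameter so unit tests can exercise the arithmetic on tiny tallies).
`Avg` metrics are arithmetic means over the identities where a metric is
reported, with the number of contributing identities attached; identities
where a metric is unreported are skipped rather than zero-filled.

Two structural facts make useful smoke tests: a top-hit classifier never
under-classifies when a hit exists (`AvgUCR = 0`) and always
over-classifies novel taxa (`AvgOCR = 100` wherever reportable); and any
classifier that always emits full lineages satisfies `UC = 0`, `OC = L`
and `Acc = AccRDP` exactly.

## Classifiers

All four baselines share the prediction container: a full candidate
lineage plus per-rank confidence, reported as the longest gapless rank
prefix whose confidences reach the cutoff (so raising the cutoff never
adds ranks).

* **TOP / BTOP** (`topClassify()`, global/local): copy the top hit's
  lineage, confidence 1. Ties go to the earliest database record.
* **KTOP** (`topClassify(mode = "kmer")`): top hit by shared distinct
  8-mers — the alignment-free variant.
* **NBC** (`trainNbc()` + `nbcClassify()`): genus-level naive Bayes over
  distinct 8-mers with add-half document-frequency smoothing
  `P(w|g) = (n_g(w) + 0.5)/(N_g + 1)`; bootstrap confidence from 100
  draws of `⌊V/8⌋` of the query's `V` distinct words. The model is
  genus-level: each genus maps to one lineage down to the genus rank, and
  ranks below genus are never predicted by it.
* **SINTAX-style** (`sintaxClassify()`): each of 100 bootstrap rounds
  draws 32 words and votes the lineage of the record sharing most drawn
  words; confidence is the vote fraction agreeing with the most-voted
  lineage at each rank. Votes are cast per record, so species-level
  annotations are usable when present.

Bootstrap parameters (word size 8, 100 rounds, `⌊V/8⌋` or 32 words per
round) follow the classical formulations of the respective algorithms.
Confidence comparisons use `>=` (a confidence exactly at the cutoff is
kept). Cutoffs 0, 0.5 and 0.8 are the conventional presets. Each query
draws from an RNG stream derived from `(seed, query id)`, so results are
bit-reproducible and independent of query order.

## Alignment identity

Identity is the package's one deliberately hand-built numerical kernel
(C++): percent matches over alignment columns under an affine-gap global
alignment with match +1, mismatch −2, gap open −10, gap extension −1 (a
gap of length L costs 10 + L). Terminal gap columns are excluded from the
identity denominator and are charged the extension penalty only, with no
opening cost. Fully free terminal gaps were rejected after analysis: with
them the maximum-score alignment for distant pairs degenerates to a few-nt
spurious perfect overlap in one corner, reporting ~100% identity for
~50%-diverged sequences; the reduced (but nonzero) terminal charge keeps
alignments honest while barely affecting near-identical pairs. Integer
identities round half up (87.5 → 88).

Tie-breaking is fully deterministic: among equal-score alignments the one
with more matches wins, then the one with more substitution columns, with
a fixed candidate order in the recurrences. This makes "the identity of
the optimal alignment" a well-defined quantity, which the test suite pins
against an independent plain-R dynamic-programming oracle on hundreds of
short random pairs. Local mode (Smith–Waterman, same scoring) backs the
local-alignment top-hit variant. Ambiguity letters in sequences never
match anything (they count as mismatches); degenerate letters in primers,
by contrast, match their expansion sets during amplicon extraction —
primers are degenerate by design, reference ambiguity is noise.

Bit-parity with any particular search tool is a non-goal; the contract is
internal consistency plus oracle equivalence.

## The synthetic reference generator

`simulateReference()` emulates the identity–rank structure of a curated
marker-gene reference so that the entire pipeline can be exercised without
external downloads. A random root sequence evolves down a configurable
taxonomy tree; the edge into each taxon carries the substitution budget
separating its rank band from the next, so two leaves whose LCR is `r` are
separated by twice the configured per-rank divergence (before multiple-hit
saturation). Substitutions are uniform over the three alternative bases;
indels are off by default, so alignment identities track Hamming-derived
expectations closely. Per-edge lognormal rate factors (sd 0.6 on the log
scale) add lineage rate heterogeneity, which spreads the discrete bands
into continuous, overlapping identity distributions — without this, the
identity targets between bands (e.g. 97) would find no admissible pairs,
which real references do not suffer from.

Default conditions: 2 phyla × 2 classes × 2 orders × 2 families × 3 genera
× 2 species with 2 sequences per species (192 records, 300 nt), and
divergences species 0.005, genus 0.02, family 0.05, order 0.09, class
0.14, phylum 0.20. These place within-species pairs near 99% identity,
congeneric species near 96%, confamilial genera near 91% and deeper pairs
below — covering the five identity targets — and are sized so that a full
sweep (split, classify, score at five identities) runs in well under a
minute on one CPU. The test suite uses a smaller sibling of this
configuration (64 records, 240 nt) for most properties.

What the generator does **not** emulate: realistic substitution models
(GTR, site-rate heterogeneity), chimeras, sequencing error (state-of-the-art
denoising makes error modelling unnecessary for this benchmark's purpose),
taxonomic misannotation, or the extreme abundance skew of real references
(`subsampleByTaxon()` exists to tame that skew in real data). Passing
tests on synthetic references therefore demonstrate correctness of the
machinery and the structural properties of the metrics, not field accuracy
of any classifier.

`simulateQueries()` mutates seeded source records until realignment
confirms the requested top-hit identity within one point, which gives
query sets with known construction labels for validating the known/novel
estimator: copies of reference members are known at species, while
queries mutated to 90% sit far below the species band and are novel by
construction.

## Degenerate inputs and edge policies

* Lineage gaps (a named rank below an unnamed one) are parse errors, not
  silently tolerated.
* `lcr()` compares only ranks named in both lineages; disjoint rank sets
  give the virtual none outcome.
* Masking for leave-one-out is by record id, not sequence equality:
  duplicate sequences under other ids remain eligible hits.
* A test sequence unannotated at the evaluated rank is excluded from `N`
  at that rank.
* An empty test set (no admissible pair at the requested identity) is a
  warning, not an error; verification reports violations rather than
  throwing.
* At `d = 100` the split is the degenerate `S = T = R` case and self-hits
  are intentionally allowed.

## Known limitations

* The greedy split builder is best-effort; it makes no attempt at the
  NP-flavored maximal test set, and very sparse references can yield small
  or empty test sets at some identities.
* The LCR table treats identity bins independently; no smoothing across
  adjacent identities is applied.
* The aligner is exhaustive (no banding or indexing heuristics); it is
  sized for references of hundreds to a few thousand sequences, not for
  full-scale production databases.
* Amplicon extraction scans the forward strand and falls back to the
  reverse complement; mismatch tolerance and strand policy for primer
  matching are package decisions, as are the alignment scoring constants —
  quantities derived from them (identity bands, thresholds) are internally
  consistent but not bit-comparable to any specific external tool.
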