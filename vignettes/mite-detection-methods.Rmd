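---
title: "Structure-based MITE detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based MITE detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitescan)
```

## The detection problem

Miniature inverted-repeat transposable elements (MITEs) are short
(50–800 bp) non-autonomous class II elements present at high copy number
in many eukaryotic genomes. They encode no protein, so they cannot be
found by homology to transposase; what identifies them is pure
structure: a terminal inverted repeat (TIR) of at least 10 bp at both
ends, and a target-site duplication (TSD) of 2–10 bp — a direct repeat
created on insertion — immediately flanking the element on both sides.

`mitescan` detects this structure in six stages:

1. **Fragmentation and k-mer indexing.** Each chromosome is cut into
   10 kb fragments overlapping by 800 bp (the maximum element length),
   so every element lies wholly inside at least one fragment. Every
   10-mer of a fragment is hashed to its positions.
2. **Seed search.** For each 10-mer the index is probed with its
   reverse complement (perfect seeds) and with every interior
   single-substitution variant of it (1-mismatch seeds; a mismatch on a
   window edge is not accepted because it carries no alignment
   evidence). A seed pair is kept when the implied element span is
   50–800 bp and neither window is low complexity.
3. **Merging.** Seeds whose left starts step by +1 while right starts
   step by −1 describe one TIR read through a sliding window and
   collapse into a single candidate whose TIR grows by 1 per seed. A
   gap of 2 is bridged across a perfect/imperfect junction — exactly
   the gap a single mismatched base leaves, because the two windows
   with the mismatch on their edge are excluded. A merge that would
   require two distinct mismatch positions would describe a 2-mismatch
   TIR and is refused; the chain is cut there.
4. **TSD validation.** For lengths 10 down to 2, the bases immediately
   left of the element are compared with the bases immediately right of
   it; the longest exact match is the TSD. A 2 bp TSD must be `TA`
   (the Stowaway signature; other 2-mers are indistinguishable from
   chance). Candidates without a valid TSD are dropped.
5. **Scoring.** A 6-mer log2 likelihood-ratio model trained on positive
   versus null sequence sets scores each candidate per word;
   candidates must exceed a threshold (default 0) to survive.
6. **Family selection.** Candidates whose 60 bp genomic flanks match
   another candidate's flanks are segmental duplications, not
   transpositions, and are removed, as are candidates with no similar
   partner at all. Survivors are clustered on a similarity network
   (components with ≥ 3 members become families), each family exports
   its highest-degree member as representative, and the TSD assigns a
   superfamily (`TA` Stowaway, `TAA` Tourist, 5/6/8 bp hAT, 9/10 bp
   Mutator).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k` | 10 | bp | seed length = minimum TIR; smaller floods the index, larger misses short TIRs |
| `min_length`, `max_length` | 50, 800 | bp | the definitional MITE span |
| `max_mismatch` | 1 | count | imperfect TIRs are common; ≥2 mismatches are indistinguishable from background at k = 10 |
| `fragment_length`, `overlap` | 10000, 800 | bp | overlap must reach `max_length` so no element is split across all fragments containing it |
| `homopolymer_min` | 8 | bp | run (or two-base alternation) length that marks a TIR as simple sequence |
| `composition_min_pct` | 20 | % | minimum G+C and minimum A+T content of a TIR |
| `score_threshold` | 0 | log2 units | retain candidates more likely under the positive than the null model (strictly greater) |
| `flank` | 60 | bp | genomic context compared by the segmental-duplication filter |
| `pident_min` | 80 | % | identity floor for "same element" evidence |
| `cluster_pident`, `cluster_coverage` | 90, 0.9 | %, fraction | family-network edge: near-identity over most of the shorter element |
| `min_family_size` | 3 | members | a family is a repeat: fewer copies is not evidence of amplification |

Alignment-based thresholds replace BLASTN e-values deliberately: an
e-value depends on database size and is not reproducible inside a
self-contained library, whereas "≥ 30 aligned bp at ≥ 80% identity"
(reporting floor, standing in for 1e-10) and "≥ 90% identity over ≥ 90%
of the shorter element" (clustering, standing in for 1e-100) are exact,
configurable statements. Local alignment uses match +1, mismatch −1,
gap open −2, gap extend −1, with identity = matches / alignment columns.

## The scoring model

For every 6-mer $s$ the model stores

$$F(s) = \log_2 \frac{\Pr(s \mid M)}{\Pr(s \mid N)}$$

with $M$ the positive set and $N$ the null set, estimated from
overlapping word counts with add-1 smoothing
($\Pr(s \mid M) = (c_M(s) + 1)/(T_M + 4^6)$). Smoothing is not
optional: the ratio is undefined for words absent from $N$. A
sequence of length $n$ scores the mean of $F$ over its $n - 5$
windows, which removes the length dependence; windows containing `N`
carry no evidence and are excluded from the divisor. Swapping $M$ and
$N$ negates every score exactly — a property the tests assert.

The reference training corpora behind the published model are not
distributed, so the package ships the training operation
([train_model()], [run_train()]), a plain-text model format with a
byte-exact read/write round trip, and a seeded synthetic training-set
generator ([make_training_sets()]) whose default enrichment (100-fold
over the uniform per-window rate) puts about five motif copies in a
200 bp positive sequence — a realistic density for a conserved family
motif, and enough signal that a trained model separates motif-bearing
from uniform sequences with AUC above 0.9 at 200 sequences per set.
Scores from a synthetic model are for testing the machinery, not for
annotating real genomes; train on curated positive/null sets there.

## What the synthetic generator emulates — and what it does not

[random_genome()], [make_mite()] and [implant()] build seeded genomes
with implanted elements and a machine-readable truth table. They
emulate the structural definition exactly: TSD + TIR + internal +
inverted TIR + TSD, optional single interior TIR mismatch, per-copy
internal decay (substitutions only, never touching TIRs or TSDs),
non-overlapping placement ≥ 900 bp apart, and optionally a shared
carried flank that mimics segmental duplication (the decoy mode the
flank filter must remove). Two generator guarantees keep the truth
table honest: the TIR is redrawn until none of its windows trips the
low-complexity filter, and the two innermost internal base pairs are
forced non-complementary so the element's actual maximal inverted
repeat equals the specified TIR length (with a `TA` TSD — itself
reverse-complementary — an unguarded "TIR 9" element would often truly
carry a 10 bp repeat).

The generator does not model insertion-site preference, nested or
truncated elements, indels inside TIRs, or genome-scale base
composition structure (isochores, satellite arrays). Passing tests
therefore demonstrate correctness of the structural logic under clean
conditions, not annotation accuracy on real genomes, where the score
and flank filters carry much more of the burden.

## Numerical and boundary choices

**Boundary trimming.** When the two ends of a TSD are
reverse-complementary (`TA`, `TTA`, ...), the inverted repeat provably
continues into the TSD, and chance or 1-mismatch windows can extend it
further, so the maximal seed chain overshoots the element. TSD
validation therefore tests symmetric trims of the maximal repeat,
outside-in, under three rules distilled from failure modes one can
construct analytically:

* *Interior-repeat hop*: a boundary overshot by one base always sees an
  exact direct repeat made of the TSD's interior (length − 2), so after
  any hit the next trim is peeked at and the boundary hops inward when
  it shows exactly that signature (a valid TSD two bases longer whose
  interior equals the current one).
* *Perfect readings first*: a chance 1-mismatch window absorbing
  flanking sequence leaves `mis = 1` on the overshot reading, while the
  true reading of a perfect element is again perfect after trimming;
  mismatch-free readings are preferred.
* *Terminal-mismatch extension*: a TIR mismatch at window offset
  k − 1 excludes the outermost seed window, leaving the chain one base
  short; that configuration (observed mismatch at chain-TIR offset
  k − 2) earns one outward extension trial.

**Residual localization jitter.** One ambiguity survives all three
rules: with probability about 1/16 per element, the two genome bases
just outside the TSD complete an exact direct repeat two bases longer
than the true TSD, and the longer (equally valid) reading wins. Both
readings describe a structurally legitimate MITE; there is no
sequence-level discriminator. Element boundaries are therefore exact
in most cases but can shift by ±1 bp, and recovery in the validation
suite is scored within a ±1 bp boundary tolerance (or reciprocal
overlap for whole-pipeline recall).

**Flank-coverage margin.** Two genuine copies of one family share
their TSD (up to 10 bp, re-created at every insertion) and often a
chance base or two immediately outside the element, so their best
local alignment almost always extends slightly past the element
boundary. An alignment counts as covering the flank only when it
reaches more than 15 bp outside the element; segmental duplicates,
which share the full 60 bp context, are far beyond the margin.

**Determinism.** All randomness flows from explicit seeds; ties are
broken by fixed rules (ascending coordinates; representative = maximal
degree, then smallest (`record_id`, `start`)), and repeated runs with
identical inputs produce byte-identical reports.

## Problem sizes in the validation suite

The suite validates on sizes a laptop handles in minutes: oracle
equivalence against a brute-force scanner on fifty 5 kb fragments;
recovery of twenty perfect implants (one deliberately straddling a
fragment joint) on a 100 kb genome; family recovery with three decayed
families, two flank-carried decoys and a singleton on 80 kb; scoring
separation at 200 training sequences per set. These sizes exercise
every code path — fragment overlap, deduplication, both mismatch merge
forms, all superfamily classes — while staying small enough to run as
ordinary tests.

## Known limitations

* Only substitutions are tolerated in TIRs (at most one, interior);
  indel-containing TIRs are out of scope at k = 10.
* TSDs are matched exactly; a TSD with a post-insertion mutation
  rejects the element.
* The family stage picks an existing member as exemplar rather than
  building a consensus; heavily decayed families may fall below the
  90%-identity clustering edge and fragment into smaller families.
* Background inverted repeats that happen to enclose a true element
  can join its family when the score filter is disabled; with a trained
  model and the default threshold they are removed upstream.
* A genome consisting mostly of `N` or of simple sequence yields few
  indexable windows and correspondingly little statistical power for
  the score model.
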