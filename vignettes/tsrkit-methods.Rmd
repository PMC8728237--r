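---
title: "Methods: calling and using tRNA-derived small RNAs with tsrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and using tRNA-derived small RNAs with tsrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrkit)
```

## The problem

Small RNA-seq libraries from most tissues are full of reads that map to
tRNAs. Some of these are tRNA-derived small RNAs (tsRNAs) — discrete,
regulated cleavage products with their own biology — but many are ordinary
degradation fragments. A caller that reports every tRNA-mapping read as a
tsRNA produces thousands of candidates of which only a handful are real.
`tsrkit` separates the two by asking a positional question: a bona fide
cleavage product starts at the same nucleotide over and over again, while
degradation scatters read starts across the transcript.

## Reference model

Mature tRNAs are built from gene annotations by removing intron intervals
and appending the non-templated `CCA` tail; tRF-1 fragments come from the
precursor's 3' trailer, so the 50 nt downstream of each gene are extracted
as a second reference. Coordinates are 1-based and closed everywhere inside
the package; BED input is converted at the file boundary.

The anticodon is located on the spliced sequence as the occurrence of the
anticodon triplet nearest the sequence midpoint. The anticodon *loop* is
taken as positions `a - 2` through `a + 4` around the anticodon start `a`.
These offsets are not dictated by any data source; they approximate the
canonical 7-nt loop of tRNA secondary structure and are exposed as the
`loop_offsets` argument of `build_mature_trna()` for users who prefer
structure-derived loop boundaries.

Modification positions are interpreted on the mature (spliced,
CCA-appended) sequence. Tables distributed in genomic coordinates can be
converted with `lift_genomic_to_mature()`, which honours strand and skips
introns.

## Alignment with modification-aware scoring

Reads are collapsed to unique sequences with multiplicities, filtered
against other small RNA classes (rRNA, snoRNA, snRNA, miRNA, mRNA
fragments, repeats) and — when a genome is supplied — for exogenous
sequences, then aligned to the mature and trailer references.

Because the references are tiny (tens of sequences under 130 nt), alignment
is an exhaustive ungapped offset scan rather than an index-based heuristic:
every placement with at most `max_edits` mismatches is found, and reads
with a perfect hit take a hash-table fast path
(`build_alignment_index()`). Single-indel placements (one bulged base on
either side, the rest of the budget spent on mismatches) are explored only
when no ungapped placement fits the budget — under the scoring rule a
one-indel alignment has one fewer matched base at equal penalty, so it can
tie but never beat an ungapped placement.

Scoring reflects reverse-transcriptase behaviour at modified bases: +1 per
matched base, −1 per mismatch or indel, but only −0.5 when the event falls
on a known modification site, where misincorporation and stuttering are
expected rather than evidence against the placement. The reported score
always satisfies

```
score = n_match − n_mismatch_plain − n_indel_plain − 0.5 (n_mismatch_mod + n_indel_mod)
```

and all best-scoring placements are kept, so a fragment shared by several
isodecoders multi-maps to all of them with its full count. This matches the
downstream merge rule: identical sequences become a single named call
listing every source.

## The positional binomial test

For one transcript of length `L` carrying `n` tags in total, a fragment of
length `l` placed uniformly at random can start at any of `L − l + 1`
positions, each with probability `p = 1/(L − l + 1)`. The evidence that a
position is a true cleavage site is the upper binomial tail

```
P(X >= k) = sum_{x=k}^{n} C(n, x) p^x (1 − p)^(n−x)
```

where `k` is the tag count at that start position. Positions with
`P < 0.01` (default) whose fragment length lies in 14–45 nt become calls.
The tail is evaluated through the survival function (`pbinom(k − 1, n, p,
lower.tail = FALSE)`), which is numerically stable for the small `p`, large
`n` regime; the test suite checks it against direct log-space summation of
the series to below 1e−9 relative error.

Two counting choices deserve explanation.

**Which `l` enters `p`.** Tags of different lengths share a start position,
and `k` pools all of them. Pairing that pooled `k` with the placement
probability of the *shortest* fragment (the smallest `p`) overstates
significance; on uniform-background simulations the per-position
significant fraction then exceeds the nominal level (we measured ≈1.8% at a
1% threshold). `call_tsrnas()` therefore uses a representative length per
transcript — the count-weighted median tag length — giving one `p` per
transcript and an empirically conservative test (≈0.6% of positions at the
1% threshold under the null). Per-fragment lengths remain available via
`length_mode = "per-fragment"`.

**What `k` counts.** `k` is the tag count at a fragment *start* position by
default (`count_mode = "start"`); 3'-anchored analyses can count end
positions instead. `n` counts read copies (collapsed multiplicities), and a
multi-mapped read contributes its full count to every best-scoring
transcript, consistent with merging identical sequences across isodecoders.

### Expected false calls under the null

A per-position test at level 0.01 over a 10-tRNA reference performs roughly
600 tests per library. The discreteness of counts makes each test
conservative (the achievable level just below 0.01 is typically 0.003–
0.005), but the expected number of false sites per background-only library
is still on the order of 600 × 0.004 ≈ 2 — for *any* background depth,
because the effective level and the number of occupied positions scale
together. Users should expect a few positional false positives per library
under pure degradation and treat the call list as candidates ranked by P
value, not as a finally filtered catalogue. The acceptance checks therefore
validate what the test actually promises: the per-position significant
fraction stays at or below the nominal level, and the per-transcript
any-call fraction stays below its Bonferroni-style envelope
`1 − (1 − 0.01)^m` for `m` tested positions. A requirement that
background-only libraries yield *zero* calls in ≥95% of runs is not
attainable under per-position testing at this threshold and is not claimed.

## Classification and naming

With the anticodon loop `[ls, le]` on a mature tRNA of length `L`, a called
interval `[s, e]` is classified by its cleavage ends:

* trailer reference → `tRF-1`;
* `s ≤ 2` and `e` inside the loop → `tiRNA-5`; `s ≤ 2` and `e` before the
  loop → `tRF-5`;
* `e > L − 3` (the CCA tail) and `s` inside the loop → `tiRNA-3`;
  `e > L − 3` and `s` after the loop → `tRF-3`;
* anything else → `tRF-i`.

The 5'-anchor window (2 nt) and 3'-anchor window (3 nt, the CCA tail) are
the `s5`/`s3` arguments. Names follow
`tsRNA-<amino acid>-<type code>-<serial>` with type codes 5/3/i/1 for tRFs
and 5i/3i for tRNA halves (halves need their own codes to keep names
unambiguous); serials are zero-padded and assigned in lexicographic
sequence order within each (amino acid, type) group, so identical inputs
always produce identical names. Whitelist membership (catalogues from
modification-erasing protocols such as PANDORA-seq) is annotation only — it
never rescues a sub-threshold fragment, it marks confidence on called ones.

## Quantification and normalization

Expression is reads-per-million tRNA-mapped counts, `RPM = 1e6 C / N`. For
cross-cohort comparisons `rank_inverse_gaussian()` replaces values by
normal quantiles of their average-tie ranks, `z_i = qnorm((r_i − 0.5)/m)`,
and rescales by the maximum |z| so every cohort lands on [−1, 1] with a
zero median (odd, tie-free case). The `(r − 0.5)/m` rank offset is one of
several standard inverse-normal variants; it was chosen because it is
symmetric and keeps the extremes finite, and it is a package constant. The
transform depends only on ranks, so it is invariant to any strictly
monotone distortion (depth, scaling) of the input — the property that makes
pooling heterogeneous cohorts defensible. Whether to transform within each
cohort and then pool, or pool first, is left to the caller;
`normalize_expression()` applies the transform along one margin of
whatever matrix it is given (per tsRNA across samples by default).

## Target discovery

**CLIP mode.** Tags are collapsed, short (<14 nt) reads dropped, and reads
matching a tRNA reference only in antisense orientation removed as
artifacts. Target-side tags are placed on transcripts by exact substring
search and per-base coverage is accumulated. Peaks are strict local maxima
(leftmost position of a plateau) of height at least `min_height`, extended
while coverage stays at or above half the summit; peaks are claimed in
decreasing height order and trimmed so that no two overlap. This is a
deliberately minimal pileup model — no background model, no read-shift
correction — because peak calling here only delimits candidate windows for
the duplex search.

**Duplex search.** `find_duplex()` finds the best antiparallel hybrid
between a small RNA and a target window. The duplex must contain a fully
paired, gap-free helix across the tsRNA seed (positions 2–7), extended on
both sides allowing Watson–Crick and G·U pairs, at most 2 interior
mismatches and at most 2 bulged bases per strand (all configurable). The
energy is a surrogate stacking score — −3 per GC, −2 per AU, −1 per GU,
+1 per mismatch or bulged base — not a nearest-neighbour free energy; the
default reporting cutoff of −10 then demands roughly four strong or five to
six mixed pairs beyond any penalties, i.e. a stable helix rather than a
chance 6-mer. Ties are resolved toward more pairs, then the leftmost
target position. The implementation is a memoized two-sided extension
around each seed register; the test suite proves it equivalent to an
unpruned enumeration of every register and every mismatch/bulge placement
on hundreds of sequence pairs.

**CLASH/CLEAR mode.** Reads that map contiguously to the genome (either
strand, 1 mismatch allowed) are fake chimeras — single fragments, not
ligation products — and are removed. Remaining reads are split at the
longest prefix or suffix matching a tRNA reference; the split is accepted
when the tRNA arm is 14–40 nt and the remainder exceeds 8 nt. Arm matching
is exact by default: with a mismatch budget, a chance match immediately
after a sequencing error can extend the arm past the true ligation
boundary, so edit tolerance is opt-in (`split_edits`). Both ligation orders
(tsRNA-first and target-first) are searched. The two arms then go through
the same duplex search.

**Conservation.** When a per-base conservation track is supplied,
interactions are kept only if the mean conservation over the binding site
exceeds 0.3; positions missing from the track count as zero. The mean is
taken over the reported binding-site interval (not only the paired bases),
which is the more stringent choice for gapped duplexes.

## ceRNA inference

Two regulators that share more mRNA targets than chance predicts are
candidate competing endogenous RNAs. With `N` mRNAs in the universe, `K`
targets of the miRNA, `n` of the tsRNA and `k` shared, the P value is the
hypergeometric upper tail `P(X ≥ k)`, evaluated through `phyper()`'s
survival function and verified in tests against exhaustive enumeration of
all draws for every parameter combination with `N ≤ 15`. P values are
corrected by Benjamini–Hochberg and pairs with FDR < 0.05 become
"competes" edges. The universe defaults to the distinct mRNAs observed in
the union of both target tables — no fixed human mRNA count is assumed —
and can be overridden. Pairs with `k = 0` are not tested: they cannot be
significant and would only dilute the correction; their count is logged.

## Synthetic data: what it emulates and what it does not

Every input has a seeded generator, so the full pipeline runs and is tested
without downloads. `generate_trna_reference()` makes tRNA-like genes
(72–90 nt spliced, anticodon embedded mid-sequence, an intron inserted 3'
of the anticodon in ~30% of genes, where real tRNA introns sit) on a toy
chromosome with 60-nt flanks and alternating strands, plus sampled
modification sites. `simulate_small_rna_library()` plants tsRNAs at stated
abundances and adds degradation background in which a fragment length is
drawn with a geometric tail above 14 nt and its start is uniform over all
admissible positions — deliberately the *exact* null of the positional
binomial test, so the caller's type-I behaviour is directly checkable.
Chimera simulation picks junction bases that cannot extend the tRNA-arm
match into any reference, making the planted ligation boundary recoverable
exactly; boundary cases (8-nt target arms) are labelled rejects in the
truth manifest. The conservation track gives conserved sites 0.6 and
background 0.05, so the 0.3 cutoff separates them exactly.

These generators are idealisations. Real libraries have sequence-dependent
ligation bias, position-dependent degradation (tRNA halves accumulate under
stress), adapter artefacts, and modification-induced truncations far more
structured than a uniform mismatch-rate bump at modification sites. Passing
the planted-recovery and type-I checks therefore shows the statistics and
bookkeeping are correct under the stated model, not that real-data
candidate lists are free of biological artefacts.

## Problem sizes and numerical choices

The test and acceptance workloads use 10 synthetic tRNAs, background at one
tag per position, 20 planted fragments at 100× the background for recovery
checks, 200 background-only libraries for the type-I estimate, 500 sequence
pairs for duplex-oracle equivalence (full 2/2/2 budgets on short
near-complementary pairs, where unpruned enumeration is exponential in
length, and sampled budgets on longer random pairs), and 200 permutation
replicates for the ceRNA FDR check — sizes chosen so the whole suite runs
in a few minutes on one CPU while keeping every Monte-Carlo margin at three
standard errors or better. Degenerate inputs are handled explicitly: zero
total counts give RPM 0 with a warning, constant vectors normalize to zeros
with a warning, `k = 0` gives P = 1, and `L = l` gives the degenerate
single-position distribution.

## Known limitations

* Alignment explores at most one indel per placement; longer indels are out
  of scope for reads of 14–45 nt.
* The duplex energy is a surrogate; scores are comparable within `tsrkit`
  but are not free energies in kcal/mol.
* The peak caller has no local background model; it relies on the duplex
  and conservation filters downstream.
* Survival modelling and enrichment analysis of call sets are deliberately
  out of scope; the expression matrices are written in plain TSV for use
  with the standard tools.
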