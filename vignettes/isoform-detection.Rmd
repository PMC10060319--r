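---
title: "Consensus exon coordinates and isoform quantification at a single locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus exon coordinates and isoform quantification at a single locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(isoquantr)
```

## The problem

Targeted long-read sequencing of one locus — a minigene splicing assay, an
RT-PCR amplicon, a spike-in mix — yields reads that each span a whole
transcript. In principle every read reports its complete exon chain; in
practice aligners place exon boundaries with a few bases of noise, some
reads are truncated PCR or library artifacts, and some reads are
off-target. The analysis task is to recover the set of distinct exon
chains (isoforms) actually present and their relative abundances.

`isoquantr` does this without any prior splice-site annotation. The key
idea is that at genuine splice sites many reads pile up on (almost) the
same boundary position, while alignment noise spreads a minority of reads
over neighbouring positions. Boundary positions are therefore treated as a
frequency distribution, separately for exon starts and exon ends, and
consensus exon coordinates (CECs) are extracted from its peaks.

## The procedure and its assumptions

Given reads as ordered exon interval chains (1-based, inclusive, reference
forward — strand is ignored because amplicon data come from one known
template), `run_locus()` applies, in order:

1. **Region restriction** (optional). Exons outside the analysis region
   are dropped; exons straddling a region edge are clipped to the edge.
   Clipped boundaries are anchored to a *sentinel* coordinate placed at
   the region limit (unless an existing window already covers it). This
   keeps the biological part of reads that run into vector sequence
   instead of discarding them, which is the main reason to restrict a
   region at all.
2. **Boundary frequencies.** Each read with *k* exons contributes *k*
   start and *k* end positions; percentages are relative to the number of
   reads analysed, not to the number of boundary occurrences, so a
   position's height reads directly as "x % of reads start an exon here".
3. **Frequency threshold** (`read_threshold_percent`, default 2, unit: %
   of reads). A position is a candidate iff its percentage is *strictly*
   above the threshold. Strictness is a deliberate reading of "above":
   it makes a threshold of 100 select nothing rather than requiring
   unanimity, and a threshold of 0 select every observed position.
4. **Close-candidate merging** (`merge_distance_nt`, default 3 nt).
   Candidates whose sorted chain has consecutive gaps at most the merge
   distance collapse to the most frequent member of the chain (frequency
   ties go to the smaller coordinate). Two points were genuinely open and
   are fixed as follows. First, "closer than" is implemented inclusively
   (`|a − b| <= d`), with `merge_inclusive = FALSE` exposing the strict
   alternative. Second, merging is *transitive* (single linkage): in a
   candidate chain 100/102/104 with counts 30/30/40 and distance 3, all
   three collapse to 104, even though 100 and 104 are 4 apart. Pairwise
   merging would leave two candidates two bases apart from the survivor's
   absorbed neighbour, defeating the purpose of the rule; transitive
   merging is also the only interpretation under which the merged set is
   stable under re-application.
5. **Assignment windows** (`window_nt`, default 5 nt per side). Each
   surviving breakpoint *b* gets the window `[b − w, b + w]`. Where
   adjacent windows would overlap they are truncated at the midpoint so
   that windows stay pairwise disjoint — disjointness is what makes read
   assignment unambiguous. An exactly equidistant position joins the more
   frequent candidate's window, with frequency ties going to the left
   candidate; this collision rule is our own choice, as any tie-break is
   equally defensible and it only matters when two real splice sites sit
   within `2w` of each other.
6. **Assignment and grouping.** Every boundary of a read must fall in
   exactly one window of its side; the read is rewritten onto the
   breakpoints and reads with identical consensus chains become one
   isoform. Reads with any unmatched boundary are rejected
   (`unmatched_boundary`) rather than force-fitted. Breakpoints are never
   re-centred to a weighted mean: the candidate position itself is the
   coordinate, which keeps coordinates editable and stable under
   reanalysis. Isoforms are ranked by read count, ties broken by length
   (longer first) and then leftmost start, and named `Iso1`, `Iso2`, …
   Abundance is `100 · read_count / n_assigned`. The denominator is the
   number of *assigned* reads: rejected reads carry no isoform
   information, and including them would make percentages depend on the
   rejection configuration in an uninterpretable way.

Optional **full-length filtering** keeps only reads whose first boundary
is assigned to the 5′-most start coordinate and whose last boundary to
the 3′-most end coordinate. In an amplicon design these outermost
coordinates are the PCR primer positions, so this is the natural
operationalisation of "complete PCR sequence"; reads failing it are
rejected as `not_full_length`.

**Custom coordinates** (`load_custom_cecs()`, `apply_custom_cecs()`)
either replace the detected set or merge with it; on overlap the custom
window wins and the detected one is dropped, on the view that a
user-asserted splice site outranks an automatic call at the same place.
`edit_cec_set()` adds, deletes or updates single coordinates with full
revalidation; isoforms must then be recomputed, and the editing tests
check that no stale chain survives.

## Parameters that matter

| parameter | default | unit | effect |
|---|---|---|---|
| `read_threshold_percent` | 2 | % of reads | sensitivity/precision trade-off: lowering it recovers rarer isoforms at the cost of spurious coordinates from alignment noise. Coordinate counts are provably non-increasing in this threshold. |
| `window_nt` | 5 | nt | how much boundary jitter is absorbed; must exceed the typical aligner placement error. Windows wider than half the distance between true splice sites get truncated at midpoints. |
| `merge_distance_nt` | 3 | nt | collapses split peaks (e.g. homopolymer wobble) into one coordinate. |
| `display_min_percent` | 1 | % | display cut for tables/plots only; never enters any denominator. |

## Input formats

BAM alignments are reduced to exon chains by splitting the CIGAR at `N`
operations only; deletions (`D`) of any length stay inside their exon,
because splice-aware aligners encode introns as `N` and deletions as
sequencing error. Secondary, supplementary and unmapped records are
dropped. GFF3 reads are `exon` features grouped by `Parent`; BED6
(0-based half-open, converted on input) uses one line per exon with the
read id in the name column. The same reads expressed in the three formats
load identically, which the tests assert.

## The simulator: what it emulates, and what it does not

`simulate_reads()` generates amplicon-style alignments from a known truth:
a small set of exon chains with per-isoform read counts, bounded integer
jitter on every boundary, an optional fraction of truncated reads
(terminal exons removed), and optional noise reads whose boundaries stay
at least `noise_margin` (default 8 nt) from every true boundary.

Jitter is applied per boundary with probability `jitter_prob` (default
0.35); a jittered boundary moves by a uniform non-zero offset in
`[−jitter, +jitter]`. Two properties follow. Offsets are *bounded*, so
with `jitter <= window_nt` every jittered boundary stays inside its
coordinate's window; and the true position remains the *modal* observed
position, so the merge rule provably selects it. Together these make
exact recovery — true chains and exact simulated counts — a theorem for
the default conditions rather than a lucky draw, and the acceptance
checks assert it exactly. (A jitter model in which every boundary moves,
e.g. plain uniform noise, breaks the second property: the modal position
becomes a random draw among `2j + 1` cells and no method could recover
the exact boundary.)

The simulator deliberately omits several features of real data:
sequence-level errors and their interaction with alignment, heavy-tailed
and strand-asymmetric boundary noise near homopolymers, chimeric reads,
length-dependent truncation bias, and abundance-dependent PCR bias.
Passing the synthetic tests therefore shows that the engine implements
its rules correctly and recovers truth under bounded, mode-preserving
noise — it does not show that the defaults are optimal for any particular
aligner or chemistry, which is exactly why every threshold is exposed and
editable.

## Comparison with a reference annotation

`reciprocal_overlap()` computes the intersection of two transcripts'
exonic base sets as a fraction of each side; `match_isoforms()` first
merges reference transcripts that mutually intersect in more than
`min_frac` (default 0.99) of their bases — such transcripts are
indistinguishable at the evaluation's own resolution, so detections
matching either are credited to the merged group — and then matches
detected isoforms one-to-one, greedily by mean overlap. "More than 99%"
is strict; at `min_frac = 1` only base-identical transcripts match.
`build_report()` builds per-gene abundance vectors (reference shares
equimolar unless the reference carries its own abundances, merged groups
summed; matched detections at their group's index, unmatched groups 0),
scores each gene by cosine similarity and also reports the cosine over
the concatenated per-gene vectors, since a single-number summary can be
aggregated either way. Detection counts are reported both in merged-group
units and in transcript units, as the two conventions genuinely differ.
Unmatched detected isoforms keep their abundance mass (shares stay
relative to the gene); they are simply absent from the vector.

## Numerical and degenerate-input choices

* Zero-count positions are never stored; frequency tables are exact
  integer counts, percentages are derived, and all tie-breaks are on
  counts, so no floating-point comparison affects the result.
* The whole pipeline is deterministic and invariant under read-order
  permutation (tested by property).
* Zero assigned reads is an explicit error carrying the rejection
  breakdown, not an empty result.
* Degenerate windows (`lower == breakpoint == upper`) are legal, as are
  single-exon isoforms.
* Cosine similarity of a zero vector is an error at the function level;
  the report layer converts "nothing detected for this gene" into an
  undefined-similarity flag and a detection count of 0.

## Problem sizes

The test-suite and acceptance computations use 200–240 simulated reads
per run, 3 true isoforms over an 800 nt amplicon, and 200 random
instances of up to 50 boundary positions for the brute-force
equivalence checks; these sizes exercise every rule (including merge
chains, window collisions and noise rejection) while keeping a full run
in well under a minute.

## Known limitations

* One locus at a time; reads on several references must be analysed
  per reference.
* Strand is ignored; antisense artifacts are not detected as such.
* The abundance model is a plain read-count ratio: no correction for the
  known tendency of long-read library preparations to over-represent
  short isoforms.
* Greedy one-to-one matching is not guaranteed optimal for pathological
  overlap structures, though at a 0.99 reciprocal threshold collisions
  are essentially absent (the tests include an all-or-nothing
  equivalence check against exhaustive assignment).
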