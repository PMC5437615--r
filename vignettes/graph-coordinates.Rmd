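---
title: "Coordinates and intervals on graph-based reference genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinates and intervals on graph-based reference genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offsetgraph)
```

## The model

A reference genome is modelled as a directed acyclic *sequence graph*: each
vertex (a **block**) is a DNA segment of one or more base pairs, each edge
joins two consecutive segments, and one designated **main path** per
chromosome reproduces the primary assembly. Assemblies with alternative
loci (regions represented by several substantially different sequences) map
onto this model directly: each alt locus runs in parallel to the chromosome
span it is placed on. Blocks may carry a length without sequence, so all
coordinate arithmetic works on topology alone; operations that need bases
(sequence spelling, fuzzy distances, flank detection) fail loudly when
sequence is absent rather than fabricating it. Edges are unlabeled and
strandless; reverse-complement traversal and cyclic graphs are out of
scope.

An **offset-based coordinate system** is obtained by partitioning the graph
into non-overlapping linear **region paths**; a coordinate is a
`(region path, offset)` pair. Desirable properties pull in different
directions — spatial coherence of coordinates, readability, monotonicity
along the genome, and *backward compatibility* (coordinates minted on an
older graph should still address the same bases after an update). The two
partitionings implemented trade these off differently:

* **Hierarchical** (`hierarchical_partition()`): one region path per
  chromosome per layer; every alternative locus (including alternatives of
  alternatives) is its own region path. Adding a path never disturbs
  existing region paths, so backward compatibility is free; spatial
  coherence between a locus and its parallel main segment is poor.
* **Sequential** (`sequential_partition()`): additionally, every region
  path is divided wherever another region path attaches or detaches.
  Coordinates on parallel paths become comparable, but an update replaces
  one region path by up to three. `apply_update()` therefore returns an
  `update_mapping` — for each new piece, its parent and start offset — and
  `resolve_legacy()` pushes any old coordinate through a chain of such
  mappings to the equivalent current coordinate.

Layered alternatives raise a genuine design question: which path is "main"
within a nested alternative subgraph is not derivable from topology. The
resolution here is explicit caller designation (`alt_paths`), with
automatic inference only in the unambiguous case where the non-main blocks
form simple chains; anything else is a partition error, never a guess.

## Conventions and numerical choices

* Offsets are **0-based** and intervals **half-open** `[start, end)`,
  matching the dominant BED convention. The choice is invisible to the
  graph machinery but fixed once, here, because mixed conventions are the
  classic source of off-by-one liftover bugs.
* An interval end at offset 0 of a region path is legal: it contributes no
  bases of that region path, which nevertheless terminates the interval's
  region-path list. This is the only convention under which half-open
  arithmetic and the conventional printed notation `(A:1 D C F:0)` agree.
* Position text accepts SI-style suffixes on input (`chr14:150m`); output
  is always plain integers.
* All iteration is deterministic (blocks and successors sorted by id), so
  equal inputs give byte-identical outputs, including serialized graphs.
* Block splits performed by `apply_update()` rename a block `b` to `b.1`
  and `b.2`; region-path identities and offsets are unaffected, which is
  what backward-compatibility statements quantify over.

## Interval notation

A **single-path interval** stores start and end coordinates plus the
ordered region paths traversed — the *full* form lists the identifier at
every change; the *minimal* form lists an inner region path only where the
walk is ambiguous. "Ambiguous" is operationalized as: at the block where a
region-path run begins, the preceding block has more than one successor
from which the interval's end block is still reachable. A greedy
drop-what-still-parses rule was rejected because it can elide the branch
actually taken while keeping a redundant main-path mention, producing
technically-unambiguous but misleading text.

Parsing accepts both the space- and comma-separated dialects and expands
minimal input back to the full form by path search. When several block
paths are consistent with the given inner list, an exact match of the full
inner list outranks subsequence matches (a full form is also a subsequence
of longer walks); residual ambiguity is an error that lists the candidates
rather than a silent choice.

One intrinsic limit is worth stating: the notation distinguishes paths by
region-path names, so two walks that differ only by an edge *skipping
blocks within a single region path* (a deletion bubble inside a main
segment) print identically. This is a property of name-based interval
notation on such graphs, not of this implementation; the property tests
exercise the faithful regime, and deletion-carrying walks are handled
exactly by the structural APIs (block paths, multipath membership), which
never round-trip through text.

## Multipath intervals

Two representations denote a *set* of paths between two coordinates:

* **Critical subpaths**: all start-to-end paths traversing every listed
  subpath. Subpaths must match contiguously — a "subpath" that matched as a
  scattered subsequence would not be a path. The empty set is the implicit
  all-paths interval; adding subpaths only ever shrinks the denoted set.
* **Fuzzy path**: a central single-path interval plus a threshold;
  members deviate by *strictly less than* the threshold. Strictness is the
  only reading consistent with the standard worked example (a 3-edit
  alternative excluded at threshold 2, any 1-edit alternative excluded at
  threshold 1). Distance is either the global edit distance of the spelled
  sequences, or `max_local`: the maximum over maximal diverging segments.

The exact local-distance decomposition is an open design point (no
authoritative definition was available), resolved as follows: the blocks
shared between the candidate and the central path (their longest common
subsequence; both endpoints always anchor) delimit maximal diverging
segments, and each candidate segment is compared against the central
segment it replaces. Anchoring on shared *blocks* rather than shared
region-path names matters: under the hierarchical partitioning a single
name like `chr14` can cover both the divergent and the shared parts of a
walk, which would corrupt a name-based decomposition. Where each region
path is one block the two readings coincide. A corollary users should
expect: two adjacent bubbles with no shared block between them form *one*
diverging segment, so `max_local` only drops below the global distance
when divergences are separated by shared sequence.

Equality of multipath intervals is extensional (same denoted set), decided
by expansion; when enumeration would exceed the path budget the comparison
falls back to canonical representation equality and flags the result with
`attr(, "method") = "canonical")`, keeping the API total without
pretending the fallback is extensional.

## Graph construction from assembly inputs

`build_simple_graph()` mirrors the naive picture: each alt locus is one
block in parallel with its placed span. Partial placement overlaps on one
chromosome are rejected (unsupported); several alts sharing an identical
span (one region, many alleles) are allowed.

`build_trimmed_graph()` removes the **flanking regions** — the leading and
trailing parts of an alt locus whose sequence is *identical* to the main
path — and connects only the **varying region**, so flank bases live on
shared main blocks. Flanks are detected as the longest common prefix and
then the longest common suffix of the remainders; prefix-first resolves the
overlap tie deterministically (identical sequences give `(L, 0)`), and an
alt identical to its main segment contributes no block at all (logged, not
an error). Exact matching rather than alignment is deliberate: the flank
definition is sequence identity, and an approximate flank would silently
move annotated bases between shared and variant blocks. The chromosome is
split at the placement borders as well as the flank boundaries, so each
alt's walk through the graph spells its full sequence — the invariant the
projection machinery relies on.

`build_merged_graph()` consumes alignment segments that partition each alt
locus and its placed span into identity and variant runs: identity runs
become shared blocks (verified to match exactly — a mislabeled segment is
an error, not a warning), variant runs become parallel blocks (one block
per contiguous run, not per base) or deletion edges. The result is a
bubble graph on which main and alt copies of a transcript can be compared
as multipath intervals.

## Transcript categorization

Transcripts are projected exon-by-exon along the source walk recorded by
the builder (chromosome main path, or the alt locus's walk across shared
and variant blocks). Alt-locus transcripts with a same-identifier main
counterpart are then labelled, on the trimmed graph, in fixed rule order:

| label | alt transcript lies on | counterpart condition |
|---|---|---|
| A | shared (flank) blocks only | projected span equals the counterpart span |
| B | varying block(s) only | within the parallel main segment |
| C | both shared and varying | within the placement span |
| D | shared blocks only | disjoint from the placement span |
| E | shared blocks only | overlaps and extends past the placement |
| none | — | no counterpart, or no rule fires |

The source notions of "nearly identical" and "similar" copies are
qualitative; they are operationalized as exact projected-coordinate
identity and span containment (a slack parameter was considered and left
at 0 — the synthetic world is exact, and slack without a calibration
target is a knob, not a model). Counterpart matching is exact identifier
equality. Rule order resolves the D/E boundary deterministically.

## The synthetic world, and what green tests establish

`generate_fixture()` states the world the tests run in: one 10 kb
chromosome; two alt loci, each 60% of an even chromosome slot; exact-match
flanks of 100–300 bp; three interior variants per alt (SNP, 5 bp
insertion, 4 bp deletion, cycling) plus one substituted base pinning each
end of the varying region — without those pins, flank detection would
legitimately extend past the planted boundary and "recovering the planted
flanks" would be ill-posed; and a planted category composition of
A=3 B=2 C=1 D=1 E=1 none=2 (two-exon flank transcripts, single-exon
varying/boundary transcripts, counterparts placed to satisfy exactly one
rule). Everything is a pure function of the seed.

This emulates the *structure* of a real assembly-plus-annotation bundle:
placements, identity/variant alignment segmentation, BED12 exon blocks,
paired transcript identifiers. It does not emulate repetitive sequence
(flank detection on real data can over-extend into repeats), alignment
error or ambiguity (identity segments here are exact by construction),
multi-chromosome interactions, strandedness, or assembly-scale sizes. A
green category-recovery test therefore establishes that projection and the
rules are implemented self-consistently and deterministically — not that
the rule thresholds reproduce any particular curated annotation set, which
would require the (version-dependent, network-scale) real data this
package deliberately does not depend on. For the same reason the merged
graph's "every walk spells a haplotype" conservation check is asserted
exhaustively only for a single-bubble alt: with several bubbles a merged
graph *denotes* recombinant walks by design, and only the two designated
walks are required to spell the input haplotypes.

## Known limitations

* No reverse strand, no cyclic graphs, no read alignment.
* Interval text cannot distinguish walks differing only by an
  intra-region-path deletion edge (see above).
* `expand_multipath()` and extensional equality are desk-scale tools,
  bounded by `max_paths`; `contains()` is the scalable membership API.
* Naming (`assign_names()`) is presentation only; nothing else consumes
  display names, so renaming policies carry no compatibility burden —
  `update_mapping` does.
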