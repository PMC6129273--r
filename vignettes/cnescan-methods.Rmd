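---
title: "Finding conserved non-coding elements with cnescan: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding conserved non-coding elements with cnescan: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnescan)
```

## The problem

Conserved non-coding elements (CNEs) are segments that stay nearly identical
between species over large evolutionary distances without coding for
protein. Operationally, a CNE pair is defined by three user thresholds: a
minimum length $\ell$, a maximum length $u$, and a relative identity
threshold $t \in (0, 1]$. A pair of substrings $(a, b)$, one from the
reference and one from the query, is reportable when

$$\ell \le |a|, |b| \le u
  \quad\text{and}\quad
  1 - \frac{d(a, b)}{\max(|a|, |b|)} \ge t,$$

where $d$ is the unit-cost (Levenshtein) edit distance. `cnescan` finds such
pairs directly from two FASTA sequences, without whole-genome alignment or a
whole-genome index, via seed (maximal exact matches), merge (co-linear
chaining) and extend (threshold-bounded growth).

## Identity normalisation

The definition of "relative identity" requires choosing a denominator. We
divide by the length of the *longer* element. This choice has three
consequences users should be aware of:

* the score always lies in $[0, 1]$ and equals 1 exactly for identical
  (N-free) strings;
* indel-driven length asymmetry is penalised — an element cannot reach a
  high score by being a short perfect fragment of a much longer partner;
* for equal-length elements it reduces to $1 - d/\ell$, which matches the
  edit budget $\ell - t\ell$ used by the anchor-length formula.

Normalising by the reference length, the query length, or the alignment
length would give slightly different scores near the threshold; anyone
comparing output against another tool should check which convention that
tool uses.

## Stage 1: seeding with maximal exact matches

A maximal exact match (MEM) is a triple `(i, j, m)` such that
`x[i..i+m) == y[j..j+m)` and the match can be extended neither left nor
right. Any element pair of length $\ell$ whose edit distance is within the
budget $e = \lfloor \ell - t\ell \rfloor$ is cut by its at most $e$ edits
into at most $e + 1$ exact aligned runs, the longest of which has length at
least $\lfloor \ell/(e+1) \rfloor$. MEMs of at least this length are
therefore a complete seed set: no reportable element can evade stage 1. The
package computes the budget as an integral operation count,
$e = \lfloor \ell(1-t) \rfloor$ (with a $10^{-9}$ fuzz against binary
round-off such as $200 \times 0.05$ evaluating just above 10), because a
fractional denominator in the printed form of the bound has no operational
meaning. A user-supplied anchor length is reconciled by taking the maximum
of the two values: a longer user anchor trades sensitivity for speed, while
a shorter one is ignored because the formula value is already guaranteed
complete.

Enumeration hashes every k-mer of the reference
($k = \min(L_{\min}, 31)$, two bits per base) and streams the query: a
candidate `(i, j)` whose left neighbours still match is skipped
(not left-maximal), the rest are verified by direct base comparison and
extended to the right. Every MEM is found exactly once, at its left end.
The hash only proposes positions — matching is never probabilistic. `N`
matches nothing, *including another `N`*: masked bases can never seed a
match, terminate any exact run, and cost one edit against every letter. This
is deliberate: a masked position carries no sequence information, so letting
it match would silently inflate identity.

With multiple workers the reference k-mer start positions are partitioned
into blocks; since a MEM is detected only at its left end, the block
decomposition partitions the MEM set exactly, and results are deduplicated
and sorted regardless, so output is byte-identical for any worker count.

At the formula bound the seed set is large on megabase inputs — random
background alone yields roughly $nm(3/4)^2/4^{L_{\min}}$ MEMs, about two
million for a 1 Mbp × 0.5 Mbp comparison at $L_{\min} = 9$ — which is why
enumeration, edit distance and chaining are implemented in C++ under `src/`.

## Stage 2: merging anchors into co-linear chains

Anchors are sorted by reference start and consumed greedily, left to right,
each at most once. From the current chain end, the eligible successors are
the unused anchors that start at or after the chain end in *both* sequences
(strict co-linearity, no overlap) with both gaps at most `merge_max_gap`;
they are tried in increasing order of (reference gap + query gap), ties
broken on the smaller query start, and the first one that keeps both spans
at most $u$ and the chain identity at least $t$ is appended. The chain
identity is $1 - g/\max(\text{spans})$ where $g$ accumulates the edit
distance of the paired gap substrings — an empty-versus-nonempty gap pair
costs the nonempty length, and $g$ is always at least the summed gap-length
differences. Merging a chain stops when no eligible successor remains.

Greedy chaining (rather than optimal dynamic-programming chaining) was a
deliberate choice: termination is defined incrementally ("adding the next
gap would cross $t$"), the greedy scan implements exactly that, and it runs
in near-linear time over millions of anchors. The cost is that an
adversarial anchor layout could be chained suboptimally; for planted and
real conservation structure, anchors along one element lie on essentially
one diagonal and the greedy chain is the natural one.

Chains whose combined anchor length is below `min_chain_coverage`
(default $\lfloor \ell/2 \rfloor$) are dropped before extension. This is the
main guard against the background seed mass: a spurious 9 bp anchor cannot
reach 100 bp of coverage, while a genuine 2%-divergent element of length
$\ell$ keeps most of its length in exact runs. The default is a balance, not
a theorem — raising it toward $\ell$ makes the filter stricter but starts to
reject highly indel-interrupted elements.

`merge_max_gap` defaults to $\ell$: a gap longer than the minimum element
length cannot sit inside a $\ge t$-identity element of length $\le u$ in any
common regime ($t$ near 1), and bounding the gap keeps the candidate scan
local.

## Stage 3: threshold-bounded extension

The chain hull then grows in windows of `ext_step` bases (default 5) per
side. Each iteration computes the edit distance of the left extension
windows (reference-left vs query-left) and of the right windows. If the
estimated identity — accumulated cost over the grown spans — stays at or
above $t$ with both sides added, both are taken; otherwise only the cheaper
side. When even the cheaper side would cross $t$, the *actual* edit distance
of the whole current element is recomputed. The accumulated estimate is an
upper bound (window-by-window costs cannot be below the global optimum), so
this re-adjustment can only lower the distance, and extension continues if
it does; if not, extension stops. Extension also stops when either element
reaches $u$, and a side is blocked when a sequence boundary or an adjacent
`N` is reached.

Two consequences of this design are worth stating plainly:

* **Reported elements end near $t$, not at the planted identity.** A
  2%-divergent element searched at $t = 0.9$ will usually be reported with
  some flanking sequence attached and an identity between 0.9 and ~0.95,
  because extension keeps absorbing flank while the threshold allows. The
  elements are longer than the conserved core, never shorter, and the final
  identity — recomputed once more over the final element and checked against
  $t$ — is the verified value stored in the output.
* **An exactly conserved region longer than $u$ is not reportable.** The
  length cap is enforced on both elements throughout merging and extension;
  a single exact match longer than $u$ yields no hit rather than an
  arbitrarily truncated one. Users who want such regions should raise $u$.

The per-side window pairing (reference-left vs query-left, right vs right)
is the straightforward one; cross-pairings would only matter for elements
whose conserved core is shifted far off-diagonal, which the gap-bounded
chaining already excludes. `ext_step = 5` bounds the number of full-element
distance recomputations while keeping the overshoot beyond the point where
identity reaches $t$ to a few bases per side.

Finally, hits whose reference *and* query intervals reciprocally overlap
another hit by more than 50% are grouped transitively and only the best
representative survives (highest identity, then longest reference span, then
smallest start). Output is sorted by reference coordinate; rerunning the
same input, with any thread count, reproduces the same bytes.

## Preprocessing: masking and search modes

Exons are not non-coding and repeats are conserved for the wrong reasons, so
both are removed from the search space before seeding. The mask is the union
of: exon-typed GFF3 features (`exon` and `CDS` by default — the feature
vocabulary is configurable because annotations vary), BED repeat intervals,
and (on by default) maximal lowercase runs of the input, since soft-masked
assemblies encode simple and low-complexity repeats exactly that way.
Masked positions are *replaced by `N`*, never deleted, so every downstream
coordinate remains in source-sequence space with no translation table; the
operation is idempotent. GFF3 (1-based inclusive) and BED (0-based
half-open) conventions are converted at this boundary and nowhere else; all
internal and output coordinates are 0-based half-open, and command-line
range strings `chr:start-end` are 1-based inclusive to match genome-browser
habit.

Three search modes restrict the region: a whole record, an explicit
coordinate range, or a window of `flank` bp (default 1 Mbp) around a named
gene looked up in the annotation. The gene window is a fixed flank clamped
to the sequence — it is *not* bounded at neighbouring genes; 1 Mbp reflects
the scale of regulatory domains around developmental genes and is
user-configurable. Searching the minus strand is available behind an
explicit flag (`revcomp`) and off by default, matching the forward-strand
definition of the core algorithm; minus-strand hits are reported in
plus-strand query coordinates with strand `-`.

## The synthetic-data generator

`synth_spec()` / `generate_pair()` produce the validation inputs: two
independent random backgrounds (GC 0.41 by default, human-like), `n_cne`
reference segments copied into the query with exactly
$\lceil \text{divergence} \times \text{length} \rceil$ mutations at distinct
positions, decoy copies mutated above the identity budget, and fake exon
features (default density 2%, the order of exonic coverage in mammalian
genomes) over non-planted reference intervals. Substitutions always change
the base and mutation positions never collide, so realised divergence is
exact rather than binomially noisy — acceptance thresholds can then be tight
without being flaky. Indels are single-base (10% of mutations by default),
which keeps the planted identity bound
$1 - m/\max(|a|,|b|)$ simple. Everything is reproducible from one seed.

The standard validation scenario — the generator's defaults — is a 1 Mbp
reference versus a 0.5 Mbp query with 50 planted elements of 200–500 bp at
2% divergence and 10 decoys at 20%, searched at
$\ell = 200, u = 500, t = 0.9$. The unit suite works on scaled-down variants
of the same structure (tens of kilobases); the full scenario runs in the
acceptance tests and in `scripts/acceptance.R`.

What passing these tests shows: the three stages are jointly sound
(every reported pair re-verifies at $\ge t$ within the length bounds, with
zero tolerance), sensitive on cleanly planted conservation, and robust to
decoys well above the divergence budget. What it does not show: performance
on real genomes with segmental duplications, large indels, rearranged or
inverted conservation, GC heterogeneity, or annotation errors. The generator
plants co-linear, forward-strand, 1-bp-indel homology into i.i.d.
background; real comparative data are messier in all four respects, and the
masking stage depends entirely on the quality of the supplied annotation.

## Numerical and degenerate-input choices

* Identity comparisons against $t$ use an absolute $10^{-9}$ slack on the
  edit-count side (`d <= (1-t) * span + 1e-9`) so that chains and elements
  sitting exactly on the threshold are kept regardless of binary rounding.
* The edit budget and the anchor bound are computed in integer arithmetic
  after flooring, as described above.
* `edit_distance` accepts empty strings (distance is the other length);
  `identity_score` on two empty strings is an error, as no denominator
  exists.
* A fully masked (all-`N`) region yields zero anchors and an empty result,
  not an error. Empty hit tables are written as a header-only file and read
  back as empty tables.
* Ties in deduplication are broken deterministically (identity, reference
  span, start), and all outputs are fully sorted, so byte-identical
  reproduction holds across runs and worker counts.

## Known limitations

* Unit-cost edit distance only; affine or weighted gap models are out of
  scope, as is alignment traceback (the tool reports intervals and
  distances, not CIGAR strings).
* Greedy chaining is not guaranteed optimal for adversarial anchor layouts.
* Elements longer than $u$ with no internal break are not reported.
* Pairwise comparison only; no multi-species extension.
* The k-mer hash holds one position list per reference k-mer; highly
  repetitive *unmasked* reference sequence inflates both memory and
  candidate counts. Masking repeats first (the default pipeline behaviour)
  is strongly recommended.
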