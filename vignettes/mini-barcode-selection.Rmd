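---
title: "Selecting mini-barcodes by sliding-window analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting mini-barcodes by sliding-window analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibar)
```

## The problem

Full-length barcoding markers (COI and its alternatives) are often
unamplifiable from degraded DNA — digested prey tissue, faeces,
environmental samples, old collections — because the template is broken
into fragments shorter than the distance between conventional primer
sites. Identification information, however, is not spread evenly along a
marker: a well-chosen sub-region of 100 bp or so can separate a given set
of species as reliably as the full sequence. This package selects that
sub-region *objectively*, by scoring every candidate window of a range of
widths over a species-labelled reference alignment, instead of evaluating
a handful of hand-picked candidates.

## Window statistics and the selection rule

For each window `slide_analysis()` computes:

* **`zero_noncon`** — among pairs of sequences from different species
  with at least one comparable site in the window, the fraction at
  p-distance exactly 0. Distances use pairwise deletion: a column with a
  gap or an IUPAC ambiguity code in either sequence of a pair is dropped
  for that pair. Zero means "this window cannot tell the pair apart";
  the default criterion demands none at all. A single mismatch is enough
  to count a pair as separated — a deliberately liberal cut-off, since
  fixed percentage thresholds calibrated on full-length barcodes do not
  transfer to 25–250 bp fragments.
* **`congr_all` / `congr_shallow`** — the fraction of clades of the
  full-alignment neighbour-joining tree that reappear (as identical tip
  sets) in the window's tree; `congr_shallow` restricts the reference set
  to clades whose tip count lies strictly below the median over all
  reference clades. Shallow (tipward, species-group-level) structure is
  what assigns an unknown read to the right neighbourhood when its
  species is absent from the library.
* **`monophyly`** — fraction of species with at least two
  representatives that are monophyletic in the midpoint-rooted window
  tree (`NA` when every species has one representative).
* **`sum_dist`**, **`mean_gc`**, **`n_diagnostic`** — summed defined
  pairwise distance, G+C fraction over unambiguous cells, and the number
  of columns where some species is fixed for a base found in no other
  species. These support alternative selection rules and primer-site
  scouting; they do not enter the default criterion.

A window **qualifies** when `zero_noncon <= max_zero_noncon` (default 0)
and `congr_shallow > min_congr_shallow` (default 0.85, strict
inequality — so 6 of 7 shallow clades, 0.857, passes the default bar).
Among qualifying windows the smallest width wins; ties are resolved by
higher shallow congruence, then by the leftmost start. These two
tie-breaks are this package's own convention: the selection principle
only fixes "shortest". When nothing qualifies the result carries a
`nearest_miss` window, the one minimising the sum of its two criterion
deficits.

Coordinates are 1-based and inclusive in every user-facing table, so a
selected window `(start = 210, width = 100)` covers columns 210–309.

## Tree-building choices

*Distance model.* Uncorrected p-distance, because the zero-distance
criterion is a pure identity test, for which p-distance is exact, and
model-corrected distances (K2P and relatives) are unstable on windows as
short as 25 bp. Ambiguity codes are treated as missing rather than as
partial matches — conservative for the zero test. A pair with no
comparable site has an *undefined* distance: it is excluded from
`zero_noncon`, and a window whose matrix contains any undefined entry
gets no tree (the window is kept in the metrics table but cannot be
selected).

*Neighbour joining* is the classical Saitou–Nei agglomeration with two
determinism guarantees: ties in the Q criterion are broken by the
smallest pair of current matrix indices, and a negative branch-length
estimate is clamped to zero with the deficit moved to the sister branch,
preserving the joined pair's path length. Runs are therefore
bit-reproducible. (`ape`'s `nj()` serves as an independent cross-check in
the test suite, never as the implementation.)

*Rooting.* Clades — and hence "node depth" — require rooted trees, but
nothing in the inputs distinguishes a root. Both trees are midpoint
rooted before clade extraction, which is reproducible and needs no
taxon-specific knowledge; an already-rooted reference (e.g. by outgroup)
is respected by `congruence()`. Ties for the longest tip-to-tip path are
broken by the lexicographically smallest endpoint-label pair. We compare
*rooted clades* rather than unrooted bipartitions, and congruence is
directional: the fraction of *reference* clades recovered, since windows
are judged as representations of the full-data topology.

*Median-depth boundary.* Clades exactly at the median depth are excluded
from the shallow set (`shallow_rule = "strict"`); `"inclusive"` is
available for sensitivity analysis. On small or very symmetric reference
trees every cherry can sit exactly at the median, leaving the strict
shallow set empty; `slide_analysis()` then falls back to the inclusive
rule with a warning rather than failing the run.

## Primer evaluation and the amplicon pipeline

`insilico_pcr()` matches IUPAC-degenerate primers (a position matches
when the template base is in the primer code's expansion set; default 0
mismatches, because group specificity rests on exact discrimination at
the degenerate sites) on both template orientations and returns the
amplicon *including both primer sites*. Product lengths are therefore
primer-inclusive everywhere, including the 120–160 bp read filter — the
convention consistent with a 134 bp product encompassing a 100 bp
informative window. Primer sequences are always user input; the package
evaluates primers but does not design them.

The read pipeline applies, in order: exact dereplication after orienting
each read by the forward primer; rejection of reads shorter than 120 or
longer than 160 bp (both bounds inclusive — only strict violations are
excluded); rejection of reads without a complete primer flush at either
end; rejection of amplicons seen fewer than 5 times, pooled across all
samples — the copy-number heuristic against chimeras and PCR artefacts.
Each rejected amplicon records its *first* failing reason in that order,
so raw counts always decompose as kept + per-reason rejected.

Assignment compares each amplicon to every gap-stripped library sequence
by p-distance over an end-gap-free (overlap) pairwise alignment — at the
divergences involved this is equivalent to a local-alignment search while
staying dependency-free. The default acceptance ceiling
`max_assign_dist = 0.02` sits well below typical minimum inter-species
divergence for this kind of marker (≥ 4%), so correct assignments pass
with margin while cross-species assignments are excluded; an exact tie
between two species yields `"ambiguous"`. Unassigned amplicons are
clustered by single linkage at `link_dist = 0.04`, echoing the common 4%
species-delimitation floor; clusters are reported as `novel:1`,
`novel:2`, … by decreasing read count. This distance clustering stands in
for an external database-confirmation step: it delimits candidate novel
clades but cannot, by itself, prove they are real species rather than
artefacts.

## What the simulators emulate — and what they do not

`simulate_reference()` builds alignments with alternating conserved and
variable blocks, the structure that makes a marker suitable for internal
primers around a variable core. Within each variable block every species
receives `m = ceiling(inter_div * block_length / 2)` *private* mutated
positions (disjoint across species), which guarantees every species pair
differs at a fraction ≥ `inter_div` of block columns, and the remaining
capacity is spent on mutations shared along a random species hierarchy,
so distances are tree-like rather than uniform and window trees have
genuine structure to recover. Defaults emulate a small reference library
of the shape used for 16S mini-barcoding: 15 species, one representative
each, 430 columns, variable block at columns 180–300, 4% minimum
inter-species divergence. Conspecific copies mutate a fraction
`intra_div` (default 0) of non-private positions, so the inter-species
guarantee is never eroded.

`simulate_reads()` draws primer-inclusive amplicons by species abundance,
applies independent per-base substitution errors, splices a configurable
fraction of chimeras from two parent amplicons at a uniform breakpoint,
and tags reads with one of 46 sample identifiers (the pooled-samples
shape of a faecal amplicon run).

Deliberate simplifications: the mutation model is substitution-only
(keeping truth coordinates exact for window-recovery tests — an indel
mode would blur them), errors are uniform rather than
homopolymer-biased as in real pyrosequencing, chimeras are clean
two-parent splices, and abundances are independent of sample. Passing
tests on these simulations therefore demonstrate correctness of the
*computations*, not robustness to alignment error, NUMTs, or platform-
specific artefacts in real data.

## Problem sizes used by the tests

The test-suite and the acceptance script exercise: the full width ladder
on 419- and 430-column alignments (1745 and 1811 windows); brute-force
agreement on 200 random alignments of up to 8 sequences and 60 columns;
neighbour-joining consistency on 100 random 4–8-tip additive matrices;
window recovery on 100 simulated 8-species, 200-column libraries with a
planted block (widths 25/50/100 at step 5); and pipeline truth recovery
on 600 error-free reads from 18 simulated species, 15 of them in the
library. These sizes were chosen as the smallest at which each property
is meaningfully tested.

## Known limitations

* Reference input must already be aligned; the package does not align.
* Windows are scored independently; no multiple-testing view across the
  1,800-odd candidates is attempted — the criteria are descriptive, not
  inferential.
* Congruence counts exact clade identity only; a window tree that is
  "nearly right" (one tip misplaced within a clade) scores the same as a
  badly wrong one for that clade.
* Novel-clade counts depend on `link_dist` when true clades approach the
  linkage threshold; the report's minimum library distances should be
  inspected before reading the clusters as species.
* An open ambiguity in the window census: a 430-column alignment yields
  1811 windows at the standard ladder, while an effective length of 419
  yields 1745; end-trimming or removal of gap-only columns before
  enumeration explains such differences, and `enumerate_windows()` makes
  the count explicit for any length.
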