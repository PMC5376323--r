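---
title: "Chemical-group characterization of protein sequences: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-group characterization of protein sequences: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemgroups)
```

## The reduced alphabet

Every function in this package sits on one mapping: the 20 standard amino
acids partitioned into 8 classes by side-chain chemistry.

```{r}
chemical_groups()
```

The member sets are the normative definition; the names are derived from
them (group 3 = Y/F/W is the aromatic class, group 4 = I/L/V/A/G the
aliphatic one, as the side chains dictate). Codes 1–8 double as node
labels in the transition graphs, so "edge 62" always reads
sulfur-containing → basic.

Nonstandard letters (B, J, O, U, X, Z, gaps) have no group. The default
policy is a hard error naming the character and position, because every
downstream report is position-based and silent coercion would shift
coordinates. The `skip` policy drops offending positions, warns, and
records which original positions were removed; reported positions then
still refer to the original sequence. Alignment gap handling is
deliberately out of scope — all analyses are alignment-free.

## Composition and the dissimilarity

For sequence $S_i$ of length $L_i$, the group count $S_i(T_k)$ is the
number of residues in group $k$, and the percent score is

$$S_i(G_k) = \frac{S_i(T_k)}{L_i} \times 100 .$$

The dissimilarity between two sequences is the L1 distance on percent
vectors:

$$D_{ij} = \sum_{k=1}^{8} \left| S_i(G_k) - S_j(G_k) \right| .$$

$D$ is a true metric on the percent vectors (symmetry, triangle
inequality; $D = 0$ exactly for identical group composition, which
distinct sequences can share), bounded by 200. Two numerical choices:

* Percents are carried at full double precision; only display and TSV
  output round. Tests compare against 4-decimal reference values with
  absolute tolerances of 5e-5 (composition) and 5e-4 (dissimilarity),
  the precision those references are stated at.
* Compositions are computed over the sequence exactly as given. The
  packaged cytochrome tables count the full deposited sequences (signal
  peptide included: lengths 91, 91, 95, 92, 90), so the package defaults
  to the same convention; `sequence_range()` extracts a mature chain
  (e.g. residues 21–91) when that is wanted instead.

`composition_from_counts()` exists so that a published per-amino-acid
count table is a first-class input: the worked cytochrome example runs
entirely from `load_fixture("table3_counts")` without the sequences.

## Single-linkage tree

The dendrogram uses nearest-distance agglomeration: the distance between
clusters is the minimum pairwise entry, which guarantees monotone
non-decreasing merge heights. Three conventions are fixed for
determinism and lossless output:

* **Tie-break.** When two cluster pairs share the minimal distance, the
  lexicographically smallest pair of cluster indices merges first (a
  merged cluster keeps the slot of its smaller constituent). Ties are
  measure-zero for continuous data but arise in degenerate and test
  matrices.
* **Branch lengths.** Newick output places leaves at height 0 and
  assigns each branch half the parent–child height difference, the
  standard ultrametric display; leaf-to-leaf path length then equals the
  cophenetic merge height. Raw merge heights are also written as a
  sidecar TSV (`write_merges_tsv()`), so the halving convention loses
  nothing.
* **Cluster labels** in the merge table are sorted leaf sets
  (`{PpcC,PpcD}`), reproducible across runs.

On the packaged tables the merge order is {PpcC,PpcD} at 11.8535,
{PpcB,PpcE} at 12.0391, PpcA joining {PpcC,PpcD} at 16.5313, and the root
at 17.5824 — PpcA attaches to its nearest homologs only after the two
tight pairs have formed, and `autoplot()` draws exactly this structure.

## Order-pair digraphs

The digraph of a reduced sequence has an edge $u \to v$ for every
consecutive pair $(T(i), T(i+1)) = (u, v)$; self-loops are legal. The
binary adjacency matrix is the canonical object for cross-sequence
comparison; multiplicities and per-edge source position lists are kept
alongside because repeated edges are what produce alternative subdomain
windows. Edge positions are indexed by the **source** residue (1-based),
so an edge realized by residues 41–42 is reported at position 41.
Multiplicities always sum to $L - 1$.

Group contrasts follow set logic: an edge is *unique to group A* when it
is present in every member of A and absent from every member of B;
*common to all* when present in every member of both. The comparison
table reports the full presence counts per side rather than only the
extreme categories, so partial patterns remain visible.

## Cycles and subdomains

Simple directed cycles of 3–6 edges (the defaults; the enumerator
accepts 1–8) are enumerated by depth-first search rooted at each cycle's
smallest node, visiting only larger nodes — each cycle is found exactly
once, already in canonical rotation. The canonical string starts at the
smallest code and omits the closing repeat: the triangle
2 → 3 → 6 → 2 is `"236"` (its closed form `"2362"` is also reported).
Graphs have at most 8 nodes, so exhaustive search is exact and cheap; the
test suite checks it against an independent brute-force enumeration and a
closed-form count on the complete digraph
($\sum_{k=3}^{6} \binom{8}{k}\,(k-1)! = 5236$ cycles).

**Cycle presence is edge-set-wise**: a cycle is present in a sequence
when each of its edges occurs *somewhere* as a consecutive pair, not as
one contiguous traversal. This is the only reading under which a 3-cycle
can span a 36-residue subdomain, and it makes presence a function of the
edge set, so cycles shared by a whole group are exactly the cycles of the
intersected adjacency matrix.

A *subdomain window* for a cycle is the residue span $[\min p,\ \max p + 1]$
obtained by choosing one occurrence position $p$ per cycle edge — the
$+1$ covers the target residue of the rightmost pair. With repeated edges
many candidate windows exist; only the minimal ones (containing no other
candidate) are reported, sorted by start. They are computed by a sliding
sweep over the pooled occurrence list rather than by enumerating all
combinations, which is equivalent (the tests verify this against the
combination oracle) but immune to combinatorial blow-up on long
sequences. Whether a published figure's span is the minimal one cannot
generally be known; minimality is this package's defined behavior.

## Patterns

Pattern search runs over group codes with a mismatch budget: a hit may
have up to `max_mismatch` positions whose residue group differs from the
pattern code, and those within-pattern indices are reported — this is how
`CTGCHK` matches the heme-site pattern `624621` with deviations at 2 and
6. Discovery is exact k-mer intersection (`conserved_kmers()`) and
set-difference (`group_specific_kmers()`), alignment-free by
construction. A conserved k-mer is additionally flagged
*residue-conserved* when every occurrence in every sequence realizes the
identical residue string, a group-free notion of conservation that needs
no alignment either. The default report length $k = 4$ in
`run_characterize()` matches the scale of the short conserved blocks in
the cytochrome family (`HKKH`, `44441`); it is a report granularity
knob, not a model parameter.

## Synthetic sequences

`generate_sequence()` emits sequences with an exact per-group count
vector (or percent targets converted by largest-remainder rounding),
drawing residues uniformly within each group and shuffling the order
under a caller-supplied seed; the RNG state is isolated with
`withr::with_seed`, so generation never perturbs the caller's stream.
This emulates precisely what every downstream computation consumes —
group composition and group order statistics — and nothing else: there is
no positional structure, no heme-binding motif, no residue-level usage
bias. Tests passing on synthetic data therefore validate the arithmetic
and the invariants (round-trip of composition, edge conservation, metric
axioms), not biological realism.

The test suite runs the brute-force cycle oracle on 200 random digraphs
and the invariant battery on 100 random instances with sequence lengths
of 10–150 residues — comfortably past the ~90-residue scale of the
motivating family, where every computation is effectively instantaneous.

## Limitations

* The dissimilarity sees composition only: sequences with permuted
  residues are indistinguishable, and $D = 0$ does not imply identity.
  The digraph and pattern layers recover order information, but only at
  group resolution.
* No similarity percentage is derived from $D$; only the dissimilarity
  itself is reported, since any similarity transform would add an
  arbitrary normalization.
* Group contrasts (`unique to A`) are sensitive to single-member noise
  by design — one edge gained or lost in one sequence moves an edge
  between categories. For larger families a frequency-based contrast
  would be more robust; with 1-vs-4 sized homolog groups the set logic
  is the intended behavior.
* The reduced alphabet is fixed to the 8 side-chain classes. Alternative
  reductions (hydrophobicity classes etc.) are out of scope.
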