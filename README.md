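# chemgroups

Alignment-free characterization of protein sequences through the chemistry
of their amino acid side chains.

Protein homologs can share structure and function at modest sequence
identity, and conversely a single residue swap within the same chemical
class often changes nothing that matters. `chemgroups` works at the level
where those swaps are invisible: it re-expresses a protein over a reduced
alphabet of 8 chemical groups and characterizes sequences by their group
composition, group-transition graph and group-level patterns. The package
is aimed at sequence analysts comparing small homolog families — the
motivating system is the five periplasmic triheme c7-type cytochromes
PpcA–E of *Geobacter sulfurreducens*, where PpcA alone binds deoxycholate
and PpcD is the structural outlier, and the packaged worked-example tables
come from that family.

## The method

**Reduced alphabet.** Each residue maps to one of 8 chemical groups:

| code | group | members |
|------|-------|---------|
| 1 | Acidic | D, E |
| 2 | Basic | R, H, K |
| 3 | Aromatic | Y, F, W |
| 4 | Aliphatic | I, L, V, A, G |
| 5 | Cyclic | P |
| 6 | Sulfur-containing | M, C |
| 7 | Hydroxyl-containing | S, T |
| 8 | Acidic amide | Q, N |

**Composition dissimilarity.** For sequence *S<sub>i</sub>* of length
*L<sub>i</sub>*, the group score per hundred residues is
*S<sub>i</sub>(G<sub>k</sub>) = S<sub>i</sub>(T<sub>k</sub>) / L<sub>i</sub> × 100*
with *S<sub>i</sub>(T<sub>k</sub>)* the count of residues in group *k*.
The dissimilarity between two sequences is the L1 distance on these
8-dimensional percent vectors,

*D<sub>ij</sub> = Σ<sub>k=1..8</sub> | S<sub>i</sub>(G<sub>k</sub>) − S<sub>j</sub>(G<sub>k</sub>) |*,

which ranges over [0, 200] and needs no alignment. A dendrogram is built
from the pairwise matrix by nearest-distance (single linkage)
agglomeration.

**Order-pair digraph.** Reading the reduced sequence as consecutive
ordered pairs (T(i), T(i+1)) gives a directed graph on at most 8 nodes.
Edges, bounded-length simple cycles (default 3–6 edges) and the residue
windows ("subdomains") that realize a cycle's edges are compared across
homolog groups to find features unique to one set — e.g. an edge present
in every member of one group and absent from the contrasted group.

**Chemical patterns.** Group-level k-mer search with a mismatch budget
(mismatch = residue whose group differs from the pattern code) and
conserved/group-specific k-mer discovery, all on unaligned sequences with
1-based coordinates.

## Worked example

The package ships the per-amino-acid count table of the five cytochromes
(`load_fixture("table3_counts")`), so the full composition analysis runs
without the sequences themselves:

```r
library(chemgroups)

comp <- composition_from_counts(load_fixture("table3_counts"))
composition_wide(comp)
#> # A tibble: 5 × 10
#>   id    length    G1    G2    G3    G4    G5    G6    G7    G8
#>   <chr>  <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 PpcA      91 11.0   27.5  4.40  36.3  4.40 11.0   3.30  2.20
#> 2 PpcB      91  8.79  23.1  4.40  35.2  3.30 11.0  11.0   3.30
#> 3 PpcC      95  9.47  22.1  4.21  42.1  5.26  9.47  6.32  1.05
#> 4 PpcD      92  9.78  25    3.26  41.3  1.09 10.9   6.52  2.17
#> 5 PpcE      90  6.67  24.4  6.67  34.4  3.33  8.89 13.3   2.22

chem_dissimilarity(comp)
#> Chemical group dissimilarity matrix (5 sequences, % units)
#>         PpcA    PpcB    PpcC    PpcD    PpcE
#> PpcA  0.0000 17.5824 19.4563 16.5313 24.6642
#> PpcB 17.5824  0.0000 19.1787 18.1080 12.0391
#> PpcC 19.4563 19.1787  0.0000 11.8535 25.9649
#> PpcD 16.5313 18.1080 11.8535  0.0000 25.0242
#> PpcE 24.6642 12.0391 25.9649 25.0242  0.0000
```

PpcA and PpcB differ by 17.58 percentage points of group composition —
the acidic group alone contributes |10.99 − 8.79| = 2.20 of that. PpcA's
*nearest* homolog is 16.53 away (PpcD), while the closest pair overall is
PpcC–PpcD at 11.85: PpcA stands apart from all of its homologs in group
composition. Single linkage turns the matrix into a tree:

```r
tree <- single_linkage(chem_dissimilarity(comp))
tidy(tree)
#> # A tibble: 4 × 4
#>    step cluster_a        cluster_b   height
#>   <int> <chr>            <chr>        <dbl>
#> 1     1 {PpcC}           {PpcD}        11.9
#> 2     2 {PpcB}           {PpcE}        12.0
#> 3     3 {PpcA}           {PpcC,PpcD}   16.5
#> 4     4 {PpcA,PpcC,PpcD} {PpcB,PpcE}   17.6

to_newick(tree, digits = 4)
#> "((PpcA:8.266,(PpcC:5.927,PpcD:5.927):2.339):0.5256,(PpcB:6.02,PpcE:6.02):2.772);"
```

Graph and pattern analysis work from sequences. The conserved hexamer
around the third heme-binding site, `CKGCHE`, reduces to `624621`
(Sulfur–Basic–Aliphatic–Sulfur–Basic–Acidic) and walks a 4-edge digraph
in which the sulfur-to-basic transition `62` occurs twice:

```r
g <- build_digraph("624621", id = "hexamer")
tidy(g)
#> # A tibble: 4 × 5
#>    from    to edge  multiplicity positions
#>   <int> <int> <chr>        <int> <list>
#> 1     2     1 21               1 <int [1]>
#> 2     2     4 24               1 <int [1]>
#> 3     4     6 46               1 <int [1]>
#> 4     6     2 62               2 <int [2]>

# the PpcD variant CTGCHK deviates chemically at positions 2 and 6
find_pattern(tibble::tibble(id = "PpcD", sequence = "CTGCHK"),
             "624621", max_mismatch = 2)$mismatches
#> [[1]]
#> [1] 2 6
```

All residue coordinates in every output are 1-based inclusive. A
command-line interface wrapping these functions (subcommands `encode`,
`compose`, `dissim`, `tree`, `graph`, `cycles`, `patterns`, `compare`,
`synth`, `characterize`) is installed at
`system.file("cli", "chemgroups", package = "chemgroups")`.

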