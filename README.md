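# quartetdist

Fast, exact quartet distances between **general** (multifurcating) unrooted
phylogenetic trees.

Different inference methods, or different data over the same species, often
produce slightly different trees. The *quartet distance* quantifies the
disagreement: of the C(n,4) four-species subsets, it counts those whose
induced quartet topology differs between the two trees. On trees whose
inner nodes may have any degree ≥ 3, a quartet can be a resolved
*butterfly* `ab|cd` or an unresolved *star*, so the distance decomposes as

    qdist(T, T') = diff_S + diff_B
    diff_S = B + B' − 2·shared_B − 2·diff_B

where `B`, `B'` are the butterfly counts of each tree, `shared_B` the
quartets resolved identically, `diff_B` those resolved as different
butterflies, and `diff_S` those resolved in one tree but starred in the
other.

`quartetdist` counts `shared_B` and `diff_B` without ever enumerating
quartets. Every directed butterfly is *claimed* by exactly one directed
inner edge (two leaves behind the edge, two in distinct subtrees in
front). For each pair of inner edges, one per tree, the number of directed
butterflies claimed identically — and the number claimed with conflicting
resolution — collapses to a constant-time expression in precomputed
aggregates of the node-pair matrix `I[i,j] = |F_i ∩ G_j|` (the leaf
intersections of the two nodes' subtrees), with the only super-quadratic
work being dense matrix products of the form `I·Iᵀ·I` carried out by BLAS.
The result is exact integer counts with overall sub-cubic cost that is
independent of node degrees, close to quadratic in practice. A brute-force
O(n⁴) enumeration oracle, seeded generators for four benchmark tree
classes, and a CLI round out the package.

## Worked example

```r
library(quartetdist)
t1 <- parse_newick("(((a,b),c,(d,e)),(f,(g,h)));")
t2 <- parse_newick("(((a,c),b,(d,h)),(f,(g,e)));")
quartet_distance(t1, t2)
#> Quartet distance components (n = 8, C(n,4) = 70)
#>   butterflies T:  58
#>   butterflies T': 58
#>   shared_B:       12
#>   diff_B:         37
#>   diff_S:         18
#>   quartet distance: 55  (normalized 0.7857142857)
```

Of the 70 quartets, each tree resolves 58 (both have one degree-4 node, so
12 quartets are stars in each); 12 are resolved identically, 37 are
resolved differently, and 18 are a butterfly in one tree but a star in the
other, giving a distance of 37 + 18 = 55. `method = "bruteforce"` computes
the same numbers by enumerating all quartets — useful as a cross-check on
small trees.

Benchmark-class trees come from the seeded generators:

```r
quartet_distance(random_general_tree(500, seed = 1),
                 sqrt_hub_tree(500, seed = 2))
butterfly_count(random_binary_tree(100, seed = 1))  # choose(100, 4)
```

## Command line

```sh
inst/cli/qdist dist T1.nwk T2.nwk --components --normalize [--json]
inst/cli/qdist gen --n 1000 --kind general --seed 3 -o T1.nwk
inst/cli/qdist bench --sizes 500,1000,2000 --kinds binary,binary
```

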