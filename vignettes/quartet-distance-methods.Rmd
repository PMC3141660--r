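---
title: "Counting quartets on general trees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting quartets on general trees: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetdist)
```

## The distance and its decomposition

For two unrooted trees $T$, $T'$ on the same $n$ leaves, the quartet
distance is the number of 4-leaf subsets whose induced topology differs.
When inner nodes may have any degree $\ge 3$ a quartet is either a
resolved *butterfly* $ab|cd$ or an unresolved *star*, so with $B$, $B'$
the butterfly counts of the two trees, $\mathrm{shared}_B$ the quartets
resolved identically and $\mathrm{diff}_B$ those resolved as different
butterflies,

$$\mathrm{diff}_S = B + B' - 2\,\mathrm{shared}_B - 2\,\mathrm{diff}_B,
\qquad
\mathrm{qdist} = \mathrm{diff}_S + \mathrm{diff}_B .$$

The first identity follows from partitioning each tree's butterflies into
"same in the other tree", "different butterfly in the other tree" and
"star in the other tree" and summing the two partitions; the package does
not trust the algebra alone but verifies the identity against the
enumeration oracle's directly tallied star-vs-butterfly count in its test
suite. Since $B = \mathrm{shared}_B(T,T)$, everything reduces to counting
shared and different butterflies between (possibly equal) tree pairs.

## Directed claims and the counting identity

Orienting the middle edge of a butterfly yields two *directed* quartets
$ab \to cd$; each directed quartet is claimed by exactly one directed
edge $e = (s_e, t_e)$ — the one with $a, b$ behind $e$ and $c, d$ in two
distinct subtrees in front. Summing over all *pairs* of directed inner
edges, one per tree, the directed butterflies claimed identically count
every shared butterfly twice, and those claimed with conflicting
resolution count every differing butterfly four times; dividing by 2 and
4 gives $\mathrm{shared}_B$ and $\mathrm{diff}_B$. These parities hold for
every input and are asserted at run time.

For inner nodes $v \in T$, $v' \in T'$ with component lists
$F_1..F_{d_v}$ and $G_1..G_{d_{v'}}$, let $I[i,j] = |F_i \cap G_j|$. With
the behind components indexed $i$, $j$, the per-edge-pair counts are

$$S(i,j) = \tfrac12\binom{I[i,j]}{2}
  \sum_{k \ne i,\, l \ne j} I[k,l] \cdot \mathrm{inner}(i,k,j,l), \qquad
D(i,j) = I[i,j] \sum_{k \ne i,\, l \ne j} I[i,l]\, I[k,j] \cdot
  \mathrm{inner}(i,k,j,l),$$

where $\mathrm{inner}$ is the sum of $I$ over all rows outside $\{i,k\}$
and columns outside $\{j,l\}$, available in O(1) by inclusion–exclusion
from the total $M$, the row sums $R$ and the column sums $C$.

## The O(1) rewrite

Substituting the inclusion–exclusion form of $\mathrm{inner}$ and
expanding, every term of $S(i,j)$ is a product of at most two entries of
$I$ sharing a row or a column index. The expansion collapses to

$$\sum_{k \ne i, l \ne j} I[k,l]\,\mathrm{inner}
 = K^2 - \Sigma R^2 - \Sigma C^2 + \Sigma I^2
 + R_i^2 + C_j^2 + 2W_j + 2V_i
 - 2 I[i,j](R_i + C_j) - 2\rho_i - 2\gamma_j + 3I[i,j]^2,$$

with $K = M - R_i - C_j + I[i,j]$, $\rho_i = \sum_l I[i,l]^2$,
$\gamma_j = \sum_k I[k,j]^2$, $W_j = \sum_k R_k I[k,j]$ and
$V_i = \sum_l C_l I[i,l]$ — all computable in $O(d_v d_{v'})$ total per
node pair, no matrix product required. The different-topology sum
additionally contains the genuinely bilinear cross term
$\sum_{k,l} I[i,l]\, I[k,j]\, I[k,l]$, which is entry $(i,j)$ of the
triple product $G_3 = I\,I^{\mathsf T} I$; restricted to $k \ne i$,
$l \ne j$ it becomes
$G_3[i,j] - I[i,j](\rho_i + \gamma_j) + I[i,j]^3$, and the remaining
terms of $D(i,j)$ factor over $k$ and $l$ into the same aggregates as
above. $G_3$ is the only quantity whose cost exceeds $O(d_v d_{v'})$; it
is evaluated through dense (BLAS) products with the cheaper association —
$(I I^{\mathsf T}) I$ when $d_v \le d_{v'}$ ("left", square shape
$d_v \times d_v$), $I (I^{\mathsf T} I)$ otherwise ("right") — with ties
broken left. Both associations are computed in the tests and must agree
exactly; `compute_product_aggregates()` also retains the product pair
itself ($I I^{\mathsf T}$ and $I_2 I^{\mathsf T}$, or their transposed
analogues) so every contraction the rewrite uses can be spot-checked
against its definition.

Because the closed forms are a re-derivation, the package treats
input–output equivalence as the specification: property tests compare
them against literal quadruple sums on random integer matrices
(dimensions 3–8, entries 0–5, both product sides, every behind pair), and
the full pipeline against the enumeration oracle on random tree pairs
from all four generator classes.

## Preprocessing

The matrix $I$ is assembled in O(1) per entry from a global table of
rooted-subtree leaf intersections: both trees are rooted at their first
internal node (parse order — any internal root gives the same counts;
fixing it makes every intermediate table reproducible), and
$|L(u) \cap L(u')|$ satisfies a child-sum recursion over either argument
with leaf-label base cases, filling an
$O(n^2)$ table. Front sets of directed edges are either a rooted subtree
or its complement, so the four orientation cases reduce to the table, the
subtree sizes, and $n$. Edges whose source is a leaf claim nothing (one
leaf behind cannot host two), so only inner-edge pairs are visited; a
star tree, having no inner edge, contributes zero claims without any
node-pair work.

## Arithmetic

All counts are integers held exactly in doubles; accumulators on the C++
side are extended precision. The largest intermediates are the raw
directed totals (at most $4\binom{n}{4}$) and triple-product entries (at
most $n^3$), which stay below the $2^{53}$ exact-integer capacity of a
double for $n \le 10{,}000$; the package refuses larger inputs rather
than return silently inexact counts. Trees with $n < 4$ have no quartets
and return all-zero components. Negative components, odd shared totals or
diff totals not divisible by four abort with an internal-consistency
error rather than being silently corrected.

## Synthetic data

The four generator classes span the degree spectrum the counting loop
encounters:

* `random_binary_tree(n, seed)` — sequential uniform edge subdivision;
  every internal node has degree 3, so all $\binom{n}{4}$ quartets are
  butterflies.
* `random_general_tree(n, seed, contraction_p = 0.5)` — a random binary
  tree whose inner edges are independently contracted with probability
  `contraction_p`. The default 0.5 yields a broad mix of node degrees;
  the limits 0 and 1 recover binary and star trees.
* `star_tree(n)` — one degree-$n$ node; resolves nothing.
* `sqrt_hub_tree(n, seed)` — a hub of degree $\lceil\sqrt n\rceil$
  carrying balanced random binary subtrees; exercises one large node-pair
  matrix amid many small ones.

The generators are pure functions of `(n, seed)` and restore the global
RNG state. They emulate *topology classes*, not evolutionary processes:
no coalescent or birth–death branch structure, no branch lengths, no
label-topology correlation. Passing the oracle-equivalence tests on these
classes therefore certifies the counting algebra on the full degree
range, but says nothing about statistical properties of distances on real
phylogenies — nor does it need to, since the algorithm is exact for every
topology.

## Problem sizes and design choices in the tests

Oracle-equivalence tests run 200 seeded pairs at $n \in [5, 40]$, where
the $O(n^4)$ oracle is itself fast and obviously correct (it determines
each quartet's topology from the four-point condition on unit-length path
distances). Closed-form identities are checked for all
$n \in [4, 100]$. The informational scaling check times binary-vs-binary
pairs at $n \in \{500, 1000, 2000\}$ — sizes chosen to keep the whole
suite in a couple of minutes on one core — and asserts only that the
fitted log–log slope stays below 3; in practice it lands near 2.1–2.4,
consistent with close-to-quadratic behaviour when node degrees are
bounded.

Two design points were genuinely open and are resolved as follows.
Leaf-set mismatches are hard errors (no silent pruning to the
intersection: pruning hides user mistakes and changes the distance's
meaning); duplicate or empty labels are rejected at parse time. And the
pure-R implementations of every pipeline stage are kept alongside the
C++ production loop — the R path is the readable specification and the
cross-check, the C++ path the one users run; the tests pin them to each
other on every generator class.

## Limitations

* Exactness is guaranteed only to $n \le 10{,}000$ (integer capacity of
  the double-precision pipeline); the cap is enforced.
* The worst case — two high-degree nodes with many *internal*
  neighbours — costs a dense $d \times d$ matrix product per node pair
  and approaches cubic time overall, as expected when the multiplication
  backend is cubic.
* Branch lengths are ignored by construction; this is a topological
  distance.
* Only the first tree of a multi-tree file is read.
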