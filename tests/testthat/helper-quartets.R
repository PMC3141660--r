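# Shared fixtures and independent reference implementations.

component_names <- c("B", "Bp", "shared_B", "diff_B", "diff_S", "qdist")

component_vec <- function(x) {
  vapply(x[component_names], as.numeric, numeric(1))
}

expect_components_equal <- function(fast, slow, info = NULL) {
  expect_equal(component_vec(fast), component_vec(slow), info = info)
}

# Literal quadruple-sum references for the per-edge-pair counts, evaluated
# by explicit enumeration over the remaining rows and columns.  These stay
# independent of the O(1) closed forms they check.
inner_sum_direct <- function(I, i, k, j, l) {
  sum(I[-c(i, k), -c(j, l)])
}

shared_directed_direct <- function(I, i, j) {
  d1 <- nrow(I); d2 <- ncol(I)
  tot <- 0
  for (k in seq_len(d1)[-i])
    for (l in seq_len(d2)[-j])
      tot <- tot + I[k, l] * inner_sum_direct(I, i, k, j, l)
  choose(I[i, j], 2) * tot / 2
}

diff_directed_direct <- function(I, i, j) {
  d1 <- nrow(I); d2 <- ncol(I)
  tot <- 0
  for (k in seq_len(d1)[-i])
    for (l in seq_len(d2)[-j])
      tot <- tot + I[i, l] * I[k, j] * inner_sum_direct(I, i, k, j, l)
  I[i, j] * tot
}

random_int_matrix <- function(d1, d2, max_entry = 5L) {
  matrix(sample(0:max_entry, d1 * d2, replace = TRUE), d1, d2)
}

# internal node of `tree` whose neighbours include the leaves labelled
# `labs` (e.g. the cd-node of the ab|cd butterfly)
node_adjacent_to_leaves <- function(tree, labs) {
  target <- which(tree$labels %in% labs)
  for (v in tree$internal)
    if (all(target %in% tree$adj[[v]])) return(v)
  stop("no internal node adjacent to all of: ", paste(labs, collapse = ","))
}

butterfly_ab_cd <- function() parse_newick("((a,b),(c,d));")
butterfly_ac_bd <- function() parse_newick("((a,c),(b,d));")

leaf_bipartitions_of <- function(tree) quartetdist:::leaf_bipartitions(tree)

tree_kinds <- c("general", "binary", "star", "sqrt_hub")

random_pair <- function(n, kind1, kind2, seed) {
  list(t1 = generate_tree(n, kind1, seed = seed),
       t2 = generate_tree(n, kind2, seed = seed + 10000L))
}
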