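test_that("inner_sum equals literal summation over excluded rows/columns", {
  I <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1))
  tp <- as_node_pair_tables(I)
  expect_equal(inner_sum(tp, 1, 2, 1, 2), 1)         # = I[3,3]
  expect_equal(inner_sum(tp, 1, 2, 1, 2),
               inner_sum_direct(I, 1, 2, 1, 2))
  tp2 <- as_node_pair_tables(rbind(c(2, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(inner_sum(tp2, 1, 2, 1, 2), 1)
  # 2x2: no rows/columns remain
  expect_equal(inner_sum(as_node_pair_tables(rbind(1:2, 3:4)), 1, 2, 1, 2), 0)
  expect_error(inner_sum(tp, 1, 1, 1, 2), "i != k")

  set.seed(21)
  for (rep in 1:25) {
    I <- random_int_matrix(sample(3:6, 1), sample(3:6, 1))
    tp <- as_node_pair_tables(I)
    idx <- c(sample(nrow(I), 2), sample(ncol(I), 2))
    expect_equal(inner_sum(tp, idx[1], idx[2], idx[3], idx[4]),
                 inner_sum_direct(I, idx[1], idx[2], idx[3], idx[4]))
  }
})

test_that("per-edge-pair closed forms reproduce the worked butterfly values", {
  t1 <- butterfly_ab_cd()
  tab <- build_intersection_table(t1, butterfly_ab_cd())
  cd <- node_adjacent_to_leaves(t1, c("c", "d"))
  tp <- compute_product_aggregates(build_node_pair_tables(cd, cd, tab))
  expect_equal(shared_directed_for_edge_pair(tp, 1, 1), 1)
  expect_equal(shared_directed_for_edge_pair(tp, 2, 2), 0)  # behind = {c}

  t3 <- butterfly_ac_bd()
  tab13 <- build_intersection_table(t1, t3)
  bd <- node_adjacent_to_leaves(t3, c("b", "d"))
  tpx <- compute_product_aggregates(build_node_pair_tables(cd, bd, tab13))
  expect_equal(shared_directed_for_edge_pair(tpx, 1, 1), 0)
  expect_equal(diff_directed_for_edge_pair(tpx, 1, 1), 1)
  expect_error(shared_directed_for_edge_pair(tpx, 0, 1), "out of range")
})

test_that("closed forms equal the literal quadruple sums on random matrices", {
  set.seed(33)
  for (rep in 1:60) {
    I <- random_int_matrix(sample(3:8, 1), sample(3:8, 1))
    left <- compute_product_aggregates(as_node_pair_tables(I), "left")
    right <- compute_product_aggregates(as_node_pair_tables(I), "right")
    for (i in seq_len(nrow(I)))
      for (j in seq_len(ncol(I))) {
        sd <- shared_directed_direct(I, i, j)
        dd <- diff_directed_direct(I, i, j)
        expect_equal(shared_directed_for_edge_pair(left, i, j), sd)
        expect_equal(shared_directed_for_edge_pair(right, i, j), sd)
        expect_equal(diff_directed_for_edge_pair(left, i, j), dd)
        expect_equal(diff_directed_for_edge_pair(right, i, j), dd)
      }
  }
})

test_that("zero factors annihilate the diff count", {
  set.seed(5)
  I <- random_int_matrix(4, 5)
  I[2, 3] <- 0
  tp <- compute_product_aggregates(as_node_pair_tables(I))
  expect_equal(diff_directed_for_edge_pair(tp, 2, 3), 0)
})

test_that("butterfly and shared/diff totals match hand counts on quartets", {
  ab <- butterfly_ab_cd()
  ac <- butterfly_ac_bd()
  expect_equal(count_shared_butterflies(ab, ab), 1)
  expect_equal(count_shared_butterflies(ab, ac), 0)
  expect_equal(count_diff_butterflies(ab, ac), 1)
  expect_equal(quartetdist:::qd_raw_counts(ab, ac)$diff_raw, 4)
  expect_equal(count_diff_butterflies(ab, ab), 0)
  expect_equal(count_diff_butterflies(parse_newick("(a,b,c,d);"), ab), 0)

  expect_equal(butterfly_count(random_binary_tree(10, 2)), choose(10, 4))
  expect_equal(butterfly_count(star_tree(9)), 0)
  # 5-leaf caterpillar resolves all five quartets
  expect_equal(butterfly_count(parse_newick("(((a,b),c),(d,e));")), 5)
})

test_that("R reference loop and C++ core agree on all generator classes", {
  seed <- 0L
  for (k1 in tree_kinds)
    for (k2 in tree_kinds) {
      seed <- seed + 1L
      p <- random_pair(10 + seed %% 8, k1, k2, seed)
      r <- quartetdist:::qd_raw_counts(p$t1, p$t2, engine = "r")
      cc <- quartetdist:::qd_raw_counts(p$t1, p$t2, engine = "cpp")
      expect_equal(r, cc, info = paste(k1, k2))
    }
})

test_that("quartet_distance satisfies its defining identities", {
  ab <- butterfly_ab_cd()
  expect_equal(quartet_distance(ab, ab)$qdist, 0)
  res <- quartet_distance(ab, butterfly_ac_bd())
  expect_equal(component_vec(res),
               c(B = 1, Bp = 1, shared_B = 0, diff_B = 1, diff_S = 0,
                 qdist = 1))

  n <- 12
  bin <- random_binary_tree(n, 4)
  expect_equal(quartet_distance(bin, star_tree(n))$qdist, choose(n, 4))

  # trees with fewer than 4 leaves have no quartets
  for (nwk in c("a;", "(a,b);", "(a,b,c);"))
    expect_equal(quartet_distance(parse_newick(nwk),
                                  parse_newick(nwk))$qdist, 0)
})

test_that("distance is symmetric and label-permutation invariant", {
  relabel <- function(tree, perm) {
    tree$labels[tree$leaves] <- perm[tree$labels[tree$leaves]]
    tree
  }
  for (seed in 1:6) {
    p <- random_pair(14, sample(tree_kinds, 1), sample(tree_kinds, 1),
                     seed + 50)
    a <- quartet_distance(p$t1, p$t2)
    b <- quartet_distance(p$t2, p$t1)
    expect_equal(a$qdist, b$qdist)
    expect_equal(a$shared_B, b$shared_B)
    expect_equal(a$diff_B, b$diff_B)

    labs <- sort(p$t1$labels[p$t1$leaves])
    perm <- stats::setNames(sample(labs), labs)
    pr <- quartet_distance(relabel(p$t1, perm), relabel(p$t2, perm))
    expect_equal(component_vec(pr), component_vec(a))
  }
})

test_that("raw totals keep their parity and counts their ranges", {
  for (seed in 1:8) {
    n <- 8 + seed
    p <- random_pair(n, sample(tree_kinds, 1), sample(tree_kinds, 1),
                     seed + 70)
    raw <- quartetdist:::qd_raw_counts(p$t1, p$t2)
    expect_equal(raw$shared_raw %% 2, 0)
    expect_equal(raw$diff_raw %% 4, 0)
    res <- quartet_distance(p$t1, p$t2)
    expect_gte(res$qdist, 0)
    expect_lte(res$qdist, choose(n, 4))
    expect_lte(res$shared_B + res$diff_B, min(res$B, res$Bp))
    expect_equal(res$diff_S,
                 res$B + res$Bp - 2 * res$shared_B - 2 * res$diff_B)
  }
})
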