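test_that("intersection table matches direct set intersections on butterflies", {
  t1 <- butterfly_ab_cd()
  t2 <- butterfly_ab_cd()
  tab <- build_intersection_table(t1, t2)

  cd1 <- node_adjacent_to_leaves(t1, c("c", "d"))
  cd2 <- node_adjacent_to_leaves(t2, c("c", "d"))
  ab1 <- node_adjacent_to_leaves(t1, c("a", "b"))
  ab2 <- node_adjacent_to_leaves(t2, c("a", "b"))

  # F = {c,d} in front of (ab -> cd), same in T' -> 2
  expect_equal(front_intersection(tab, c(ab1, cd1), c(ab2, cd2)), 2)
  # F = {c,d} against G = {a,b,d} (front of c -> cd-node)
  expect_equal(front_intersection(tab, c(ab1, cd1),
                                  c(which(t2$labels == "c"), cd2)),
               2 - 1)  # {c,d} against L \ {c} = {a,b,d}

  t3 <- butterfly_ac_bd()
  tab13 <- build_intersection_table(t1, t3)
  ac3 <- node_adjacent_to_leaves(t3, c("a", "c"))
  bd3 <- node_adjacent_to_leaves(t3, c("b", "d"))
  # F = {a,b} (front of cd -> ab), G = {a,c} (front of bd -> ac) -> 1
  expect_equal(front_intersection(tab13, c(cd1, ab1), c(bd3, ac3)), 1)
})

test_that("complement identities hold on random tree pairs", {
  for (seed in 1:5) {
    p <- random_pair(12, "general", "sqrt_hub", seed)
    tab <- build_intersection_table(p$t1, p$t2)
    n <- tab$n
    # all directed edges of each tree as (s, t) rows
    edges1 <- do.call(rbind, lapply(seq_along(p$t1$adj), function(v)
      cbind(v, p$t1$adj[[v]])))
    edges2 <- do.call(rbind, lapply(seq_along(p$t2$adj), function(v)
      cbind(v, p$t2$adj[[v]])))
    pick1 <- edges1[sample.int(nrow(edges1), 8), , drop = FALSE]
    pick2 <- edges2[sample.int(nrow(edges2), 8), , drop = FALSE]
    for (r1 in seq_len(nrow(pick1)))
      for (r2 in seq_len(nrow(pick2))) {
        e1 <- pick1[r1, ]; e2 <- pick2[r2, ]
        fg <- front_intersection(tab, e1, e2)
        f_size <- quartetdist:::front_size(tab$rt1, n, e1[1], e1[2])
        g_size <- quartetdist:::front_size(tab$rt2, n, e2[1], e2[2])
        expect_gte(fg, 0)
        expect_lte(fg, min(f_size, g_size))
        # |F-bar cap G| = |G| - |F cap G| (front of the reversed edge)
        expect_equal(front_intersection(tab, rev(e1), e2), g_size - fg)
        expect_equal(front_intersection(tab, e1, rev(e2)), f_size - fg)
      }
  }
})

test_that("node-pair tables reproduce the hand-derived butterfly matrices", {
  t1 <- butterfly_ab_cd()
  tab11 <- build_intersection_table(t1, butterfly_ab_cd())
  cd <- node_adjacent_to_leaves(t1, c("c", "d"))
  tp <- build_node_pair_tables(cd, cd, tab11)
  # component order at the cd-node is ({a,b}, {c}, {d})
  expect_equal(tp$I, rbind(c(2, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(tp$R, c(2, 1, 1))
  expect_equal(tp$C, c(2, 1, 1))
  expect_equal(tp$M, 4)

  t3 <- butterfly_ac_bd()
  tab13 <- build_intersection_table(t1, t3)
  bd <- node_adjacent_to_leaves(t3, c("b", "d"))
  tp2 <- build_node_pair_tables(cd, bd, tab13)
  # rows ({a,b},{c},{d}) x cols ({a,c},{b},{d})
  expect_equal(tp2$I, rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1)))
  expect_equal(tp2$M, 4)
})

test_that("M equals n and marginal sums agree for every node pair", {
  p <- random_pair(15, "general", "general", 3)
  tab <- build_intersection_table(p$t1, p$t2)
  for (v in p$t1$internal)
    for (vp in p$t2$internal) {
      tp <- build_node_pair_tables(v, vp, tab)
      expect_equal(tp$M, 15)
      expect_equal(sum(tp$R), tp$M)
      expect_equal(sum(tp$C), tp$M)
      expect_equal(tp$I2, tp$I^2)
    }
})

test_that("product side choice and product entries match their definitions", {
  expect_equal(choose_product_side(3, 100), "left")
  expect_equal(choose_product_side(100, 3), "right")
  expect_equal(choose_product_side(5, 5), "left")

  I <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1))
  tp <- compute_product_aggregates(as_node_pair_tables(I), side = "left")
  expect_equal(tp$P[1, 1], 2)
  expect_equal(tp$P[1, 2], 1)
  expect_equal(tp$P[3, 3], 1)
  expect_equal(tp$Q, I^2 %*% t(I))  # 0/1 entries: I2 equals I
  expect_equal(tp$G3, I %*% t(I) %*% I)

  I2m <- rbind(c(2, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tpl <- compute_product_aggregates(as_node_pair_tables(I2m), side = "left")
  expect_equal(tpl$P, diag(c(4, 1, 1)))

  # products equal explicit contractions on random matrices, both sides
  set.seed(11)
  for (rep in 1:20) {
    I <- random_int_matrix(sample(3:7, 1), sample(3:7, 1))
    left <- compute_product_aggregates(as_node_pair_tables(I), "left")
    right <- compute_product_aggregates(as_node_pair_tables(I), "right")
    d1 <- nrow(I); d2 <- ncol(I)
    PIIt <- matrix(0, d1, d1)
    for (i in seq_len(d1)) for (k in seq_len(d1))
      PIIt[i, k] <- sum(I[i, ] * I[k, ])
    expect_equal(left$P, PIIt)
    PtI <- matrix(0, d2, d2)
    for (j in seq_len(d2)) for (l in seq_len(d2))
      PtI[j, l] <- sum(I[, j] * I[, l])
    expect_equal(right$P, PtI)
    expect_equal(left$G3, right$G3)   # both associations of I I^T I
    # W and V contractions
    expect_equal(left$W, as.vector(colSums(rowSums(I) * I)))
    expect_equal(left$V, as.vector(I %*% colSums(I)))
  }
})

test_that("table footprint over all node pairs is the product of degree sums", {
  p <- random_pair(20, "general", "general", 9)
  cells <- 0
  tab <- build_intersection_table(p$t1, p$t2)
  for (v in p$t1$internal)
    for (vp in p$t2$internal)
      cells <- cells + length(build_node_pair_tables(v, vp, tab)$I)
  d1 <- sum(lengths(p$t1$adj[p$t1$internal]))
  d2 <- sum(lengths(p$t2$adj[p$t2$internal]))
  expect_equal(cells, d1 * d2)
})
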