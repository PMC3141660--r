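# ---------------------------------------------------------------------------
# Preprocessing: the O(n^2) subtree-intersection table and, per pair of
# internal nodes, the matrix I of component-wise leaf intersections together
# with every aggregate the O(1) per-edge-pair counting formulas consume.
# ---------------------------------------------------------------------------

#' Subtree-intersection table for a tree pair
#'
#' Roots both trees at their first internal node and computes, by dynamic
#' programming over node pairs, the number of common leaves
#' \eqn{|L(u) \cap L(u')|} below every rooted-node pair.  Together with the
#' subtree sizes and the total leaf count this gives, in O(1), the leaf
#' intersection of any two directed-edge "front" sets via complement rules
#' (e.g. \eqn{|\bar F \cap G| = |G| - |F \cap G|}).  Construction touches
#' O(n^2) cells.
#'
#' @param t1,t2 `qtree` objects on the same leaf set.
#' @param map common leaf index, from [shared_leaf_map()].
#' @return an object of class `intersection_table`.
#' @seealso [front_intersection()], [build_node_pair_tables()]
#' @export
build_intersection_table <- function(t1, t2, map = shared_leaf_map(t1, t2)) {
  rt1 <- root_qtree(t1)
  rt2 <- root_qtree(t2)
  N1 <- length(t1$adj); N2 <- length(t2$adj)
  n <- length(map)

  children2 <- lapply(seq_len(N2), function(v)
    setdiff(t2$adj[[v]], rt2$parent[v]))
  children1 <- lapply(seq_len(N1), function(v)
    setdiff(t1$adj[[v]], rt1$parent[v]))
  # node of t2 carrying each common leaf index
  leaf2_node <- integer(n)
  leaf2_node[map[t2$labels[t2$leaves]]] <- t2$leaves

  C <- matrix(0, N1, N2)
  for (u in rt1$post) {
    if (t1$is_leaf[u]) {
      row <- numeric(N2)
      row[leaf2_node[map[[t1$labels[u]]]]] <- 1
      for (u2 in rt2$post)
        if (!t2$is_leaf[u2])
          row[u2] <- sum(row[children2[[u2]]])
      C[u, ] <- row
    } else {
      C[u, ] <- colSums(C[children1[[u]], , drop = FALSE])
    }
  }
  structure(
    list(C = C, t1 = t1, t2 = t2, rt1 = rt1, rt2 = rt2, n = n, map = map),
    class = "intersection_table"
  )
}

# leaf count of the component of T - v containing neighbour a, i.e. the
# front set of the directed edge v -> a, in rooted terms
front_size <- function(rt, n, v, a) {
  if (a == rt$parent[v]) n - rt$size[v] else rt$size[a]
}

# |front(v -> a)  \cap  front(v' -> b)| from the rooted DP table
front_pair_count <- function(tab, v, a, vp, b) {
  up1 <- a == tab$rt1$parent[v]
  up2 <- b == tab$rt2$parent[vp]
  if (!up1 && !up2) tab$C[a, b]
  else if (!up1 && up2) tab$rt1$size[a] - tab$C[a, vp]
  else if (up1 && !up2) tab$rt2$size[b] - tab$C[v, b]
  else tab$n - tab$rt1$size[v] - tab$rt2$size[vp] + tab$C[v, vp]
}

#' Leaf intersection of two directed-edge front sets
#'
#' For directed edges `e1 = c(s, t)` in the first tree and `e2` in the
#' second, returns the number of leaves lying both in front of `e1` (on the
#' `t` side) and in front of `e2`.
#'
#' @param table an `intersection_table`.
#' @param e1,e2 integer vectors `c(source, target)` naming an edge of the
#'   respective tree.
#' @return a non-negative integer count.
#' @export
front_intersection <- function(table, e1, e2) {
  stopifnot(inherits(table, "intersection_table"),
            length(e1) == 2L, length(e2) == 2L)
  if (!(e1[2L] %in% table$t1$adj[[e1[1L]]]))
    stop("e1 is not an edge of the first tree", call. = FALSE)
  if (!(e2[2L] %in% table$t2$adj[[e2[1L]]]))
    stop("e2 is not an edge of the second tree", call. = FALSE)
  # front of (s, t) is the component containing t, i.e. component t of node s
  front_pair_count(table, e1[1L], e1[2L], e2[1L], e2[2L])
}

aggregate_tables <- function(I, v = NA_integer_, vp = NA_integer_) {
  I2 <- I * I
  R <- rowSums(I); Cv <- colSums(I)
  structure(
    list(
      v = v, vp = vp,
      d1 = nrow(I), d2 = ncol(I),
      I = I, I2 = I2,
      R = R, C = Cv, M = sum(I),
      R2 = rowSums(I2), C2 = colSums(I2), M2 = sum(I2),
      SR2 = sum(R * R), SC2 = sum(Cv * Cv),
      W = as.vector(crossprod(I, R)),   # W[j] = sum_k R[k] I[k, j]
      V = as.vector(I %*% Cv),          # V[i] = sum_l C[l] I[i, l]
      side = NULL, P = NULL, Q = NULL, G3 = NULL
    ),
    class = "node_pair_tables"
  )
}

#' Node-pair intersection matrix and its aggregates
#'
#' For internal nodes `v` of the first tree and `vp` of the second, with
#' component lists \eqn{F_1..F_{d_v}} and \eqn{G_1..G_{d_{v'}}} fixed by the
#' trees' neighbour order, builds the matrix
#' \eqn{I[i,j] = |F_i \cap G_j|} plus its row sums R, column sums C, total M,
#' the elementwise square I2 with its row/column/total sums, the squared-sum
#' scalars \eqn{\sum_i R_i^2}, \eqn{\sum_j C_j^2}, and the contractions
#' \eqn{W_j = \sum_k R_k I[k,j]}, \eqn{V_i = \sum_l C_l I[i,l]}.  All are
#' computed in O(d_v d_v') time.
#'
#' @param v internal node id in the first tree.
#' @param vp internal node id in the second tree.
#' @param table an [build_intersection_table()] result.
#' @return an object of class `node_pair_tables` (product slots empty until
#'   [compute_product_aggregates()] is applied).
#' @export
build_node_pair_tables <- function(v, vp, table) {
  stopifnot(inherits(table, "intersection_table"))
  if (table$t1$is_leaf[v] || table$t2$is_leaf[vp])
    stop("v and vp must be internal nodes", call. = FALSE)
  nb1 <- table$t1$adj[[v]]
  nb2 <- table$t2$adj[[vp]]
  I <- matrix(0, length(nb1), length(nb2))
  for (i in seq_along(nb1))
    for (j in seq_along(nb2))
      I[i, j] <- front_pair_count(table, v, nb1[i], vp, nb2[j])
  aggregate_tables(I, v, vp)
}

#' Aggregates from a bare intersection matrix
#'
#' Treats any non-negative integer matrix as the node-pair matrix I of a
#' hypothetical node pair; useful for testing the counting formulas in
#' isolation from trees.
#'
#' @param I a non-negative numeric matrix with integer entries.
#' @return a `node_pair_tables` object.
#' @export
as_node_pair_tables <- function(I) {
  I <- as.matrix(I)
  stopifnot(is.numeric(I), all(I >= 0), all(I == round(I)))
  aggregate_tables(I)
}

#' Choose the cheaper matrix-product side
#'
#' The counting step needs the cross-correlation entries
#' \eqn{\sum_{k,l} I[i,l] I[k,j] I[k,l]}, obtainable from either the
#' \eqn{d_v \times d_v} products (left side) or the
#' \eqn{d_{v'} \times d_{v'}} products (right side); the side with the
#' smaller square shape is cheaper.  Ties go left.
#'
#' @param d1,d2 the degrees of the node pair.
#' @return `"left"` if `d1 <= d2`, else `"right"`.
#' @export
choose_product_side <- function(d1, d2) {
  if (d1 <= d2) "left" else "right"
}

#' Matrix-product aggregates for a node pair
#'
#' Augments a `node_pair_tables` object with the dense products of the
#' chosen side — left: \eqn{P = I I^T}, \eqn{Q = I_2 I^T}; right:
#' \eqn{P = I^T I}, \eqn{Q = I^T I_2} — and the triple product
#' \eqn{G3 = I I^T I}, computed as \eqn{P I} (left) or \eqn{I P} (right).
#' `G3[i, j]` equals \eqn{\sum_{k,l} I[i,l] I[k,j] I[k,l]}, the only
#' product-derived quantity the O(1) counting formulas consume.  All
#' products are exact integer values (validated against the double-precision
#' exact-integer capacity).
#'
#' @param tables a `node_pair_tables` object.
#' @param side `"left"` or `"right"`; defaults to
#'   [choose_product_side()] on the node degrees.
#' @return the augmented `node_pair_tables`.
#' @export
compute_product_aggregates <- function(tables,
                                       side = choose_product_side(tables$d1,
                                                                  tables$d2)) {
  stopifnot(inherits(tables, "node_pair_tables"))
  side <- match.arg(side, c("left", "right"))
  I <- tables$I; I2 <- tables$I2
  if (side == "left") {
    P <- tcrossprod(I)         # I I^T,  d1 x d1
    Q <- tcrossprod(I2, I)     # I2 I^T, d1 x d1
    G3 <- P %*% I
  } else {
    P <- crossprod(I)          # I^T I,  d2 x d2
    Q <- crossprod(I, I2)      # I^T I2, d2 x d2
    G3 <- I %*% P
  }
  if (max(G3) >= 2^53)
    stop("arithmetic capacity exceeded: product entries reach 2^53",
         call. = FALSE)
  tables$side <- side
  tables$P <- P
  tables$Q <- Q
  tables$G3 <- G3
  tables
}
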