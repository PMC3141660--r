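# ---------------------------------------------------------------------------
# Seeded generators for the four benchmark topology classes: random binary
# trees, random general (multifurcating) trees, star trees, and trees with a
# ceiling(sqrt(n))-degree hub surrounded by binary subtrees.  All are pure
# functions of (n, seed).
# ---------------------------------------------------------------------------

leaf_labels <- function(n) paste0("t", seq_len(n) - 1L)

# Sequential random edge subdivision on an edge matrix; returns the edge
# list of an unrooted binary tree whose leaves are nodes 1..n.
random_binary_edges <- function(n) {
  if (n == 1L) return(matrix(integer(0), 0L, 2L))
  if (n == 2L) return(matrix(c(1L, 2L), 1L, 2L))
  # start from the 3-leaf star with centre n+1
  centre <- n + 1L
  edges <- rbind(c(centre, 1L), c(centre, 2L), c(centre, 3L))
  next_id <- n + 2L
  for (leaf in seq_len(n)[-(1:3)]) {
    e <- sample.int(nrow(edges), 1L)
    w <- next_id; next_id <- next_id + 1L
    a <- edges[e, 1L]; b <- edges[e, 2L]
    edges[e, ] <- c(a, w)
    edges <- rbind(edges, c(w, b), c(w, leaf))
  }
  edges
}

edges_to_qtree <- function(edges, n) {
  n_nodes <- max(n, if (nrow(edges)) max(edges) else n)
  labels <- c(leaf_labels(n), rep(NA_character_, n_nodes - n))
  qtree_from_edges(edges, labels, n_nodes)
}

#' Random unrooted binary tree
#'
#' Grows a tree by sequential random edge subdivision: starting from the
#' 3-leaf star, each further leaf is attached to a uniformly chosen existing
#' edge.  Every internal node of the result has degree 3.  Deterministic for
#' a given `(n, seed)`; leaf labels are `t0 ... t{n-1}`.
#'
#' @param n number of leaves (>= 1).
#' @param seed integer random seed.
#' @return a `qtree`.
#' @export
random_binary_tree <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  withr::with_seed(seed, edges_to_qtree(random_binary_edges(n), n))
}

#' Random general (multifurcating) tree
#'
#' A random binary tree in which each inner edge is independently contracted
#' with probability `contraction_p`, producing internal nodes of arbitrary
#' degree >= 3.  With `contraction_p = 0` this is a binary tree; with
#' `contraction_p = 1`, a star.
#'
#' @inheritParams random_binary_tree
#' @param contraction_p probability of contracting each inner edge
#'   (default 0.5).
#' @return a `qtree`.
#' @export
random_general_tree <- function(n, seed = 1L, contraction_p = 0.5) {
  stopifnot(n >= 1L, contraction_p >= 0, contraction_p <= 1)
  withr::with_seed(seed, {
    edges <- random_binary_edges(n)
    inner <- which(edges[, 1L] > n & edges[, 2L] > n)
    contract <- inner[stats::runif(length(inner)) < contraction_p]
    if (length(contract)) {
      # union-find over node ids; merge endpoints of contracted edges
      n_nodes <- max(n, if (nrow(edges)) max(edges) else n)
      rep_of <- seq_len(n_nodes)
      find <- function(x) {
        while (rep_of[x] != x) {
          rep_of[x] <<- rep_of[rep_of[x]]
          x <- rep_of[x]
        }
        x
      }
      for (e in contract) {
        ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
        if (ra != rb) rep_of[rb] <- ra
      }
      keep <- setdiff(seq_len(nrow(edges)), contract)
      edges <- cbind(vapply(edges[keep, 1L], find, numeric(1)),
                     vapply(edges[keep, 2L], find, numeric(1)))
    }
    edges_to_qtree(edges, n)
  })
}

#' Star tree
#'
#' A single internal node of degree `n` (for `n >= 3`) joined to all
#' leaves; it resolves no quartet.
#'
#' @param n number of leaves (>= 1).
#' @return a `qtree`.
#' @export
star_tree <- function(n) {
  stopifnot(n >= 1L)
  if (n == 1L) return(edges_to_qtree(matrix(integer(0), 0L, 2L), 1L))
  if (n == 2L) return(edges_to_qtree(matrix(c(1L, 2L), 1L, 2L), 2L))
  edges_to_qtree(cbind(n + 1L, seq_len(n)), n)
}

#' Hub-and-spoke tree with a sqrt(n)-degree centre
#'
#' A central node of degree `ceiling(sqrt(n))` whose neighbouring subtrees
#' are random binary trees over an (as even as possible) partition of the
#' leaves; every non-hub internal node has degree 3.
#'
#' @inheritParams random_binary_tree
#' @param n number of leaves (>= 4).
#' @return a `qtree`.
#' @export
sqrt_hub_tree <- function(n, seed = 1L) {
  stopifnot(n >= 4L)
  withr::with_seed(seed, {
    h <- as.integer(ceiling(sqrt(n)))
    sizes <- rep(n %/% h, h)
    extra <- n %% h
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    hub <- n + 1L
    next_id <- n + 2L
    edges <- matrix(integer(0), 0L, 2L)
    offset <- 0L
    for (g in seq_len(h)) {
      g_leaves <- offset + seq_len(sizes[g])
      offset <- offset + sizes[g]
      if (sizes[g] == 1L) {
        edges <- rbind(edges, c(hub, g_leaves))
        next
      }
      # rooted random binary subtree on the group, root attached to hub
      root <- next_id; next_id <- next_id + 1L
      sub <- rbind(c(root, g_leaves[1L]),
                   if (sizes[g] >= 2L) c(root, g_leaves[2L]))
      if (sizes[g] > 2L) {
        for (leaf in g_leaves[-(1:2)]) {
          e <- sample.int(nrow(sub), 1L)
          w <- next_id; next_id <- next_id + 1L
          a <- sub[e, 1L]; b <- sub[e, 2L]
          sub[e, ] <- c(a, w)
          sub <- rbind(sub, c(w, b), c(w, leaf))
        }
      }
      edges <- rbind(edges, c(hub, root), sub)
    }
    edges_to_qtree(edges, n)
  })
}

#' Generate a benchmark tree by class name
#'
#' @param n number of leaves.
#' @param kind one of `"general"`, `"binary"`, `"star"`, `"sqrt_hub"`.
#' @param seed integer random seed (ignored for `"star"`).
#' @param contraction_p inner-edge contraction probability for
#'   `kind = "general"`.
#' @return a `qtree`.
#' @export
generate_tree <- function(n, kind = c("general", "binary", "star",
                                      "sqrt_hub"),
                          seed = 1L, contraction_p = 0.5) {
  switch(match.arg(kind),
         general  = random_general_tree(n, seed, contraction_p),
         binary   = random_binary_tree(n, seed),
         star     = star_tree(n),
         sqrt_hub = sqrt_hub_tree(n, seed))
}
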