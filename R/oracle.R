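# ---------------------------------------------------------------------------
# Brute-force oracle: quartet-by-quartet enumeration of all C(n,4) leaf
# subsets.  Topologies are read off the four-point condition on topological
# (unit-branch-length) leaf distances: among the three pairings of a
# quadruple the two larger path-length sums are always equal; the quartet
# is resolved as the strictly smaller pairing, and is a star exactly when
# all three sums coincide.
# ---------------------------------------------------------------------------

# pairwise topological distances between leaves, ordered by the common map
leaf_distance_matrix <- function(tree, map) {
  edges <- do.call(rbind, lapply(seq_along(tree$adj), function(v) {
    nb <- tree$adj[[v]]
    nb <- nb[nb > v]
    if (length(nb)) cbind(v, nb) else NULL
  }))
  if (is.null(edges)) return(matrix(0, 1, 1))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ord <- tree$leaves[order(map[tree$labels[tree$leaves]])]
  igraph::distances(g, v = ord, to = ord)
}

# topology codes for quadruple columns of `quads` (indices into D's order):
# 0 = star, 1 = 12|34, 2 = 13|24, 3 = 14|23
topology_codes <- function(D, quads) {
  a <- quads[1L, ]; b <- quads[2L, ]; c <- quads[3L, ]; d <- quads[4L, ]
  s12 <- D[cbind(a, b)] + D[cbind(c, d)]
  s13 <- D[cbind(a, c)] + D[cbind(b, d)]
  s14 <- D[cbind(a, d)] + D[cbind(b, c)]
  m <- pmin(s12, s13, s14)
  code <- integer(length(a))
  star <- s12 == s13 & s13 == s14
  code[!star & s12 == m] <- 1L
  code[!star & code == 0L & s13 == m] <- 2L
  code[!star & code == 0L & s14 == m] <- 3L
  code
}

#' Topology of one quartet in a tree
#'
#' Determines the topology induced by the minimal subtree spanning four
#' leaves: a butterfly pairing, or the star when all three pairings' paths
#' meet at a single point (possible only with internal degree > 3).
#'
#' @param tree a `qtree`.
#' @param quad four distinct leaf labels (character).
#' @return one of `"star"`, `"12|34"`, `"13|24"`, `"14|23"`, the pairing
#'   expressed in positions of the alphabetically sorted quadruple.
#' @examples
#' quartet_topology(parse_newick("((a,b),(c,d));"), c("a", "b", "c", "d"))
#' quartet_topology(parse_newick("(a,b,c,d);"), c("a", "b", "c", "d"))
#' @export
quartet_topology <- function(tree, quad) {
  stopifnot(inherits(tree, "qtree"), is.character(quad), length(quad) == 4L)
  if (anyDuplicated(quad)) stop("quartet leaves must be distinct",
                                call. = FALSE)
  labs <- tree$labels[tree$leaves]
  if (!all(quad %in% labs))
    stop("unknown leaf label(s): ",
         paste(setdiff(quad, labs), collapse = ", "), call. = FALSE)
  quad <- sort(quad)
  map <- stats::setNames(seq_along(labs), sort(labs))
  D <- leaf_distance_matrix(tree, map)
  code <- topology_codes(D, matrix(map[quad], 4L, 1L))
  c("star", "12|34", "13|24", "14|23")[code + 1L]
}

#' Brute-force quartet distance components
#'
#' Enumerates every four-leaf subset, determines its topology in both trees
#' and tallies all distance components directly.  Ground truth for the
#' sub-cubic method; O(n^4) time, intended for small trees (a warning is
#' issued above 100 leaves).
#'
#' @param t1,t2 `qtree` objects on the same leaf set.
#' @return a `quartet_components` object (see [quartet_distance()]).
#' @export
brute_force_components <- function(t1, t2) {
  map <- shared_leaf_map(t1, t2)
  n <- length(map)
  if (n < 4L) return(new_quartet_components(n, 0, 0, 0, 0, 0, 0))
  if (n > 100L)
    warning("brute-force enumeration of choose(", n,
            ", 4) quartets will be slow", call. = FALSE)
  D1 <- leaf_distance_matrix(t1, map)
  D2 <- leaf_distance_matrix(t2, map)
  quads <- utils::combn(n, 4L)
  c1 <- topology_codes(D1, quads)
  c2 <- topology_codes(D2, quads)
  B <- sum(c1 > 0L)
  Bp <- sum(c2 > 0L)
  shared_B <- sum(c1 > 0L & c1 == c2)
  diff_B <- sum(c1 > 0L & c2 > 0L & c1 != c2)
  diff_S <- sum((c1 == 0L) != (c2 == 0L))
  qdist <- sum(c1 != c2)
  new_quartet_components(n, B, Bp, shared_B, diff_B, diff_S, qdist)
}
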