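# ---------------------------------------------------------------------------
# Counting shared and different butterfly topologies over pairs of directed
# inner edges, and assembling the quartet distance.
#
# For an edge pair with behind indices (i, j) and node-pair matrix I, the
# directed counts are
#   shared(i, j) = (1/2) C(I[i,j], 2) * sum_{k!=i, l!=j} I[k,l] * inner
#   diff(i, j)   = sum_{k!=i, l!=j} I[i,j] I[i,l] I[k,j] * inner
# with inner = inclusion-exclusion sum over the rows/columns excluding
# {i,k} x {j,l}.  Both collapse to O(1) expressions in the precomputed
# aggregates; `diff` additionally needs one entry of the triple product
# G3 = I I^T I.
# ---------------------------------------------------------------------------

#' Inclusion-exclusion inner sum of a node-pair matrix
#'
#' Returns \eqn{\sum_{m \notin \{i,k\}, n \notin \{j,l\}} I[m,n]} in O(1)
#' as \eqn{M - R_i - R_k - C_j - C_l + I[i,j] + I[i,l] + I[k,j] + I[k,l]}.
#'
#' @param tables a `node_pair_tables` object.
#' @param i,k distinct row indices.
#' @param j,l distinct column indices.
#' @return the inner sum (non-negative integer).
#' @export
inner_sum <- function(tables, i, k, j, l) {
  stopifnot(inherits(tables, "node_pair_tables"))
  if (i == k || j == l)
    stop("inner_sum requires i != k and j != l", call. = FALSE)
  I <- tables$I
  tables$M - tables$R[i] - tables$R[k] - tables$C[j] - tables$C[l] +
    I[i, j] + I[i, l] + I[k, j] + I[k, l]
}

#' Directed butterflies claimed identically by an edge pair
#'
#' O(1) closed form of the shared-count double sum for the directed inner
#' edges whose behind-subtree indices are `i` (first tree) and `j` (second):
#' the number of directed quartets \eqn{ab \to cd} with a, b in
#' \eqn{F_i \cap G_j} and c, d in distinct front components of both nodes.
#' The halving compensates the symmetry between the two front pairs.
#'
#' @param tables a `node_pair_tables` object.
#' @param i behind-subtree index in the first tree's component list.
#' @param j behind-subtree index in the second tree's component list.
#' @return a non-negative integer count.
#' @export
shared_directed_for_edge_pair <- function(tables, i, j) {
  stopifnot(inherits(tables, "node_pair_tables"))
  if (i < 1L || i > tables$d1 || j < 1L || j > tables$d2)
    stop("behind index out of range", call. = FALSE)
  Iij <- tables$I[i, j]
  if (Iij < 2) return(0)
  Ri <- tables$R[i]; Cj <- tables$C[j]
  K <- tables$M - Ri - Cj + Iij
  Tsum <- K * K - tables$SR2 - tables$SC2 + tables$M2 +
    Ri * Ri + Cj * Cj + 2 * tables$W[j] + 2 * tables$V[i] -
    2 * Ri * Iij - 2 * Cj * Iij -
    2 * tables$R2[i] - 2 * tables$C2[j] + 3 * Iij * Iij
  Iij * (Iij - 1) / 2 * Tsum / 2
}

#' Directed butterflies claimed by an edge pair with conflicting topology
#'
#' O(1) closed form of the different-count sum for behind indices `i`, `j`:
#' directed quartets claimed by both edges but resolved differently
#' (\eqn{a \in F_i \cap G_j}, \eqn{b \in F_i \cap G_l},
#' \eqn{c \in F_k \cap G_j}, \eqn{d} elsewhere).  No symmetry division
#' applies.  Uses one entry of the triple product G3 from
#' [compute_product_aggregates()]; if the products are absent they are
#' computed on the fly on the side chosen by [choose_product_side()].
#'
#' @inheritParams shared_directed_for_edge_pair
#' @return a non-negative integer count.
#' @export
diff_directed_for_edge_pair <- function(tables, i, j) {
  stopifnot(inherits(tables, "node_pair_tables"))
  if (i < 1L || i > tables$d1 || j < 1L || j > tables$d2)
    stop("behind index out of range", call. = FALSE)
  if (is.null(tables$G3)) tables <- compute_product_aggregates(tables)
  Iij <- tables$I[i, j]
  if (Iij == 0) return(0)
  Ri <- tables$R[i]; Cj <- tables$C[j]
  a  <- Ri - Iij
  b  <- Cj - Iij
  v  <- tables$V[i] - Cj * Iij
  w  <- tables$W[j] - Ri * Iij
  a2 <- tables$R2[i] - Iij * Iij
  b2 <- tables$C2[j] - Iij * Iij
  cross <- tables$G3[i, j] - Iij * tables$R2[i] - Iij * tables$C2[j] +
    Iij * Iij * Iij
  K <- tables$M - Ri - Cj + Iij
  Iij * (K * a * b - a * w - v * b + a2 * b + a * b2 + cross)
}

# --- raw directed totals over all inner-edge pairs -------------------------

# Pure-R reference loop over internal node pairs; exact but O(n^2) with a
# large constant, used for cross-checks at small n.
qd_raw_counts_r <- function(t1, t2, map = shared_leaf_map(t1, t2)) {
  tab <- build_intersection_table(t1, t2, map)
  shared2 <- 0  # twice the directed shared total, to stay integral
  diff_raw <- 0
  for (v in t1$internal) {
    nb1 <- t1$adj[[v]]
    in1 <- which(!t1$is_leaf[nb1])
    if (!length(in1)) next
    for (vp in t2$internal) {
      nb2 <- t2$adj[[vp]]
      in2 <- which(!t2$is_leaf[nb2])
      if (!length(in2)) next
      tabs <- build_node_pair_tables(v, vp, tab)
      tabs <- compute_product_aggregates(tabs)
      for (i in in1)
        for (j in in2) {
          shared2 <- shared2 + 2 * shared_directed_for_edge_pair(tabs, i, j)
          diff_raw <- diff_raw + diff_directed_for_edge_pair(tabs, i, j)
        }
    }
  }
  list(shared_raw = shared2 / 2, diff_raw = diff_raw)
}

# C++ production path
qd_raw_counts_cpp <- function(t1, t2, map = shared_leaf_map(t1, t2)) {
  leafidx <- function(tree) {
    idx <- integer(length(tree$adj))
    idx[tree$leaves] <- map[tree$labels[tree$leaves]]
    idx
  }
  root_of <- function(tree) if (length(tree$internal)) tree$internal[1L] else 1L
  res <- qd_core_cpp(t1$adj, leafidx(t1), root_of(t1),
                     t2$adj, leafidx(t2), root_of(t2), length(map))
  list(shared_raw = res[[1L]], diff_raw = res[[2L]])
}

qd_raw_counts <- function(t1, t2, map = shared_leaf_map(t1, t2),
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (length(map) > 10000L)
    stop("arithmetic capacity: exact integer counting is guaranteed only ",
         "for n <= 10000 leaves", call. = FALSE)
  if (length(map) < 4L) return(list(shared_raw = 0, diff_raw = 0))
  if (engine == "cpp") qd_raw_counts_cpp(t1, t2, map)
  else qd_raw_counts_r(t1, t2, map)
}

#' Number of quartets with the same butterfly topology in both trees
#'
#' Sums the shared directed count over all ordered pairs of directed inner
#' edges and halves it (each shared butterfly is claimed twice).
#'
#' @param t1,t2 `qtree` objects on the same leaf set.
#' @param engine `"cpp"` (production) or `"r"` (reference loop).
#' @return a non-negative integer count.
#' @export
count_shared_butterflies <- function(t1, t2, engine = c("cpp", "r")) {
  raw <- qd_raw_counts(t1, t2, engine = match.arg(engine))$shared_raw
  if (raw %% 2 != 0)
    stop("internal consistency error: raw shared total ", raw, " is odd",
         call. = FALSE)
  raw / 2
}

#' Number of quartets resolved as different butterflies in the two trees
#'
#' Sums the different-topology directed count over all ordered pairs of
#' directed inner edges and divides by four (each differing butterfly pair
#' is claimed four times).
#'
#' @inheritParams count_shared_butterflies
#' @return a non-negative integer count.
#' @export
count_diff_butterflies <- function(t1, t2, engine = c("cpp", "r")) {
  raw <- qd_raw_counts(t1, t2, engine = match.arg(engine))$diff_raw
  if (raw %% 4 != 0)
    stop("internal consistency error: raw different total ", raw,
         " is not divisible by 4", call. = FALSE)
  raw / 4
}

#' Number of resolved (butterfly) quartets in a tree
#'
#' Equals the shared-butterfly count of the tree against itself; for a
#' binary tree this is \eqn{\binom{n}{4}}, for a star tree 0.
#'
#' @param tree a `qtree`.
#' @param engine `"cpp"` or `"r"`.
#' @return a non-negative integer count.
#' @export
butterfly_count <- function(tree, engine = c("cpp", "r")) {
  count_shared_butterflies(tree, tree, engine = engine)
}

new_quartet_components <- function(n, B, Bp, shared_B, diff_B, diff_S,
                                   qdist) {
  comp <- list(n = n, B = B, Bp = Bp, shared_B = shared_B,
               diff_B = diff_B, diff_S = diff_S, qdist = qdist,
               n_quartets = choose(n, 4),
               normalized = if (n >= 4) qdist / choose(n, 4) else NA_real_)
  vals <- unlist(comp[c("B", "Bp", "shared_B", "diff_B", "diff_S", "qdist")])
  if (any(vals < 0))
    stop("internal consistency error: negative component (",
         paste(names(vals)[vals < 0], collapse = ", "), ")", call. = FALSE)
  structure(comp, class = "quartet_components")
}

#' @export
print.quartet_components <- function(x, ...) {
  cat("Quartet distance components (n = ", x$n, ", C(n,4) = ",
      format(x$n_quartets, big.mark = ","), ")\n", sep = "")
  cat(sprintf("  butterflies T:  %.0f\n", x$B))
  cat(sprintf("  butterflies T': %.0f\n", x$Bp))
  cat(sprintf("  shared_B:       %.0f\n", x$shared_B))
  cat(sprintf("  diff_B:         %.0f\n", x$diff_B))
  cat(sprintf("  diff_S:         %.0f\n", x$diff_S))
  cat(sprintf("  quartet distance: %.0f", x$qdist))
  if (!is.na(x$normalized))
    cat(sprintf("  (normalized %.10g)", x$normalized))
  cat("\n")
  invisible(x)
}

#' Quartet distance between two general trees
#'
#' Computes the number of four-leaf subsets whose induced quartet topology
#' differs between the two trees.  The sub-cubic method counts shared and
#' differently-resolved butterflies over all pairs of directed inner edges
#' in O(1) each, after O(n^2) preprocessing plus per-node-pair dense matrix
#' products; star-vs-butterfly disagreements follow from the accounting
#' identity `diff_S = B + B' - 2 shared_B - 2 diff_B`.  The brute-force
#' method enumerates all C(n,4) quartets and is intended as a ground-truth
#' oracle for small trees.
#'
#' @param t1,t2 `qtree` objects (see [parse_newick()]) on the same leaf set;
#'   a differing leaf set is an error.
#' @param method `"subcubic"` (default) or `"bruteforce"`.
#' @return an object of class `quartet_components` with fields `B`, `Bp`,
#'   `shared_B`, `diff_B`, `diff_S`, `qdist`, `n_quartets` and `normalized`
#'   (`qdist / choose(n, 4)`).
#' @examples
#' t1 <- parse_newick("((a,b),(c,d));")
#' t2 <- parse_newick("((a,c),(b,d));")
#' quartet_distance(t1, t2)$qdist   # 1: the only quartet differs
#' @export
quartet_distance <- function(t1, t2, method = c("subcubic", "bruteforce")) {
  method <- match.arg(method)
  map <- shared_leaf_map(t1, t2)
  n <- length(map)
  if (n < 4L)
    return(new_quartet_components(n, 0, 0, 0, 0, 0, 0))
  if (method == "bruteforce")
    return(brute_force_components(t1, t2))
  raw <- qd_raw_counts(t1, t2, map)
  if (raw$shared_raw %% 2 != 0 || raw$diff_raw %% 4 != 0)
    stop("internal consistency error: raw totals violate parity",
         call. = FALSE)
  shared_B <- raw$shared_raw / 2
  diff_B <- raw$diff_raw / 4
  B <- butterfly_count(t1)
  Bp <- butterfly_count(t2)
  diff_S <- B + Bp - 2 * shared_B - 2 * diff_B
  new_quartet_components(n, B, Bp, shared_B, diff_B, diff_S,
                         diff_S + diff_B)
}
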