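#' @useDynLib quartetdist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom runif lm coef
#' @importFrom utils combn
NULL

# ---------------------------------------------------------------------------
# qtree: an unrooted, multifurcating phylogenetic tree stored as an adjacency
# list with deterministic neighbour order (parse order).  Leaves are the
# labelled nodes; after normalization every internal node has degree >= 3.
# ---------------------------------------------------------------------------

new_qtree <- function(adj, labels) {
  stopifnot(length(adj) == length(labels))
  is_leaf <- !is.na(labels)
  structure(
    list(
      adj      = adj,
      labels   = labels,
      is_leaf  = is_leaf,
      leaves   = which(is_leaf),
      internal = which(!is_leaf),
      n        = sum(is_leaf)
    ),
    class = "qtree"
  )
}

validate_qtree <- function(tree) {
  deg <- lengths(tree$adj)
  N <- length(tree$adj)
  n_edges <- sum(deg) / 2L
  if (N > 1L && n_edges != N - 1L)
    stop("invalid tree: ", n_edges, " edges for ", N, " nodes", call. = FALSE)
  labs <- tree$labels[tree$is_leaf]
  if (anyDuplicated(labs))
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(labs)))
    stop("empty leaf labels are not allowed", call. = FALSE)
  bad <- !tree$is_leaf & deg < 3L
  if (any(bad))
    stop("internal node of degree < 3 after normalization (node ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  if (tree$n < 1L)
    stop("tree must have at least one leaf", call. = FALSE)
  invisible(tree)
}

# Suppress unlabelled degree-2 nodes (including a rooted tree's binary root)
# and drop orphaned nodes, preserving the relative order of surviving nodes.
normalize_adjacency <- function(adj, labels) {
  repeat {
    deg <- lengths(adj)
    sup <- which(is.na(labels) & deg == 2L)
    if (!length(sup)) break
    v <- sup[1L]
    nb <- adj[[v]]
    a <- nb[1L]; b <- nb[2L]
    adj[[a]][adj[[a]] == v] <- b
    adj[[b]][adj[[b]] == v] <- a
    adj[[v]] <- integer(0)
    labels[v] <- NA_character_  # stays unlabelled; dropped below
  }
  deg <- lengths(adj)
  keep <- deg > 0L | !is.na(labels)
  if (!all(keep)) {
    newid <- cumsum(keep)
    adj <- lapply(adj[keep], function(x) as.integer(newid[x]))
    labels <- labels[keep]
  }
  list(adj = adj, labels = labels)
}

qtree_from_edges <- function(edge, labels_by_node, n_nodes) {
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1L]; b <- edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(x) if (is.null(x)) integer(0) else as.integer(x))
  norm <- normalize_adjacency(adj, labels_by_node)
  tree <- new_qtree(norm$adj, norm$labels)
  validate_qtree(tree)
  tree
}

check_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  quoted <- FALSE
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at position ", pos, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  invisible(TRUE)
}

#' Parse a Newick string into an unrooted multifurcating tree
#'
#' Accepts branch lengths, internal node labels and quoted labels, all of
#' which are discarded except the topology and the leaf labels.  A rooted
#' input (top-level node of degree 2) is silently unrooted by suppressing
#' that node, and any other unlabelled degree-2 node is likewise suppressed,
#' so every internal node of the result has degree at least 3.  Node
#' numbering, and hence the neighbour order that fixes subtree indices, is
#' deterministic for a given input string.
#'
#' @param text a single character string containing one Newick tree,
#'   terminated by a semicolon.  If several trees are present only the first
#'   is read.
#' @return an object of class `qtree`: an adjacency-list representation with
#'   fields `adj`, `labels` (`NA` for internal nodes), `leaves`, `internal`
#'   and `n` (the leaf count).
#' @examples
#' t1 <- parse_newick("((a,b),(c,d));")   # the 4-leaf butterfly ab|cd
#' t1$n
#' parse_newick("(a,b,c,d);")             # the 4-leaf star
#' @seealso [write_newick()], [quartet_distance()]
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string", call. = FALSE)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick input", call. = FALSE)
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi < 0L)
    stop("Newick parse error: missing terminating ';' (position ",
         nchar(text) + 1L, ")", call. = FALSE)
  core <- trimws(substr(text, 1L, semi - 1L))
  if (!nzchar(core)) stop("Newick parse error: empty tree before ';'",
                          call. = FALSE)
  check_balanced(core)

  if (!grepl("[(),]", core)) {
    # single-leaf tree, e.g. "a;" or "'a b':1.0;"
    lab <- sub(":.*$", "", core)
    lab <- gsub("^'|'$", "", lab)
    if (!nzchar(lab)) stop("empty leaf label", call. = FALSE)
    return(new_qtree(list(integer(0)), lab))
  }

  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = paste0(core, ";"))),
    error = function(e) NULL
  )
  if (is.null(phy))
    stop("Newick parse error: ", substr(core, 1L, 60L), call. = FALSE)
  ntip <- length(phy$tip.label)
  n_nodes <- ntip + phy$Nnode
  tips <- as.character(phy$tip.label)
  quoted <- grepl("^'.*'$", tips)
  tips[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", tips[quoted]))
  labels <- c(tips, rep(NA_character_, phy$Nnode))
  if (anyDuplicated(labels[seq_len(ntip)]))
    stop("duplicate leaf labels: ",
         paste(unique(labels[duplicated(labels[seq_len(ntip)])]),
               collapse = ", "), call. = FALSE)
  qtree_from_edges(phy$edge, labels, n_nodes)
}

#' Read the first Newick tree from a file
#'
#' @param path path to a file whose first tree (first semicolon-terminated
#'   statement) is parsed with [parse_newick()].
#' @return a `qtree`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parse_newick(txt)
}

quote_label <- function(lab) {
  if (grepl("[ (),:;'\\[\\]]", lab)) paste0("'", gsub("'", "''", lab), "'")
  else lab
}

#' Serialize a tree to Newick
#'
#' Writes topology and leaf labels only (no branch lengths).  The output
#' round-trips: parsing it again yields a tree with the same edge-induced
#' leaf bipartitions.
#'
#' @param tree a `qtree`.
#' @return a single Newick string terminated by `";"`.
#' @examples
#' write_newick(parse_newick("((a,b),(c,d));"))
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "qtree"))
  if (tree$n == 1L) return(paste0(quote_label(tree$labels[tree$leaves]), ";"))
  rec <- function(v, from) {
    if (tree$is_leaf[v]) return(quote_label(tree$labels[v]))
    kids <- setdiff(tree$adj[[v]], from)
    paste0("(", paste(vapply(kids, rec, "", from = v), collapse = ","), ")")
  }
  if (length(tree$internal)) {
    root <- tree$internal[1L]
    kids <- tree$adj[[root]]
    body <- paste(vapply(kids, rec, "", from = root), collapse = ",")
    paste0("(", body, ");")
  } else {
    # two leaves joined by a single edge
    paste0("(", paste(vapply(tree$leaves, function(v)
      quote_label(tree$labels[v]), ""), collapse = ","), ");")
  }
}

#' Common leaf index over two trees
#'
#' Both trees must carry exactly the same set of leaf labels; the returned
#' map assigns each label a fixed integer index (alphabetical order) through
#' which both trees address their leaves.
#'
#' @param t1,t2 `qtree` objects.
#' @return a named integer vector mapping each leaf label to an index in
#'   `1:n`.
#' @export
shared_leaf_map <- function(t1, t2) {
  stopifnot(inherits(t1, "qtree"), inherits(t2, "qtree"))
  l1 <- sort(t1$labels[t1$leaves])
  l2 <- sort(t2$labels[t2$leaves])
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2)
    only2 <- setdiff(l2, l1)
    stop("leaf sets differ; symmetric difference: {",
         paste(c(only1, only2), collapse = ", "), "}", call. = FALSE)
  }
  stats::setNames(seq_along(l1), l1)
}

#' @export
print.qtree <- function(x, ...) {
  cat("Unrooted multifurcating tree: ", x$n, " leaves, ",
      length(x$internal), " internal nodes\n", sep = "")
  if (x$n <= 20L) cat("  ", write_newick(x), "\n", sep = "")
  invisible(x)
}

# Root a qtree for dynamic programming: returns parent array, a postorder
# node sequence and subtree leaf counts.  Root defaults to the first
# internal node (parse order), or node 1 when no internal node exists.
root_qtree <- function(tree, root = NULL) {
  if (is.null(root))
    root <- if (length(tree$internal)) tree$internal[1L] else 1L
  N <- length(tree$adj)
  parent <- integer(N)
  order <- integer(N)
  stack <- c(root)
  parent[root] <- 0L
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order[k] <- v
    for (u in tree$adj[[v]])
      if (u != parent[v]) {
        parent[u] <- v
        stack <- c(stack, u)
      }
  }
  post <- rev(order)
  size <- numeric(N)
  for (v in post) {
    if (tree$is_leaf[v]) size[v] <- 1
    for (u in tree$adj[[v]]) if (u != parent[v]) size[v] <- size[v] + size[u]
  }
  list(root = root, parent = parent, post = post, size = size)
}

# Edge-induced leaf bipartitions as a canonical character set; used for
# topology-isomorphism checks.
leaf_bipartitions <- function(tree) {
  rt <- root_qtree(tree)
  all_labs <- sort(tree$labels[tree$leaves])
  below <- vector("list", length(tree$adj))
  for (v in rt$post) {
    if (tree$is_leaf[v]) below[[v]] <- tree$labels[v]
    else {
      kids <- setdiff(tree$adj[[v]], rt$parent[v])
      below[[v]] <- unlist(below[kids])
    }
  }
  splits <- character(0)
  for (v in seq_along(tree$adj)) {
    if (v == rt$root) next
    side <- sort(below[[v]])
    other <- setdiff(all_labs, side)
    canon <- if (length(side) <= length(other) &&
                 !(length(side) == length(other) && side[1] > other[1]))
      side else other
    splits <- c(splits, paste(canon, collapse = "\r"))
  }
  sort(unique(splits))
}
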