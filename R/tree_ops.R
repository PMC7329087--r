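# Low-level unrooted-tree operations on ape "phylo" objects: adjacency,
# BFS, diameter path, middle-edge splits and rooted clades. All path
# lengths here are edge counts; branch lengths play no role in the
# sensitivity procedures.

tree_adj <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1L]; b <- tree$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS over the adjacency list; optionally with one edge (from-to) removed.
# Returns integer distances (NA where unreachable) and parents.
bfs_tree <- function(adj, start, drop_edge = NULL) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!is.null(drop_edge) &&
          ((v == drop_edge[1L] && w == drop_edge[2L]) ||
           (v == drop_edge[2L] && w == drop_edge[1L]))) next
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  list(dist = dist, parent = parent)
}

path_from_parents <- function(parent, start, end) {
  path <- end
  while (path[1L] != start) path <- c(parent[path[1L]], path)
  path
}

#' Longest leaf-to-leaf path of a phylogram
#'
#' A diameter path by edge count. Ties between equally long leaf pairs are
#' broken by the lexicographically smallest (start, end) leaf-label pair
#' with start <= end, so the result is deterministic.
#'
#' @param tree An `fsopa_phylogram` or `phylo` object with >= 2 leaves.
#' @return Integer vector of node ids along the path (first and last are
#'   leaves).
#' @export
longest_path <- function(tree) {
  tree <- as_phylo(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least 2 leaves")
  adj <- tree_adj(tree)
  labs <- tree$tip.label
  best <- NULL; best_d <- -1L; best_key <- NULL
  for (i in seq_len(ntip)) {
    b <- bfs_tree(adj, i)
    for (j in seq_len(ntip)) {
      if (j == i) next
      d <- b$dist[j]
      pair <- sort(c(labs[i], labs[j]))
      key <- paste(pair, collapse = "\r")
      if (d > best_d || (d == best_d && key < best_key)) {
        best_d <- d; best_key <- key
        # orient the path from the lexicographically smaller endpoint
        if (labs[i] <= labs[j]) {
          best <- path_from_parents(b$parent, i, j)
        } else {
          best <- rev(path_from_parents(b$parent, i, j))
        }
      }
    }
  }
  best
}

# A clade: the rooted subtree on one side of a cut edge, rooted at the cut
# point. `parent` holds BFS parents from the root within the clade.
make_clade <- function(tree, root, other) {
  adj <- tree_adj(tree)
  b <- bfs_tree(adj, root, drop_edge = c(root, other))
  nodes <- which(!is.na(b$dist))
  ntip <- length(tree$tip.label)
  tips <- nodes[nodes <= ntip]
  structure(list(tree = tree, root = root, cut_other = other,
                 nodes = nodes, parent = b$parent,
                 leaves = sort(tree$tip.label[tips]), tip_ids = tips),
            class = "fsopa_clade")
}

#' @export
print.fsopa_clade <- function(x, ...) {
  cat("<fsopa_clade> ", length(x$leaves), " leaves: ",
      paste(x$leaves, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Candidate middle-edge splits of a phylogram
#'
#' Removes the edge in the middle of the longest (diameter) path, splitting
#' the phylogram into two clades rooted at the cut. When the diameter has an
#' odd number of edges the middle edge is unique; when it is even both
#' middle candidates are returned, to be arbitrated downstream by
#' congruence.
#'
#' @param tree An `fsopa_phylogram` or `phylo` object.
#' @return List of candidate splits, each a list with `c1`, `c2`
#'   (`fsopa_clade`; `c1` is the side containing the path start) and
#'   `cut_edge` (node-id pair).
#' @export
split_middle <- function(tree) {
  tree <- as_phylo(tree)
  path <- longest_path(tree)
  m <- length(path) - 1L                     # number of edges on the path
  mids <- if (m %% 2L == 1L) (m + 1L) %/% 2L else c(m %/% 2L, m %/% 2L + 1L)
  lapply(mids, function(e) {
    u <- path[e]; v <- path[e + 1L]
    list(c1 = make_clade(tree, u, v), c2 = make_clade(tree, v, u),
         cut_edge = c(u, v))
  })
}

as_phylo <- function(x) {
  if (inherits(x, "fsopa_phylogram")) x$tree
  else if (inherits(x, "phylo")) x
  else stop("expected an fsopa_phylogram or phylo object")
}

#' Sibling leaf set of a leaf within a clade
#'
#' With the clade rooted at its cut point, the siblings of leaf x are the
#' leaves of the subtree hanging from the other side of x's parent node:
#' everything reachable from the parent without passing through x or back
#' toward the root. A singleton clade has an empty sibling set.
#'
#' @param leaf Leaf label.
#' @param clade An `fsopa_clade` from [split_middle()].
#' @return Sorted character vector of leaf labels (possibly empty).
#' @export
sibling_set <- function(leaf, clade) {
  stopifnot(inherits(clade, "fsopa_clade"))
  x <- match(leaf, clade$tree$tip.label)
  if (is.na(x) || !(x %in% clade$nodes)) stop("leaf not in clade: ", leaf)
  if (x == clade$root) return(character(0))  # singleton clade
  p <- clade$parent[x]
  up <- clade$parent[p]                      # NA when p is the clade root
  adj <- tree_adj(clade$tree)
  kids <- setdiff(adj[[p]], c(x, if (!is.na(up)) up, clade$cut_other))
  if (length(kids) == 0L) return(character(0))
  out <- integer(0)
  for (k in kids) {
    b <- bfs_tree(adj, k, drop_edge = c(k, p))
    out <- c(out, which(!is.na(b$dist)))
  }
  ntip <- length(clade$tree$tip.label)
  sort(clade$tree$tip.label[out[out <= ntip]])
}
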