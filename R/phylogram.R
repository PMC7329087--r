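#' Serialize one feature column over a sample subset to a byte object
#'
#' Each feature column, restricted to a sample subset and kept in subset
#' rank order, becomes one byte object: the raw cell strings joined with
#' newlines, missing cells emitted as the sentinel token. These objects are
#' what the compressor sees, so row order is the alignment key that lets the
#' compression distance pick up co-variation between columns.
#'
#' @param table An `fsopa_table`.
#' @param column Column name.
#' @param subset Integer vector of row indices (subset rank order).
#' @return List with `name` and `payload` (raw vector), class `fsopa_bytes`.
#' @export
serialize_column <- function(table, column, subset) {
  stopifnot(inherits(table, "fsopa_table"))
  if (!column %in% names(table$data)) stop("unknown column: ", column)
  if (length(subset) == 0L) stop("empty subset: no object can be built")
  if (any(subset < 1L | subset > table$n)) stop("subset indices out of range")
  cells <- table$data[[column]][subset]
  cells[table$missing[subset, column]] <- missing_sentinel(table)
  structure(list(name = column,
                 payload = charToRaw(paste(cells, collapse = "\n"))),
            class = "fsopa_bytes")
}

compressed_size <- function(payload, compressor) {
  type <- switch(compressor,
                 gzip = "gzip", zlib = "gzip", bzip2 = "bzip2",
                 bz2 = "bzip2", xz = "xz", lzma = "xz",
                 stop("unknown compressor: ", compressor))
  length(memCompress(payload, type = type))
}

#' Normalized compression distance between two byte objects
#'
#' NCD(x, y) = (C(xy) - min(C(x), C(y))) / max(C(x), C(y)), with C the
#' compressed size in bytes. The concatenation xy is always taken in
#' canonical order (lexicographically smaller object name first), so the
#' distance is exactly symmetric regardless of argument order. Values are
#' clamped to be non-negative; compressor overhead can push them slightly
#' above 1.
#'
#' @param x,y `fsopa_bytes` objects with distinct names.
#' @param compressor `"gzip"` (default), `"bzip2"`, or `"xz"`.
#' @param cx,cy Optional precomputed compressed sizes of `x` and `y`.
#' @return The distance, a non-negative number (typically in `[0, ~1.1]`).
#' @export
ncd <- function(x, y, compressor = "gzip", cx = NULL, cy = NULL) {
  stopifnot(inherits(x, "fsopa_bytes"), inherits(y, "fsopa_bytes"))
  if (length(x$payload) == 0L || length(y$payload) == 0L)
    stop("payloads must be non-empty")
  if (is.null(cx)) cx <- compressed_size(x$payload, compressor)
  if (is.null(cy)) cy <- compressed_size(y$payload, compressor)
  pair <- if (x$name <= y$name) c(x$payload, y$payload) else c(y$payload, x$payload)
  cxy <- compressed_size(pair, compressor)
  max(0, (cxy - min(cx, cy)) / max(cx, cy))
}

#' Pairwise NCD matrix over a list of byte objects
#'
#' Compressed sizes C(x) are computed once per object and reused across
#' pairs. The result is exactly symmetric with a zero diagonal.
#'
#' @param objects List of `fsopa_bytes` with unique names.
#' @param compressor Compressor name, see [ncd()].
#' @return Symmetric numeric matrix with dimnames set to the object names.
#' @export
ncd_matrix <- function(objects, compressor = "gzip") {
  l <- length(objects)
  if (l < 2L) stop("need at least 2 objects")
  nms <- unname(vapply(objects, `[[`, character(1), "name"))
  if (anyDuplicated(nms))
    stop("duplicate object names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sizes <- vapply(objects, function(o) compressed_size(o$payload, compressor),
                  numeric(1))
  d <- matrix(0, l, l, dimnames = list(nms, nms))
  for (i in seq_len(l - 1L)) {
    for (j in seq.int(i + 1L, l)) {
      v <- ncd(objects[[i]], objects[[j]], compressor,
               cx = sizes[i], cy = sizes[j])
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  d
}

#' Neighbor-joining phylogram from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining, returning an unrooted tree whose
#' internal nodes all have degree 3 (for l >= 3). Negative branch lengths,
#' which NJ can produce on non-additive matrices, are clamped to zero with
#' the deficit transferred to the sister branch so path lengths through the
#' parent node are preserved. For l = 2 the tree is the single edge of
#' length d(1,2) (represented with a degree-2 junction node as required by
#' the `phylo` format).
#'
#' @param d Symmetric numeric matrix with zero diagonal, finite entries and
#'   unique dimnames.
#' @return An [ape::ape-package] `phylo` object (unrooted).
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (nrow(d) < 2L) stop("need at least 2 leaves")
  if (any(!is.finite(d))) stop("non-finite entries in distance matrix")
  nms <- rownames(d)
  if (is.null(nms) || anyDuplicated(nms)) stop("d needs unique dimnames")
  if (nrow(d) == 2L) {
    tr <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                         edge.length = rep(d[1, 2] / 2, 2L),
                         tip.label = nms, Nnode = 1L),
                    class = "phylo")
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::nj(d)
  clamp_negative_branches(tr)
}

# Clamp negative branch lengths to 0, adding the deficit to the sister edge
# (another edge incident to the same parent) so distances through the parent
# are unchanged.
clamp_negative_branches <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    i <- neg[which.min(tr$edge.length[neg])]
    deficit <- -tr$edge.length[i]
    tr$edge.length[i] <- 0
    parent <- tr$edge[i, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent | tr$edge[, 2L] == parent),
                   i)
    if (length(sib)) {
      j <- sib[which.max(tr$edge.length[sib])]
      tr$edge.length[j] <- tr$edge.length[j] + deficit
    }
  }
  tr
}

#' Fast greedy modularity communities (Newman's fast algorithm)
#'
#' Greedy agglomerative modularity maximization: start from singleton
#' communities, repeatedly perform the merge with the largest modularity
#' increase, and return the partition with maximum modularity along the
#' merge path.
#'
#' @param graph An [igraph::igraph] undirected simple graph with >= 1 node.
#' @return List with `membership` (integer vector) and `modularity` (Q of
#'   the returned partition; 0 for edgeless graphs, where Q is undefined).
#' @export
fast_newman <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("graph must be an igraph object")
  nv <- igraph::vcount(graph)
  if (nv == 0L) stop("empty graph")
  if (igraph::ecount(graph) == 0L)
    return(list(membership = seq_len(nv), modularity = 0))
  cl <- igraph::cluster_fast_greedy(graph)
  memb <- as.integer(igraph::membership(cl))
  list(membership = memb,
       modularity = igraph::modularity(graph, memb))
}

phylo_to_igraph <- function(tree) {
  igraph::graph_from_edgelist(tree$edge, directed = FALSE)
}

node_labels <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  labs <- character(n_all)
  labs[seq_along(tree$tip.label)] <- tree$tip.label
  labs[seq.int(length(tree$tip.label) + 1L, n_all)] <-
    paste0(".n", seq_len(tree$Nnode))
  labs
}

#' Build one phylogram-based model from a sample subset
#'
#' The model-construction stage: serialize every feature column over the
#' subset, compute the pairwise NCD matrix, build the neighbor-joining
#' phylogram, and annotate communities found by fast greedy modularity on
#' the tree graph. Deterministic for fixed inputs.
#'
#' @param table An `fsopa_table`.
#' @param subset Integer row indices (from an [ss_sample()] subset).
#' @param compressor Compressor name, see [ncd()].
#' @param columns Columns to use as objects; default every column of the
#'   table (the criterion itself included). Pass e.g.
#'   `setdiff(feature_names(tab), "los")` to exclude it.
#' @param label Optional subset label (e.g. `"B2C"`) kept as metadata.
#' @return An object of class `fsopa_phylogram`: list with `tree` (`phylo`),
#'   `dist` (NCD matrix), `communities` (membership over tree nodes in
#'   `node_labels` order plus modularity), `label`, `compressor`.
#' @export
build_model <- function(table, subset, compressor = "gzip", columns = NULL,
                        label = NULL) {
  if (is.null(columns)) columns <- feature_names(table)
  if (length(columns) < 2L) stop("need at least 2 feature columns")
  objects <- lapply(columns, function(col) serialize_column(table, col, subset))
  d <- ncd_matrix(objects, compressor)
  tree <- neighbor_joining(d)
  g <- phylo_to_igraph(tree)
  comm <- fast_newman(g)
  structure(list(tree = tree, dist = d,
                 communities = list(membership = comm$membership,
                                    modularity = comm$modularity,
                                    node_labels = node_labels(tree)),
                 label = label, compressor = compressor),
            class = "fsopa_phylogram")
}

#' @export
print.fsopa_phylogram <- function(x, ...) {
  cat("<fsopa_phylogram>", if (!is.null(x$label)) paste0(" [", x$label, "]"),
      " ", length(x$tree$tip.label), " leaves, compressor = ", x$compressor,
      ", modularity = ", format(x$communities$modularity, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Newick serialization of a phylogram
#' @param model An `fsopa_phylogram` or a `phylo` tree.
#' @param path Optional output file; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(model, path = NULL) {
  tree <- if (inherits(model, "fsopa_phylogram")) model$tree else model
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Export a distance matrix in PHYLIP square format
#' @param d Symmetric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  nms <- rownames(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(nms[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
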