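# Distance-based tree inference with bootstrap clade support. Neighbor-joining
# and Newick I/O go through ape; bootstrap column resampling and
# unrooted-bipartition support counting are implemented here so their
# semantics (splits, not rooted clades) are explicit.

#' Neighbor-joining tree from an IWSS distance matrix
#'
#' Canonical Saitou-Nei neighbor joining over the samples. Negative branch
#' lengths, which NJ can produce on non-additive dissimilarities, are clamped
#' to zero with a warning.
#'
#' @param D An `iwss_dist` object or square symmetric distance matrix with at
#'   least 3 samples.
#' @return An unrooted `phylo` tree (tips = sample ids).
#' @export
nj_tree <- function(D) {
  M <- as_dist_matrix(D)
  if (nrow(M) < 3) stop("neighbor joining needs at least 3 samples")
  tree <- ape::nj(stats::as.dist(M))
  if (any(tree$edge.length < 0)) {
    warning("clamping ", sum(tree$edge.length < 0),
            " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# Leaf set below every internal node, as canonical split keys. The side of the
# bipartition NOT containing the alphabetically first tip is kept, so keys are
# rooting-invariant; trivial splits (terminal edges) are excluded.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (is.null(tree$Nnode) || tree$Nnode < 2) return(character(0))
  nodes <- n + seq_len(tree$Nnode)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  # children precede parents in reverse order of ape's edge matrix after
  # reordering postorder
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  anchor <- sort(tree$tip.label)[1]
  root <- n + 1L
  keys <- character(0)
  for (v in setdiff(nodes, root)) {
    clade <- desc[[v]]
    if (length(clade) <= 1 || length(clade) >= n - 1) next
    side <- if (anchor %in% clade) setdiff(tree$tip.label, clade) else clade
    keys[as.character(v)] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' Bootstrap clade support for the scar tree
#'
#' Builds the reference neighbor-joining tree from the full binary matrix, then
#' resamples scar columns (the characters) with replacement `n_boot` times,
#' recomputing weights, distances and the NJ tree for every replicate. The
#' support of each internal edge of the reference tree is the number of
#' replicate trees containing the same unrooted bipartition, following the
#' standard 100-replicate phylogenetic bootstrap.
#'
#' @param B A `binary_scar_matrix` (or 0/1 matrix) with at least 4 samples
#'   (3-sample trees have no internal edge to support).
#' @param n_boot Number of bootstrap replicates; default 100.
#' @param seed Integer seed making the resampling reproducible.
#' @param alpha Pseudocount for [scar_weights()].
#' @param as_proportion If `TRUE`, node labels are written as support /
#'   `n_boot` instead of raw counts.
#' @return The reference `phylo` tree with bootstrap counts as internal node
#'   labels, plus attributes `support` (named by bipartition) and `n_boot`.
#' @export
bootstrap_support <- function(B, n_boot = 100, seed = 1L, alpha = 0.5,
                              as_proportion = FALSE) {
  pres <- if (inherits(B, "binary_scar_matrix")) B$presence else as.matrix(B)
  stopifnot(n_boot >= 1)
  ref <- nj_tree(distance_matrix(pres, alpha = alpha))
  ref_splits <- tree_bipartitions(ref)
  counts <- stats::setNames(integer(length(ref_splits)), ref_splits)
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(pres), ncol(pres), replace = TRUE)
    Bb <- pres[, cols, drop = FALSE]
    tb <- suppressWarnings(nj_tree(distance_matrix(Bb, alpha = alpha)))
    hits <- intersect(ref_splits, tree_bipartitions(tb))
    counts[hits] <- counts[hits] + 1L
  }
  n <- length(ref$tip.label)
  labs <- rep("", ref$Nnode)
  for (v in names(ref_splits)) {
    val <- counts[[ref_splits[[v]]]]
    if (as_proportion) val <- val / n_boot
    labs[as.integer(v) - n] <- as.character(val)
  }
  ref$node.label <- labs
  attr(ref, "support") <- counts
  attr(ref, "n_boot") <- n_boot
  ref
}

#' Newick serialization of clade trees
#'
#' Standard Newick with bootstrap supports as internal node labels; unrooted
#' trees use the conventional trifurcating root. Round-tripping preserves
#' topology, branch lengths and supports.
#'
#' @param tree A `phylo` tree.
#' @param path File path.
#' @return `path` invisibly ([write_newick()]); a `phylo` ([read_newick()]).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick in '", path, "': ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in '", path, "'")
  tree
}
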