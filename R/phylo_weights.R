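#' Identity distance matrix under pairwise gap deletion
#'
#' For every pair of aligned rows the distance is `1 - matches/compared`,
#' where only columns in which neither row has a gap are compared. Pairs with
#' no comparable column get distance 1. This mirrors tree construction with
#' the pairwise gap-deletion option, which keeps information from
#' gap-containing columns.
#'
#' @param rows character vector of equal-length gapped sequences.
#' @param ids labels (default `names(rows)` or `seq_along`).
#' @return symmetric numeric matrix with zero diagonal and `ids` dimnames.
#' @export
sequence_distance_matrix <- function(rows, ids = NULL) {
  if (length(rows) < 2L)
    tfsc_error("need >= 2 sequences for a distance matrix", "size_error")
  if (is.null(ids)) ids <- if (!is.null(names(rows))) names(rows) else as.character(seq_along(rows))
  m <- rows_to_matrix(toupper(rows))
  n <- length(rows)
  nongap <- (m != GAP_CHAR) * 1
  # pairwise match and comparable-column counts via indicator cross-products
  comparable <- tcrossprod(nongap)
  matches <- matrix(0, n, n)
  for (s in setdiff(unique(as.vector(m)), GAP_CHAR)) {
    ind <- (m == s) * 1
    matches <- matches + tcrossprod(ind)
  }
  d <- ifelse(comparable > 0, 1 - matches / pmax(comparable, 1), 1)
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei NJ (via [ape::nj()]); negative branch-length estimates
#' are clamped to zero. Two taxa yield a single edge bisected into equal
#' halves.
#'
#' @param D symmetric distance matrix with labelled dimnames.
#' @return an unrooted `phylo` tree.
#' @export
build_nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    tfsc_error("distance matrix must be square and symmetric", "validation_error")
  n <- nrow(D)
  if (n < 2L) tfsc_error("need >= 2 taxa", "size_error")
  if (n == 2L) {
    tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                         edge.length = rep(D[1, 2] / 2, 2),
                         tip.label = rownames(D), Nnode = 1L),
                    class = "phylo", order = "cladewise")
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return a rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) < 2L) tfsc_error("need >= 2 leaves", "size_error")
  if (length(tree$tip.label) == 2L) {
    half <- sum(tree$edge.length) / 2
    tree$edge.length <- rep(half, 2)
    return(tree)
  }
  phangorn::midpoint(tree)
}

#' Collapse clusters of near-identical leaves to one representative
#'
#' Leaves closer than `threshold` (patristic path distance on the tree) are
#' greedily clustered: scanning leaves in input order, a leaf is dropped if it
#' is within `threshold` of an already retained leaf. Near-identical
#' sequences (e.g. the same regulator from many strains of one species)
#' otherwise dominate the alignment.
#'
#' @param tree a `phylo` tree.
#' @param threshold path-distance threshold (default 0.02).
#' @return list with `tree` (pruned; `NULL` if a single leaf survives) and
#'   `kept_ids`.
#' @export
prune_similar_leaves <- function(tree, threshold = 0.02) {
  d <- ape::cophenetic.phylo(tree)
  labs <- tree$tip.label
  kept <- character(0)
  for (l in labs) {
    if (!length(kept) || all(d[l, kept] >= threshold)) kept <- c(kept, l)
  }
  pruned <- if (length(kept) >= 2L) ape::keep.tip(tree, kept) else NULL
  list(tree = pruned, kept_ids = kept)
}

#' Gerstein-Sonnhammer-Chothia leaf weights
#'
#' Leaf-up GSC weighting on a rooted tree: each leaf starts with its own
#' branch length; the length of every deeper internal edge is then divided
#' among the leaves below it in proportion to their current weights (equal
#' split where all current weights are zero, e.g. zero-length subtrees).
#' Redundant leaves in tight clades thereby share branch length and are
#' down-weighted. Weights are normalised to sum to the number of leaves, so
#' the weighted sequence count stays on the scale of the raw count.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return named numeric weight vector over the leaf labels.
#' @export
gsc_weights <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip == 1L) return(stats::setNames(1, tree$tip.label))
  tr <- stats::reorder(tree, "postorder")
  el <- if (is.null(tr$edge.length)) rep(0, nrow(tr$edge)) else tr$edge.length
  w <- rep(0, ntip)
  desc <- vector("list", ntip + tr$Nnode)
  for (t in seq_len(ntip)) desc[[t]] <- t
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    if (child <= ntip) {
      w[child] <- w[child] + el[e]
    } else {
      tips <- desc[[child]]
      tot <- sum(w[tips])
      w[tips] <- if (tot > 0) w[tips] + el[e] * w[tips] / tot
                 else w[tips] + el[e] / length(tips)
    }
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  s <- sum(w)
  w <- if (s > 0) w * ntip / s else rep(1, ntip)
  stats::setNames(w, tr$tip.label)
}

#' Compute per-sequence weights for one side of a paired set
#'
#' Distance matrix (pairwise gap deletion) over the distinct sequences,
#' NJ tree, midpoint rooting, GSC weighting. With `mode = "uniform"` every
#' sequence gets weight 1.
#'
#' @param rows gapped sequences named by id (one entry per distinct id).
#' @param mode `"gsc"` or `"uniform"`.
#' @return named weight vector, normalised to sum to `length(rows)`.
#' @export
sequence_weights <- function(rows, mode = c("gsc", "uniform")) {
  mode <- match.arg(mode)
  ids <- names(rows)
  if (is.null(ids)) tfsc_error("rows must be named by sequence id", "reference_error")
  if (mode == "uniform" || length(rows) == 1L)
    return(stats::setNames(rep(1, length(rows)), ids))
  D <- sequence_distance_matrix(rows, ids)
  gsc_weights(midpoint_root(build_nj_tree(D)))
}

#' Attach per-sequence weights and recompute pair weights
#'
#' Sets each record's pair weight to `w(r) * w(s)` and records the total
#' weight N.
#'
#' @param set a `paired_alignment_set`.
#' @param tf_weights,site_weights named weight vectors covering every id in
#'   the set.
#' @return the reweighted `paired_alignment_set`.
#' @export
assign_pair_weights <- function(set, tf_weights, site_weights) {
  if (!all(set$tf_id %in% names(tf_weights)))
    tfsc_error("TF id missing from tf_weights", "reference_error")
  if (!all(set$site_id %in% names(site_weights)))
    tfsc_error("site id missing from site_weights", "reference_error")
  paired_alignment_set(set$tf_id, set$site_id, set$tf_row, set$site_row,
                       tf_weights, site_weights)
}

#' GSC-weight both sides of a paired set
#'
#' Convenience wrapper: computes per-TF and per-site weights over the
#' distinct sequences of each side and attaches the products as pair
#' weights. TF weights always use GSC; how the original method weighted the
#' site side is unstated, so the site mode is an explicit option.
#'
#' @param set a `paired_alignment_set`.
#' @param site_weights_mode `"gsc"` (default, symmetric treatment) or
#'   `"uniform"`.
#' @return the reweighted `paired_alignment_set`.
#' @export
weight_paired_set <- function(set, site_weights_mode = c("gsc", "uniform")) {
  site_weights_mode <- match.arg(site_weights_mode)
  keep_tf <- !duplicated(set$tf_id)
  keep_site <- !duplicated(set$site_id)
  tf_w <- sequence_weights(stats::setNames(set$tf_row[keep_tf], set$tf_id[keep_tf]), "gsc")
  site_w <- sequence_weights(stats::setNames(set$site_row[keep_site], set$site_id[keep_site]),
                             site_weights_mode)
  assign_pair_weights(set, tf_w, site_w)
}
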