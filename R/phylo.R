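#' Trim an alignment to median motif anchor columns
#'
#' Rep alignments are trimmed close to the RCR motif I and the helicase
#' arginine finger: the left anchor column is the median alignment column of
#' RCR-I across rows, the right anchor the median column of the arginine
#' finger; columns outside `[left, right]` are dropped. Rows whose remaining
#' ungapped length falls below `min_len` are removed and reported.
#'
#' @param alignment Named character vector of equal-length gapped amino-acid
#'   rows (`-` gaps).
#' @param anchors Tibble with columns `id`, `rcr1_aa_pos`, `argf_aa_pos`:
#'   0-based ungapped residue positions of the two anchor motifs per row
#'   (`NA` allowed); at least half the rows must have both anchors.
#' @param min_len Minimum retained ungapped row length (default 200).
#' @return List of class `cress_trim`: `alignment` (trimmed rows),
#'   `left_anchor_col`, `right_anchor_col` (1-based column indices in the
#'   input), `dropped` (ids removed by the length filter).
#' @export
trim_to_motif_anchors <- function(alignment, anchors, min_len = 200L) {
  ids <- names(alignment)
  stopifnot(!is.null(ids), all(anchors$id %in% ids))
  w <- unique(nchar(alignment))
  if (length(w) != 1L) abort("rows have unequal lengths")

  aa_pos_to_col <- function(row, aa_pos) {
    # aa_pos is 0-based among non-gap characters; returns 1-based column.
    ch <- strsplit(row, "", fixed = TRUE)[[1]]
    res <- which(ch != "-")
    if (aa_pos + 1L > length(res)) return(NA_integer_)
    res[aa_pos + 1L]
  }
  lcols <- rcols <- rep(NA_integer_, length(ids))
  for (k in seq_len(nrow(anchors))) {
    i <- match(anchors$id[k], ids)
    if (!is.na(anchors$rcr1_aa_pos[k]))
      lcols[i] <- aa_pos_to_col(alignment[[i]], anchors$rcr1_aa_pos[k])
    if (!is.na(anchors$argf_aa_pos[k]))
      rcols[i] <- aa_pos_to_col(alignment[[i]], anchors$argf_aa_pos[k])
  }
  ok <- !is.na(lcols) & !is.na(rcols)
  if (mean(ok) < 0.5) abort("fewer than half of rows have both anchor motifs")
  left <- as.integer(round(median(lcols[ok])))
  right <- as.integer(round(median(rcols[ok])))
  if (right < left) abort("anchors inverted (right anchor before left)")

  trimmed <- vapply(alignment, function(r) substr(r, left, right), character(1))
  ungapped <- nchar(gsub("-", "", trimmed, fixed = TRUE))
  keep <- ungapped >= min_len
  structure(list(alignment = trimmed[keep], left_anchor_col = left,
                 right_anchor_col = right, dropped = ids[!keep],
                 min_len_filter = min_len),
            class = "cress_trim")
}

#' Neighbour-joining tree from a pairwise-identity matrix
#'
#' Distances are `1 - PI`. Standard neighbour joining (via \pkg{ape});
#' negative branch lengths are clamped to zero with the deficit moved to the
#' sister edge, preserving path lengths through the parent node. Taxa are
#' ordered by id before joining so ties resolve deterministically.
#'
#' @param pim A `cress_pim` from [build_pi_matrix()], or a symmetric
#'   distance matrix with dimnames (taken as distances directly).
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(pim) {
  if (inherits(pim, "cress_pim")) {
    d <- 1 - pim$values
  } else {
    d <- as.matrix(pim)
  }
  if (nrow(d) < 3L) abort("need at least 3 taxa")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(stats::as.dist(d))
  # Clamp negative edges; move each deficit onto the sister edge.
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1]
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs) > 0L) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Parse node supports from a phylo object's node labels. Returns numeric
# vector (NA where absent).
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Collapse branches below a support threshold
#'
#' Contracts every internal edge whose child node's support value is
#' strictly below `threshold`: the node's children are reattached to its
#' parent (each child keeps its own edge length by default, or has the
#' collapsed edge's length added with `sum_lengths = TRUE`). Leaves are
#' never removed. The result is written in canonical form (children ordered
#' by their smallest leaf label).
#'
#' @param tree An `ape::phylo` with support values as `node.label`, or a
#'   Newick string.
#' @param threshold Support threshold, on the same scale as the labels
#'   (`[0, 1]` or `[0, 100]`); mixed scales in one tree error.
#' @param sum_lengths Add the collapsed edge's length to the reattached
#'   children's edges (default `FALSE`: children keep their own lengths).
#' @return The collapsed `ape::phylo`, with a canonical `newick` attribute.
#' @export
collapse_low_support <- function(tree, threshold, sum_lengths = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  sup <- node_supports(tree)
  vals <- sup[!is.na(sup)]
  if (length(vals) > 0L && any(vals > 1) && any(vals <= 1 & vals > 0))
    abort("mixed support scales detected (values both <= 1 and > 1)")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # Internal nodes (excluding root) whose support is below threshold.
  drop_nodes <- which(!is.na(sup) & sup < threshold) + ntip
  drop_nodes <- setdiff(drop_nodes, root)
  edge <- tree$edge
  elen <- tree$edge.length %||% rep(NA_real_, nrow(edge))
  for (nd in drop_nodes) {
    e_in <- which(edge[, 2] == nd)
    if (length(e_in) == 0L) next
    parent <- edge[e_in, 1]
    kids <- which(edge[, 1] == nd)
    edge[kids, 1] <- parent
    if (sum_lengths && !is.na(elen[e_in])) {
      elen[kids] <- elen[kids] + elen[e_in]
    }
    edge <- edge[-e_in, , drop = FALSE]
    elen <- elen[-e_in]
  }
  out <- rebuild_phylo(edge, elen, tree$tip.label, sup, ntip, root)
  out
}

# Rebuild a clean phylo (renumbered internal nodes, canonical child order)
# from an edge list that may have unreferenced internal nodes.
rebuild_phylo <- function(edge, elen, tips, sup, ntip, root) {
  children <- function(nd) edge[edge[, 1] == nd, 2]
  # Smallest leaf label under each node, for canonical ordering.
  min_leaf <- function(nd) {
    if (nd <= ntip) return(tips[nd])
    min(vapply(children(nd), min_leaf, character(1)))
  }
  new_newick <- character(0)
  emit <- function(nd, len) {
    lab <- if (nd <= ntip) tips[nd] else {
      s <- sup[nd - ntip]
      if (is.na(s)) "" else format(s, trim = TRUE)
    }
    if (nd <= ntip) {
      node_str <- lab
    } else {
      kids <- children(nd)
      kids <- kids[order(vapply(kids, min_leaf, character(1)))]
      inner <- vapply(seq_along(kids), function(i) {
        e <- which(edge[, 1] == nd & edge[, 2] == kids[i])[1]
        emit(kids[i], elen[e])
      }, character(1))
      node_str <- paste0("(", paste(inner, collapse = ","), ")", lab)
    }
    if (is.na(len)) node_str else paste0(node_str, ":", format(len, trim = TRUE))
  }
  nwk <- paste0(emit(root, NA_real_), ";")
  out <- ape::read.tree(text = nwk)
  attr(out, "newick") <- nwk
  out
}
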