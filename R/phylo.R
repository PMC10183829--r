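# Gene trees for paralog screening and Dollo parsimony loss mapping on the
# species tree.

#' Poisson-corrected pairwise distances from an alignment
#'
#' p-distance over mutually non-gap columns with `d = -ln(1 - p)`;
#' saturated pairs (`p >= 1`, impossible for finite alignments but the
#' clamp also catches `d > max_dist`) are clamped to `max_dist`.
#'
#' @param msa a [grouped_msa()] with >= 2 rows.
#' @param max_dist clamp for saturated pairs (default 5).
#' @return symmetric numeric matrix; `NA` for pairs with zero shared
#'   columns (undefined distance, warned).
#' @export
pairwise_distance <- function(msa, max_dist = 5) {
  stopifnot(inherits(msa, "grouped_msa"), nrow(msa$aln) >= 2L)
  n <- nrow(msa$aln)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  undef <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- msa$aln[i, ]; b <- msa$aln[j, ]
    shared <- a != "-" & b != "-"
    if (!any(shared)) { D[i, j] <- D[j, i] <- NA; undef <- TRUE; next }
    p <- mean(a[shared] != b[shared])
    d <- if (p >= 1) max_dist else min(-log(1 - p), max_dist)
    D[i, j] <- D[j, i] <- d
  }
  if (undef) warning("pairs with zero shared columns: distance undefined",
                     call. = FALSE)
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (via ape) on a symmetric distance matrix with
#' rows pre-sorted lexicographically so ties resolve deterministically;
#' negative branch lengths are clamped to zero. Exact topology recovery on
#' additive matrices. For 3 taxa the closed-form three-point branch lengths
#' are used.
#'
#' @param D symmetric distance matrix with unique dimnames, >= 3 ids.
#' @return unrooted `phylo` object.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 3L, !is.null(rownames(D)))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  if (nrow(D) == 3L) {
    ids <- rownames(D)
    x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f,%s:%f);",
                                        ids[1], x, ids[2], y, ids[3], z))
  } else {
    tr <- ape::nj(as.dist(D))
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Phylogenetic paralog screen
#'
#' Roots the gene tree (midpoint by default, or on a designated outgroup
#' leaf such as the search query) and returns the leaf set of the smallest
#' clade containing every reference id; everything outside it is treated as
#' paralog or contaminant. With a single reference the clade under the
#' reference's parent (its cherry or larger) is returned. Outgroup rooting
#' is preferred when the reference query is in the tree: with paralogs that
#' duplicated near the family root, the midpoint falls inside the paralog
#' clade and splits it across the root.
#'
#' @param gene_tree a `phylo`.
#' @param reference_ids character vector of leaf labels anchoring the
#'   ortholog clade.
#' @param outgroup optional leaf label to root on instead of the midpoint;
#'   the outgroup itself is never part of the returned clade unless listed
#'   in `reference_ids`.
#' @return character vector of retained (ortholog) leaf labels.
#' @export
screen_paralogs <- function(gene_tree, reference_ids, outgroup = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), length(reference_ids) >= 1L)
  if (!all(reference_ids %in% gene_tree$tip.label))
    stop("reference id missing from gene tree", call. = FALSE)
  if (length(setdiff(gene_tree$tip.label, reference_ids)) == 0L)
    return(sort(gene_tree$tip.label))
  tr <- if (!is.null(outgroup)) {
    stopifnot(outgroup %in% gene_tree$tip.label)
    ape::root(gene_tree, outgroup = outgroup, resolve.root = TRUE)
  } else if (ape::is.rooted(gene_tree) && length(gene_tree$tip.label) <= 2L) {
    gene_tree
  } else {
    phangorn::midpoint(gene_tree)
  }
  ntip <- length(tr$tip.label)
  refs <- match(reference_ids, tr$tip.label)
  node <- if (length(refs) == 1L) {
    tr$edge[tr$edge[, 2] == refs, 1]   # parent of the single reference
  } else {
    ape::getMRCA(tr, refs)
  }
  if (is.null(node) || node == ntip + 1L) return(sort(tr$tip.label))
  sub <- ape::extract.clade(tr, node)
  sort(sub$tip.label)
}

#' Map gene losses by Dollo parsimony
#'
#' Single gain fixed at the root (configurable to the MRCA of present
#' taxa); the losses are the maximal subtrees whose leaves are all absent.
#'
#' @param species_tree rooted `phylo`; internal nodes are auto-labelled
#'   `n<k>` when unlabelled.
#' @param presence named 0/1 vector over all leaves; at least one 1.
#' @param gain `"root"` (default) or `"mrca"`.
#' @return object of class `loss_map`: list with `gain_node`,
#'   `loss_branches` (child-node labels), `loss_leaves` (leaf sets below
#'   each loss), `n_losses`.
#' @export
dollo_losses <- function(species_tree, presence, gain = c("root", "mrca")) {
  gain <- match.arg(gain)
  stopifnot(inherits(species_tree, "phylo"))
  tr <- species_tree
  tips <- tr$tip.label
  if (!all(tips %in% names(presence)))
    stop("presence must be defined for every leaf", call. = FALSE)
  pres <- presence[tips]
  if (all(pres == 0)) stop("all-absent: gain placement undefined", call. = FALSE)
  ntip <- length(tips)
  nnode <- tr$Nnode
  if (is.null(tr$node.label) || !length(tr$node.label))
    tr$node.label <- paste0("n", seq_len(nnode))
  node_id <- function(v) ifelse(v <= ntip, tips[v], tr$node.label[v - ntip])

  if (gain == "mrca") {
    pt <- which(pres == 1)
    gain_node <- if (length(pt) == 1L) pt else ape::getMRCA(tr, pt)
    keep_tips <- if (gain_node <= ntip) tips[gain_node] else
      ape::extract.clade(tr, gain_node)$tip.label
  } else {
    gain_node <- ntip + 1L
    keep_tips <- tips
  }

  # postorder all-absent status below the gain node
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  absent <- logical(ntip + nnode)
  po <- rev(.preorder_nodes(tr, gain_node))
  for (v in po) {
    if (v <= ntip) absent[v] <- pres[tips[v]] == 0
    else {
      ch <- kids[[as.character(v)]]
      absent[v] <- all(absent[ch])
    }
  }
  losses <- integer(0)
  for (v in .preorder_nodes(tr, gain_node)) {
    if (v == gain_node) next
    par <- tr$edge[tr$edge[, 2] == v, 1]
    if (absent[v] && !absent[par]) losses <- c(losses, v)
  }
  loss_leaves <- lapply(losses, function(v)
    if (v <= ntip) tips[v] else sort(ape::extract.clade(tr, v)$tip.label))
  structure(list(gain_node = node_id(gain_node),
                 loss_branches = vapply(losses, node_id, character(1)),
                 loss_leaves = loss_leaves,
                 n_losses = length(losses),
                 tree = tr, scope_tips = keep_tips),
            class = "loss_map")
}

#' @export
print.loss_map <- function(x, ...) {
  cat("loss_map: gain at", x$gain_node, "-", x$n_losses, "loss(es):",
      paste(x$loss_branches, collapse = ", "), "\n")
  invisible(x)
}

.preorder_nodes <- function(tr, start) {
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  out <- integer(0)
  stack <- start
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(ch, stack)
  }
  out
}

#' Forward-simulate presence from a loss map
#'
#' Re-applies single-gain-at-root semantics: a leaf is present iff no loss
#' branch lies on its root path. Used to check Dollo consistency.
#'
#' @param species_tree rooted `phylo` (internal labels as in
#'   [dollo_losses()]).
#' @param loss_branches character vector of child-node labels.
#' @return named 0/1 vector over leaves.
#' @export
dollo_presence <- function(species_tree, loss_branches) {
  tr <- species_tree
  ntip <- length(tr$tip.label)
  if (is.null(tr$node.label) || !length(tr$node.label))
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
  labels <- c(tr$tip.label, tr$node.label)
  lost_nodes <- match(loss_branches, labels)
  stopifnot(!anyNA(lost_nodes))
  pres <- setNames(rep(1L, ntip), tr$tip.label)
  for (v in lost_nodes) {
    lv <- if (v <= ntip) tr$tip.label[v] else
      ape::extract.clade(tr, v)$tip.label
    pres[lv] <- 0L
  }
  pres
}
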