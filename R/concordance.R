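#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining on the Q criterion. Ties in Q are
#' broken by the lowest index pair (column-major order) for determinism;
#' negative branch lengths are clamped to zero and the total clamped
#' deficit is recorded in the `"nj_negative_deficit"` attribute.
#'
#' @param dm A `distance_matrix` from [pairwise_matrix()], or a symmetric
#'   numeric matrix with dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  D <- if (inherits(dm, "distance_matrix")) dm$d else dm
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 3L) stop("need at least 3 taxa for neighbor joining")
  if (anyNA(D)) {
    idx <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop("undefined distance(s) for pair(s): ",
         paste(paste(rownames(D)[idx[, 1L]], colnames(D)[idx[, 2L]], sep = ":"),
               collapse = ", "))
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  # working set of subtree newick strings
  sub <- labels
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) {
      deficit <<- deficit - x
      0
    } else x
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (length(sub) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    k <- which.min(Q)  # column-major first minimum = lowest-index tie-break
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    merged <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":", fmt(lj), ")")
    others <- setdiff(seq_len(n), c(i, j))
    newd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D2 <- rbind(cbind(D[others, others, drop = FALSE], newd),
                c(newd, 0))
    sub <- c(sub[others], merged)
    D <- D2
  }
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", sub[1L], ":", fmt(la), ",", sub[2L], ":", fmt(lb), ",",
                sub[3L], ":", fmt(lc), ");")
  tr <- ape::read.tree(text = nwk)
  if (deficit > 0) {
    message("nj_tree: clamped negative branch lengths, total deficit ",
            signif(deficit, 4), " substitutions/site")
  }
  attr(tr, "nj_negative_deficit") <- deficit
  tr
}

# Leaf set below each node (indexed by node id) of a phylo tree.
node_leafsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  # edges in postorder so children are filled before parents
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1L]
    c <- ord[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

# Non-trivial bipartitions of an unrooted tree, canonicalized as the sorted
# side not containing the alphabetically first leaf.
tree_bipartitions <- function(tree) {
  leaves <- sort(tree$tip.label)
  ref <- leaves[1L]
  n <- length(leaves)
  sets <- node_leafsets(tree)
  n_tip <- length(tree$tip.label)
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n_tip) next  # trivial split
    s <- sets[[child]]
    if (length(s) >= n - 1L) next  # trivial on the other side (root edge)
    side <- if (ref %in% s) setdiff(leaves, s) else s
    if (length(side) < 2L || length(side) > n - 2L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Minimum losses under Dollo parsimony
#'
#' Assumes a single gain of the character (a TE family's presence) at the
#' most recent common ancestor of the leaves carrying it, and counts the
#' minimum number of loss events needed to explain the absences below that
#' ancestor. A patchy presence pattern requires many losses under vertical
#' inheritance — the quantity the horizontal-transfer alternative is
#' weighed against.
#'
#' @param tree Rooted `phylo` tree.
#' @param presence Named logical vector over all leaf labels.
#' @return A list with `gains` (always 1) and `losses`.
#' @export
dollo_min_losses <- function(tree, presence) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(presence))) {
    stop("presence vector missing leaf label(s): ",
         paste(setdiff(tree$tip.label, names(presence)), collapse = ", "))
  }
  pres <- presence[tree$tip.label]
  if (!any(pres)) stop("no present leaf; character never gained")
  present_leaves <- tree$tip.label[pres]
  if (length(present_leaves) == 1L) {
    return(list(gains = 1L, losses = 0L))
  }
  n_tip <- length(tree$tip.label)
  mrca <- ape::getMRCA(tree, present_leaves)
  sets <- node_leafsets(tree)
  # all-absent status per node
  all_absent <- vapply(sets, function(s) !any(pres[match(s, tree$tip.label)]),
                       logical(1))
  # nodes within the MRCA clade
  in_clade <- vapply(sets, function(s) all(s %in% sets[[mrca]]), logical(1))
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  losses <- 0L
  for (v in which(in_clade & all_absent)) {
    if (v == mrca) next
    p <- parent[v]
    if (p != 0L && in_clade[p] && !all_absent[p]) losses <- losses + 1L
  }
  list(gains = 1L, losses = losses)
}

#' Per-species monophyly of element copies
#'
#' A species' copies are monophyletic when some edge of the unrooted copy
#' tree splits exactly those copies from all others. Species with a single
#' copy are trivially monophyletic and reported as singletons, excluded
#' from the multi-copy count.
#'
#' @param copy_tree Unrooted `phylo` tree over element copies.
#' @param species_of_copy Named character vector mapping copy labels to
#'   species.
#' @return A list with `per_species` (data.frame: species, n_copies,
#'   singleton, monophyletic), `n_monophyletic` and
#'   `n_species_with_multiple_copies`.
#' @export
copy_monophyly <- function(copy_tree, species_of_copy) {
  stopifnot(inherits(copy_tree, "phylo"))
  missing_lab <- setdiff(copy_tree$tip.label, names(species_of_copy))
  if (length(missing_lab) > 0L) {
    stop("copy label(s) missing from species mapping: ",
         paste(missing_lab, collapse = ", "))
  }
  leaves <- copy_tree$tip.label
  sp <- species_of_copy[leaves]
  species <- sort(unique(sp))
  # every edge split, as leaf sets of the child side (including terminal
  # edges: a 1-copy side matters only for singletons, handled separately)
  sets <- node_leafsets(copy_tree)
  sides <- lapply(seq_len(nrow(copy_tree$edge)),
                  function(e) sort(sets[[copy_tree$edge[e, 2L]]]))
  all_leaves <- sort(leaves)
  side_keys <- unique(c(
    vapply(sides, paste, character(1), collapse = "|"),
    vapply(sides, function(s) paste(setdiff(all_leaves, s), collapse = "|"),
           character(1))
  ))
  res <- data.frame(species = species,
                    n_copies = as.integer(table(sp)[species]),
                    stringsAsFactors = FALSE)
  res$singleton <- res$n_copies == 1L
  res$monophyletic <- vapply(species, function(s) {
    copies <- sort(leaves[sp == s])
    if (length(copies) == 1L) return(TRUE)
    paste(copies, collapse = "|") %in% side_keys
  }, logical(1))
  list(per_species = res,
       n_monophyletic = sum(res$monophyletic & !res$singleton),
       n_species_with_multiple_copies = sum(!res$singleton))
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartition sets of two unrooted
#' trees on the same leaves; `max_rf = 2 * (n - 3)` for binary trees.
#'
#' @param t1,t2 `phylo` trees with identical leaf sets.
#' @return A list with `rf` and `max_rf`.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    diff <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("leaf sets differ: ", paste(diff, collapse = ", "))
  }
  b1 <- tree_bipartitions(ape::unroot(t1))
  b2 <- tree_bipartitions(ape::unroot(t2))
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  list(rf = as.integer(rf), max_rf = 2L * (length(l1) - 3L))
}
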