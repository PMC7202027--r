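## Rooted-tree helpers built on ape's phylo representation.
##
## Branches are identified by their derived (child) side. A terminal branch
## is named by its tip label; an internal branch by the sorted labels of the
## tips it subtends, joined with "+". These identifiers are stable under
## reordering of the tree and are used in all reports.

#' Prepare a tree for analysis
#'
#' Ensures the tree is rooted (rooting at a named outgroup if requested),
#' binary at the root or not, and carries branch lengths when
#' \code{requireLengths} is set.
#'
#' @param tree a \code{phylo} object or path to a Newick file.
#' @param outgroup optional taxon label used to root an unrooted input.
#' @param requireLengths fail unless every branch has a length.
#' @return a rooted \code{phylo} object.
#' @export
prepareTree <- function(tree, outgroup = NULL, requireLengths = FALSE) {
  if (is.character(tree) && length(tree) == 1L && file.exists(tree))
    tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup))
      stop("tree is unrooted; supply an outgroup taxon to root it")
    if (!outgroup %in% tree$tip.label)
      stop("outgroup '", outgroup, "' is not a tip of the tree")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  if (requireLengths &&
      (is.null(tree$edge.length) || anyNA(tree$edge.length)))
    stop("tree must carry branch lengths")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree
}

## Tip labels subtended by each node (index = node number).
.nodeTipSets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]
    child <- ord$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  lapply(sets, sort)
}

## Stable per-node identifiers: tip label, or sorted subtended tips joined
## with "+".
nodeIds <- function(tree) {
  vapply(.nodeTipSets(tree), paste, character(1), collapse = "+")
}

#' Branch identifiers of a rooted tree
#'
#' @param tree a rooted \code{phylo} object.
#' @return character vector along \code{tree$edge} rows: the derived-side
#'   identifier of each branch.
#' @export
branchIds <- function(tree) {
  nodeIds(tree)[tree$edge[, 2]]
}

#' Resolve a branch identifier to an edge index
#'
#' Accepts a tip label, a "tipA+tipB+..." clade identifier (order of tips
#' irrelevant), or a character vector of tip labels defining the clade.
#'
#' @param tree a rooted \code{phylo} object.
#' @param id branch identifier.
#' @return the matching row index of \code{tree$edge}.
#' @export
resolveBranch <- function(tree, id) {
  if (length(id) > 1L || grepl("+", id, fixed = TRUE))
    id <- paste(sort(unique(unlist(strsplit(id, "+", fixed = TRUE)))),
                collapse = "+")
  ids <- branchIds(tree)
  hit <- which(ids == id)
  if (length(hit) != 1L)
    stop("branch '", id, "' not found in tree")
  hit
}

## Is edge index e1 an ancestor of (or equal to) edge e2? Branches are
## nested when one derived clade contains the other.
edgesNested <- function(tree, e1, e2) {
  sets <- .nodeTipSets(tree)
  a <- sets[[tree$edge[e1, 2]]]
  b <- sets[[tree$edge[e2, 2]]]
  all(a %in% b) || all(b %in% a)
}

## All unordered non-nested branch pairs; optionally terminal branches only.
#' Enumerate testable branch pairs
#'
#' All unordered pairs of branches excluding nested (ancestor-descendant)
#' pairs, for which independent derivation is undefined.
#'
#' @param tree a rooted \code{phylo} object.
#' @param terminalOnly restrict to terminal (tip) branches.
#' @return data frame with branch identifier columns \code{branchA},
#'   \code{branchB}.
#' @export
branchPairs <- function(tree, terminalOnly = FALSE) {
  ids <- branchIds(tree)
  keep <- seq_along(ids)
  if (terminalOnly)
    keep <- which(tree$edge[, 2] <= length(tree$tip.label))
  sets <- .nodeTipSets(tree)
  out <- list()
  for (i in seq_along(keep)) {
    for (j in seq_len(i - 1L)) {
      e1 <- keep[i]; e2 <- keep[j]
      a <- sets[[tree$edge[e1, 2]]]
      b <- sets[[tree$edge[e2, 2]]]
      if (all(a %in% b) || all(b %in% a)) next
      out[[length(out) + 1L]] <- c(ids[e2], ids[e1])
    }
  }
  if (!length(out))
    return(data.frame(branchA = character(), branchB = character()))
  m <- do.call(rbind, out)
  data.frame(branchA = m[, 1], branchB = m[, 2], stringsAsFactors = FALSE)
}
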