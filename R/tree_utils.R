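#' Newick input and output
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] so all tree
#' text I/O in the package goes through one door. `parse_newick` accepts a
#' single Newick string; `write_newick` returns one.
#'
#' @param text a Newick string (terminating `;` optional).
#' @return `parse_newick`: an [ape::phylo] object; `write_newick`: a string.
#' @export
parse_newick <- function(text) {
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("Newick syntax error in: ", text)
  tr
}

#' @rdname parse_newick
#' @param tree an [ape::phylo] object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Nontrivial bipartitions of a tree
#'
#' Each internal edge splits the leaf set in two; the split is stored
#' canonically as the sorted side that does not contain the reference leaf
#' (the lexicographically smallest label), so keys are stable under
#' re-rooting.
#'
#' @param tree an [ape::phylo] object.
#' @return a list of character vectors (tip labels of the canonical side);
#'   names are the canonical keys used for set comparisons.
#' @export
bipartitions <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4L) return(structure(list(), names = character(0)))
  ref <- sort(labs)[1]
  sets <- descendant_tip_sets(tree)
  out <- list()
  for (s in sets) {
    if (length(s) < 2L || length(s) > n - 2L) next
    side <- labs[s]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    key <- paste(sort(side), collapse = "\r")
    out[[key]] <- sort(side)
  }
  if (!length(out)) return(structure(list(), names = character(0)))
  out[order(names(out))]
}

split_key <- function(side, all_labels) {
  ref <- sort(all_labels)[1]
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "\r")
}

## Tip-index sets below each internal edge (child side), as a list of integer
## vectors, one per edge with an internal child.
descendant_tip_sets <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  internal_children <- tree$edge[tree$edge[, 2] > n, 2]
  lapply(internal_children, function(v) sort(below[[v]]))
}

#' Strict consensus of a tree set
#'
#' Returns the tree whose internal edges are exactly the bipartitions shared
#' by every member (the 100 percent majority rule). Delegates to
#' [ape::consensus()]; a `p` below 1 gives general majority-rule consensus.
#'
#' @param trees a list of [ape::phylo] objects, a `multiPhylo`, or a
#'   [tree_ensemble()].
#' @param p minimum split frequency, default 1 (strict).
#' @return an [ape::phylo] object, possibly with polytomies.
#' @export
strict_consensus <- function(trees, p = 1) {
  if (inherits(trees, "tree_ensemble")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree set")
  labs <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(labs)) != 1L) stop("trees have mismatched leaf sets")
  if (length(trees) == 1L) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = p, rooted = FALSE)
}

#' Enumerate all unrooted binary topologies
#'
#' Exhaustive enumeration for small leaf sets, used as the testing oracle
#' against which heuristic searches are checked. Yields all
#' `(2n - 5)!!` distinct topologies via [phangorn::allTrees()].
#'
#' @param tip_labels leaf labels (3 to 8 of them).
#' @return a `multiPhylo` of unrooted binary trees.
#' @export
enumerate_trees <- function(tip_labels) {
  if (is.numeric(tip_labels) && length(tip_labels) == 1L) {
    tip_labels <- paste0("t", seq_len(tip_labels))
  }
  n <- length(tip_labels)
  if (n < 3L || n > 8L) stop("enumeration supported for 3 to 8 leaves, got ", n)
  tt <- phangorn::allTrees(n, rooted = FALSE, tip.label = tip_labels)
  ## materialize per-tree tip labels so plain iteration sees complete trees
  out <- lapply(seq_along(tt), function(i) tt[[i]])
  class(out) <- "multiPhylo"
  out
}

#' Set of equally parsimonious trees
#'
#' Container for the result of a parsimony search: the distinct best trees
#' found and their shared length `S`.
#'
#' @param trees list of [ape::phylo] objects over one leaf set.
#' @param length parsimony steps shared by all members.
#' @param cap_hit whether the stored-tree cap was saturated.
#' @param config the [search_config()] used.
#' @return an object of class `tree_ensemble`.
#' @export
tree_ensemble <- function(trees, length, cap_hit = FALSE, config = NULL) {
  structure(list(trees = trees, length = as.integer(length),
                 cap_hit = cap_hit, config = config),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("tree_ensemble:", length(x$trees), "tree(s) of length", x$length,
      if (isTRUE(x$cap_hit)) "(cap saturated)" else "", "\n")
  invisible(x)
}

## Canonical topology key of an unrooted tree: sorted nontrivial split keys.
topology_key <- function(tree) {
  paste(names(bipartitions(tree)), collapse = ";")
}
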