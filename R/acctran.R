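#' ACCTRAN/DELTRAN character optimization
#'
#' Reconstructs a single ancestral state per node and character on a tree
#' rooted at the hypothetical-ancestor leaf, and lists every state change as
#' an event. Ambiguity is resolved by a 0/1-cost dynamic programme traceback:
#' under ACCTRAN ties are broken towards changing state on the current edge
#' (changes placed as close to the root as possible, which favours reversions
#' over convergences); under DELTRAN towards keeping the parent state
#' (changes delayed tipwards). Both modes realize the same minimal number of
#' changes — they differ only in placement. Polytomies (consensus trees) are
#' scored as hard polytomies.
#'
#' @param tree an [ape::phylo] tree containing the `root` leaf; polytomies
#'   allowed.
#' @param cm a [character_matrix()] covering the tree's tips.
#' @param root label of the leaf to root on (the all-zero hypothetical
#'   ancestor).
#' @param mode `"acctran"` (default) or `"deltran"`.
#' @return an object of class `reconstruction`: fields `tree` (rooted phylo),
#'   `root`, `mode`, `node_states` (nodes x characters; `NA` where a
#'   character has no data), `events` (data frame: `character` 1-based,
#'   `parent`, `child` node ids, `from`, `to` state codes, `kind` in
#'   `gain`/`reversion`/`convergence`), `per_char_steps`, and the input
#'   matrix `cm`.
#' @export
acctran_optimize <- function(tree, cm, root = "ANC",
                             mode = c("acctran", "deltran")) {
  mode <- match.arg(mode)
  if (!(root %in% tree$tip.label)) stop("root leaf absent from tree: ", root)
  miss <- setdiff(tree$tip.label, cm$taxa)
  if (length(miss)) stop("tree leaves without matrix rows: ",
                         paste(miss, collapse = ", "))
  ## root on the ancestor leaf's edge
  if (!ape::is.rooted(tree) || !is_outgroup(tree, root)) {
    tree <- ape::root(tree, outgroup = root, resolve.root = TRUE)
  }
  tree <- stats::reorder(tree, "postorder")
  cmt <- subset_taxa(cm, tree$tip.label)
  kids <- edge_children(tree)
  internals <- unique(tree$edge[, 1])
  rootnode <- internals[length(internals)]
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  root_tip <- match(root, tree$tip.label)
  k <- cmt$n_chars
  node_states <- matrix(NA_integer_, nn, k)
  events <- list()
  per_char_steps <- integer(k)
  BIG <- 1e9
  prefer_change <- mode == "acctran"
  for (j in seq_len(k)) {
    obs <- observed_states(cmt, j)
    sj <- cmt$states[, j]
    if (length(obs) == 0L) next
    ns <- length(obs)
    ## leaves take their own state everywhere (ambiguous leaves resolved to
    ## the parent's state, i.e. never charged a change)
    if (length(obs) == 1L) {
      node_states[, j] <- obs
      next
    }
    C <- matrix(0, nn, ns)
    for (i in seq_len(n)) {
      if (!is.na(sj[i])) {
        C[i, ] <- BIG
        C[i, match(sj[i], obs)] <- 0
      }
    }
    for (v in internals) {
      acc <- numeric(ns)
      for (c2 in kids[[v]]) {
        cc <- C[c2, ]
        acc <- acc + pmin(cc, min(cc) + 1)
      }
      C[v, ] <- acc
    }
    ## traceback from the ancestor leaf downwards
    F <- integer(nn)                     # assigned state (index into obs)
    anc_state <- if (is.na(sj[root_tip])) 1L else match(sj[root_tip], obs)
    F[root_tip] <- anc_state
    F[rootnode] <- pick_state(C[rootnode, ], anc_state, prefer_change)
    for (v in rev(internals)) {          # preorder: parents before children
      f <- F[v]
      for (c2 in kids[[v]]) {
        if (c2 == root_tip) next
        if (c2 <= n) {
          F[c2] <- if (is.na(sj[c2])) f else match(sj[c2], obs)
        } else {
          F[c2] <- pick_state(C[c2, ] + as.numeric(seq_len(ns) != f), f,
                              prefer_change)
        }
      }
    }
    node_states[, j] <- obs[F]
    ## events on edges (including the root edge ancestor -> rootnode)
    ep <- c(tree$edge[, 1], root_tip)
    ec <- c(tree$edge[, 2], rootnode)
    chg <- which(F[ep] != F[ec] & ec != root_tip)
    per_char_steps[j] <- length(chg)
    if (length(chg)) {
      events[[length(events) + 1L]] <- data.frame(
        character = j,
        parent = ep[chg], child = ec[chg],
        from = obs[F[ep[chg]]], to = obs[F[ec[chg]]]
      )
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(character = integer(0), parent = integer(0),
               child = integer(0), from = integer(0), to = integer(0))
  ev <- classify_events(ev, tree, kids, rootnode, root_tip, node_states)
  structure(list(tree = tree, root = root, mode = mode,
                 node_states = node_states, events = ev,
                 per_char_steps = per_char_steps, cm = cmt),
            class = "reconstruction")
}

## is `label` already the direct outgroup of a (binary-rooted) tree?
is_outgroup <- function(tree, label) {
  n <- length(tree$tip.label)
  rootnode <- n + 1L
  kids <- tree$edge[tree$edge[, 1] == rootnode, 2]
  match(label, tree$tip.label) %in% kids
}

## argmin with ACCTRAN/DELTRAN tie preference relative to the parent state f
## (costs already include the edge-change term where applicable)
pick_state <- function(costs, f, prefer_change) {
  m <- min(costs)
  cand <- which(costs <= m + 1e-9)
  if (length(cand) == 1L) return(cand)
  if (prefer_change) {
    notf <- cand[cand != f]
    if (length(notf)) notf[1] else f
  } else {
    if (f %in% cand) f else cand[1]
  }
}

## classify each change event: reversion if the target state already occurred
## on the root path above the edge; otherwise gain, or convergence when the
## same (character, state) is gained on more than one edge.
classify_events <- function(ev, tree, kids, rootnode, root_tip, node_states) {
  if (!nrow(ev)) { ev$kind <- character(0); return(ev) }
  n <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  parent_of[rootnode] <- root_tip
  kind <- character(nrow(ev))
  for (r in seq_len(nrow(ev))) {
    j <- ev$character[r]
    ## walk the path strictly above the edge's parent end
    v <- ev$parent[r]
    seen <- integer(0)
    while (v != 0L) {
      seen <- c(seen, node_states[v, j])
      v <- if (v == root_tip) 0L else parent_of[v]
    }
    kind[r] <- if (ev$to[r] %in% seen) "reversion" else "gain"
  }
  gains <- ev[kind == "gain", c("character", "to")]
  if (nrow(gains)) {
    key <- paste(ev$character, ev$to)
    gkey <- paste(gains$character, gains$to)
    multi <- names(which(table(gkey) > 1L))
    kind[kind == "gain" & key %in% multi] <- "convergence"
  }
  ev$kind <- kind
  ev
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("reconstruction (", x$mode, ") rooted at '", x$root, "': ",
      sum(x$per_char_steps), " changes over ", ncol(x$node_states),
      " characters\n", sep = "")
  if (nrow(x$events)) print(table(x$events$kind))
  invisible(x)
}

#' Synapomorphies on a clade's stem edge
#'
#' The character-state changes ACCTRAN places on the edge subtending a clade
#' of the reconstruction's tree: the characters that support the group.
#'
#' @param recon a [acctran_optimize()] reconstruction.
#' @param clade character vector of tip labels forming the clade (the side
#'   away from the root).
#' @return the subset of `recon$events` on the clade's stem edge, with a
#'   `label` column formatted `"Character #k (state)"`.
#' @export
synapomorphies_at <- function(recon, clade) {
  tree <- recon$tree
  v <- clade_node(tree, clade)
  if (is.na(v)) stop("clade is not an edge of the tree")
  ev <- recon$events[recon$events$child == v, , drop = FALSE]
  nm <- if (!is.null(recon$cm$char_labels)) recon$cm$char_labels else
    paste0("c", seq_len(recon$cm$n_chars))
  ev$label <- sprintf("Character #%d (%s: %s)", ev$character,
                      nm[ev$character], recon$cm$symbols[ev$to + 1L])
  ev
}

## node whose descendant tip set equals `clade`; NA if absent
clade_node <- function(tree, clade) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  target <- sort(match(clade, tree$tip.label))
  if (anyNA(target)) return(NA_integer_)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  for (v in tree$edge[, 2]) {
    if (identical(sort(below[[v]]), target)) return(v)
  }
  NA_integer_
}

#' Per-character consistency index on a reconstruction
#'
#' For each character, the minimum conceivable changes `m` (observed states
#' minus one) divided by the steps `s` realized on the tree; 1 marks a
#' homoplasy-free character, values below 1 homoplasy. Characters with no
#' steps on the tree have an undefined ratio and are reported `NA`.
#'
#' @param recon a [acctran_optimize()] reconstruction.
#' @return data frame with `character`, `m`, `s`, `ci`.
#' @export
per_character_ci <- function(recon) {
  cmt <- recon$cm
  k <- cmt$n_chars
  m <- vapply(seq_len(k), function(j) max(n_observed_states(cmt, j) - 1L, 0L), 0L)
  s <- recon$per_char_steps
  data.frame(character = seq_len(k), m = m, s = s,
             ci = ifelse(s > 0L, m / s, NA_real_))
}
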