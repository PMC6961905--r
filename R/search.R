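## Heuristic parsimony search.
##
## Internally trees are stored in a compact rooted representation ("itree"):
## tip nodes 1..ntip are identified with rows of the Fitch encoding, internal
## nodes ntip+1 .. 2*ntip-1 each have exactly two children, and the root is an
## arbitrary internal node (Fitch length is rooting-invariant, so the rooted
## form is only bookkeeping for an unrooted search). Branch-swapping moves are
## generated as small integer descriptors and applied by array surgery.

it_new <- function(ntip) {
  nmax <- 2L * ntip - 1L
  list(ntip = ntip, par = integer(nmax), k1 = integer(nmax),
       k2 = integer(nmax), root = 0L, nint = 0L)
}

## start tree on three tips
it_start3 <- function(ntip, a, b, c) {
  tr <- it_new(ntip)
  r <- ntip + 1L
  m <- ntip + 2L
  tr$nint <- 2L
  tr$root <- r
  tr$k1[r] <- a; tr$k2[r] <- m
  tr$par[a] <- r; tr$par[m] <- r
  tr$k1[m] <- b; tr$k2[m] <- c
  tr$par[b] <- m; tr$par[c] <- m
  tr
}

## insert tip t on the edge above node w, consuming a fresh internal node
it_insert <- function(tr, t, w) {
  tr$nint <- tr$nint + 1L
  m <- tr$ntip + tr$nint
  p <- tr$par[w]
  tr$par[m] <- p
  if (tr$k1[p] == w) tr$k1[p] <- m else tr$k2[p] <- m
  tr$k1[m] <- w; tr$k2[m] <- t
  tr$par[w] <- m; tr$par[t] <- m
  tr
}

## active nodes in postorder (children before parents), from the root
it_postorder <- function(tr) {
  stack <- tr$root
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    if (v > tr$ntip) stack <- c(stack, tr$k1[v], tr$k2[v])
  }
  rev(out)
}

it_active <- function(tr) it_postorder(tr)

## tips (in increasing order) below node v
it_tips_below <- function(tr, v) {
  stack <- v
  out <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (u <= tr$ntip) out <- c(out, u)
    else stack <- c(stack, tr$k1[u], tr$k2[u])
  }
  sort(out)
}

## Fitch length on an itree under a (possibly compressed) encoding.
## State-set matrix is patterns x nodes so each node touches one contiguous
## column; enc$tB is the pre-transposed tip block.
it_fitch <- function(tr, enc, bound = Inf) {
  po <- it_postorder(tr)
  po <- po[po > tr$ntip]
  ntip <- tr$ntip
  S <- matrix(0L, enc$n_pat, 2L * ntip - 1L)
  S[, seq_len(ntip)] <- enc$tB
  total <- 0L
  k1 <- tr$k1; k2 <- tr$k2; w <- enc$w
  for (v in po) {
    a <- S[, k1[v]]; b <- S[, k2[v]]
    i <- bitwAnd(a, b)
    z <- i == 0L
    if (any(z)) {
      total <- total + sum(w[z])
      if (total > bound) return(total)   # already worse than the bound
      i[z] <- bitwOr(a[z], b[z])
    }
    S[, v] <- i
  }
  total
}

## Canonical topology key: the set of nontrivial splits, each written as the
## side not containing tip 1. For up to 52 tips a split side is encoded
## exactly as a sum of powers of two in a double; larger trees fall back to
## sorted index strings.
it_split_masks <- function(tr) {
  po <- it_postorder(tr)
  ntip <- tr$ntip
  nmax <- 2L * ntip - 1L
  mask <- numeric(nmax)
  sz <- integer(nmax)
  pw <- 2^(seq_len(ntip) - 1L)
  act_tips <- it_tips_below(tr, tr$root)
  full <- sum(pw[act_tips])
  nact <- length(act_tips)
  pieces <- numeric(0)
  for (v in po) {
    if (v <= ntip) { mask[v] <- pw[v]; sz[v] <- 1L; next }
    m <- mask[tr$k1[v]] + mask[tr$k2[v]]
    mask[v] <- m
    sz[v] <- sz[tr$k1[v]] + sz[tr$k2[v]]
    ## only nontrivial splits: trivial ones are shared by every topology but
    ## whether they surface here depends on the arbitrary rooting
    if (v != tr$root && sz[v] >= 2L && sz[v] <= nact - 2L) {
      pieces <- c(pieces, if (m %% 2 == 1) full - m else m)
    }
  }
  unique(pieces)
}

it_key <- function(tr) {
  if (tr$ntip <= 52L) {
    return(paste(sort(it_split_masks(tr)), collapse = ","))
  }
  po <- it_postorder(tr)
  ntip <- tr$ntip
  below <- vector("list", 2L * ntip - 1L)
  all_tips <- it_tips_below(tr, tr$root)
  pieces <- character(0)
  for (v in po) {
    if (v <= ntip) { below[[v]] <- v; next }
    s <- sort(c(below[[tr$k1[v]]], below[[tr$k2[v]]]))
    below[[v]] <- s
    if (v != tr$root) {
      side <- if (1L %in% s) setdiff(all_tips, s) else s
      if (length(side) >= 2L && length(side) <= length(all_tips) - 2L) {
        pieces <- c(pieces, paste(side, collapse = ","))
      }
    }
  }
  paste(sort(unique(pieces)), collapse = ";")
}

## split membership: does the tree display the split given by tip-index side?
it_has_split <- function(tr, side) {
  if (tr$ntip <= 52L) {
    pw <- 2^(seq_len(tr$ntip) - 1L)
    full <- sum(pw[it_tips_below(tr, tr$root)])
    m <- sum(pw[side])
    if (m %% 2 == 1) m <- full - m
    return(m %in% it_split_masks(tr))
  }
  all_tips <- it_tips_below(tr, tr$root)
  canon <- function(s) {
    if (1L %in% s) s <- setdiff(all_tips, s)
    paste(sort(s), collapse = ",")
  }
  target <- canon(side)
  pieces <- strsplit(it_key(tr), ";", fixed = TRUE)[[1]]
  target %in% pieces
}

## ---- moves -----------------------------------------------------------------

## Move descriptors, rows of an integer matrix:
##   type 1: NNI      (v, variant in 1:2, 0)
##   type 2: SPR/TBR  (v = pruned subtree root, w = target edge's child node,
##                     x = re-rooting edge inside the pruned subtree, 0 = keep)
it_moves <- function(tr, swap = c("SPR", "TBR", "NNI")) {
  swap <- match.arg(swap)
  act <- it_active(tr)
  root <- tr$root
  if (swap == "NNI") {
    vs <- act[act > tr$ntip & act != root]
    rows <- list()
    for (v in vs) rows[[length(rows) + 1L]] <- rbind(c(1L, v, 1L, 0L),
                                                     c(1L, v, 2L, 0L))
    return(do.call(rbind, c(list(matrix(integer(0), 0, 4)), rows)))
  }
  rows <- list()
  for (v in act) {
    if (v == root) next
    p <- tr$par[v]
    if (p == root) {
      s <- if (tr$k1[root] == v) tr$k2[root] else tr$k1[root]
      if (s <= tr$ntip) next            # nothing to regraft onto
      inside <- it_tips_below_nodes(tr, v)
      t2 <- setdiff(act, c(inside, root, s))
    } else {
      inside <- it_tips_below_nodes(tr, v)
      t2 <- setdiff(act, c(inside, root, p))  # p is spliced out by the move
    }
    xs <- 0L
    if (swap == "TBR" && v > tr$ntip) {
      ## re-rooting at a direct child of v reproduces the original rooting
      xs <- c(0L, setdiff(inside, c(v, tr$k1[v], tr$k2[v])))
    }
    for (w in t2) for (x in xs) {
      rows[[length(rows) + 1L]] <- c(2L, v, w, x)
    }
  }
  out <- do.call(rbind, c(list(matrix(integer(0), 0, 4)), rows))
  out
}

## all nodes (tips and internals) in the subtree rooted at v
it_tips_below_nodes <- function(tr, v) {
  stack <- v
  out <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, u)
    if (u > tr$ntip) stack <- c(stack, tr$k1[u], tr$k2[u])
  }
  out
}

it_apply <- function(tr, mv) {
  if (mv[1] == 1L) it_apply_nni(tr, mv[2], mv[3]) else
    it_apply_spr(tr, mv[2], mv[3], mv[4])
}

it_apply_nni <- function(tr, v, variant) {
  p <- tr$par[v]
  root <- tr$root
  if (p != root) {
    s <- if (tr$k1[p] == v) tr$k2[p] else tr$k1[p]
    a <- if (variant == 1L) tr$k1[v] else tr$k2[v]
    ## swap s and a
    if (tr$k1[p] == s) tr$k1[p] <- a else tr$k2[p] <- a
    if (tr$k1[v] == a) tr$k1[v] <- s else tr$k2[v] <- s
    tr$par[a] <- p; tr$par[s] <- v
  } else {
    s <- if (tr$k1[root] == v) tr$k2[root] else tr$k1[root]
    if (s <= tr$ntip) return(tr)        # leaf sibling: no unrooted NNI here
    a <- tr$k1[v]
    b <- if (variant == 1L) tr$k1[s] else tr$k2[s]
    if (tr$k1[v] == a) tr$k1[v] <- b else tr$k2[v] <- b
    if (tr$k1[s] == b) tr$k1[s] <- a else tr$k2[s] <- a
    tr$par[a] <- s; tr$par[b] <- v
  }
  tr
}

## SPR: prune subtree at v, optionally re-root it at the edge above x (TBR),
## regraft on the edge above w. The spliced-out connector node is reused.
it_apply_spr <- function(tr, v, w, x) {
  p <- tr$par[v]
  root <- tr$root
  if (p == root) {
    s <- if (tr$k1[root] == v) tr$k2[root] else tr$k1[root]
    tr$par[s] <- 0L
    tr$root <- s
    f <- p                               # old root becomes the connector
  } else {
    g <- tr$par[p]
    s <- if (tr$k1[p] == v) tr$k2[p] else tr$k1[p]
    tr$par[s] <- g
    if (tr$k1[g] == p) tr$k1[g] <- s else tr$k2[g] <- s
    f <- p
  }
  rv <- v
  if (x != 0L) {
    res <- it_reroot_subtree(tr, v, x)
    tr <- res$tr
    rv <- res$new_root
  }
  ## regraft: connector f subdivides the edge above w
  q <- tr$par[w]
  tr$par[f] <- q
  if (tr$k1[q] == w) tr$k1[q] <- f else tr$k2[q] <- f
  tr$k1[f] <- w; tr$k2[f] <- rv
  tr$par[w] <- f; tr$par[rv] <- f
  tr
}

## Re-root the detached subtree currently rooted at v (par[v] meaningless) so
## that its root lies on the edge above x; the old root v is reused as the new
## root node. Returns the modified tree and the new subtree root id.
it_reroot_subtree <- function(tr, v, x) {
  a <- tr$k1[v]; b <- tr$k2[v]
  ## path from x up to v
  path <- x
  u <- tr$par[x]
  while (u != v) { path <- c(path, u); u <- tr$par[u] }
  top <- path[length(path)]              # child of v on x's side
  other <- if (top == a) b else a
  ## reverse parent/child links along path (excluding x itself's subtree)
  if (length(path) >= 2L) {
    for (i in seq(length(path), 2L)) {
      y <- path[i]; cdown <- path[i - 1L]
      up <- if (i == length(path)) other else path[i + 1L]
      if (tr$k1[y] == cdown) tr$k1[y] <- up else tr$k2[y] <- up
      tr$par[up] <- y
    }
  } else {
    ## x is a direct child of v: splice is a no-op (same rooting)
    return(list(tr = tr, new_root = v))
  }
  p_x <- path[2L]                        # old parent of x, now below new root
  tr$k1[v] <- x; tr$k2[v] <- p_x
  tr$par[x] <- v; tr$par[p_x] <- v
  list(tr = tr, new_root = v)
}

## ---- conversions -----------------------------------------------------------

it_to_phylo <- function(tr, labels) {
  nw <- it_newick(tr, tr$root, safe_label(labels))
  ape::read.tree(text = paste0(nw, ";"))
}

it_newick <- function(tr, v, labels) {
  if (v <= tr$ntip) return(labels[v])
  paste0("(", it_newick(tr, tr$k1[v], labels), ",",
         it_newick(tr, tr$k2[v], labels), ")")
}

## phylo -> itree; tips mapped by label onto positions in `labels`. The phylo
## may be rooted-binary or have a basal trifurcation (unrooted form).
it_from_phylo <- function(phy, labels) {
  ntip <- length(labels)
  if (length(phy$tip.label) != ntip) stop("leaf count mismatch")
  phy <- stats::reorder(phy, "postorder")
  kids <- edge_children(phy)
  internals <- unique(phy$edge[, 1])
  root_ph <- internals[length(internals)]
  deg <- lengths(kids[internals])
  if (any(deg[-length(deg)] != 2L) || deg[length(deg)] > 3L) {
    stop("search trees must be binary")
  }
  tr <- it_new(ntip)
  tipmap <- match(phy$tip.label, labels)
  if (anyNA(tipmap)) stop("unknown tip labels")
  counter <- new.env()
  counter$nint <- 0L
  build <- function(node) {
    if (node <= length(phy$tip.label)) return(tipmap[node])
    counter$nint <- counter$nint + 1L
    id <- ntip + counter$nint
    ch <- kids[[node]]
    if (length(ch) == 2L) {
      c1 <- build(ch[1]); c2 <- build(ch[2])
      tr$k1[id] <<- c1; tr$k2[id] <<- c2
      tr$par[c1] <<- id; tr$par[c2] <<- id
    } else {                             # basal trifurcation: nest last two
      counter$nint <- counter$nint + 1L
      id2 <- ntip + counter$nint
      c1 <- build(ch[1]); c2 <- build(ch[2]); c3 <- build(ch[3])
      tr$k1[id2] <<- c2; tr$k2[id2] <<- c3
      tr$par[c2] <<- id2; tr$par[c3] <<- id2
      tr$k1[id] <<- c1; tr$k2[id] <<- id2
      tr$par[c1] <<- id; tr$par[id2] <<- id
    }
    id
  }
  ## build children of root so ids stay within bounds
  rt <- build(root_ph)
  tr$root <- rt
  tr$par[rt] <- 0L
  tr$nint <- counter$nint
  tr
}

## ---- configuration and public search API -----------------------------------

#' Search configuration
#'
#' Settings of the heuristic parsimony search: number of random-addition
#' replicates, branch-swapping neighbourhood (NNI, SPR, or TBR — TBR is SPR
#' plus re-rooting of the pruned subtree), the cap on stored equally best
#' trees, the random seed, and whether swapping is steepest-descent (default
#' is first improvement).
#'
#' @param n_replicates random addition sequences (>= 1).
#' @param swap one of `"NNI"`, `"SPR"`, `"TBR"`.
#' @param max_trees cap on stored equally parsimonious trees.
#' @param seed integer random seed; every stochastic choice in the search
#'   derives from it.
#' @param steepest if `TRUE`, scan the full neighbourhood and take the best
#'   move; otherwise accept the first improving move.
#' @return an object of class `search_config`.
#' @export
search_config <- function(n_replicates = 10, swap = "TBR", max_trees = 5000,
                          seed = 1, steepest = FALSE) {
  swap <- match.arg(toupper(swap), c("NNI", "SPR", "TBR"))
  stopifnot(n_replicates >= 1, max_trees >= 1)
  structure(list(n_replicates = as.integer(n_replicates), swap = swap,
                 max_trees = as.integer(max_trees), seed = as.integer(seed),
                 steepest = isTRUE(steepest)),
            class = "search_config")
}

#' Stepwise random-addition starting tree
#'
#' Builds a tree by adding taxa one at a time in the given order, each on the
#' insertion edge minimising the Fitch length of the partial tree. Ties are
#' broken by a seeded random permutation of the candidate edges, so a fixed
#' seed gives a reproducible tree.
#'
#' @param cm a [character_matrix()] with at least 3 taxa.
#' @param order taxon labels in addition order (default: a seeded shuffle).
#' @param seed seed used when `order` is `NULL` and for tie-breaking.
#' @return an [ape::phylo] tree on all taxa of `cm`.
#' @export
random_addition_tree <- function(cm, order = NULL, seed = 1) {
  if (cm$n_taxa < 3L) stop("need at least 3 taxa")
  set.seed(seed)
  ord <- if (is.null(order)) sample(cm$n_taxa) else match(order, cm$taxa)
  if (anyNA(ord) || length(ord) != cm$n_taxa) stop("order must permute cm$taxa")
  enc <- fitch_compress(fitch_encode(cm))
  tr <- it_addition(ord, enc, cm$n_taxa)
  it_to_phylo(tr, cm$taxa)
}

it_addition <- function(ord, enc, ntip) {
  tr <- it_start3(ntip, ord[1], ord[2], ord[3])
  if (length(ord) > 3L) {
    for (t in ord[-(1:3)]) {
      act <- it_active(tr)
      cand <- act[act != tr$root]
      cand <- cand[sample.int(length(cand))]
      best <- NULL; best_len <- Inf
      for (w in cand) {
        t1 <- it_insert(tr, t, w)
        len <- it_fitch(t1, enc, bound = best_len)
        if (len < best_len) { best_len <- len; best <- t1 }
      }
      tr <- best
    }
  }
  tr
}

#' Branch swapping from a starting tree
#'
#' Hill-climbs over the chosen neighbourhood (NNI, SPR or TBR) until no
#' neighbour is shorter, collecting all distinct equally shortest trees
#' encountered (up to `max_trees`). Neighbour order is a seeded permutation,
#' making the run reproducible.
#'
#' @param start an [ape::phylo] binary tree on `cm$taxa`.
#' @param cm a [character_matrix()].
#' @param config a [search_config()].
#' @param forbid_split optional character vector of tip labels: trees
#'   displaying this bipartition are rejected (reverse-constraint search, used
#'   for Bremer support).
#' @return a [tree_ensemble()].
#' @export
branch_swap_search <- function(start, cm, config = search_config(),
                               forbid_split = NULL) {
  set.seed(config$seed)
  enc <- fitch_compress(fitch_encode(cm))
  tr <- it_from_phylo(start, cm$taxa)
  forbid <- if (is.null(forbid_split)) NULL else match(forbid_split, cm$taxa)
  if (!is.null(forbid) && anyNA(forbid)) stop("forbid_split labels not in matrix")
  res <- it_swap(tr, enc, config, forbid)
  tree_ensemble(lapply(res$trees, it_to_phylo, labels = cm$taxa),
                res$length, cap_hit = res$cap_hit, config = config)
}

## core hill-climb; returns list(trees = list of itree, length, cap_hit)
it_swap <- function(tr, enc, config, forbid = NULL) {
  ok <- function(t) is.null(forbid) || !it_has_split(t, forbid)
  if (!ok(tr)) stop("starting tree displays the forbidden split")
  best_len <- it_fitch(tr, enc)
  best <- list(tr)
  keys <- it_key(tr)
  cap_hit <- FALSE
  done <- 0L                             # members already fully swapped
  repeat {
    improved <- FALSE
    while (done < length(best)) {
      t0 <- best[[done + 1L]]
      mv <- it_moves(t0, config$swap)
      if (nrow(mv)) mv <- mv[sample.int(nrow(mv)), , drop = FALSE]
      best_mv_len <- Inf; best_mv_tree <- NULL
      for (r in seq_len(nrow(mv))) {
        t1 <- it_apply(t0, mv[r, ])
        if (!ok(t1)) next
        len <- it_fitch(t1, enc, bound = best_len)
        if (len < best_len) {
          if (config$steepest) {
            if (len < best_mv_len) { best_mv_len <- len; best_mv_tree <- t1 }
          } else {
            best <- list(t1); keys <- it_key(t1); best_len <- len
            done <- 0L; improved <- TRUE
            break
          }
        } else if (len == best_len && length(best) < config$max_trees) {
          k <- it_key(t1)
          if (!(k %in% keys)) { best <- c(best, list(t1)); keys <- c(keys, k) }
        } else if (len == best_len && length(best) >= config$max_trees) {
          cap_hit <- TRUE
        }
      }
      if (improved) break
      if (config$steepest && !is.null(best_mv_tree)) {
        best <- list(best_mv_tree); keys <- it_key(best_mv_tree)
        best_len <- best_mv_len; done <- 0L; improved <- TRUE
        break
      }
      done <- done + 1L
    }
    if (!improved) break
  }
  list(trees = best, length = best_len, cap_hit = cap_hit)
}

#' Heuristic maximum-parsimony search
#'
#' The full search protocol: `n_replicates` independent seeded rounds of
#' stepwise random addition followed by branch swapping, pooling the distinct
#' best trees across rounds. Equality of the returned length with the global
#' optimum is not guaranteed (it is a heuristic), but on small matrices it is
#' routinely exact — the test suite checks it against exhaustive enumeration.
#'
#' @param cm a [character_matrix()] with at least 4 taxa.
#' @param config a [search_config()].
#' @return a [tree_ensemble()] of the distinct best trees found.
#' @export
heuristic_search <- function(cm, config = search_config()) {
  if (cm$n_taxa < 4L) stop("need at least 4 taxa")
  enc <- fitch_compress(fitch_encode(cm))
  best_len <- Inf
  pool <- list(); keys <- character(0)
  cap_hit <- FALSE
  for (rep in seq_len(config$n_replicates)) {
    rep_seed <- config$seed + 7919L * (rep - 1L)
    set.seed(rep_seed)
    ord <- sample(cm$n_taxa)
    tr0 <- it_addition(ord, enc, cm$n_taxa)
    res <- it_swap(tr0, enc, config)
    if (res$length < best_len) {
      best_len <- res$length
      pool <- list(); keys <- character(0)
      cap_hit <- FALSE
    }
    if (res$length == best_len) {
      cap_hit <- cap_hit || res$cap_hit
      for (t in res$trees) {
        k <- it_key(t)
        if (!(k %in% keys)) {
          if (length(pool) < config$max_trees) {
            pool <- c(pool, list(t)); keys <- c(keys, k)
          } else cap_hit <- TRUE
        }
      }
    }
  }
  tree_ensemble(lapply(pool, it_to_phylo, labels = cm$taxa),
                best_len, cap_hit = cap_hit, config = config)
}
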