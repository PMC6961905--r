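## Fitch/Sankoff parsimony scoring.
##
## Characters are unordered and unweighted. Missing and inapplicable cells
## are scored as fully ambiguous (any observed state of that character), the
## PAUP* default. State sets are bit masks, so the shared symbol alphabet is
## limited to 31 states -- far above anything a coded-idea matrix uses.

## Bitmask encoding of a character_matrix, rows aligned with cm$taxa.
## full[j] = union of observed state bits (the set an ambiguous cell takes).
fitch_encode <- function(cm) {
  n <- cm$n_taxa; k <- cm$n_chars
  B <- matrix(0L, n, k)
  full <- integer(k)
  for (j in seq_len(k)) {
    sj <- cm$states[, j]
    obs <- unique(sj[!is.na(sj)])
    fj <- if (length(obs)) Reduce(bitwOr, bitwShiftL(1L, obs)) else 1L
    col <- ifelse(is.na(sj), fj, bitwShiftL(1L, ifelse(is.na(sj), 0L, sj)))
    B[, j] <- col
    full[j] <- fj
  }
  list(B = B, full = full, w = rep(1L, k), taxa = cm$taxa, n_pat = k)
}

## Collapse duplicate (column, full-mask) patterns into weighted patterns.
## Scores are unchanged; searches get a roughly constant-factor speedup.
fitch_compress <- function(enc) {
  key <- apply(rbind(enc$B, enc$full), 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.integer(table(factor(key, levels = key[first])))
  B <- enc$B[, first, drop = FALSE]
  list(B = B, tB = t(B), full = enc$full[first],
       w = w, taxa = enc$taxa, n_pat = sum(first))
}

#' Fitch parsimony length of a tree
#'
#' Number of character-state changes the tree requires for the matrix under
#' unordered parsimony. Binary trees are scored with the Fitch set algorithm;
#' trees with polytomies (e.g. strict consensus trees) are scored as hard
#' polytomies with the exact 0/1-cost dynamic programme. Missing and
#' inapplicable leaves contribute the full observed state set; characters
#' with data on at most one leaf contribute 0 steps. The length does not
#' depend on rooting or leaf order.
#'
#' @param tree an [ape::phylo] object whose tips are a subset of `cm$taxa`.
#' @param cm a [character_matrix()].
#' @param per_character return the per-character step vector instead of the
#'   total.
#' @return integer total steps, or an integer vector per character.
#' @export
fitch_length <- function(tree, cm, per_character = FALSE) {
  miss <- setdiff(tree$tip.label, cm$taxa)
  if (length(miss)) stop("tree leaves without matrix rows: ",
                         paste(miss, collapse = ", "))
  cmt <- subset_taxa(cm, tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  kids <- edge_children(tree)
  internals <- unique(tree$edge[, 1])
  root <- internals[length(internals)]
  deg <- lengths(kids[internals])
  ## an unrooted binary tree carries its basal trifurcation at the root node;
  ## combining its children sequentially is exact there (it amounts to rooting
  ## on the last child's edge), so only true polytomies need the DP
  binary <- all(deg[-length(deg)] == 2L) && deg[length(deg)] <= 3L
  steps <- if (binary) fitch_steps_phylo(tree, kids, fitch_encode(cmt))
           else sankoff_steps_phylo(tree, kids, cmt)
  if (per_character) steps else sum(steps)
}

## children lists indexed by node id (NULL for tips)
edge_children <- function(tree) {
  nn <- max(tree$edge)
  kids <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[k, 2])
  }
  kids
}

## Fitch downpass on a (rooted or unrooted) binary phylo; per-pattern steps.
fitch_steps_phylo <- function(tree, kids, enc) {
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  S <- matrix(0L, nn, enc$n_pat)
  S[seq_len(n), ] <- enc$B
  steps <- integer(enc$n_pat)
  internals <- unique(tree$edge[, 1])  # postorder: children first
  for (v in internals) {
    ch <- kids[[v]]
    a <- S[ch[1], ]
    for (c2 in ch[-1]) {
      b <- S[c2, ]
      i <- bitwAnd(a, b)
      z <- i == 0L
      if (any(z)) {
        steps[z] <- steps[z] + 1L
        u <- bitwOr(a, b)
        i[z] <- u[z]
      }
      a <- i
    }
    S[v, ] <- a
  }
  steps * enc$w
}

## Exact minimum steps per character on an arbitrary (multifurcating) tree:
## Sankoff dynamic programme with unit substitution costs.
sankoff_steps_phylo <- function(tree, kids, cmt) {
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  internals <- unique(tree$edge[, 1])
  root <- internals[length(internals)]
  k <- cmt$n_chars
  steps <- integer(k)
  BIG <- 1e9
  for (j in seq_len(k)) {
    obs <- observed_states(cmt, j)
    if (length(obs) <= 1L) next
    ns <- length(obs)
    C <- matrix(0, nn, ns)
    sj <- cmt$states[, j]
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
        m <- min(cc)
        acc <- acc + pmin(cc, m + 1)
      }
      C[v, ] <- acc
    }
    steps[j] <- as.integer(round(min(C[root, ])))
  }
  steps
}

#' Convert a character matrix to a phangorn phyDat object
#'
#' Interoperability bridge: missing and inapplicable cells become the fully
#' ambiguous symbol `?`. Used by the test suite to cross-check scores against
#' phangorn's independent Fitch implementation.
#'
#' @param cm a [character_matrix()].
#' @return a [phangorn::phyDat] object of type `"USER"`.
#' @export
cm_to_phyDat <- function(cm) {
  ch <- matrix(cm$symbols[cm$states + 1L], cm$n_taxa, cm$n_chars)
  ch[is.na(cm$states)] <- "?"
  rownames(ch) <- cm$taxa
  lev <- cm$symbols[seq_len(observed_codes_max(cm) + 1L)]
  phangorn::phyDat(ch, type = "USER", levels = lev, ambiguity = "?")
}
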