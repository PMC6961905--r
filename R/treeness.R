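#' Minimum conceivable steps M
#'
#' Sum over characters of (number of distinct observed states - 1): the
#' length every tree must pay at least (the sum of character amplitudes).
#' Constant and empty characters contribute 0.
#'
#' @param cm a [character_matrix()].
#' @return integer.
#' @export
min_steps <- function(cm) {
  sum(vapply(seq_len(cm$n_chars),
             function(j) max(n_observed_states(cm, j) - 1L, 0L), 0L))
}

#' Maximum steps G (star tree)
#'
#' The matrix length on a completely unresolved tree: for each character,
#' the number of taxa with data minus the frequency of its most common
#' state. This is the Fitch length of the star topology.
#'
#' @param cm a [character_matrix()].
#' @return integer.
#' @export
max_steps_star <- function(cm) {
  sum(vapply(seq_len(cm$n_chars), function(j) {
    tab <- table(cm$states[, j])
    if (length(tab) <= 1L) 0L else as.integer(sum(tab) - max(tab))
  }, 0L))
}

#' Consistency and retention indices
#'
#' `CI = M/S` and `RI = (G - S)/(G - M)`: the classic homoplasy measures.
#' CI decreases with homoplasy but is inflated by autapomorphies; RI is the
#' fraction of possible synapomorphy retained by the tree (1 = homoplasy
#' free, 0 = no better than a star tree). Undefined cases (S = 0 for CI,
#' G = M for RI) return `NA` with a warning rather than a silent 0.
#'
#' @param M minimum steps, from [min_steps()].
#' @param S realized steps on the tree.
#' @param G star-tree steps, from [max_steps_star()].
#' @return numeric scalar.
#' @export
consistency_index <- function(M, S) {
  if (S < M) stop("S < M is impossible: S = ", S, ", M = ", M)
  if (S == 0) { warning("CI undefined: S = 0"); return(NA_real_) }
  M / S
}

#' @rdname consistency_index
#' @export
retention_index <- function(G, S, M) {
  if (S < M) stop("S < M is impossible")
  if (G == M) { warning("RI undefined: G = M"); return(NA_real_) }
  (G - S) / (G - M)
}

#' Homoplasy excess ratio
#'
#' The RI-like randomization statistic: each replicate permutes every
#' character column independently across taxa (preserving each character's
#' exact state multiset, missing cells shuffled with the rest), runs a
#' reduced heuristic search on the permuted matrix and records its best
#' length. With `A` the mean permuted length, `HER = (A - S)/(A - M)`:
#' 1 when the original matrix is perfectly hierarchical, about 0 when it is
#' no more structured than its own permutations.
#'
#' @param cm the (unpermuted) [character_matrix()], including the
#'   hypothetical ancestor if the main search used one, so `S` and `A` are
#'   comparable.
#' @param S best length found on `cm` by a completed search.
#' @param n_reps permutation replicates (>= 2).
#' @param search a [search_config()] for the per-replicate searches;
#'   the default is deliberately light (2 additions, SPR).
#' @param seed integer seed driving the permutations and replicate searches.
#' @return list with `her`, `A`, `lengths` (per replicate), `M`, `S`,
#'   `n_reps`, `seed`.
#' @export
homoplasy_excess_ratio <- function(cm, S, n_reps = 20,
                                   search = search_config(n_replicates = 2,
                                                          swap = "SPR",
                                                          max_trees = 1),
                                   seed = 1) {
  if (n_reps < 2) stop("need at least 2 permutation replicates")
  M <- min_steps(cm)
  lengths <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + 1000L * r)
    st <- cm$states
    for (j in seq_len(cm$n_chars)) st[, j] <- st[sample.int(cm$n_taxa), j]
    cmp <- character_matrix(st, taxa = cm$taxa, char_labels = cm$char_labels,
                            symbols = cm$symbols)
    cfg <- search
    cfg$seed <- seed + 1000L * r + 1L
    lengths[r] <- heuristic_search(cmp, cfg)$length
  }
  A <- mean(lengths)
  her <- if (A == M) { warning("HER undefined: A = M"); NA_real_ }
         else (A - S) / (A - M)
  list(her = her, A = A, lengths = lengths, M = M, S = S,
       n_reps = n_reps, seed = seed)
}

#' Pairwise mismatch distances
#'
#' Uncorrected mismatch proportion between taxa: the fraction of characters
#' that differ among those where both taxa have data (pairwise deletion of
#' missing/inapplicable cells). Intended for binary-recoded matrices, the
#' convention split-network software applies. Pairs with no comparable
#' characters get `NA` and are reported in the `no_overlap` attribute.
#'
#' @param cm a [character_matrix()] (run [recode_binary()] first for the
#'   split-network convention).
#' @return symmetric numeric matrix with zero diagonal; attribute
#'   `no_overlap` lists taxon pairs without comparable characters.
#' @export
hamming_distance_matrix <- function(cm) {
  n <- cm$n_taxa
  X <- cm$states
  D <- matrix(0, n, n, dimnames = list(cm$taxa, cm$taxa))
  bad <- character(0)
  for (i in seq_len(n - 1L)) {
    xi <- X[i, ]
    for (j in (i + 1L):n) {
      comp <- !is.na(xi) & !is.na(X[j, ])
      nc <- sum(comp)
      if (nc == 0L) {
        D[i, j] <- D[j, i] <- NA_real_
        bad <- c(bad, paste(cm$taxa[i], cm$taxa[j], sep = " / "))
      } else {
        d <- sum(xi[comp] != X[j, comp]) / nc
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  attr(D, "no_overlap") <- bad
  D
}

#' Quartet delta-score
#'
#' Treeness of a distance matrix via the four-point condition. For each
#' quartet the three pairwise-sum combinations are sorted `s1 <= s2 <= s3`
#' and the quartet's score is `(s3 - s2)/(s3 - s1)` (0 when `s3 = s1`,
#' the degenerate quartet). The delta-score is the mean over all `C(n,4)`
#' quartets (`mode = "exact"`) or over a seeded uniform sample
#' (`mode = "sampled"`). Additive (tree-realizable) distances give 0; a
#' "box" metric gives 1.
#'
#' @param d symmetric distance matrix (e.g. [hamming_distance_matrix()]).
#' @param mode `"exact"` or `"sampled"`.
#' @param sample_size quartets to draw in sampled mode.
#' @param seed seed for sampled mode.
#' @param chunk quartets evaluated per vectorized block in exact mode.
#' @return list with `delta`, `per_taxon` (mean score of quartets containing
#'   each taxon), `mode`, `quartets_used`, `seed`.
#' @export
delta_score <- function(d, mode = c("exact", "sampled"),
                        sample_size = 1e5, seed = 1, chunk = 2e5) {
  mode <- match.arg(mode)
  n <- nrow(d)
  if (n < 4L) stop("delta-score needs at least 4 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  per_num <- numeric(n); per_den <- numeric(n)
  tot <- 0; used <- 0
  eval_block <- function(q) {
    ## q: 4 x m matrix of taxon indices
    i <- q[1, ]; j <- q[2, ]; k <- q[3, ]; l <- q[4, ]
    s1 <- d[cbind(i, j)] + d[cbind(k, l)]
    s2 <- d[cbind(i, k)] + d[cbind(j, l)]
    s3 <- d[cbind(i, l)] + d[cbind(j, k)]
    hi <- pmax(s1, s2, s3); lo <- pmin(s1, s2, s3)
    mid <- s1 + s2 + s3 - hi - lo
    dq <- ifelse(hi - lo > 0, (hi - mid) / (hi - lo), 0)
    keep <- !is.na(dq)
    for (col in 1:4) {
      idx <- q[col, keep]
      agg <- tapply(dq[keep], idx, sum)
      ids <- as.integer(names(agg))
      per_num[ids] <<- per_num[ids] + as.numeric(agg)
      cnt <- tapply(rep(1, sum(keep)), idx, sum)
      per_den[ids] <<- per_den[ids] + as.numeric(cnt)
    }
    tot <<- tot + sum(dq[keep])
    used <<- used + sum(keep)
  }
  if (mode == "exact") {
    q <- utils::combn(n, 4)
    nb <- ncol(q)
    starts <- seq(1L, nb, by = as.integer(chunk))
    for (s in starts) {
      e <- min(s + chunk - 1L, nb)
      eval_block(q[, s:e, drop = FALSE])
    }
  } else {
    set.seed(seed)
    m <- as.integer(sample_size)
    drawn <- 0L
    while (drawn < m) {
      b <- min(10000L, m - drawn)
      qq <- vapply(seq_len(b), function(...) sample.int(n, 4L), integer(4))
      eval_block(qq)
      drawn <- drawn + b
    }
  }
  list(delta = tot / used,
       per_taxon = stats::setNames(per_num / pmax(per_den, 1), labs),
       mode = mode, quartets_used = used, seed = seed)
}

#' Assemble a treeness report
#'
#' Bundles the treeness statistics of one analysis: the parsimony length
#' `S`, the analytic bounds `M` and `G`, CI and RI, the permutation-based
#' HER (with its replicate lengths), and the quartet delta-score on the
#' binary-recoded distance matrix.
#'
#' @param cm the searched [character_matrix()] (ancestor included if used).
#' @param S best length from the search.
#' @param her result of [homoplasy_excess_ratio()], or `NULL` to skip.
#' @param delta result of [delta_score()], or `NULL` to skip.
#' @return object of class `treeness_report`.
#' @export
treeness_report <- function(cm, S, her = NULL, delta = NULL) {
  M <- min_steps(cm)
  G <- max_steps_star(cm)
  structure(list(
    S = S, M = M, G = G,
    CI = consistency_index(M, S),
    RI = retention_index(G, S, M),
    A = if (!is.null(her)) her$A else NA_real_,
    HER = if (!is.null(her)) her$her else NA_real_,
    her_replicates = if (!is.null(her)) her$n_reps else 0L,
    her_lengths = if (!is.null(her)) her$lengths else integer(0),
    delta = if (!is.null(delta)) delta$delta else NA_real_,
    delta_mode = if (!is.null(delta)) delta$mode else NA_character_,
    quartets_used = if (!is.null(delta)) delta$quartets_used else 0L,
    seed = if (!is.null(her)) her$seed else NA_integer_
  ), class = "treeness_report")
}

#' @export
print.treeness_report <- function(x, ...) {
  cat("treeness report\n")
  cat(sprintf("  S = %d, M = %d, G = %d\n", x$S, x$M, x$G))
  cat(sprintf("  CI = %.3f  RI = %.3f\n", x$CI, x$RI))
  if (!is.na(x$HER)) {
    cat(sprintf("  HER = %.3f  (A = %.1f over %d permutation replicates)\n",
                x$HER, x$A, x$her_replicates))
  }
  if (!is.na(x$delta)) {
    cat(sprintf("  delta-score = %.3f  (%s, %d quartets)\n",
                x$delta, x$delta_mode, x$quartets_used))
  }
  invisible(x)
}
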