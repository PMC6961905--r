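#' Simulation settings for synthetic idea matrices
#'
#' The generator emulates the structure of a coded corpus of historical
#' diagrams: characters evolve vertically on a dated rooted tree from an
#' all-zero root by gains (and rarer losses), a controllable fraction of
#' cells is overwritten by horizontal borrowing from an earlier-dated donor,
#' and cells are masked missing/inapplicable at controllable rates. Default
#' shape follows the study corpus (235 diagrams, 141 characters, 19/141
#' multistate, publication years 1555-2012); analyses and tests pass smaller
#' explicit sizes.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_chars number of characters (>= 1).
#' @param fraction_multistate probability a character has more than two
#'   states.
#' @param max_states maximum states of a multistate character.
#' @param gain_rate per-edge, per-character probability of a gain
#'   (state `s -> s + 1`); chosen so a character changes about once on a
#'   30-taxon tree.
#' @param loss_rate per-edge, per-character probability of a loss
#'   (`s -> 0`); kept well below `gain_rate` (idea evolution is
#'   gain-biased).
#' @param borrowing_rate `h`: per-cell probability that a taxon's state is
#'   overwritten by that of a donor published no later than it.
#' @param missing_fraction probability a cell is masked missing (`?`).
#' @param inapplicable_fraction probability a cell is masked inapplicable
#'   (`-`).
#' @param year_span root and latest-leaf publication years.
#' @param seed integer seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 235, n_chars = 141,
                              fraction_multistate = 19 / 141,
                              max_states = 4,
                              gain_rate = 0.02, loss_rate = 0.005,
                              borrowing_rate = 0,
                              missing_fraction = 0.02,
                              inapplicable_fraction = 0,
                              year_span = c(1555, 2012),
                              seed = 1) {
  stopifnot(n_taxa >= 4, n_chars >= 1, max_states >= 2,
            year_span[1] < year_span[2])
  rates <- c(fraction_multistate, gain_rate, loss_rate, borrowing_rate,
             missing_fraction, inapplicable_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(n_taxa = as.integer(n_taxa), n_chars = as.integer(n_chars),
                 fraction_multistate = fraction_multistate,
                 max_states = as.integer(max_states),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 borrowing_rate = borrowing_rate,
                 missing_fraction = missing_fraction,
                 inapplicable_fraction = inapplicable_fraction,
                 year_span = year_span, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a dated rooted tree
#'
#' Draws a random rooted binary topology with continuous node dates mapped
#' onto the configured year span: the root sits at the span's start, node
#' dates strictly increase along every root-to-leaf path, and the deepest
#' leaf reaches the span's end, so leaves (publication dates) are spread
#' through the period. Tip publication years (rounded) are returned as the
#' taxon metadata table.
#'
#' @param config a [simulation_config()].
#' @return object of class `sim_tree`: `tree` (phylo, tips `t1..tn`),
#'   `node_dates` (numeric by node id), `years` (data frame `taxon`,
#'   `year`), `config`.
#' @export
simulate_tree <- function(config = simulation_config()) {
  set.seed(config$seed)
  n <- config$n_taxa
  phy <- ape::rtree(n)
  depths <- ape::node.depth.edgelength(phy)
  y0 <- config$year_span[1]; y1 <- config$year_span[2]
  dates <- y0 + depths / max(depths) * (y1 - y0)
  years <- data.frame(taxon = phy$tip.label,
                      year = as.integer(round(dates[seq_len(n)])))
  structure(list(tree = phy, node_dates = dates, years = years,
                 config = config), class = "sim_tree")
}

#' Simulate a character matrix on a dated tree
#'
#' Vertical pass: every character starts in state 0 at the root; along each
#' edge a gain (`s -> s + 1`, up to the character's state count) occurs with
#' `gain_rate` and otherwise a loss (`s -> 0`) with `loss_rate`. Horizontal
#' pass: with probability `borrowing_rate` per (character, taxon), the cell
#' is overwritten by the current value of a donor taxon published no later
#' than the recipient (recipients processed in date order, so borrowed
#' states can propagate forward in time but never backwards). Finally cells
#' are masked missing/inapplicable. The full event log (true change edges
#' and borrowing events) is returned so tests can check recovery against
#' ground truth.
#'
#' @param sim a [simulate_tree()] result.
#' @param config a [simulation_config()]; defaults to `sim$config`.
#' @return list with `matrix` (a [character_matrix()]), `years`, and
#'   `truth` (list: `tree`, `events` data frame of vertical changes,
#'   `borrowings` data frame, `n_states` per character).
#' @export
simulate_matrix <- function(sim, config = sim$config) {
  set.seed(config$seed + 1L)
  phy <- stats::reorder(sim$tree, "postorder")
  n <- config$n_taxa
  k <- config$n_chars
  nn <- max(phy$edge)
  internals <- unique(phy$edge[, 1])
  rootnode <- internals[length(internals)]
  ## preorder edges (parents before children)
  eord <- rev(seq_len(nrow(phy$edge)))
  nst <- ifelse(stats::runif(k) < config$fraction_multistate,
                sample(3:config$max_states, k, replace = TRUE), 2L)
  states <- matrix(0L, nn, k)
  events <- list()
  for (e in eord) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    s <- states[p, ]
    u <- stats::runif(k)
    gain <- u < config$gain_rate & s < nst - 1L
    loss <- !gain & u >= config$gain_rate &
      u < config$gain_rate + config$loss_rate & s > 0L
    s2 <- s
    s2[gain] <- s[gain] + 1L
    s2[loss] <- 0L
    chg <- which(s2 != s)
    if (length(chg)) {
      events[[length(events) + 1L]] <- data.frame(
        character = chg, parent = p, child = ch,
        from = s[chg], to = s2[chg],
        kind = ifelse(s2[chg] > s[chg], "gain", "loss"))
    }
    states[ch, ] <- s2
  }
  X <- states[seq_len(n), , drop = FALSE]
  rownames(X) <- phy$tip.label
  ## horizontal borrowing, recipients in publication order
  borrow <- list()
  if (config$borrowing_rate > 0) {
    tipdates <- sim$node_dates[seq_len(n)]
    ord <- order(tipdates)
    for (pos in seq_along(ord)) {
      i <- ord[pos]
      donors <- which(tipdates <= tipdates[i])
      donors <- setdiff(donors, i)
      if (!length(donors)) next
      hit <- which(stats::runif(k) < config$borrowing_rate)
      for (j in hit) {
        don <- if (length(donors) == 1L) donors else sample(donors, 1L)
        if (X[i, j] != X[don, j]) {
          borrow[[length(borrow) + 1L]] <- data.frame(
            character = j, donor = phy$tip.label[don],
            recipient = phy$tip.label[i],
            from = X[i, j], to = X[don, j])
          X[i, j] <- X[don, j]
        }
      }
    }
  }
  inap <- matrix(FALSE, n, k)
  mask <- matrix(stats::runif(n * k), n, k)
  X[mask < config$missing_fraction] <- NA_integer_
  both <- config$missing_fraction + config$inapplicable_fraction
  iw <- mask >= config$missing_fraction & mask < both
  X[iw] <- NA_integer_
  inap[iw] <- TRUE
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(character = integer(0), parent = integer(0),
               child = integer(0), from = integer(0), to = integer(0),
               kind = character(0))
  bw <- if (length(borrow)) do.call(rbind, borrow) else
    data.frame(character = integer(0), donor = character(0),
               recipient = character(0), from = integer(0), to = integer(0))
  list(matrix = character_matrix(X, taxa = phy$tip.label,
                                 inapplicable = inap),
       years = sim$years,
       truth = list(tree = phy, events = ev, borrowings = bw,
                    n_states = nst))
}

#' Attach a hypothetical-ancestor tip to a rooted tree
#'
#' Adds a leaf as sister to the whole tree, i.e. on the root edge — the tree
#' counterpart of [add_hypothetical_ancestor()] on the matrix.
#'
#' @param tree a rooted [ape::phylo].
#' @param label the new tip's label.
#' @return an [ape::phylo] with one more tip.
#' @export
add_ancestor_tip <- function(tree, label = "ANC") {
  if (label %in% tree$tip.label) stop("tip already present: ", label)
  nw <- sub(";\\s*$", "", ape::write.tree(ape::ladderize(tree)))
  nw <- gsub(":[0-9.eE+-]+", "", nw)
  ape::read.tree(text = paste0("(", nw, ",", label, ");"))
}

#' Borrowing-rate calibration of treeness statistics
#'
#' Runs the full simulate-search-score pipeline over a grid of horizontal
#' borrowing rates `h`, recording the retention index and delta-score per
#' replicate. High RI indicates predominantly vertical transmission; as `h`
#' grows the retention index should fall and the delta-score rise, which the
#' returned one-sided Kendall trend tests quantify.
#'
#' @param h_values borrowing rates to simulate.
#' @param n_reps replicates per rate.
#' @param config base [simulation_config()] (its `borrowing_rate`/`seed` are
#'   overridden per cell).
#' @param search a [search_config()] for each replicate's tree search.
#' @param seed master seed.
#' @return list with `table` (per-replicate `h`, `rep`, `S`, `M`, `G`,
#'   `RI`, `delta`), `summary` (means by `h`), and `trend` (Kendall tests:
#'   RI decreasing, delta increasing in `h`).
#' @export
ri_vs_borrowing <- function(h_values = c(0, 0.2, 0.5), n_reps = 10,
                            config = simulation_config(n_taxa = 16,
                                                       n_chars = 40),
                            search = search_config(n_replicates = 2,
                                                   swap = "SPR",
                                                   max_trees = 1),
                            seed = 1) {
  rows <- list()
  for (hi in seq_along(h_values)) {
    for (r in seq_len(n_reps)) {
      cfg <- config
      cfg$borrowing_rate <- h_values[hi]
      cfg$seed <- seed + 1009L * hi + 31L * r
      sim <- simulate_tree(cfg)
      dat <- simulate_matrix(sim, cfg)
      cm <- add_hypothetical_ancestor(dat$matrix)
      scfg <- search
      scfg$seed <- cfg$seed + 5L
      best <- heuristic_search(cm, scfg)
      M <- min_steps(cm); G <- max_steps_star(cm)
      ri <- retention_index(G, best$length, M)
      d <- hamming_distance_matrix(recode_binary(dat$matrix))
      dl <- delta_score(d, mode = "exact")$delta
      rows[[length(rows) + 1L]] <- data.frame(
        h = h_values[hi], rep = r, S = best$length, M = M, G = G,
        RI = ri, delta = dl, seed = cfg$seed)
    }
  }
  tab <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(RI, delta) ~ h, data = tab, FUN = mean)
  trend <- list(
    ri_decreasing = stats::cor.test(tab$h, tab$RI, method = "kendall",
                                    alternative = "less", exact = FALSE),
    delta_increasing = stats::cor.test(tab$h, tab$delta, method = "kendall",
                                       alternative = "greater", exact = FALSE)
  )
  list(table = tab, summary = summary, trend = trend)
}
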