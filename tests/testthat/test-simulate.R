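test_that("simulated trees are dated, reproducible and span the year range", {
  cfg <- simulation_config(n_taxa = 10, n_chars = 5, seed = 12)
  s1 <- simulate_tree(cfg)
  s2 <- simulate_tree(cfg)
  expect_equal(topo_key(s1$tree), topo_key(s2$tree))
  expect_equal(s1$node_dates, s2$node_dates)
  ## dates strictly increase along every root-to-leaf path
  tr <- stats::reorder(s1$tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    expect_true(s1$node_dates[tr$edge[k, 2]] > s1$node_dates[tr$edge[k, 1]])
  }
  expect_true(all(s1$years$year >= cfg$year_span[1]))
  expect_true(all(s1$years$year <= cfg$year_span[2]))
  ## mean leaf date sits inside the span across seeds
  means <- vapply(1:40, function(s) {
    st <- simulate_tree(simulation_config(n_taxa = 8, n_chars = 2, seed = s))
    mean(st$years$year)
  }, 0)
  expect_true(all(means > simulation_config()$year_span[1]))
  expect_true(all(means < simulation_config()$year_span[2]))
})

test_that("vertical-only evolution with one gain yields a clade indicator", {
  cfg <- simulation_config(n_taxa = 12, n_chars = 40, fraction_multistate = 0,
                           gain_rate = 0.03, loss_rate = 0,
                           missing_fraction = 0, seed = 21)
  sim <- simulate_tree(cfg)
  dat <- simulate_matrix(sim)
  ev <- dat$truth$events
  singles <- as.integer(names(which(table(ev$character) == 1L)))
  expect_true(length(singles) > 0)
  for (j in singles) {
    child <- ev$child[ev$character == j]
    clade <- dat$truth$tree$tip.label[tips_below_for_test(dat$truth$tree, child)]
    want <- as.integer(dat$matrix$taxa %in% clade)
    expect_equal(unname(dat$matrix$states[, j]), want)
  }
})

test_that("borrowing only flows forward in time and is fully logged", {
  cfg <- simulation_config(n_taxa = 15, n_chars = 30, gain_rate = 0.05,
                           borrowing_rate = 0.3, missing_fraction = 0,
                           seed = 31)
  sim <- simulate_tree(cfg)
  dat <- simulate_matrix(sim)
  bw <- dat$truth$borrowings
  expect_true(nrow(bw) > 0)
  ymap <- stats::setNames(sim$years$year, sim$years$taxon)
  expect_true(all(ymap[bw$donor] <= ymap[bw$recipient]))
})

test_that("masking cells changes the matrix but not the underlying history", {
  base <- simulation_config(n_taxa = 10, n_chars = 20, gain_rate = 0.05,
                            missing_fraction = 0, seed = 41)
  masked <- base; masked$missing_fraction <- 0.15
  d0 <- simulate_matrix(simulate_tree(base), base)
  d1 <- simulate_matrix(simulate_tree(masked), masked)
  expect_equal(d0$truth$events, d1$truth$events)
  expect_equal(topo_key(d0$truth$tree), topo_key(d1$truth$tree))
  expect_true(sum(is.na(d1$matrix$states)) > 0)
  ## unmasked cells agree
  keep <- !is.na(d1$matrix$states)
  expect_equal(d0$matrix$states[keep], d1$matrix$states[keep])
})

test_that("under clean vertical transmission the recovered tree retains most synapomorphy", {
  ris <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_taxa = 12, n_chars = 60,
                             fraction_multistate = 0, gain_rate = 0.01,
                             loss_rate = 0, missing_fraction = 0,
                             seed = 200 + s)
    dat <- simulate_matrix(simulate_tree(cfg))
    cm <- add_hypothetical_ancestor(dat$matrix)
    best <- heuristic_search(cm, search_config(2, "SPR", 1, seed = s))
    retention_index(max_steps_star(cm), best$length, min_steps(cm))
  }, 0)
  expect_gte(mean(ris), 0.9)
  expect_true(all(ris > 0.6))
})

test_that("heavy borrowing lowers the retention index (rank comparison)", {
  ri_at <- function(h, s) {
    cfg <- simulation_config(n_taxa = 12, n_chars = 30, gain_rate = 0.06,
                             borrowing_rate = h, seed = 500 + s)
    dat <- simulate_matrix(simulate_tree(cfg))
    cm <- add_hypothetical_ancestor(dat$matrix)
    best <- heuristic_search(cm, search_config(2, "SPR", 1, seed = s))
    retention_index(max_steps_star(cm), best$length, min_steps(cm))
  }
  ri0 <- vapply(1:8, function(s) ri_at(0, s), 0)
  ri5 <- vapply(1:8, function(s) ri_at(0.5, s), 0)
  wt <- stats::wilcox.test(ri5, ri0, alternative = "less", exact = FALSE)
  expect_lt(wt$p.value, 0.05)
})
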