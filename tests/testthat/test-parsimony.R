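test_that("Fitch length matches hand-computable cases", {
  tr <- parse_newick("((A,B),(C,D));")
  cm1 <- character_matrix(rbind(A = 0L, B = 0L, C = 1L, D = 1L))
  expect_equal(fitch_length(tr, cm1), 1L)
  cm2 <- character_matrix(rbind(A = 0L, B = 1L, C = 0L, D = 1L))
  expect_equal(fitch_length(tr, cm2), 2L)
  ## a character with data on a single leaf costs nothing
  cm3 <- character_matrix(rbind(A = 1L, B = NA, C = NA, D = NA))
  expect_equal(fitch_length(tr, cm3), 0L)
  expect_error(fitch_length(parse_newick("((A,B),(C,X));"), cm1),
               "without matrix rows")
})

test_that("Fitch length is invariant to rooting and leaf order and matches phangorn", {
  set.seed(13)
  for (rep in 1:6) {
    cm <- random_cm(8, 12, n_states = 3, miss = 0.1, seed = 30 + rep)
    tr <- ape::rtree(8)
    tr$tip.label <- sample(cm$taxa)
    len <- fitch_length(tr, cm)
    expect_equal(fitch_length(ape::unroot(tr), cm), len)
    rr <- ape::root(tr, outgroup = cm$taxa[1], resolve.root = TRUE)
    expect_equal(fitch_length(rr, cm), len)
    ## independent implementation agrees
    expect_equal(len, as.integer(phangorn::parsimony(tr, cm_to_phyDat(cm))))
    ## per-character steps sum to the total
    expect_equal(sum(fitch_length(tr, cm, per_character = TRUE)), len)
  }
})

test_that("star trees and polytomies are scored as hard polytomies", {
  cm <- character_matrix(rbind(A = 0L, B = 0L, C = 1L, D = 1L, E = 1L))
  star <- parse_newick("(A,B,C,D,E);")
  expect_equal(fitch_length(star, cm), max_steps_star(cm))
})

test_that("random addition is deterministic and exact on compatible data", {
  ## 3 taxa: the only topology
  cm3 <- random_cm(3, 4, seed = 2)
  t3 <- random_addition_tree(cm3, seed = 5)
  expect_equal(sort(t3$tip.label), cm3$taxa)
  ## fixed seed reproduces the same tree
  cm <- random_cm(9, 12, miss = 0.05, seed = 6)
  expect_equal(topo_key(random_addition_tree(cm, seed = 11)),
               topo_key(random_addition_tree(cm, seed = 11)))
  ## homoplasy-free matrix: greedy addition attains M (checked for n <= 7
  ## against the exhaustive optimum too)
  set.seed(40)
  for (rep in 1:4) {
    n <- sample(5:7, 1)
    base <- ape::rtree(n); base$tip.label <- paste0("t", 1:n)
    sets <- bipartitions(base)
    st <- vapply(sets, function(side)
      as.integer(paste0("t", 1:n) %in% side), integer(n))
    if (!is.matrix(st)) st <- matrix(st, ncol = 1)
    rownames(st) <- paste0("t", 1:n)
    cmc <- character_matrix(st)
    tr <- random_addition_tree(cmc, seed = rep)
    expect_equal(fitch_length(tr, cmc), min_steps(cmc))
    expect_equal(exhaustive_min(cmc), min_steps(cmc))
  }
})

test_that("branch swapping keeps an optimal start and respects NNI < SPR < TBR", {
  base <- parse_newick("((t1,t2),((t3,t4),(t5,t6)));")
  sets <- bipartitions(base)
  st <- vapply(sets, function(side)
    as.integer(paste0("t", 1:6) %in% side), integer(6))
  rownames(st) <- paste0("t", 1:6)
  cmc <- character_matrix(st)
  res <- branch_swap_search(base, cmc, search_config(1, "SPR", 10, seed = 3))
  expect_equal(res$length, min_steps(cmc))
  expect_true(topo_key(base) %in% vapply(res$trees, topo_key, ""))
  ## same start and seed: a larger neighbourhood can only do at least as well
  cm <- random_cm(8, 10, seed = 17)
  start <- random_addition_tree(cm, seed = 1)
  lens <- vapply(c("NNI", "SPR", "TBR"), function(sw)
    branch_swap_search(start, cm, search_config(1, sw, 5, seed = 2))$length,
    0L)
  expect_true(lens["NNI"] >= lens["SPR"])
  expect_true(lens["SPR"] >= lens["TBR"])
})

test_that("TBR swapping from arbitrary starts reaches the exhaustive optimum", {
  set.seed(50)
  for (rep in 1:5) {
    cm <- random_cm(6, 8, n_states = 3, seed = 60 + rep)
    exact <- exhaustive_min(cm)
    start <- random_addition_tree(cm, order = sample(cm$taxa), seed = rep)
    res <- branch_swap_search(start, cm, search_config(1, "TBR", 20, seed = rep))
    expect_equal(res$length, exact)
  }
})

test_that("heuristic search is reproducible and bounded below by M", {
  cm <- random_cm(10, 15, miss = 0.05, seed = 23)
  r1 <- heuristic_search(cm, search_config(3, "SPR", 20, seed = 7))
  r2 <- heuristic_search(cm, search_config(3, "SPR", 20, seed = 7))
  expect_equal(r1$length, r2$length)
  expect_equal(vapply(r1$trees, topo_key, ""), vapply(r2$trees, topo_key, ""))
  expect_true(r1$length >= min_steps(cm))
  ## ensemble members share the reported length and are distinct
  lens <- vapply(r1$trees, fitch_length, 0L, cm = cm)
  expect_true(all(lens == r1$length))
  expect_equal(anyDuplicated(vapply(r1$trees, topo_key, "")), 0L)
})

test_that("adding the all-zero ancestor never decreases the optimal length", {
  set.seed(71)
  for (rep in 1:4) {
    cm <- random_cm(6, 8, n_states = 3, miss = 0.1, seed = 80 + rep)
    with_anc <- add_hypothetical_ancestor(cm)
    expect_gte(exhaustive_min(with_anc), exhaustive_min(cm))
  }
})
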