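test_that("M and G follow their closed forms and the star-tree oracle", {
  cm <- character_matrix(rbind(A = c(0L, 0L, 0L), B = c(1L, 0L, 1L),
                               C = c(2L, 1L, 1L), D = c(0L, 1L, 1L)))
  expect_equal(min_steps(cm), 4L)        # (3-1) + (2-1) + (2-1)
  expect_equal(max_steps_star(cm), 5L)   # 2 + 2 + 1
  one_bin <- character_matrix(rbind(A = 0L, B = 0L, C = 1L, D = 1L, E = 1L))
  expect_equal(min_steps(one_bin), 1L)
  expect_equal(max_steps_star(one_bin), 2L)
  const <- character_matrix(rbind(A = 0L, B = 0L, C = 0L))
  expect_equal(min_steps(const), 0L)
  expect_equal(max_steps_star(const), 0L)
  ## G equals the Fitch length of an explicit star tree
  set.seed(31)
  for (rep in 1:5) {
    cmr <- random_cm(7, 10, n_states = 3, miss = 0.1, seed = 140 + rep)
    star <- parse_newick(paste0("(", paste(cmr$taxa, collapse = ","), ");"))
    expect_equal(max_steps_star(cmr), fitch_length(star, cmr))
  }
})

test_that("CI and RI hit their analytic endpoints and flag undefined cases", {
  expect_equal(consistency_index(10, 10), 1)
  expect_equal(retention_index(G = 25, S = 10, M = 10), 1)  # S = M
  expect_equal(retention_index(G = 25, S = 25, M = 10), 0)  # S = G
  expect_warning(ci0 <- consistency_index(0, 0), "undefined")
  expect_true(is.na(ci0))
  expect_warning(ri0 <- retention_index(G = 5, S = 5, M = 5), "undefined")
  expect_true(is.na(ri0))
  expect_error(consistency_index(5, 4), "impossible")
})

test_that("M <= S <= G holds on searched random matrices", {
  set.seed(33)
  for (rep in 1:6) {
    cm <- random_cm(8, 12, n_states = 3, miss = 0.1, seed = 150 + rep)
    S <- heuristic_search(cm, search_config(2, "SPR", 1, seed = rep))$length
    expect_true(min_steps(cm) <= S)
    expect_true(S <= max_steps_star(cm))
  }
})

test_that("HER is near zero for structureless noise and flags degeneracy", {
  cm <- random_cm(10, 25, seed = 44)      # pure noise: permutation-like
  S <- heuristic_search(cm, search_config(2, "SPR", 1, seed = 1))$length
  her <- homoplasy_excess_ratio(cm, S, n_reps = 8, seed = 2)
  expect_equal(length(her$lengths), 8L)
  expect_lt(abs(her$her), 0.2)
  expect_error(homoplasy_excess_ratio(cm, S, n_reps = 1), "at least 2")
  ## HER is reproducible under a fixed seed
  her2 <- homoplasy_excess_ratio(cm, S, n_reps = 8, seed = 2)
  expect_equal(her$lengths, her2$lengths)
})

test_that("mismatch distances use pairwise deletion and flag empty overlap", {
  cm <- character_matrix(rbind(A = c(0L, 1L, NA), B = c(0L, 0L, NA)))
  d <- hamming_distance_matrix(cm)
  expect_equal(d["A", "B"], 0.5)
  ident <- character_matrix(rbind(A = c(0L, 1L), B = c(0L, 1L)))
  expect_equal(hamming_distance_matrix(ident)["A", "B"], 0)
  comp <- character_matrix(rbind(A = c(0L, 1L, 0L), B = c(1L, 0L, 1L)))
  expect_equal(hamming_distance_matrix(comp)["A", "B"], 1)
  disj <- character_matrix(rbind(A = c(0L, NA), B = c(NA, 1L)))
  dd <- hamming_distance_matrix(disj)
  expect_true(is.na(dd["A", "B"]))
  expect_equal(attr(dd, "no_overlap"), "A / B")
})

test_that("delta-score is 0 on additive distances and 1 on the box metric", {
  set.seed(5)
  tr <- ape::rtree(9)
  expect_equal(delta_score(ape::cophenetic.phylo(tr))$delta, 0)
  box <- matrix(c(0, 1, 1, 2, 1, 0, 2, 1, 1, 2, 0, 1, 2, 1, 1, 0), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  res <- delta_score(box)
  expect_equal(res$delta, 1)
  expect_equal(res$quartets_used, 1L)
  expect_error(delta_score(box[1:3, 1:3]), "at least 4")
  ## degenerate quartet (all sums equal) scores 0, not NaN
  flat <- matrix(1, 4, 4); diag(flat) <- 0
  expect_equal(delta_score(flat)$delta, 0)
})

test_that("sampled delta converges to the exact value", {
  cm <- random_cm(15, 40, seed = 55)
  d <- hamming_distance_matrix(cm)
  ex <- delta_score(d, mode = "exact")
  sa <- delta_score(d, mode = "sampled", sample_size = 5e4, seed = 9)
  expect_equal(ex$quartets_used, choose(15, 4))
  expect_lt(abs(ex$delta - sa$delta), 0.01)
  ## chunked evaluation equals one-shot evaluation
  ex2 <- delta_score(d, mode = "exact", chunk = 97)
  expect_equal(ex$delta, ex2$delta)
})

test_that("treeness reports assemble all statistics coherently", {
  cm <- random_cm(8, 15, seed = 66)
  cma <- add_hypothetical_ancestor(cm)
  best <- heuristic_search(cma, search_config(2, "SPR", 5, seed = 3))
  her <- homoplasy_excess_ratio(cma, best$length, n_reps = 5, seed = 4)
  delta <- delta_score(hamming_distance_matrix(recode_binary(cm)))
  rep <- treeness_report(cma, best$length, her = her, delta = delta)
  expect_true(rep$M <= rep$S && rep$S <= rep$G)
  expect_equal(rep$CI, rep$M / rep$S)
  expect_equal(rep$RI, (rep$G - rep$S) / (rep$G - rep$M))
  expect_equal(rep$HER, (rep$A - rep$S) / (rep$A - rep$M))
  expect_equal(rep$delta, delta$delta)
  expect_output(print(rep), "treeness report")
})
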