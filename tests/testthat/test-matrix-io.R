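test_that("a minimal NEXUS DATA block parses with missing cells", {
  f <- write_nexus_text(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=2 NCHAR=2;",
    "  FORMAT SYMBOLS=\"01\" MISSING=? GAP=-;",
    "  MATRIX",
    "    taxA 01",
    "    taxB 0?",
    "  ;",
    "END;"
  ))
  cm <- read_nexus(f)
  expect_equal(dim(cm), c(2L, 2L))
  expect_equal(cm$taxa, c("taxA", "taxB"))
  expect_equal(cm$states[1, ], c(0L, 1L))
  expect_true(is.na(cm$states[2, 2]))
  expect_false(cm$inapplicable[2, 2])
})

test_that("CHARACTERS blocks, interleaving, custom symbols and gap cells parse", {
  f <- write_nexus_text(c(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "  DIMENSIONS NTAX=3 NCHAR=4;",
    "  FORMAT SYMBOLS=\"abc\" MISSING=* GAP=~ INTERLEAVE;",
    "  MATRIX",
    "    t1 ab",
    "    t2 ba",
    "    t3 a*",
    "",
    "    t1 ca",
    "    t2 ~b",
    "    t3 aa",
    "  ;",
    "END;"
  ))
  cm <- read_nexus(f)
  expect_equal(dim(cm), c(3L, 4L))
  expect_equal(cm$states[1, ], c(0L, 1L, 2L, 0L))   # a,b,c -> 0,1,2
  expect_true(is.na(cm$states[2, 3]) && cm$inapplicable[2, 3])
  expect_true(is.na(cm$states[3, 2]) && !cm$inapplicable[3, 2])
})

test_that("malformed NEXUS input raises informative parse errors", {
  dup <- write_nexus_text(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;", "MATRIX",
    "t1 01", "t1 10", ";", "END;"))
  expect_error(read_nexus(dup), "duplicate taxon")
  short <- write_nexus_text(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=3;", "MATRIX",
    "t1 01", "t2 010", ";", "END;"))
  expect_error(read_nexus(short), "expected NCHAR")
  bad <- write_nexus_text(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;", "MATRIX",
    "t1 0x", "t2 01", ";", "END;"))
  expect_error(read_nexus(bad), "unknown state symbol")
  expect_error(read_nexus(write_nexus_text("not nexus")), "NEXUS")
})

test_that("write_nexus / read_nexus round-trips states and special cells", {
  set.seed(3)
  st <- matrix(sample(0:3, 8 * 12, replace = TRUE), 8, 12)
  st[sample(length(st), 10)] <- NA
  rownames(st) <- paste0("tree", 1:8)
  inap <- matrix(FALSE, 8, 12)
  inap[is.na(st)][1:4] <- TRUE
  inap[!is.na(st)] <- FALSE
  cm <- character_matrix(st, inapplicable = inap)
  f <- tempfile(fileext = ".nex")
  write_nexus(cm, f)
  cm2 <- read_nexus(f)
  expect_equal(cm2$taxa, cm$taxa)
  expect_equal(cm2$states, cm$states, ignore_attr = TRUE)
  expect_equal(cm2$inapplicable, cm$inapplicable, ignore_attr = TRUE)
  ## independent reader agrees on the cells
  nd <- ape::read.nexus.data(f)
  expect_equal(names(nd), cm$taxa)
  row1 <- vapply(nd[[1]], as.character, "")
  want1 <- ifelse(is.na(cm$states[1, ]), ifelse(cm$inapplicable[1, ], "-", "?"),
                  cm$symbols[cm$states[1, ] + 1L])
  expect_equal(unname(row1), unname(want1))
})

test_that("tab-delimited export preserves ? and -", {
  st <- rbind(A = c(0L, NA), B = c(1L, NA))
  inap <- rbind(c(FALSE, FALSE), c(FALSE, TRUE))
  cm <- character_matrix(st, inapplicable = inap)
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(cm, f)
  expect_equal(readLines(f), c("A\t0?", "B\t1-"))
})

test_that("year tables parse, validate and report missing taxa", {
  cm <- random_cm(3, 2, seed = 1)
  f <- tempfile(fileext = ".csv")
  writeLines(c("taxon,year", "t1,1859", "t3,1966"), f)
  yt <- read_year_table(f, cm)
  expect_equal(yt$year[yt$taxon == "t1"], 1859L)
  expect_equal(attr(yt, "missing_taxa"), "t2")
  writeLines("taxon,year", f)
  empty <- read_year_table(f, cm)
  expect_equal(nrow(empty), 0L)
  expect_setequal(attr(empty, "missing_taxa"), cm$taxa)
  writeLines(c("taxon,year", "t1,1850", "t1,1860"), f)
  expect_error(read_year_table(f, cm), "duplicate")
  writeLines(c("taxon,year", "nope,1900"), f)
  expect_error(read_year_table(f, cm), "not in matrix")
  writeLines(c("taxon,year", "t1,18.5"), f)
  expect_error(read_year_table(f, cm), "non-integer")
  writeLines(c("taxon,year", "t1,1200"), f)
  expect_error(read_year_table(f, cm), "1400")
})

test_that("one-hot recoding expands multistate characters and only them", {
  st <- cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 0L, NA))
  rownames(st) <- paste0("t", 1:4)
  cm <- character_matrix(st)
  rb <- recode_binary(cm)
  expect_equal(rb$n_chars, 4L)          # 3 indicators + 1 pass-through
  expect_equal(rb$states[, 1], c(1L, 0L, 0L, 1L), ignore_attr = TRUE)
  expect_equal(rb$states[, 2], c(0L, 1L, 0L, 0L), ignore_attr = TRUE)
  expect_equal(rb$states[, 3], c(0L, 0L, 1L, 0L), ignore_attr = TRUE)
  expect_true(is.na(rb$states[4, 4]))
  map <- attr(rb, "recode_map")
  expect_equal(map$orig_char, c(1L, 1L, 1L, 2L))
  ## all-binary input passes through unchanged
  cmb <- random_cm(5, 6, seed = 2)
  expect_equal(recode_binary(cmb)$states, cmb$states, ignore_attr = TRUE)
})

test_that("recoding preserves pairwise equality of the original states", {
  cm <- random_cm(8, 6, n_states = 4, miss = 0.1, seed = 9)
  rb <- recode_binary(cm)
  map <- attr(rb, "recode_map")
  for (j in seq_len(cm$n_chars)) {
    cols <- map$new_char[map$orig_char == j]
    for (a in 1:7) for (b in (a + 1):8) {
      va <- cm$states[a, j]; vb <- cm$states[b, j]
      if (is.na(va) || is.na(vb)) next
      same_orig <- unname(va == vb)
      same_ind <- all(rb$states[a, cols] == rb$states[b, cols])
      expect_equal(same_ind, same_orig)
    }
  }
})

test_that("the hypothetical ancestor adds one all-zero untouched row", {
  cm <- random_cm(3, 5, n_states = 3, miss = 0.1, seed = 4)
  out <- add_hypothetical_ancestor(cm, "ANC")
  expect_equal(dim(out), c(4L, 5L))
  expect_equal(unname(out$states[4, ]), rep(0L, 5))
  expect_equal(out$states[1:3, ], cm$states, ignore_attr = TRUE)
  expect_error(add_hypothetical_ancestor(out, "ANC"), "already present")
  empty <- character_matrix(matrix(integer(0), 2, 0), taxa = c("a", "b"))
  expect_error(add_hypothetical_ancestor(empty), "no characters")
})

test_that("parsimony-informative characters follow the two-by-two rule", {
  st <- cbind(c(0L, 0L, 1L, 1L),    # informative
              c(0L, 0L, 0L, 1L),    # autapomorphy
              c(0L, 1L, 2L, NA),    # all singletons
              c(0L, 0L, 0L, 0L))    # constant
  rownames(st) <- paste0("t", 1:4)
  info <- informative_characters(character_matrix(st))
  expect_equal(info$informative, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(info$n_informative, 1L)
})

test_that("uninformative singleton characters never favour a topology", {
  ## brute force: character 0,1,2,? adds the same length to every tree
  st <- cbind(c(0L, 1L, 2L, NA, 0L))
  rownames(st) <- paste0("t", 1:5)
  cm <- character_matrix(st)
  lens <- vapply(enumerate_trees(cm$taxa), fitch_length, 0L, cm = cm)
  expect_equal(length(unique(lens)), 1L)
})
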