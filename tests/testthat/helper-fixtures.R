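## Shared fixtures: everything is generated in code at test time.

## random multistate matrix with optional missing cells
random_cm <- function(n, k, n_states = 2, miss = 0, seed = 1) {
  set.seed(seed)
  st <- matrix(sample(0:(n_states - 1), n * k, replace = TRUE), n, k)
  if (miss > 0) st[sample(length(st), round(miss * length(st)))] <- NA
  rownames(st) <- paste0("t", seq_len(n))
  character_matrix(st)
}

## exact minimum length by exhaustive enumeration, scored independently by
## phangorn's Fitch implementation
exhaustive_min <- function(cm) {
  min(phangorn::parsimony(enumerate_trees(cm$taxa), cm_to_phyDat(cm)))
}

## canonical unrooted-topology fingerprint of a phylo tree
topo_key <- function(tree) paste(names(bipartitions(tree)), collapse = ";")

## a small NEXUS text written to a temp file
write_nexus_text <- function(lines) {
  f <- tempfile(fileext = ".nex")
  writeLines(lines, f)
  f
}

## tip indices below a node of a phylo tree
tips_below_for_test <- function(tree, node) {
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  below <- vector("list", max(tree$edge))
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  below[[node]]
}
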