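#!/usr/bin/env Rscript
## Parsimony search on the simulated corpus: root with the all-zero
## hypothetical ancestor, run seeded random-addition + SPR swapping, and keep
## the strict consensus of the equally shortest trees.

library(ideotree)

cm0 <- read_nexus("results/sim/matrix.nex")
cm <- add_hypothetical_ancestor(cm0)
best <- heuristic_search(cm, search_config(n_replicates = 5, swap = "SPR",
                                           max_trees = 50, seed = 7))
cons <- strict_consensus(best)

writeLines(vapply(best$trees, write_newick, ""), "results/trees.nwk")
writeLines(write_newick(cons), "results/consensus.nwk")
write.csv(data.frame(length = best$length, n_trees = length(best$trees),
                     cap_hit = best$cap_hit),
          "results/search_summary.csv", row.names = FALSE)

cat(sprintf("search found %d tree(s) of length %d; consensus keeps %d clades\n",
            length(best$trees), best$length, length(bipartitions(cons))))
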