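#!/usr/bin/env Rscript
## Treeness of the simulated corpus: CI and RI from the search, HER from a
## 20-replicate permutation null, and the exact quartet delta-score on the
## one-hot recoded matrix.

library(ideotree)

cm0 <- read_nexus("results/sim/matrix.nex")
cm <- add_hypothetical_ancestor(cm0)
S <- as.integer(read.csv("results/search_summary.csv")$length)

her <- homoplasy_excess_ratio(cm, S, n_reps = 20, seed = 15)
delta <- delta_score(hamming_distance_matrix(recode_binary(cm0)),
                     mode = "exact")
report <- treeness_report(cm, S, her = her, delta = delta)
print(report)

jsonlite::write_json(unclass(report), "results/treeness.json",
                     auto_unbox = TRUE, digits = NA)
cat("written to results/treeness.json\n")
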